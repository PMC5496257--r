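## Small shared helpers (no exported surface except noted).

`%||%` <- function(a, b) if (is.null(a)) b else a

## Karlin-Altschul expected number of chance local alignments with raw
## score >= S for a search space of m x n letters.
ka_evalue <- function(score, m, n, lambda, K) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

ka_bitscore <- function(score, lambda, K) {
  (lambda * score - log(K)) / log(2)
}

## Exact k-mer set of a sequence, used to pre-screen alignment pairs the
## way a word-seeded search does: pairs sharing no exact k-mer are skipped.
kmer_set <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  unique(substring(seq, seq_len(n - k + 1L), k:n))
}

## Seeding rule of the word-seeded searches: a pair is aligned only when
## at least `min_hits` distinct query words occur in the subject (capped
## at the number of words a short query has at all).
shares_kmer <- function(query_kmers, subject_kmers, min_hits = 1L) {
  need <- min(min_hits, length(query_kmers))
  need > 0L && sum(query_kmers %in% subject_kmers) >= need
}

revcomp <- function(seq) {
  vapply(seq, function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

## Accept a FASTA path, an XStringSet or a named character vector and
## return a named character vector of sequences.
as_seq_vector <- function(x, type = c("DNA", "AA")) {
  type <- match.arg(type)
  if (is.character(x) && length(x) == 1L && is.null(names(x)) &&
      file.exists(x)) {
    x <- if (type == "DNA") Biostrings::readDNAStringSet(x)
         else Biostrings::readAAStringSet(x)
  }
  if (methods::is(x, "XStringSet")) {
    out <- as.character(x)
    names(out) <- sub("\\s.*$", "", names(x))
    return(out)
  }
  if (is.character(x)) {
    if (is.null(names(x)) && length(x) > 0L)
      names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  stop("cannot interpret sequence input of class ", class(x)[1])
}

## Nucleotide scoring matrix over A/C/G/T/N; N never matches anything.
nuc_matrix <- function(match, mismatch) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

is_empty_records <- function(records) {
  is.null(records) || nrow(records) == 0L
}
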