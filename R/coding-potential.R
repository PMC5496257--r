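## Codon table shared by the ORF scanner and the simulator.
codon_table <- function() Biostrings::GENETIC_CODE

#' Find ATG-initiated open reading frames
#'
#' Scans the three reading frames of the sense strand (and, by default,
#' of the reverse complement) for maximal ATG-initiated ORFs: within each
#' frame, an ORF runs from the first ATG after the previous terminator to
#' the next stop codon. ORFs reaching the end of the sequence without a
#' stop are reported with `partial = TRUE`. Codons containing an
#' ambiguous base (N) do not translate and terminate any open ORF
#' (also `partial = TRUE`). Only ORFs of at least `min_aa` amino acids
#' (stop codon excluded) are returned.
#'
#' @param seq a nucleotide string over A/C/G/T/N.
#' @param min_aa minimum peptide length in amino acids (default 100).
#' @param both_strands scan the antisense frames too (default `TRUE`).
#' @return data.frame with columns `strand` (`sense`/`antisense`),
#'   `frame` (0-2 on the scanned strand), `start`, `end` (1-based closed
#'   coordinates on the sense-oriented transcript; the stop codon is
#'   included when present), `peptide`, `length_aa`, `partial`; sorted by
#'   decreasing `length_aa`.
#' @export
find_orfs <- function(seq, min_aa = 100, both_strands = TRUE) {
  seq <- toupper(seq)
  out <- scan_strand_orfs(seq, min_aa, "sense", nchar(seq))
  if (both_strands) {
    rc <- revcomp(seq)
    out <- rbind(out, scan_strand_orfs(rc, min_aa, "antisense", nchar(seq)))
  }
  out <- out[order(-out$length_aa, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## One strand's three frames; coordinates mapped back to the sense
## orientation for antisense scans.
scan_strand_orfs <- function(s, min_aa, strand_label, sense_len) {
  gc <- codon_table()
  n <- nchar(s)
  res <- list()
  for (frame in 0:2) {
    ncod <- (n - frame) %/% 3L
    if (ncod < 1L) next
    starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
    codons <- substring(s, starts, starts + 2L)
    aa <- unname(gc[codons])          # NA for codons containing N etc.
    is_stop <- !is.na(aa) & aa == "*"
    is_break <- is_stop | is.na(aa)
    is_atg <- codons == "ATG"
    i <- 1L
    while (i <= ncod) {
      brk <- which(is_break[i:ncod])
      brk <- if (length(brk)) i + brk[1L] - 1L else ncod + 1L
      m <- which(is_atg[i:ncod])
      m <- if (length(m)) i + m[1L] - 1L else ncod + 1L
      if (m < brk) {
        len_aa <- brk - m
        if (len_aa >= min_aa) {
          stopped <- brk <= ncod && is_stop[brk]
          nt_start <- starts[m]
          nt_end <- if (stopped) starts[brk] + 2L
                    else starts[brk - 1L] + 2L
          if (strand_label == "antisense") {
            tmp <- sense_len - nt_end + 1L
            nt_end <- sense_len - nt_start + 1L
            nt_start <- tmp
          }
          res[[length(res) + 1L]] <- data.frame(
            strand = strand_label, frame = frame,
            start = nt_start, end = nt_end,
            peptide = paste(aa[m:(brk - 1L)], collapse = ""),
            length_aa = len_aa, partial = !stopped,
            stringsAsFactors = FALSE)
        }
      }
      i <- brk + 1L
    }
  }
  if (!length(res))
    return(data.frame(strand = character(0), frame = integer(0),
                      start = integer(0), end = integer(0),
                      peptide = character(0), length_aa = integer(0),
                      partial = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, res)
}

#' Search a peptide against a protein database
#'
#' Smith-Waterman local alignment (BLOSUM62, affine gaps) against every
#' database entry sharing at least one exact `seed_k`-mer with the query,
#' with Karlin-Altschul e-values
#' `E = K * m * n * exp(-lambda * S)` where `m` is the query length and
#' `n` the total database length. Defaults are the gapped BLOSUM62
#' (open 11 / extend 1) parameters `lambda = 0.267`, `K = 0.041`;
#' effective lengths are the raw lengths (no edge correction).
#'
#' @param peptide amino-acid string (no stops).
#' @param db protein database: FASTA path, `AAStringSet` or named
#'   character vector.
#' @param gap_open,gap_extend affine gap penalties (positive costs).
#' @param lambda,K Karlin-Altschul parameters for the scoring scheme.
#' @param evalue_max only hits with e-value below this are returned
#'   (default 10).
#' @param seed_k word size of the seeding pre-screen (default 4).
#' @param min_seed_hits minimum number of distinct query words that must
#'   occur exactly in a subject before the pair is aligned (default 3).
#' @return data.frame of hits sorted by ascending e-value: `subject_id`,
#'   `score`, `bitscore`, `evalue`, `percent_identity`, `source`.
#' @export
search_protein_db <- function(peptide, db, gap_open = 11, gap_extend = 1,
                              lambda = 0.267, K = 0.041, evalue_max = 10,
                              seed_k = 4, min_seed_hits = 3) {
  if (is.null(peptide) || is.na(peptide) || nchar(peptide) == 0L)
    stop("empty peptide")
  idx <- protein_db_index(db, seed_k)
  subjects <- idx$seqs
  if (length(subjects) == 0L) {
    warning("empty protein database; no hits")
    return(empty_protein_hits())
  }
  qk <- kmer_set(peptide, seed_k)
  cand <- names(subjects)[vapply(idx$kmers, function(sk)
    shares_kmer(qk, sk, min_seed_hits), logical(1))]
  if (!length(cand)) return(empty_protein_hits())
  data_env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = data_env)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(peptide, length(cand))),
    subject = Biostrings::AAStringSet(subjects[cand]),
    type = "local", substitutionMatrix = data_env$BLOSUM62,
    gapOpening = gap_open, gapExtension = gap_extend)
  score <- Biostrings::score(aln)
  n_db <- idx$total_len
  ev <- ka_evalue(score, nchar(peptide), n_db, lambda, K)
  alen <- nchar(as.character(Biostrings::pattern(aln)))
  out <- data.frame(
    subject_id = cand,
    score = score,
    bitscore = ka_bitscore(score, lambda, K),
    evalue = ev,
    percent_identity = 100 * Biostrings::nmatch(aln) / alen,
    source = "protein_db",
    stringsAsFactors = FALSE)
  out <- out[out$evalue < evalue_max, , drop = FALSE]
  out <- out[order(out$evalue, out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Pre-indexed protein database: sequences, per-entry k-mer sets and the
## total residue count, so repeated ORF searches skip re-reading.
protein_db_index <- function(db, seed_k = 4) {
  if (inherits(db, "protein_db_index")) return(db)
  seqs <- if (is.null(db)) character(0) else as_seq_vector(db, "AA")
  structure(list(seqs = seqs,
                 kmers = lapply(seqs, kmer_set, k = seed_k),
                 total_len = sum(nchar(seqs))),
            class = "protein_db_index")
}

empty_protein_hits <- function() {
  data.frame(subject_id = character(0), score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0),
             percent_identity = numeric(0), source = character(0),
             stringsAsFactors = FALSE)
}

#' Convert a Prosite-style pattern to a regular expression
#'
#' Supported elements, separated by `-`: a residue letter, `x` (any),
#' `[ABC]` (alternatives), `{ABC}` (exclusions), each optionally followed
#' by a repeat `(n)` or `(n,m)`; `<` anchors to the N terminus, `>` to
#' the C terminus; an optional trailing `.` is ignored.
#'
#' @param pattern the Prosite-style pattern string.
#' @return a regular expression string.
#' @export
prosite_to_regex <- function(pattern) {
  p <- sub("\\.$", "", trimws(pattern))
  anchor_start <- startsWith(p, "<")
  anchor_end <- endsWith(p, ">")
  p <- sub("^<", "", sub(">$", "", p))
  tokens <- strsplit(p, "-", fixed = TRUE)[[1]]
  if (!length(tokens)) stop("malformed Prosite pattern: '", pattern, "'")
  rx <- vapply(tokens, function(tok) {
    m <- regmatches(tok, regexec(
      "^(x|[A-Z]|\\[[A-Z]+\\]|\\{[A-Z]+\\})(\\(([0-9]+)(,([0-9]+))?\\))?$",
      tok))[[1]]
    if (!length(m)) stop("malformed Prosite pattern: '", pattern,
                         "' (element '", tok, "')")
    core <- m[2]
    base <- if (core == "x") "."
            else if (startsWith(core, "[")) core
            else if (startsWith(core, "{"))
              paste0("[^", substr(core, 2, nchar(core) - 1L), "]")
            else core
    if (m[3] != "") {
      rep <- if (m[6] != "") paste0("{", m[4], ",", m[6], "}")
             else paste0("{", m[4], "}")
      paste0(base, rep)
    } else base
  }, character(1))
  paste0(if (anchor_start) "^" else "", paste(rx, collapse = ""),
         if (anchor_end) "$" else "")
}

#' Match a peptide against a set of protein motifs
#'
#' Deterministic Prosite-style pattern matching standing in for
#' profile-HMM motif search; a match is treated as conclusive protein
#' evidence (e-value 0).
#'
#' @param peptide amino-acid string.
#' @param motifs named character vector of Prosite-style patterns, or a
#'   path to a text file with lines `name<whitespace>pattern`
#'   (`#` comments allowed).
#' @return data.frame with one row per matching motif, same columns as
#'   [search_protein_db()] with `source = "motif"`.
#' @export
match_motifs <- function(peptide, motifs) {
  motifs <- read_motifs(motifs)
  if (!length(motifs)) return(empty_protein_hits())
  hit <- vapply(motifs, function(p)
    grepl(prosite_to_regex(p), peptide), logical(1))
  if (!any(hit)) return(empty_protein_hits())
  data.frame(subject_id = names(motifs)[hit], score = NA_real_,
             bitscore = NA_real_, evalue = 0,
             percent_identity = NA_real_, source = "motif",
             stringsAsFactors = FALSE)
}

read_motifs <- function(motifs) {
  if (is.character(motifs) && length(motifs) == 1L &&
      is.null(names(motifs)) && file.exists(motifs)) {
    lines <- readLines(motifs, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines)) return(character(0))
    parts <- regmatches(lines, regexec("^(\\S+)\\s+(\\S+)$", lines))
    bad <- lengths(parts) == 0L
    if (any(bad))
      stop("malformed motif line: '", lines[bad][1], "'")
    out <- vapply(parts, `[`, character(1), 3L)
    names(out) <- vapply(parts, `[`, character(1), 2L)
    return(out)
  }
  if (is.null(motifs)) return(character(0))
  motifs
}

#' Filter 3: remove transcripts with protein-coding capability
#'
#' A transcript is removed iff it carries at least one ORF of at least
#' `min_aa` amino acids whose peptide has protein-level evidence: a motif
#' match, or a protein-database hit with e-value below `evalue_max`.
#' Transcripts with long ORFs but no evidence are retained, as are
#' transcripts whose ORFs are all shorter than `min_aa`. Transcripts
#' without an attached sequence are skipped (retained) with a message.
#'
#' @param records a [transcript_set()] with sequences attached.
#' @param db protein database (see [search_protein_db()]).
#' @param motifs motif patterns (see [match_motifs()]); `NULL` for none.
#' @param min_aa ORF length floor in amino acids (default 100).
#' @param evalue_max e-value cutoff for database hits (default 1e-3,
#'   strict `<`).
#' @param both_strands scan both strands for ORFs (default `TRUE`).
#' @param external_hits optional precomputed evidence table with columns
#'   `transcript_id`, `subject`, `evalue`, `source`; replaces the
#'   built-in search.
#' @return `list(retained =, removed =, orfs =)` where `orfs` tabulates
#'   the qualifying ORFs and their best evidence per transcript.
#' @export
apply_filter3 <- function(records, db, motifs = NULL, min_aa = 100,
                          evalue_max = 1e-3, both_strands = TRUE,
                          external_hits = NULL) {
  if (is_empty_records(records))
    return(list(retained = records, removed = records,
                orfs = data.frame()))
  no_seq <- records$sequence_missing
  if (any(no_seq))
    message(sum(no_seq), " transcript(s) without sequence skipped by the ",
            "coding-potential filter")
  if (is.null(external_hits)) db <- protein_db_index(db)
  motif_pats <- read_motifs(motifs)
  removed <- logical(nrow(records))
  orf_log <- list()
  for (i in which(!no_seq)) {
    orfs <- find_orfs(records$sequence[i], min_aa = min_aa,
                      both_strands = both_strands)
    if (!nrow(orfs)) next
    if (!is.null(external_hits)) {
      ev <- external_hits[external_hits$transcript_id ==
                            records$transcript_id[i], , drop = FALSE]
      hit <- nrow(ev) > 0L && any(ev$evalue < evalue_max)
      best <- if (hit) min(ev$evalue) else NA_real_
    } else {
      best <- NA_real_
      hit <- FALSE
      for (j in seq_len(nrow(orfs))) {
        mh <- if (length(motif_pats))
          match_motifs(orfs$peptide[j], motif_pats) else empty_protein_hits()
        if (nrow(mh)) { hit <- TRUE; best <- 0; break }
        if (length(db$seqs) == 0L) next
        ph <- search_protein_db(orfs$peptide[j], db,
                                evalue_max = evalue_max)
        if (nrow(ph)) { hit <- TRUE; best <- ph$evalue[1]; break }
      }
    }
    removed[i] <- hit
    orf_log[[length(orf_log) + 1L]] <- data.frame(
      transcript_id = records$transcript_id[i],
      n_long_orfs = nrow(orfs),
      longest_aa = orfs$length_aa[1],
      partial = orfs$partial[1],
      evidence = hit,
      best_evalue = best,
      stringsAsFactors = FALSE)
  }
  list(retained = subset_records(records, !removed),
       removed = subset_records(records, removed),
       orfs = if (length(orf_log)) do.call(rbind, orf_log)
              else data.frame())
}
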