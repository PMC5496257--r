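#' Transcript categories recognised by the pipeline
#'
#' The five input categories of the discovery pipeline plus
#' `protein_coding` (used for reference/comparison transcripts).
#' @export
TRANSCRIPT_CATEGORIES <- c("novel_I", "novel_II", "novel_III",
                           "intergenic", "known_lncRNA", "protein_coding")

#' Construct a transcript set
#'
#' The central container of the package: one row per transcript, with exon
#' structure carried as list columns of 1-based closed genomic intervals
#' (GTF convention) and the spliced sense-strand sequence (when attached).
#'
#' @param transcript_id character vector of unique transcript identifiers.
#' @param chrom chromosome/scaffold name per transcript.
#' @param strand `"+"`, `"-"` or `"*"` (unknown).
#' @param exon_start,exon_end lists of integer vectors, one vector per
#'   transcript; exons must be non-overlapping and are stored sorted.
#' @param gene_id gene identifiers (defaults to `transcript_id`).
#' @param category one of [TRANSCRIPT_CATEGORIES] per transcript.
#' @param sequence optional spliced nucleotide sequence per transcript
#'   (`NA` when not attached).
#'
#' @return A `data.frame` of class `transcript_set` with columns
#'   `transcript_id`, `gene_id`, `category`, `chrom`, `strand`,
#'   `exon_start`, `exon_end`, `length_bp`, `sequence`, `gc_percent`,
#'   `sequence_missing`.
#' @export
transcript_set <- function(transcript_id, chrom, strand, exon_start,
                           exon_end, gene_id = transcript_id,
                           category = "intergenic", sequence = NA_character_) {
  n <- length(transcript_id)
  stopifnot(length(exon_start) == n, length(exon_end) == n)
  if (anyDuplicated(transcript_id))
    stop("duplicate transcript_id in transcript set")
  chrom <- rep_len(as.character(chrom), n)
  strand <- rep_len(as.character(strand), n)
  strand[!strand %in% c("+", "-")] <- "*"
  category <- rep_len(as.character(category), n)
  bad <- setdiff(unique(category), TRANSCRIPT_CATEGORIES)
  if (length(bad))
    warning("unrecognised transcript categories kept as-is: ",
            paste(bad, collapse = ", "))
  exons <- mapply(function(s, e) {
    o <- order(s)
    s <- as.integer(s[o]); e <- as.integer(e[o])
    if (any(e < s)) stop("exon end < start")
    if (length(s) > 1L && any(s[-1L] <= e[-length(e)]))
      stop("overlapping exons within a transcript")
    list(start = s, end = e)
  }, exon_start, exon_end, SIMPLIFY = FALSE)
  sequence <- rep_len(as.character(sequence), n)
  out <- data.frame(
    transcript_id = as.character(transcript_id),
    gene_id       = rep_len(as.character(gene_id), n),
    category      = category,
    chrom         = chrom,
    strand        = strand,
    stringsAsFactors = FALSE
  )
  out$exon_start <- lapply(exons, `[[`, "start")
  out$exon_end   <- lapply(exons, `[[`, "end")
  out$length_bp  <- vapply(exons, function(x)
    sum(x$end - x$start + 1L), integer(1))
  out$sequence   <- sequence
  out$gc_percent <- gc_percent(sequence)
  out$sequence_missing <- is.na(sequence)
  class(out) <- c("transcript_set", "data.frame")
  rownames(out) <- NULL
  out
}

#' GC content of nucleotide sequences
#'
#' Percentage of G/C among unambiguous bases. IUPAC ambiguity codes
#' (including N) are excluded from both numerator and denominator, so
#' `gc_percent(s) + at_percent(s) == 100` for any sequence with at least
#' one unambiguous base.
#'
#' @param seq character vector of nucleotide sequences.
#' @return numeric vector in `[0, 100]` (`NA` for `NA` or all-ambiguous
#'   input).
#' @export
gc_percent <- function(seq) {
  vapply(seq, function(s) {
    if (is.na(s)) return(NA_real_)
    s <- toupper(s)
    gc <- lengths(regmatches(s, gregexpr("[GC]", s)))
    at <- lengths(regmatches(s, gregexpr("[AT]", s)))
    if (gc + at == 0L) return(NA_real_)
    100 * gc / (gc + at)
  }, numeric(1), USE.NAMES = FALSE)
}

#' @rdname gc_percent
#' @export
at_percent <- function(seq) {
  g <- gc_percent(seq)
  ifelse(is.na(g), NA_real_, 100 - g)
}

n_exons <- function(records) lengths(records$exon_start)

## Genomic span (first exon start to last exon end) per transcript.
tx_span <- function(records) {
  data.frame(
    transcript_id = records$transcript_id,
    chrom = records$chrom,
    strand = records$strand,
    start = vapply(records$exon_start, min, integer(1)),
    end   = vapply(records$exon_end, max, integer(1)),
    stringsAsFactors = FALSE
  )
}

tx_granges <- function(records, span = TRUE) {
  if (is_empty_records(records)) {
    return(GenomicRanges::GRanges())
  }
  if (span) {
    sp <- tx_span(records)
    GenomicRanges::GRanges(sp$chrom,
                           IRanges::IRanges(sp$start, sp$end),
                           strand = sp$strand,
                           transcript_id = sp$transcript_id)
  } else {
    GenomicRanges::GRanges(
      rep(records$chrom, n_exons(records)),
      IRanges::IRanges(unlist(records$exon_start),
                       unlist(records$exon_end)),
      strand = rep(records$strand, n_exons(records)),
      transcript_id = rep(records$transcript_id, n_exons(records)))
  }
}

subset_records <- function(records, keep) {
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("transcript_set", "data.frame")
  out
}

#' @export
print.transcript_set <- function(x, ...) {
  cat("transcript_set:", nrow(x), "transcripts on",
      length(unique(x$chrom)), "sequences\n")
  if (nrow(x)) {
    tab <- table(factor(x$category, levels = TRANSCRIPT_CATEGORIES))
    tab <- tab[tab > 0]
    cat("  categories:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
    cat("  with sequence:", sum(!x$sequence_missing), "/", nrow(x), "\n")
  }
  invisible(x)
}

#' Construct a table of protein-coding gene spans
#'
#' Gene spans are the reference intervals of the UTR-proximity filter
#' (gene body extended by a flank; see [apply_filter4()]).
#'
#' @param gene_id,chrom,strand,start,end vectors describing one gene per
#'   element; coordinates 1-based closed.
#' @return data.frame of class `gene_spans`.
#' @export
gene_spans <- function(gene_id, chrom, strand, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end < start)) stop("gene span end < start")
  strand <- as.character(strand)
  strand[!strand %in% c("+", "-")] <- "*"
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom), strand = strand,
                    start = start, end = end, stringsAsFactors = FALSE)
  class(out) <- c("gene_spans", "data.frame")
  out
}

#' Expression matrix with tissue metadata
#'
#' @param values numeric matrix of TPM values, transcripts in rows
#'   (rownames = transcript ids), tissues in columns.
#' @param tissues data.frame with columns `name` and `library_prep`
#'   (`rRNA_depleted`, `polyA`, `ovation` or `unknown`); defaults to all
#'   `unknown`.
#' @return list of class `expression_matrix` with elements `values` and
#'   `tissues`.
#' @export
expression_matrix <- function(values, tissues = NULL) {
  values <- as.matrix(values)
  if (is.null(rownames(values))) stop("values must have transcript rownames")
  if (is.null(colnames(values))) stop("values must have tissue colnames")
  if (anyDuplicated(colnames(values))) stop("tissue names must be unique")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(tissues)) {
    tissues <- data.frame(name = colnames(values),
                          library_prep = "unknown",
                          stringsAsFactors = FALSE)
  }
  missing_meta <- setdiff(colnames(values), tissues$name)
  if (length(missing_meta)) {
    warning("no library_prep metadata for tissue(s): ",
            paste(missing_meta, collapse = ", "), "; set to 'unknown'")
    tissues <- rbind(tissues,
                     data.frame(name = missing_meta,
                                library_prep = "unknown",
                                stringsAsFactors = FALSE))
  }
  tissues <- tissues[match(colnames(values), tissues$name), , drop = FALSE]
  rownames(tissues) <- NULL
  structure(list(values = values, tissues = tissues),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix:", nrow(x$values), "transcripts x",
      ncol(x$values), "tissues\n")
  cat("  library prep:",
      paste(x$tissues$name, x$tissues$library_prep, sep = ":",
            collapse = ", "), "\n")
  invisible(x)
}

## TPM rows for a set of ids; ids absent from the matrix come back as
## all-zero rows (a transcript that attracted no reads), with a message.
expr_rows <- function(expr, ids, warn = TRUE) {
  vals <- expr$values
  out <- matrix(0, nrow = length(ids), ncol = ncol(vals),
                dimnames = list(ids, colnames(vals)))
  hit <- ids %in% rownames(vals)
  if (any(hit)) out[hit, ] <- vals[ids[hit], , drop = FALSE]
  if (warn && any(!hit))
    message(sum(!hit), " transcript(s) missing from expression matrix; ",
            "treated as zero TPM")
  out
}
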