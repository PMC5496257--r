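#' Compute TPM from counts and effective lengths
#'
#' Standard transcripts-per-million: within each tissue,
#' `TPM_i = (count_i / len_i) / sum_j(count_j / len_j) * 1e6`, so each
#' column with any signal sums to 1e6.
#'
#' @param counts numeric matrix of read counts (transcripts x tissues,
#'   rownames = transcript ids).
#' @param effective_lengths positive numeric vector, one per transcript
#'   (recycled by name when named).
#' @param tissues optional tissue metadata (see [expression_matrix()]).
#' @return an [expression_matrix()] of TPM values.
#' @export
compute_tpm <- function(counts, effective_lengths, tissues = NULL) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (!is.null(names(effective_lengths)) && !is.null(rownames(counts)))
    effective_lengths <- effective_lengths[rownames(counts)]
  if (length(effective_lengths) != nrow(counts))
    stop("need one effective length per transcript")
  if (any(effective_lengths <= 0)) stop("effective lengths must be > 0")
  rate <- counts / effective_lengths
  denom <- colSums(rate)
  zero <- denom == 0
  if (any(zero)) {
    warning("all-zero count column(s): ",
            paste(colnames(counts)[zero], collapse = ", "),
            "; TPM left at zero")
    denom[zero] <- 1
  }
  tpm <- sweep(rate, 2, denom, "/") * 1e6
  expression_matrix(tpm, tissues)
}

#' Parameters of the low-expression filter
#'
#' @param mean_tpm_min minimum mean TPM across all tissues (default 0.1;
#'   inclusive, so a transcript sitting exactly at the threshold passes).
#' @param single_exon_tpm_min additional per-tissue TPM a single-exon
#'   transcript must reach in at least one tissue (default 5; inclusive).
#' @return list of class `filter1_params`.
#' @export
filter1_params <- function(mean_tpm_min = 0.1, single_exon_tpm_min = 5) {
  stopifnot(mean_tpm_min >= 0, single_exon_tpm_min >= 0)
  structure(list(mean_tpm_min = mean_tpm_min,
                 single_exon_tpm_min = single_exon_tpm_min),
            class = "filter1_params")
}

#' Filter 1: remove lowly expressed transcripts
#'
#' A multi-exon transcript is retained iff its arithmetic mean TPM over
#' all tissue columns (zeros included) is at least `mean_tpm_min`.
#' Single-exon transcripts must additionally reach
#' `single_exon_tpm_min` TPM in at least one tissue — the rules stack.
#' Transcripts absent from the expression matrix count as all-zero.
#'
#' @param records a [transcript_set()].
#' @param expr an [expression_matrix()].
#' @param params a [filter1_params()].
#' @return `list(retained =, removed =)`, a partition of `records`.
#' @export
apply_filter1 <- function(records, expr, params = filter1_params()) {
  if (is_empty_records(records))
    return(list(retained = records, removed = records))
  tpm <- expr_rows(expr, records$transcript_id)
  mean_tpm <- rowMeans(tpm)
  max_tpm <- apply(tpm, 1, max)
  keep <- mean_tpm >= params$mean_tpm_min
  single <- n_exons(records) == 1L
  keep[single] <- keep[single] &
    (max_tpm[single] >= params$single_exon_tpm_min)
  list(retained = subset_records(records, keep),
       removed = subset_records(records, !keep))
}
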