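#' Transcripts expressed in a tissue
#'
#' Expressed means TPM strictly greater than `threshold` in that tissue
#' (a transcript at exactly the threshold is not expressed).
#'
#' @param expr an [expression_matrix()].
#' @param tissue tissue name (must be a column of the matrix).
#' @param threshold TPM cutoff (default 0.1).
#' @return character vector of transcript ids.
#' @export
expressed_set <- function(expr, tissue, threshold = 0.1) {
  if (!tissue %in% colnames(expr$values))
    stop("unknown tissue: ", tissue)
  v <- expr$values[, tissue]
  rownames(expr$values)[v > threshold]
}

#' Uniquely present transcripts per tissue
#'
#' A transcript is uniquely present in tissue `k` iff its TPM is at
#' least `threshold` in `k` and strictly below `threshold` in every
#' other tissue. (Note the deliberate asymmetry with [expressed_set()]:
#' presence here is inclusive, expression there is strict.)
#'
#' @param expr an [expression_matrix()] with at least two tissues.
#' @param threshold TPM cutoff (default 0.1).
#' @return named list, one character vector of transcript ids per
#'   tissue; the sets are disjoint by construction.
#' @export
uniquely_present <- function(expr, threshold = 0.1) {
  v <- expr$values
  if (ncol(v) < 2L) stop("need at least two tissues")
  lapply(stats::setNames(colnames(v), colnames(v)), function(k) {
    others <- v[, setdiff(colnames(v), k), drop = FALSE]
    rownames(v)[v[, k] >= threshold &
                  apply(others < threshold, 1, all)]
  })
}

#' Uniquely absent transcripts per tissue
#'
#' A transcript is uniquely absent in tissue `k` iff its TPM is strictly
#' below `threshold` in `k` and strictly above `threshold` in every
#' other tissue.
#'
#' @inheritParams uniquely_present
#' @return named list of transcript-id vectors per tissue.
#' @export
uniquely_absent <- function(expr, threshold = 0.1) {
  v <- expr$values
  if (ncol(v) < 2L) stop("need at least two tissues")
  lapply(stats::setNames(colnames(v), colnames(v)), function(k) {
    others <- v[, setdiff(colnames(v), k), drop = FALSE]
    rownames(v)[v[, k] < threshold &
                  apply(others > threshold, 1, all)]
  })
}

#' Select robust, variable transcripts for clustering
#'
#' Keeps transcripts whose TPM sum across tissues is strictly above
#' `sum_min` and whose sample (n-1) standard deviation is strictly above
#' `sd_min`.
#'
#' @param expr an [expression_matrix()] with at least two tissues.
#' @param sum_min TPM-sum threshold (default 100).
#' @param sd_min TPM standard-deviation threshold (default 50).
#' @return character vector of transcript ids.
#' @export
select_variable <- function(expr, sum_min = 100, sd_min = 50) {
  v <- expr$values
  if (ncol(v) < 2L) stop("need at least two tissues")
  s <- rowSums(v)
  sdv <- apply(v, 1, stats::sd)
  rownames(v)[s > sum_min & sdv > sd_min]
}

#' Correlation-based bi-clustering of an expression subset
#'
#' Hierarchical clustering on correlation distances: transcripts are
#' clustered by `1 - Pearson` correlation of their profiles across
#' tissues, tissues by `1 - Spearman` correlation of their expression
#' profiles across transcripts; linkage is average by default. A
#' zero-variance profile has undefined correlation; its distance to
#' every other item is set to the maximum (2) with a warning. Leaf
#' orders are deterministic for a fixed input.
#'
#' @param expr an [expression_matrix()], or a plain numeric matrix
#'   (transcripts x tissues).
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default `"average"`).
#' @return object of class `biclustering`: list with `transcript_order`,
#'   `tissue_order` (ids in dendrogram order), `transcript_tree`,
#'   `tissue_tree` (`hclust` objects).
#' @export
bicluster <- function(expr, linkage = "average") {
  v <- if (inherits(expr, "expression_matrix")) expr$values else as.matrix(expr)
  if (nrow(v) < 2L || ncol(v) < 2L)
    stop("bi-clustering needs >= 2 transcripts and >= 2 tissues")
  d_tx <- cor_dist(t(v), method = "pearson")
  d_ti <- cor_dist(v, method = "spearman")
  tx_tree <- stats::hclust(stats::as.dist(d_tx), method = linkage)
  ti_tree <- stats::hclust(stats::as.dist(d_ti), method = linkage)
  structure(list(
    transcript_order = rownames(v)[tx_tree$order],
    tissue_order = colnames(v)[ti_tree$order],
    transcript_tree = tx_tree,
    tissue_tree = ti_tree), class = "biclustering")
}

## 1 - correlation distance between the COLUMNS of m; undefined
## correlations (zero variance) become the maximum distance 2.
cor_dist <- function(m, method) {
  cc <- suppressWarnings(stats::cor(m, method = method))
  if (anyNA(cc)) {
    warning("zero-variance profile(s); correlation distance set to 2")
    cc[is.na(cc)] <- -1
  }
  1 - cc
}

#' @export
print.biclustering <- function(x, ...) {
  cat("biclustering:", length(x$transcript_order), "transcripts x",
      length(x$tissue_order), "tissues\n")
  cat("  tissue order:", paste(x$tissue_order, collapse = " "), "\n")
  invisible(x)
}

#' Write bi-clustering dendrograms as Newick
#'
#' @param x a `biclustering` object.
#' @param transcript_path,tissue_path output paths (`NULL` to skip).
#' @return invisibly, the paths written.
#' @export
write_newick <- function(x, transcript_path = NULL, tissue_path = NULL) {
  if (!is.null(transcript_path))
    ape::write.tree(ape::as.phylo(x$transcript_tree), transcript_path)
  if (!is.null(tissue_path))
    ape::write.tree(ape::as.phylo(x$tissue_tree), tissue_path)
  invisible(c(transcript = transcript_path, tissue = tissue_path))
}

#' Per-tissue expression report for lncRNA versus coding transcripts
#'
#' For each tissue: the number and cumulative TPM of expressed candidate
#' lncRNA and of expressed protein-coding transcripts, their ratio, and
#' the uniquely present / uniquely absent lncRNA counts with the
#' cumulative TPM of the uniquely present set.
#'
#' @param expr an [expression_matrix()] covering both sets.
#' @param lnc_ids,coding_ids transcript-id vectors.
#' @param threshold TPM cutoff (default 0.1).
#' @return data.frame of class `tissue_report`, one row per tissue.
#' @export
tissue_report <- function(expr, lnc_ids, coding_ids, threshold = 0.1) {
  v <- expr$values
  lnc <- intersect(lnc_ids, rownames(v))
  cod <- intersect(coding_ids, rownames(v))
  lnc_expr <- expression_matrix(v[lnc, , drop = FALSE], expr$tissues)
  up <- uniquely_present(lnc_expr, threshold)
  ua <- uniquely_absent(lnc_expr, threshold)
  rows <- lapply(colnames(v), function(k) {
    el <- expressed_set(expr, k, threshold)
    el_lnc <- intersect(el, lnc)
    el_cod <- intersect(el, cod)
    data.frame(
      tissue = k,
      library_prep = expr$tissues$library_prep[expr$tissues$name == k],
      n_expressed_lnc = length(el_lnc),
      n_expressed_coding = length(el_cod),
      ratio = if (length(el_cod)) length(el_lnc) / length(el_cod)
              else NA_real_,
      cumulative_tpm_lnc = sum(v[el_lnc, k]),
      cumulative_tpm_coding = sum(v[el_cod, k]),
      n_uniquely_present = length(up[[k]]),
      n_uniquely_absent = length(ua[[k]]),
      cum_tpm_uniquely_present = sum(v[up[[k]], k]),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tissue_report", "data.frame")
  out
}
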