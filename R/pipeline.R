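#' Pipeline thresholds
#'
#' All thresholds of the discovery pipeline with their published
#' defaults: mean 0.1 TPM across tissues (5 TPM in some tissue for
#' single-exon models), 200 bp minimum length, 100 amino-acid ORF floor
#' with e-value < 1e-3 protein evidence, 1 kb same-strand gene flank,
#' and rescue at e-value < 1e-5 with coverage > 25% and identity > 75%.
#'
#' @param mean_tpm_min,single_exon_tpm_min see [filter1_params()].
#' @param min_len see [apply_filter2()].
#' @param min_aa,evalue_protein,both_strands see [apply_filter3()].
#' @param flank,same_strand_only see [apply_filter4()].
#' @param rescue_evalue,rescue_min_cov,rescue_min_ident see
#'   [rescue_transcripts()].
#' @param rescue_bypass_f4 if `TRUE`, rescued transcripts join the final
#'   set without passing the gene-proximity filter (default `FALSE`:
#'   rescue feeds back in before Filter 4, so rescued UTR fragments can
#'   still be removed).
#' @return list of class `pipeline_params`.
#' @export
pipeline_params <- function(mean_tpm_min = 0.1, single_exon_tpm_min = 5,
                            min_len = 200, min_aa = 100,
                            evalue_protein = 1e-3, both_strands = TRUE,
                            flank = 1000, same_strand_only = TRUE,
                            rescue_evalue = 1e-5, rescue_min_cov = 25,
                            rescue_min_ident = 75,
                            rescue_bypass_f4 = FALSE) {
  structure(as.list(environment()), class = "pipeline_params")
}

#' Run the candidate-lncRNA discovery pipeline
#'
#' Chains the four filters in their fixed order — expression (F1),
#' length (F2), coding potential (F3), gene proximity (F4) — with the
#' homology rescue of F3-removed transcripts re-entering before F4.
#' The gene set used by F4 is the supplied annotation with any entry
#' whose `gene_id` matches a post-F3 candidate transcript removed, so
#' candidates are never filtered against themselves.
#'
#' @param transcripts a [transcript_set()] with sequences attached, or a
#'   GTF path (then `fasta` must be given).
#' @param expression an [expression_matrix()] or a TSV path.
#' @param genes a [gene_spans()] table, or a GTF/BED path; `NULL`
#'   disables Filter 4.
#' @param protein_db,motifs,lnc_db evidence databases (see
#'   [apply_filter3()] and [rescue_transcripts()]); `lnc_db = NULL`
#'   disables rescue.
#' @param params a [pipeline_params()].
#' @param fasta,tissue_meta companion files when paths are given.
#' @param out_dir if non-`NULL`, writes `final.bed`, `final.gtf`,
#'   `filter_report.tsv`, `summary.tsv` and `run.log` there.
#' @return object of class `lnc_pipeline`: list with `final`
#'   (the candidate lncRNA [transcript_set()]), `report` (per-category
#'   [filter_report]), `stages` (named list of transcript-id vectors:
#'   `input`, `removed_F1` ... `removed_F4`, `rescued`, `final`),
#'   `summary` (per-category statistics of the final set), `params`.
#' @export
run_pipeline <- function(transcripts, expression, genes = NULL,
                         protein_db = NULL, motifs = NULL, lnc_db = NULL,
                         params = pipeline_params(), fasta = NULL,
                         tissue_meta = NULL, out_dir = NULL) {
  if (is.character(transcripts)) {
    transcripts <- read_annotation(transcripts)
    if (!is.null(fasta)) transcripts <- attach_sequences(transcripts, fasta)
  }
  if (is.character(expression))
    expression <- read_expression(expression, tissue_meta)
  if (is.character(genes)) genes <- read_gene_spans(genes)

  if (is_empty_records(transcripts)) {
    warning("empty input transcript set; empty result")
    empty <- transcripts
    res <- structure(list(final = empty,
                          report = filter_report(list(), empty),
                          stages = list(), summary = data.frame(),
                          params = params), class = "lnc_pipeline")
    return(res)
  }

  f1 <- apply_filter1(transcripts, expression,
                      filter1_params(params$mean_tpm_min,
                                     params$single_exon_tpm_min))
  f2 <- apply_filter2(f1$retained, min_len = params$min_len)
  f3 <- apply_filter3(f2$retained, db = protein_db, motifs = motifs,
                      min_aa = params$min_aa,
                      evalue_max = params$evalue_protein,
                      both_strands = params$both_strands)
  rescued <- if (!is.null(lnc_db))
    rescue_transcripts(f3$removed, lnc_db,
                       evalue_max = params$rescue_evalue,
                       min_cov = params$rescue_min_cov,
                       min_ident = params$rescue_min_ident)
  else subset_records(f3$removed, logical(nrow(f3$removed)))

  gene_set <- genes
  if (!is.null(gene_set) && nrow(gene_set)) {
    post_f3 <- c(f3$retained$transcript_id, rescued$transcript_id)
    gene_set <- gene_set[!gene_set$gene_id %in% post_f3, , drop = FALSE]
  }
  f4_main <- apply_filter4(f3$retained, gene_set, flank = params$flank,
                           same_strand_only = params$same_strand_only)
  if (params$rescue_bypass_f4) {
    f4_rescued <- list(retained = rescued,
                       removed = subset_records(rescued,
                                                logical(nrow(rescued))))
  } else {
    f4_rescued <- apply_filter4(rescued, gene_set, flank = params$flank,
                                same_strand_only = params$same_strand_only)
  }
  final <- subset_records(
    transcripts,
    transcripts$transcript_id %in% c(f4_main$retained$transcript_id,
                                     f4_rescued$retained$transcript_id))

  stages <- list(
    input = transcripts$transcript_id,
    removed_F1 = f1$removed$transcript_id,
    removed_F2 = f2$removed$transcript_id,
    removed_F3 = f3$removed$transcript_id,
    rescued = rescued$transcript_id,
    removed_F4 = c(f4_main$removed$transcript_id,
                   f4_rescued$removed$transcript_id),
    final = final$transcript_id)
  report <- filter_report(stages, transcripts, expression)
  summ <- summarize_categories(final, expression)
  res <- structure(list(final = final, report = report, stages = stages,
                        summary = summ, params = params),
                   class = "lnc_pipeline")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

#' Per-category filter ledger
#'
#' Counts per input category at each stage (initial, after F1-F4,
#' rescued, final) plus the cumulative TPM (summed over tissues) removed
#' by each filter. Counts are non-increasing from initial through F4
#' within each category and `final = F4 + rescued_final`.
#'
#' @param stages the stage list of a pipeline run.
#' @param transcripts the input [transcript_set()].
#' @param expression optional [expression_matrix()] for the TPM-removed
#'   columns.
#' @return data.frame of class `filter_report`, one row per category
#'   plus a `total` row.
#' @export
filter_report <- function(stages, transcripts, expression = NULL) {
  cats <- TRANSCRIPT_CATEGORIES
  if (is_empty_records(transcripts)) {
    out <- data.frame(category = character(0))
    class(out) <- c("filter_report", "data.frame")
    return(out)
  }
  cat_of <- stats::setNames(transcripts$category,
                            transcripts$transcript_id)
  tpm_of <- if (!is.null(expression)) {
    rs <- rowSums(expr_rows(expression, transcripts$transcript_id,
                            warn = FALSE))
    stats::setNames(rs, transcripts$transcript_id)
  } else stats::setNames(rep(0, nrow(transcripts)),
                         transcripts$transcript_id)
  count_in <- function(ids) {
    table(factor(cat_of[ids], levels = cats))
  }
  tpm_in <- function(ids) {
    vapply(cats, function(cc)
      sum(tpm_of[ids[cat_of[ids] == cc]]), numeric(1))
  }
  surv1 <- setdiff(stages$input, stages$removed_F1)
  surv2 <- setdiff(surv1, stages$removed_F2)
  surv3 <- setdiff(surv2, stages$removed_F3)
  f4_surv_main <- setdiff(surv3, stages$removed_F4)
  rescued_final <- intersect(stages$rescued, stages$final)
  out <- data.frame(
    category = cats,
    initial = as.integer(count_in(stages$input)),
    F1 = as.integer(count_in(surv1)),
    F2 = as.integer(count_in(surv2)),
    F3 = as.integer(count_in(surv3)),
    F4 = as.integer(count_in(f4_surv_main)),
    rescued = as.integer(count_in(stages$rescued)),
    rescued_final = as.integer(count_in(rescued_final)),
    final = as.integer(count_in(stages$final)),
    tpm_removed_F1 = tpm_in(stages$removed_F1),
    tpm_removed_F2 = tpm_in(stages$removed_F2),
    tpm_removed_F3 = tpm_in(setdiff(stages$removed_F3, stages$rescued)),
    tpm_removed_F4 = tpm_in(stages$removed_F4),
    stringsAsFactors = FALSE)
  keep <- out$initial > 0
  out <- out[keep, , drop = FALSE]
  total <- out[1, , drop = FALSE]
  total$category <- "total"
  for (cc in colnames(out)[-1]) total[[cc]] <- sum(out[[cc]])
  out <- rbind(out, total)
  rownames(out) <- NULL
  class(out) <- c("filter_report", "data.frame")
  out
}

#' Per-category summary statistics of a transcript set
#'
#' Mean spliced length (kb), mean of per-transcript mean TPM, mean GC%
#' and total spliced bases per input category.
#'
#' @param records a [transcript_set()] (typically the final set).
#' @param expression an [expression_matrix()].
#' @return data.frame, one row per category present (zero-count
#'   categories are reported as zero rows with `n = 0`).
#' @export
summarize_categories <- function(records, expression = NULL) {
  cats <- TRANSCRIPT_CATEGORIES
  rows <- lapply(cats, function(cc) {
    sel <- records$category == cc
    if (!any(sel))
      return(data.frame(category = cc, n = 0L, mean_length_kb = 0,
                        mean_tpm = 0, gc_percent = 0, total_bp = 0L,
                        stringsAsFactors = FALSE))
    r <- records[sel, , drop = FALSE]
    mt <- if (!is.null(expression))
      mean(rowMeans(expr_rows(expression, r$transcript_id, warn = FALSE)))
    else NA_real_
    data.frame(category = cc, n = sum(sel),
               mean_length_kb = mean(r$length_bp) / 1000,
               mean_tpm = mt,
               gc_percent = mean(r$gc_percent, na.rm = TRUE),
               total_bp = sum(r$length_bp), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[out$n > 0 | out$category %in% unique(records$category), ,
      drop = FALSE]
}

#' Chromosome distribution of a transcript set
#'
#' Counts per chromosome and input category; unplaced scaffolds
#' (names starting `chrUn`) are aggregated as `chrUn`.
#'
#' @param records a [transcript_set()].
#' @return data.frame of counts, chromosomes in rows, categories in
#'   columns.
#' @export
chromosome_distribution <- function(records) {
  if (is_empty_records(records))
    return(data.frame(chrom = character(0)))
  chrom <- ifelse(startsWith(records$chrom, "chrUn"), "chrUn",
                  records$chrom)
  tab <- table(chrom, factor(records$category,
                             levels = TRANSCRIPT_CATEGORIES))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  out <- as.data.frame.matrix(tab)
  out <- data.frame(chrom = rownames(out), out, row.names = NULL,
                    check.names = FALSE)
  out
}

#' Confusion matrix of planted truth against pipeline fate
#'
#' Cross-tabulates the ground-truth class of each simulated transcript
#' with the pipeline stage that decided it: the filter that removed it,
#' or `final` for survivors (rescued transcripts that reach the final
#' set count as `final`).
#'
#' @param result an `lnc_pipeline` object.
#' @param truth the truth table of an `lnc_sim`.
#' @return a contingency table, classes in rows, fates in columns.
#' @export
pipeline_confusion <- function(result, truth) {
  fate <- rep("final", nrow(truth))
  names(fate) <- truth$transcript_id
  st <- result$stages
  fate[truth$transcript_id %in% st$removed_F1] <- "F1"
  fate[truth$transcript_id %in% st$removed_F2] <- "F2"
  fate[truth$transcript_id %in%
         setdiff(st$removed_F3, st$rescued)] <- "F3"
  fate[truth$transcript_id %in% st$removed_F4] <- "F4"
  table(class = truth$class,
        fate = factor(fate, levels = c("F1", "F2", "F3", "F4", "final")))
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(res$final, bed_path = file.path(out_dir, "final.bed"),
                gtf_path = file.path(out_dir, "final.gtf"))
  utils::write.table(res$report, file.path(out_dir, "filter_report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(res$summary, file.path(out_dir, "summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log <- c("equilnc run",
           paste0("package_version: ",
                  as.character(utils::packageVersion("equilnc"))),
           "parameters:",
           paste0("  ", names(res$params), " = ",
                  vapply(res$params, function(x)
                    paste(format(x), collapse = ","), character(1))),
           "stage_counts:",
           paste0("  ", names(res$stages), " = ",
                  lengths(res$stages)))
  writeLines(log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.lnc_pipeline <- function(x, ...) {
  st <- x$stages
  cat("lncRNA discovery pipeline\n")
  if (!length(st)) { cat("  (empty input)\n"); return(invisible(x)) }
  cat(sprintf("  input:            %6d transcripts\n", length(st$input)))
  cat(sprintf("  removed by F1:    %6d (low expression)\n",
              length(st$removed_F1)))
  cat(sprintf("  removed by F2:    %6d (short)\n", length(st$removed_F2)))
  cat(sprintf("  removed by F3:    %6d (coding potential)\n",
              length(st$removed_F3)))
  cat(sprintf("  rescued:          %6d (lncRNA homology)\n",
              length(st$rescued)))
  cat(sprintf("  removed by F4:    %6d (gene proximity)\n",
              length(st$removed_F4)))
  cat(sprintf("  final candidates: %6d\n", length(st$final)))
  invisible(x)
}

#' @export
summary.lnc_pipeline <- function(object, ...) {
  print(object)
  cat("\nPer-category ledger:\n")
  print(as.data.frame(object$report), digits = 4)
  cat("\nFinal-set statistics:\n")
  print(object$summary, digits = 4)
  invisible(object$report)
}
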