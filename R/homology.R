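#' Local nucleotide alignment against a sequence database
#'
#' Word-seeded Smith-Waterman local alignment standing in for a BLASTN
#' search: only query/subject pairs sharing an exact `seed_k`-mer are
#' aligned (both sequences taken as sense-strand transcripts; the reverse
#' strand is not scanned). Scoring defaults to the classic
#' match 2 / mismatch -3, gap open 5 / extend 2 scheme with
#' Karlin-Altschul parameters `lambda = 0.625`, `K = 0.41`; e-values use
#' the raw query length times total database length as search space.
#'
#' Percent identity is matches over alignment columns (gaps included);
#' percent query coverage is aligned query bases over the full query
#' length.
#'
#' @param query named character vector / `DNAStringSet` / FASTA path of
#'   query sequences (each at least 20 nt; shorter queries are skipped
#'   with a warning).
#' @param subject_db the subject database in any of the same forms.
#' @param match,mismatch,gap_open,gap_extend scoring scheme.
#' @param lambda,K Karlin-Altschul parameters for that scheme.
#' @param evalue_max report only hits with e-value below this
#'   (default 10, the conventional report cutoff).
#' @param seed_k seeding word size (default 11).
#' @param min_seed_hits minimum number of distinct query words that must
#'   occur exactly in a subject before the pair is aligned (default 3;
#'   capped at the query's word count).
#' @return data.frame of hits sorted by query then descending bitscore:
#'   `query_id`, `subject_id`, `percent_identity`,
#'   `percent_query_coverage`, `score`, `bitscore`, `evalue`.
#' @export
align_nucleotide <- function(query, subject_db, match = 2, mismatch = -3,
                             gap_open = 5, gap_extend = 2,
                             lambda = 0.625, K = 0.41, evalue_max = 10,
                             seed_k = 11, min_seed_hits = 3) {
  queries <- as_seq_vector(query, "DNA")
  idx <- nuc_db_index(subject_db, seed_k)
  subjects <- idx$seqs
  if (length(subjects) == 0L) {
    warning("empty subject database; no hits")
    return(empty_nuc_hits())
  }
  short <- nchar(queries) < 20L
  if (any(short)) {
    warning(sum(short), " query sequence(s) shorter than 20 nt skipped")
    queries <- queries[!short]
  }
  mat <- nuc_matrix(match, mismatch)
  res <- list()
  for (qi in seq_along(queries)) {
    q <- queries[[qi]]
    qk <- kmer_set(q, seed_k)
    cand <- which(vapply(idx$kmers, function(sk)
      shares_kmer(qk, sk, min_seed_hits), logical(1)))
    if (!length(cand)) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAStringSet(rep(q, length(cand))),
      subject = Biostrings::DNAStringSet(subjects[cand]),
      type = "local", substitutionMatrix = mat,
      gapOpening = gap_open, gapExtension = gap_extend)
    score <- Biostrings::score(aln)
    alen <- nchar(as.character(Biostrings::pattern(aln)))
    qspan <- BiocGenerics::end(Biostrings::pattern(aln)) -
      BiocGenerics::start(Biostrings::pattern(aln)) + 1L
    ev <- ka_evalue(score, nchar(q), idx$total_len, lambda, K)
    keep <- ev < evalue_max
    if (!any(keep)) next
    res[[length(res) + 1L]] <- data.frame(
      query_id = names(queries)[qi],
      subject_id = names(subjects)[cand][keep],
      percent_identity = 100 * Biostrings::nmatch(aln)[keep] / alen[keep],
      percent_query_coverage = 100 * qspan[keep] / nchar(q),
      score = score[keep],
      bitscore = ka_bitscore(score[keep], lambda, K),
      evalue = ev[keep],
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty_nuc_hits())
  out <- do.call(rbind, res)
  out <- out[order(out$query_id, -out$bitscore, out$evalue,
                   out$subject_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

nuc_db_index <- function(db, seed_k = 11) {
  if (inherits(db, "nuc_db_index")) return(db)
  seqs <- as_seq_vector(db, "DNA")
  structure(list(seqs = seqs,
                 kmers = lapply(seqs, kmer_set, k = seed_k),
                 total_len = sum(nchar(seqs))),
            class = "nuc_db_index")
}

empty_nuc_hits <- function() {
  data.frame(query_id = character(0), subject_id = character(0),
             percent_identity = numeric(0),
             percent_query_coverage = numeric(0), score = numeric(0),
             bitscore = numeric(0), evalue = numeric(0),
             stringsAsFactors = FALSE)
}

## Best hit per query: highest bitscore, ties broken by lower e-value
## then lexicographic subject id (the sort order of align_nucleotide).
best_hits <- function(hits) {
  hits[!duplicated(hits$query_id), , drop = FALSE]
}

#' Rescue coding-filtered transcripts by homology to known lncRNA
#'
#' Transcripts removed by the coding-potential filter are re-admitted
#' when they align to a known-lncRNA database with e-value below
#' `evalue_max` and, on the same hit, query coverage strictly over
#' `min_cov` percent and identity strictly over `min_ident` percent.
#' Rescued transcripts re-enter the pipeline before the gene-proximity
#' filter.
#'
#' @param removed_by_f3 the [transcript_set()] removed by
#'   [apply_filter3()].
#' @param lnc_db nucleotide database of known lncRNA (FASTA path,
#'   `DNAStringSet` or named character vector).
#' @param evalue_max e-value cutoff (default 1e-5, strict `<`).
#' @param min_cov query-coverage threshold in percent (default 25,
#'   strict `>`).
#' @param min_ident identity threshold in percent (default 75,
#'   strict `>`).
#' @param hits optional precomputed hit table (columns as
#'   [align_nucleotide()]) replacing the built-in aligner.
#' @return the rescued [transcript_set()] (always a subset of the
#'   input), with the supporting hits as attribute `"hits"`.
#' @export
rescue_transcripts <- function(removed_by_f3, lnc_db, evalue_max = 1e-5,
                               min_cov = 25, min_ident = 75, hits = NULL) {
  if (is_empty_records(removed_by_f3)) {
    out <- removed_by_f3
    attr(out, "hits") <- empty_nuc_hits()
    return(out)
  }
  if (is.null(hits)) {
    with_seq <- !removed_by_f3$sequence_missing
    qs <- removed_by_f3$sequence[with_seq]
    names(qs) <- removed_by_f3$transcript_id[with_seq]
    hits <- if (length(qs)) align_nucleotide(qs, lnc_db,
                                             evalue_max = evalue_max)
            else empty_nuc_hits()
  }
  ok <- hits[hits$evalue < evalue_max &
               hits$percent_query_coverage > min_cov &
               hits$percent_identity > min_ident, , drop = FALSE]
  keep <- removed_by_f3$transcript_id %in% ok$query_id
  out <- subset_records(removed_by_f3, keep)
  attr(out, "hits") <- ok
  out
}

#' Sequence-conservation curve of a transcript set
#'
#' Each query's conservation measure is its best hit's percent identity
#' multiplied by percent query coverage, scaled to 0-100
#' (`id * cov / 100`); queries without a significant hit score 0. The
#' curve is the empirical cumulative frequency: the fraction of queries
#' attaining at most each observed measure.
#'
#' @param queries a [transcript_set()] with sequences, or a named
#'   sequence vector / `DNAStringSet` / FASTA path.
#' @param subject_db nucleotide database (e.g. transcriptional products
#'   of another species).
#' @param evalue_max significance cutoff defining "no hit"
#'   (default 1e-5).
#' @param scale divide the identity-coverage product by 100 (default
#'   `TRUE`); `FALSE` leaves the raw product on 0-10000.
#' @param hits optional precomputed hit table replacing the aligner.
#' @return object of class `conservation_curve`: list with `scores`
#'   (named per query), `curve` (data.frame `score`,
#'   `cumulative_fraction`), `no_hit_fraction`.
#' @export
conservation_curve <- function(queries, subject_db, evalue_max = 1e-5,
                               scale = TRUE, hits = NULL) {
  if (inherits(queries, "transcript_set")) {
    qs <- queries$sequence[!queries$sequence_missing]
    names(qs) <- queries$transcript_id[!queries$sequence_missing]
  } else {
    qs <- as_seq_vector(queries, "DNA")
  }
  if (is.null(hits)) {
    hits <- if (length(qs)) align_nucleotide(qs, subject_db,
                                             evalue_max = evalue_max)
            else empty_nuc_hits()
  } else {
    hits <- hits[hits$evalue < evalue_max, , drop = FALSE]
  }
  best <- best_hits(hits)
  scores <- stats::setNames(numeric(length(qs)), names(qs))
  m <- match(best$query_id, names(scores))
  prod <- best$percent_identity * best$percent_query_coverage
  scores[m[!is.na(m)]] <- if (scale) prod[!is.na(m)] / 100
                          else prod[!is.na(m)]
  xs <- sort(unique(scores))
  curve <- data.frame(
    score = xs,
    cumulative_fraction = vapply(xs, function(x) mean(scores <= x),
                                 numeric(1)))
  structure(list(scores = scores, curve = curve,
                 no_hit_fraction = if (length(scores))
                   mean(!names(scores) %in% best$query_id) else 0),
            class = "conservation_curve")
}

#' Evaluate a conservation curve at arbitrary scores
#'
#' @param x a `conservation_curve`.
#' @param at numeric scores.
#' @return the cumulative fraction of queries with measure `<= at`.
#' @export
curve_at <- function(x, at) {
  vapply(at, function(s) mean(x$scores <= s), numeric(1))
}

#' @export
print.conservation_curve <- function(x, ...) {
  cat("conservation_curve:", length(x$scores), "queries;",
      sprintf("%.1f%%", 100 * x$no_hit_fraction), "with no hit\n")
  if (length(x$scores))
    cat("  measure quartiles:",
        paste(sprintf("%.2f", stats::quantile(x$scores)), collapse = " "),
        "\n")
  invisible(x)
}

#' @export
plot.conservation_curve <- function(x, add = FALSE, col = "black",
                                    main = "Sequence conservation", ...) {
  cf <- x$curve
  if (!add) {
    graphics::plot(cf$score, 100 * cf$cumulative_fraction, type = "s",
                   xlab = "conservation measure (identity x coverage / 100)",
                   ylab = "cumulative frequency (%)", ylim = c(0, 100),
                   col = col, main = main, ...)
  } else {
    graphics::lines(cf$score, 100 * cf$cumulative_fraction, type = "s",
                    col = col, ...)
  }
  invisible(x)
}
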