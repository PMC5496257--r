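#' Filter 2: remove short transcripts
#'
#' Transcripts shorter than `min_len` spliced bases are removed; a
#' transcript of exactly `min_len` bases is retained.
#'
#' @param records a [transcript_set()].
#' @param min_len minimum spliced length in bp (default 200).
#' @return `list(retained =, removed =)`.
#' @export
apply_filter2 <- function(records, min_len = 200) {
  if (is_empty_records(records))
    return(list(retained = records, removed = records))
  keep <- records$length_bp >= min_len
  list(retained = subset_records(records, keep),
       removed = subset_records(records, !keep))
}

#' Extend gene spans by a flank
#'
#' Start and end are pushed outward by `flank` bases, clamped at
#' position 1; strand is unchanged.
#'
#' @param genes a [gene_spans()] table.
#' @param flank non-negative flank in bp (default 1000).
#' @return the extended [gene_spans()].
#' @export
extend_span <- function(genes, flank = 1000) {
  stopifnot(flank >= 0)
  genes$start <- pmax(1L, as.integer(genes$start - flank))
  genes$end <- as.integer(genes$end + flank)
  genes
}

#' Filter 4: remove transcripts near protein-coding genes
#'
#' A candidate is removed iff its genomic span (first exon start to last
#' exon end) overlaps, by at least one base, any gene span extended by
#' `flank` on the same chromosome and — when `same_strand_only` — the
#' same strand. Abutting at distance zero counts as within. Candidates of
#' unknown strand are compared against both strands (conservative
#' removal). This removes likely fragmented UTRs flanking genes.
#'
#' @param candidates a [transcript_set()].
#' @param genes a [gene_spans()] table of likely protein-coding genes.
#' @param flank extension in bp (default 1000).
#' @param same_strand_only restrict removal to same-strand overlap
#'   (default `TRUE`).
#' @return `list(retained =, removed =)`.
#' @export
apply_filter4 <- function(candidates, genes, flank = 1000,
                          same_strand_only = TRUE) {
  if (is_empty_records(candidates))
    return(list(retained = candidates, removed = candidates))
  if (is.null(genes) || nrow(genes) == 0L)
    return(list(retained = candidates,
                removed = subset_records(candidates, logical(nrow(candidates)))))
  ext <- extend_span(genes, flank)
  cand_gr <- tx_granges(candidates, span = TRUE)
  gene_gr <- GenomicRanges::GRanges(ext$chrom,
                                    IRanges::IRanges(ext$start, ext$end),
                                    strand = ext$strand)
  lv <- union(GenomeInfoDb::seqlevels(cand_gr),
              GenomeInfoDb::seqlevels(gene_gr))
  GenomeInfoDb::seqlevels(cand_gr) <- lv
  GenomeInfoDb::seqlevels(gene_gr) <- lv
  hits <- GenomicRanges::findOverlaps(cand_gr, gene_gr,
                                      ignore.strand = !same_strand_only)
  removed <- seq_len(nrow(candidates)) %in% S4Vectors::queryHits(hits)
  list(retained = subset_records(candidates, !removed),
       removed = subset_records(candidates, removed))
}

#' All overlapping pairs between two interval sets
#'
#' Closed 1-based intervals `a` and `b` overlap iff
#' `a$start <= b$end && b$start <= a$end` on the same chromosome.
#' Strand is ignored. Output rows are sorted by `a` index then `b` index.
#'
#' @param a,b data.frames with columns `chrom`, `start`, `end`.
#' @return data.frame with columns `a` and `b` (row indices into the
#'   inputs).
#' @export
interval_overlaps <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L)
    return(data.frame(a = integer(0), b = integer(0)))
  ga <- GenomicRanges::GRanges(a$chrom, IRanges::IRanges(a$start, a$end))
  gb <- GenomicRanges::GRanges(b$chrom, IRanges::IRanges(b$start, b$end))
  lv <- union(GenomeInfoDb::seqlevels(ga), GenomeInfoDb::seqlevels(gb))
  GenomeInfoDb::seqlevels(ga) <- lv
  GenomeInfoDb::seqlevels(gb) <- lv
  h <- GenomicRanges::findOverlaps(ga, gb, ignore.strand = TRUE)
  out <- data.frame(a = S4Vectors::queryHits(h),
                    b = S4Vectors::subjectHits(h))
  out[order(out$a, out$b), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
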