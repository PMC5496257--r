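#' Read a transcript annotation from GTF
#'
#' Builds one transcript per `transcript_id` from the exon features of a
#' GTF file (9 columns, 1-based closed coordinates). Transcript-level
#' feature lines are not required; exon grouping alone defines the models.
#' Exons of a transcript are merged (overlaps collapsed) and sorted.
#'
#' @param gtf_path path to a GTF file (Ensembl-dialect attributes).
#' @param category_attribute name of the attribute carrying the input
#'   category (one of [TRANSCRIPT_CATEGORIES]); transcripts without it are
#'   assigned `"intergenic"` with a message.
#' @param category optional single category overriding the file contents
#'   for every transcript (per-file override).
#' @return a [transcript_set()] (without sequences; see
#'   [attach_sequences()]).
#' @export
read_annotation <- function(gtf_path, category_attribute = "category",
                            category = NULL) {
  if (!validate_gtf_lines(gtf_path)) {
    warning("no feature lines in ", gtf_path, "; empty transcript set")
    return(empty_transcript_set())
  }
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
  if (length(gr) == 0L) {
    warning("no exon features in ", gtf_path, "; empty transcript set")
    return(empty_transcript_set())
  }
  if (is.null(gr$transcript_id) || anyNA(gr$transcript_id))
    stop("exon feature(s) without transcript_id attribute in ", gtf_path)
  ids <- gr$transcript_id
  uids <- unique(ids)
  idx <- split(seq_along(gr), factor(ids, levels = uids))

  strand_of <- vapply(idx, function(i) {
    s <- unique(as.character(BiocGenerics::strand(gr)[i]))
    if (length(s) > 1L)
      stop("conflicting strand for transcript ",
           unique(ids[i]))
    s
  }, character(1))
  chrom_of <- vapply(idx, function(i) {
    as.character(GenomeInfoDb::seqnames(gr))[i][1]
  }, character(1))
  exon_ranges <- lapply(idx, function(i) {
    r <- IRanges::reduce(IRanges::IRanges(BiocGenerics::start(gr)[i],
                                          BiocGenerics::end(gr)[i]))
    list(start = BiocGenerics::start(r), end = BiocGenerics::end(r))
  })
  gene_of <- if (!is.null(gr$gene_id)) {
    vapply(idx, function(i) {
      g <- gr$gene_id[i][1]
      if (is.na(g)) uids[1] else g
    }, character(1))
  } else uids
  if (is.null(category)) {
    cat_col <- if (category_attribute %in%
                   colnames(S4Vectors::mcols(gr)))
      S4Vectors::mcols(gr)[[category_attribute]] else NULL
    cat_of <- vapply(idx, function(i) {
      v <- if (is.null(cat_col)) NA_character_ else cat_col[i][1]
      if (is.na(v)) NA_character_ else v
    }, character(1))
    if (anyNA(cat_of)) {
      message(sum(is.na(cat_of)), " transcript(s) without a '",
              category_attribute, "' attribute; defaulting to intergenic")
      cat_of[is.na(cat_of)] <- "intergenic"
    }
  } else {
    cat_of <- rep(category, length(uids))
  }
  transcript_set(
    transcript_id = uids,
    gene_id = unname(gene_of),
    category = unname(cat_of),
    chrom = unname(chrom_of),
    strand = unname(strand_of),
    exon_start = lapply(exon_ranges, `[[`, "start"),
    exon_end = lapply(exon_ranges, `[[`, "end"))
}

empty_transcript_set <- function() {
  transcript_set(character(0), character(0), character(0),
                 list(), list())
}

## Light structural scan so malformed lines are reported with a line
## number before handing the file to the importer; returns FALSE for a
## file without any feature line.
validate_gtf_lines <- function(path) {
  lines <- readLines(path, warn = FALSE)
  body <- which(!grepl("^\\s*(#|$)", lines))
  if (!length(body)) return(FALSE)
  nfield <- vapply(strsplit(lines[body], "\t", fixed = TRUE),
                   length, integer(1))
  bad <- body[nfield < 8L]
  if (length(bad))
    stop("malformed GTF line ", bad[1], " in ", path,
         " (expected 9 tab-separated fields, found ",
         nfield[match(bad[1], body)], ")")
  TRUE
}

#' Attach spliced transcript sequences from FASTA
#'
#' @param records a [transcript_set()].
#' @param fasta path to a FASTA file keyed by transcript id (descriptions
#'   after the first whitespace are ignored), or a named sequence vector /
#'   `DNAStringSet`.
#' @return the transcript set with `sequence`, `gc_percent` and (on
#'   length disagreement, where the FASTA sequence wins) `length_bp`
#'   updated; transcripts with no FASTA entry keep
#'   `sequence_missing = TRUE` and are skipped by sequence-dependent
#'   filters.
#' @export
attach_sequences <- function(records, fasta) {
  seqs <- as_seq_vector(fasta, "DNA")
  hit <- records$transcript_id %in% names(seqs)
  if (any(!hit))
    message(sum(!hit), " transcript(s) missing from FASTA; flagged ",
            "sequence_missing")
  records$sequence[hit] <- toupper(unname(seqs[records$transcript_id[hit]]))
  records$sequence_missing <- is.na(records$sequence)
  records$gc_percent <- gc_percent(records$sequence)
  flen <- nchar(records$sequence[hit])
  mism <- flen != records$length_bp[hit]
  if (any(mism)) {
    warning(sum(mism), " transcript(s) with FASTA length differing from ",
            "exon sum; FASTA length retained")
    records$length_bp[hit][mism] <- flen[mism]
  }
  records
}

#' Write a transcript set as BED12 and GTF
#'
#' Emits the transcript models in both conventions: BED12 (0-based
#' half-open, blockStarts relative to chromStart) and GTF (1-based
#' closed). Coordinates round-trip exactly through [read_annotation()].
#' Unknown strand is written as `"."`.
#'
#' @param records a [transcript_set()].
#' @param bed_path,gtf_path output paths (either may be `NULL` to skip).
#' @param source source field for the GTF lines.
#' @return invisibly, the paths written.
#' @export
write_results <- function(records, bed_path = NULL, gtf_path = NULL,
                          source = "equilnc") {
  if (!is.null(bed_path)) {
    if (is_empty_records(records)) {
      writeLines(character(0), bed_path)
    } else {
      ex <- tx_granges(records, span = FALSE)
      grl <- GenomicRanges::split(ex, factor(ex$transcript_id,
                                             levels = records$transcript_id))
      bed <- rtracklayer::asBED(grl)
      rtracklayer::export(bed, bed_path, format = "bed")
    }
  }
  if (!is.null(gtf_path)) {
    if (is_empty_records(records)) {
      writeLines("##gff-version 2", gtf_path)
    } else {
      ex <- tx_granges(records, span = FALSE)
      ord <- rep(seq_len(nrow(records)), n_exons(records))
      S4Vectors::mcols(ex) <- S4Vectors::DataFrame(
        source = source, type = "exon",
        transcript_id = ex$transcript_id,
        gene_id = records$gene_id[ord],
        category = records$category[ord])
      rtracklayer::export(ex, gtf_path, format = "gtf")
      ## the exporter stamps a ##date comment; drop it so identical runs
      ## produce byte-identical files
      lines <- readLines(gtf_path, warn = FALSE)
      writeLines(lines[!grepl("^##date", lines)], gtf_path)
    }
  }
  invisible(c(bed = bed_path, gtf = gtf_path))
}

#' Read a transcript x tissue TPM table
#'
#' @param tsv_path tab-separated table: first column transcript ids,
#'   header row of tissue names, numeric TPM cells.
#' @param tissue_meta optional TSV with columns `name` and `library_prep`;
#'   tissues absent from it get `library_prep = "unknown"` with a warning.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(tsv_path, tissue_meta = NULL) {
  tab <- utils::read.delim(tsv_path, header = TRUE, sep = "\t",
                           check.names = FALSE, colClasses = "character",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("expression table needs >= 1 tissue column")
  ids <- tab[[1]]
  if (anyDuplicated(ids))
    stop("duplicate transcript row(s) in expression table: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(tab[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals),
                                 dimnames = list(ids, colnames(vals))))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop("non-numeric expression value at row ", bad[1] + 1L,
         " (", ids[bad[1]], "), column ", colnames(num)[bad[2]])
  }
  if (any(num < 0)) stop("negative expression values rejected")
  tissues <- NULL
  if (!is.null(tissue_meta)) {
    tissues <- utils::read.delim(tissue_meta, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
    if (!all(c("name", "library_prep") %in% colnames(tissues)))
      stop("tissue metadata needs columns 'name' and 'library_prep'")
  }
  expression_matrix(num, tissues)
}

#' Read protein-coding gene spans from GTF or BED
#'
#' From a GTF, uses `gene` features when present, otherwise the per-gene
#' span of the exon features; from a BED (6+ columns), one gene per line
#' with the `name` field as `gene_id`.
#'
#' @param path GTF or BED file.
#' @return a [gene_spans()] table.
#' @export
read_gene_spans <- function(path) {
  fmt <- tolower(tools::file_ext(path))
  if (fmt %in% c("bed", "bed6")) {
    gr <- rtracklayer::import(path, format = "bed")
    ids <- if (!is.null(gr$name)) gr$name else paste0("gene", seq_along(gr))
    return(gene_spans(ids, as.character(GenomeInfoDb::seqnames(gr)),
                      as.character(BiocGenerics::strand(gr)),
                      BiocGenerics::start(gr), BiocGenerics::end(gr)))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  genes <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(genes) == 0L) {
    use <- gr[!is.na(gr$type) & as.character(gr$type) == "exon"]
    if (length(use) == 0L) use <- gr
    key <- if (!is.null(use$gene_id)) use$gene_id else use$transcript_id
    idx <- split(seq_along(use), key)
    return(gene_spans(
      names(idx),
      vapply(idx, function(i)
        as.character(GenomeInfoDb::seqnames(use))[i][1], character(1)),
      vapply(idx, function(i)
        as.character(BiocGenerics::strand(use))[i][1], character(1)),
      vapply(idx, function(i) min(BiocGenerics::start(use)[i]), integer(1)),
      vapply(idx, function(i) max(BiocGenerics::end(use)[i]), integer(1))))
  }
  ids <- if (!is.null(genes$gene_id)) genes$gene_id
         else paste0("gene", seq_along(genes))
  gene_spans(ids, as.character(GenomeInfoDb::seqnames(genes)),
             as.character(BiocGenerics::strand(genes)),
             BiocGenerics::start(genes), BiocGenerics::end(genes))
}
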