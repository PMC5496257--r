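#' Configuration of the synthetic transcriptome generator
#'
#' Defines the study conditions the generator emulates: a multi-tissue
#' transcriptome whose transcripts fall into five ground-truth classes —
#' `coding` (carry a planted ORF copied from the bundled protein
#' fixture), `true_lncRNA` (violate none of the removal conditions; a
#' small fraction additionally carry a coding-like ORF plus a planted
#' match in the lncRNA fixture database, emulating orthologous lncRNA
#' lost to the coding filter and recoverable by rescue), `utr_fragment`
#' (placed within 1 kb, same strand, of a planted gene span), `short`
#' (spliced length below 200 bp) and `low_expression` (mean TPM below
#' 0.1, or single-exon models never reaching 5 TPM). The default tissue
#' panel mirrors an eight-tissue design with mixed library preparations:
#' three rRNA-depleted CNS tissues, three polyA-captured peripheral
#' tissues and two Ovation-amplified embryonic tissues; transcripts
#' flagged non-polyadenylated are attenuated in polyA-captured (and,
#' mildly, Ovation) libraries.
#'
#' @param seed integer; fully determines the generated dataset.
#' @param n_coding,n_lncrna,n_utr_fragment,n_short,n_low_expression
#'   class sizes (defaults total 2000).
#' @param tissues data.frame with columns `name`, `library_prep`.
#' @param rescue_fraction fraction of true lncRNA planted as rescue
#'   candidates (default 0.05).
#' @param orf_mutation_rate amino-acid substitution rate applied to
#'   planted ORFs relative to their source protein (default 0.02).
#' @param rescue_segment_mutation nucleotide substitution rate of the
#'   planted lncRNA-database segment (default 0.08; keeps identity well
#'   over the 75\% rescue threshold).
#' @param single_exon_fraction fraction of true lncRNA built single-exon
#'   (default 0.15; these are guaranteed to clear the 5-TPM single-exon
#'   rule in one rRNA-depleted tissue).
#' @param tissue_specific_fraction fraction of true lncRNA planted as
#'   uniquely present in one tissue (default 0.1).
#' @param non_polya_fraction fraction of true lncRNA flagged
#'   non-polyadenylated (default 0.5).
#' @param polya_attenuation,ovation_attenuation multiplicative TPM
#'   attenuation of non-polyadenylated transcripts in polyA / Ovation
#'   libraries (defaults 0.02 / 0.5: polyA capture recovers almost none
#'   of a transcript without a polyA tail, Ovation amplification part of
#'   it). Planted tissue-specific and single-exon transcripts keep a
#'   post-attenuation detection guarantee in their key tissue.
#' @param class_mean_tpm named list of log-normal TPM location
#'   parameters per class.
#' @param expr_floor TPM floor applied (before attenuation) to classes
#'   that must clear the expression filter (default 0.15).
#' @param short_len,lnc_len,utr_len,low_len length ranges in bp.
#' @param n_genes planted protein-coding gene spans (default 60).
#' @param n_proteins,protein_len protein fixture database size/lengths.
#' @param n_lnc_db,lnc_db_len lncRNA fixture database size/lengths.
#' @param n_motifs bundled Prosite-style motif count (default 10).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 42,
                       n_coding = 400, n_lncrna = 800,
                       n_utr_fragment = 300, n_short = 200,
                       n_low_expression = 300,
                       tissues = default_tissues(),
                       rescue_fraction = 0.05,
                       orf_mutation_rate = 0.02,
                       rescue_segment_mutation = 0.08,
                       single_exon_fraction = 0.15,
                       tissue_specific_fraction = 0.1,
                       non_polya_fraction = 0.5,
                       polya_attenuation = 0.02,
                       ovation_attenuation = 0.5,
                       class_mean_tpm = list(coding = 20, true_lncRNA = 4,
                                             utr_fragment = 3, short = 2),
                       expr_floor = 0.15,
                       short_len = c(60, 199),
                       lnc_len = c(250, 4000),
                       utr_len = c(250, 1500),
                       low_len = c(250, 1500),
                       n_genes = 60,
                       n_proteins = 50, protein_len = c(120, 400),
                       n_lnc_db = 30, lnc_db_len = c(400, 1500),
                       n_motifs = 10) {
  counts <- c(n_coding, n_lncrna, n_utr_fragment, n_short,
              n_low_expression)
  if (any(counts < 0)) stop("class counts must be >= 0")
  if (short_len[1] < 1 || short_len[2] >= 200)
    stop("infeasible config: the short class needs lengths in [1, 199]")
  if (lnc_len[1] < 200 || utr_len[1] < 200 || low_len[1] < 200)
    stop("infeasible config: non-short classes need lengths >= 200")
  if (!all(c("name", "library_prep") %in% colnames(tissues)) ||
      nrow(tissues) < 2L)
    stop("tissues needs columns name/library_prep and >= 2 rows")
  structure(as.list(environment()), class = "sim_config")
}

#' Default eight-tissue panel with mixed library preparations
#' @return data.frame with columns `name` and `library_prep`.
#' @export
default_tissues <- function() {
  data.frame(
    name = c("cerebellum", "brainstem", "spinal_cord",
             "retina", "muscle", "skin", "embryo_ICM", "embryo_TE"),
    library_prep = c("rRNA_depleted", "rRNA_depleted", "rRNA_depleted",
                     "polyA", "polyA", "polyA", "ovation", "ovation"),
    stringsAsFactors = FALSE)
}

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")

random_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

#' Generate a set of random nucleotide sequences
#'
#' @param n number of sequences.
#' @param min_len,max_len uniform length range in bp.
#' @param prefix id prefix.
#' @return named character vector.
#' @export
random_dna_set <- function(n, min_len = 400, max_len = 1500,
                           prefix = "S") {
  lens <- sample(min_len:max_len, n, replace = TRUE)
  stats::setNames(vapply(lens, random_dna, character(1)),
                  sprintf("%s%04d", prefix, seq_len(n)))
}

random_protein <- function(len) {
  paste0("M", paste(sample(AA20, len - 1L, replace = TRUE),
                    collapse = ""))
}

#' Apply random point substitutions to a nucleotide sequence
#'
#' Each position is substituted, independently with probability `rate`,
#' by a different base.
#'
#' @param seq nucleotide string.
#' @param rate per-base substitution probability.
#' @return the mutated sequence.
#' @export
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  ch <- strsplit(seq, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  }
  paste(ch, collapse = "")
}

mutate_peptide <- function(pep, rate) {
  if (rate <= 0) return(pep)
  ch <- strsplit(pep, "")[[1]]
  hit <- stats::runif(length(ch)) < rate
  hit[1] <- FALSE                       # keep the initiator M
  if (any(hit)) {
    ch[hit] <- vapply(ch[hit], function(a)
      sample(setdiff(AA20, a), 1L), character(1))
  }
  paste(ch, collapse = "")
}

## Sample synonymous codons for a peptide and close with a stop codon.
reverse_translate <- function(pep) {
  gc <- codon_table()
  syn <- split(names(gc), unname(gc))
  ch <- strsplit(pep, "")[[1]]
  codons <- vapply(ch, function(a) {
    cands <- syn[[a]]
    cands[sample.int(length(cands), 1L)]
  }, character(1))
  paste0(paste(codons, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

## A sequence guaranteed to carry no ORF of >= min_aa amino acids on
## either strand (rejection sampling; classes fated for non-coding
## filters must be untouchable by the coding filter).
random_noncoding_dna <- function(len, min_aa = 100, max_tries = 100) {
  for (i in seq_len(max_tries)) {
    s <- random_dna(len)
    if (nrow(find_orfs(s, min_aa = min_aa, both_strands = TRUE)) == 0L)
      return(s)
  }
  stop("failed to generate an ORF-free sequence of length ", len)
}

## Split a spliced length into n exon widths of >= 20 bp each.
make_exon_widths <- function(total, n) {
  n <- max(1L, min(n, total %/% 40L))
  if (n == 1L) return(total)
  extra <- total - 20L * n
  add <- tabulate(sample.int(n, extra, replace = TRUE), nbins = n)
  20L + add
}

## Per-chromosome placement cursors so transcripts never collide.
make_allocator <- function(gap = 3000L) {
  cursors <- new.env(parent = emptyenv())
  function(chrom, width) {
    at <- if (is.null(cursors[[chrom]])) 10000L else cursors[[chrom]]
    cursors[[chrom]] <- at + as.integer(width) + gap
    c(start = at, end = at + as.integer(width) - 1L)
  }
}

## Exon starts/ends for a transcript spanning from `at`, with the intron
## widths decided by the caller.
layout_exons <- function(widths, at, introns) {
  n <- length(widths)
  starts <- integer(n); ends <- integer(n)
  pos <- as.integer(at)
  for (i in seq_len(n)) {
    starts[i] <- pos
    ends[i] <- pos + widths[i] - 1L
    if (i < n) pos <- ends[i] + introns[i] + 1L
  }
  list(start = starts, end = ends)
}

#' Generate a synthetic multi-tissue transcriptome with planted truth
#'
#' Produces annotation, sequences, expression, fixture databases and a
#' ground-truth table, byte-reproducibly from `config$seed`. Class
#' contracts: `coding` transcripts contain an ATG-initiated ORF of at
#' least 100 amino acids copied (with substitutions at
#' `orf_mutation_rate`) from the protein fixture; `utr_fragment`
#' transcripts lie within 1 kb, same strand, of a planted gene span;
#' `short` transcripts are below 200 bp; `low_expression` transcripts
#' fail the expression filter in every tissue; `true_lncRNA` violate no
#' removal condition (their rescue-planted subset carries both a
#' coding-like ORF and a mutated segment of a lncRNA-database entry, so
#' it is removed by the coding filter and then rescued).
#'
#' @param config a [sim_config()].
#' @return list of class `lnc_sim`: `transcripts` ([transcript_set()]),
#'   `expression` ([expression_matrix()]), `genes` ([gene_spans()]),
#'   `protein_db`, `lnc_db`, `motifs` (named character vectors),
#'   `truth` (data.frame: `transcript_id`, `class`, `expected_fate`,
#'   `expected_rescue`, `planted_tissue`, `non_polya`), `config`.
#' @export
simulate_transcriptome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tiss <- config$tissues
  nt <- nrow(tiss)
  rrna_tissue <- c(which(tiss$library_prep == "rRNA_depleted"), 1L)[1]

  protein_db <- stats::setNames(
    vapply(sample(config$protein_len[1]:config$protein_len[2],
                  config$n_proteins, replace = TRUE),
           random_protein, character(1)),
    sprintf("P%04d", seq_len(config$n_proteins)))
  lnc_db <- random_dna_set(config$n_lnc_db, config$lnc_db_len[1],
                           config$lnc_db_len[2], prefix = "L")
  motifs <- make_motifs(config$n_motifs, protein_db)

  gene_chroms <- paste0("chrS", 1:10)
  other_chroms <- c(paste0("chrS", 11:30),
                    sprintf("chrUn_%04d", 1:4))
  alloc <- make_allocator(gap = 8000L)
  genes <- gene_spans(
    gene_id = sprintf("G%03d", seq_len(config$n_genes)),
    chrom = sample(gene_chroms, config$n_genes, replace = TRUE),
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    start = 0L, end = 0L)
  for (i in seq_len(config$n_genes)) {
    pos <- alloc(genes$chrom[i], sample(2000:10000, 1L))
    genes$start[i] <- pos["start"]; genes$end[i] <- pos["end"]
  }

  n_rescue <- round(config$rescue_fraction * config$n_lncrna)
  classes <- c(rep("coding", config$n_coding),
               rep("true_lncRNA", config$n_lncrna),
               rep("utr_fragment", config$n_utr_fragment),
               rep("short", config$n_short),
               rep("low_expression", config$n_low_expression))
  n <- length(classes)
  ids <- sprintf("TX%05d", seq_len(n))
  lnc_idx <- which(classes == "true_lncRNA")
  rescue_set <- if (n_rescue > 0) lnc_idx[seq_len(n_rescue)] else integer(0)
  planted_pool <- setdiff(lnc_idx, rescue_set)
  n_planted <- round(config$tissue_specific_fraction * config$n_lncrna)
  planted_set <- if (n_planted > 0 && length(planted_pool))
    sample(planted_pool, min(n_planted, length(planted_pool)))
    else integer(0)
  non_polya <- logical(n)
  non_polya[lnc_idx] <- stats::runif(length(lnc_idx)) <
    config$non_polya_fraction

  seqs <- character(n)
  chrom <- character(n); strand <- character(n)
  exon_start <- vector("list", n); exon_end <- vector("list", n)
  planted_tissue <- rep(NA_character_, n)
  low_variant <- logical(n)             # single-exon moderate-TPM lows

  for (i in seq_len(n)) {
    cl <- classes[i]
    if (cl == "coding") {
      pep <- mutate_peptide(protein_db[[sample.int(config$n_proteins, 1L)]],
                            config$orf_mutation_rate)
      seqs[i] <- paste0(random_dna(sample(100:300, 1L)),
                        reverse_translate(pep),
                        random_dna(sample(100:300, 1L)))
      nex <- sample(2:6, 1L)
    } else if (cl == "true_lncRNA" && i %in% rescue_set) {
      pep <- protein_db[[sample.int(config$n_proteins, 1L)]]
      pep <- mutate_peptide(substr(pep, 1L, min(nchar(pep), 180L)),
                            config$orf_mutation_rate)
      entry <- lnc_db[[sample.int(config$n_lnc_db, 1L)]]
      seg_len <- min(nchar(entry) - 10L,
                     max(300L, round(0.8 * 3 * (nchar(pep) + 1L))))
      at <- sample.int(nchar(entry) - seg_len + 1L, 1L)
      seg <- mutate_sequence(substr(entry, at, at + seg_len - 1L),
                             config$rescue_segment_mutation)
      seqs[i] <- paste0(random_dna(sample(50:150, 1L)),
                        reverse_translate(pep), seg,
                        random_dna(sample(50:150, 1L)))
      nex <- sample(2:5, 1L)
    } else if (cl == "true_lncRNA") {
      len <- min(config$lnc_len[2],
                 max(config$lnc_len[1], round(stats::rlnorm(1, log(1200), 0.5))))
      seqs[i] <- random_noncoding_dna(len)
      nex <- if (stats::runif(1) < config$single_exon_fraction) 1L
             else sample(2:5, 1L)
      if (i %in% planted_set)
        planted_tissue[i] <- tiss$name[sample.int(nt, 1L)]
    } else if (cl == "utr_fragment") {
      len <- sample(config$utr_len[1]:config$utr_len[2], 1L)
      seqs[i] <- random_noncoding_dna(len)
      nex <- sample(1:3, 1L)
    } else if (cl == "short") {
      len <- sample(config$short_len[1]:config$short_len[2], 1L)
      seqs[i] <- random_dna(len)
      nex <- 2L
    } else {                            # low_expression
      len <- sample(config$low_len[1]:config$low_len[2], 1L)
      seqs[i] <- random_dna(len)
      low_variant[i] <- stats::runif(1) < 0.2
      nex <- if (low_variant[i]) 1L else sample(1:4, 1L)
    }
    widths <- make_exon_widths(nchar(seqs[i]), nex)
    introns <- if (length(widths) > 1L)
      sample(50:2000, length(widths) - 1L, replace = TRUE) else integer(0)
    spanw <- sum(widths) + sum(introns)
    if (cl == "utr_fragment") {
      g <- genes[sample.int(nrow(genes), 1L), ]
      offset <- sample.int(1000L, 1L)
      downstream <- stats::runif(1) < 0.5 || g$start - offset - spanw < 1L
      at <- if (downstream) g$end + offset
            else g$start - offset - spanw + 1L
      chrom[i] <- g$chrom; strand[i] <- g$strand
      ex <- layout_exons(widths, at, introns)
    } else {
      chrom[i] <- sample(other_chroms, 1L)
      strand[i] <- sample(c("+", "-"), 1L)
      pos <- alloc(chrom[i], spanw)
      ex <- layout_exons(widths, pos["start"], introns)
    }
    exon_start[[i]] <- ex$start; exon_end[[i]] <- ex$end
  }

  expr <- matrix(0, nrow = n, ncol = nt,
                 dimnames = list(ids, tiss$name))
  prep <- tiss$library_prep
  for (i in seq_len(n)) {
    cl <- classes[i]
    single <- length(exon_start[[i]]) == 1L
    if (cl == "low_expression") {
      v <- if (low_variant[i]) stats::runif(nt, 0.1, 1)
           else stats::runif(nt, 0, 0.08)
    } else if (!is.na(planted_tissue[i])) {
      v <- stats::runif(nt, 0, 0.09)
      k <- match(planted_tissue[i], tiss$name)
      v[k] <- max(stats::rlnorm(1, log(20), 0.6), 4)
    } else {
      mu <- config$class_mean_tpm[[cl]] %||% 4
      v <- pmax(stats::rlnorm(nt, log(mu), 1), config$expr_floor)
    }
    if (non_polya[i]) {
      v[prep == "polyA"] <- v[prep == "polyA"] * config$polya_attenuation
      v[prep == "ovation"] <- v[prep == "ovation"] *
        config$ovation_attenuation
    }
    ## post-attenuation detection guarantees, so every class meets its
    ## intended filter fate exactly: planted transcripts stay detectable
    ## (and, if single-exon, above the 5 TPM rule) in their tissue;
    ## other single-exon survivors clear 5 TPM in one library; rows
    ## never drift under the 0.1 TPM mean threshold
    if (cl != "low_expression") {
      if (!is.na(planted_tissue[i])) {
        k <- match(planted_tissue[i], tiss$name)
        v[k] <- max(v[k], if (single) 5.5 else 1)
      } else if (single) {
        v[rrna_tissue] <- max(v[rrna_tissue], 5.5)
      }
      if (mean(v) < 0.12) v <- v * (0.12 / mean(v))
    }
    expr[i, ] <- v
  }

  category <- sample(c("novel_I", "novel_II", "novel_III", "intergenic",
                       "known_lncRNA"), n, replace = TRUE,
                     prob = c(0.136, 0.012, 0.075, 0.713, 0.064))
  records <- transcript_set(
    transcript_id = ids, gene_id = paste0("G", ids),
    category = category, chrom = chrom, strand = strand,
    exon_start = exon_start, exon_end = exon_end, sequence = seqs)

  truth <- data.frame(
    transcript_id = ids,
    class = classes,
    expected_fate = c(coding = "F3", true_lncRNA = "final",
                      utr_fragment = "F4", short = "F2",
                      low_expression = "F1")[classes],
    expected_rescue = seq_len(n) %in% rescue_set,
    planted_tissue = planted_tissue,
    non_polya = non_polya,
    stringsAsFactors = FALSE)

  structure(list(
    transcripts = records,
    expression = expression_matrix(expr, tiss),
    genes = genes,
    protein_db = protein_db,
    lnc_db = lnc_db,
    motifs = motifs,
    truth = truth,
    config = config), class = "lnc_sim")
}

## Random fixed-residue Prosite-style motifs guaranteed absent from the
## bundled proteins (so motif evidence never fires spuriously in the
## planted-truth regime).
make_motifs <- function(n_motifs, protein_db) {
  out <- character(0)
  tries <- 0L
  while (length(out) < n_motifs && tries < 1000L) {
    tries <- tries + 1L
    pat <- paste(sample(AA20, 8L, replace = TRUE), collapse = "-")
    rx <- prosite_to_regex(pat)
    if (!any(vapply(protein_db, grepl, logical(1), pattern = rx)))
      out <- c(out, pat)
  }
  stats::setNames(out, sprintf("M%03d", seq_along(out)))
}

#' @export
print.lnc_sim <- function(x, ...) {
  cat("lnc_sim (seed", x$config$seed, "):",
      nrow(x$transcripts), "transcripts,",
      nrow(x$expression$tissues), "tissues\n")
  print(table(x$truth$class))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the exact plain-text formats the pipeline consumes:
#' `transcripts.gtf`, `transcripts.fa`, `expression.tsv`, `tissues.tsv`,
#' `genes.bed` (BED6 gene spans), `proteins.faa`, `lnc_db.fa`,
#' `motifs.txt`, `truth.tsv`. Byte-identical for a fixed seed.
#'
#' @param sim an `lnc_sim`.
#' @param dir output directory (created if needed).
#' @return invisibly, a named vector of the paths written.
#' @export
write_sim <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_results(sim$transcripts, gtf_path = p("transcripts.gtf"))
  fa <- Biostrings::DNAStringSet(
    stats::setNames(sim$transcripts$sequence,
                    sim$transcripts$transcript_id))
  Biostrings::writeXStringSet(fa, p("transcripts.fa"))
  expr_tab <- data.frame(transcript_id = rownames(sim$expression$values),
                         sim$expression$values, check.names = FALSE)
  utils::write.table(expr_tab, p("expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(sim$expression$tissues, p("tissues.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  bed6 <- data.frame(sim$genes$chrom, sim$genes$start - 1L,
                     sim$genes$end, sim$genes$gene_id, 0L,
                     sim$genes$strand)
  utils::write.table(bed6, p("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  Biostrings::writeXStringSet(
    Biostrings::AAStringSet(sim$protein_db), p("proteins.faa"))
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(sim$lnc_db), p("lnc_db.fa"))
  writeLines(paste(names(sim$motifs), sim$motifs), p("motifs.txt"))
  utils::write.table(sim$truth, p("truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(stats::setNames(
    p(c("transcripts.gtf", "transcripts.fa", "expression.tsv",
        "tissues.tsv", "genes.bed", "proteins.faa", "lnc_db.fa",
        "motifs.txt", "truth.tsv")),
    c("gtf", "fasta", "expression", "tissues", "genes", "proteins",
      "lnc_db", "motifs", "truth")))
}

#' Degrade a simulated dataset for robustness testing
#'
#' Applies point substitutions to every transcript sequence and
#' multiplicative log-normal jitter to the expression matrix. At zero
#' noise the input is returned unchanged (bit-identical).
#'
#' @param sim an `lnc_sim`.
#' @param mutation_rate per-base substitution probability (default 0).
#' @param expression_jitter_sd sd of the log-normal expression jitter
#'   (default 0).
#' @param seed seed of the perturbation (default 1).
#' @return the perturbed `lnc_sim`.
#' @export
perturb_dataset <- function(sim, mutation_rate = 0,
                            expression_jitter_sd = 0, seed = 1) {
  stopifnot(mutation_rate >= 0, expression_jitter_sd >= 0)
  if (mutation_rate == 0 && expression_jitter_sd == 0) return(sim)
  set.seed(seed)
  if (mutation_rate > 0) {
    sim$transcripts$sequence <- vapply(sim$transcripts$sequence,
                                       mutate_sequence, character(1),
                                       rate = mutation_rate,
                                       USE.NAMES = FALSE)
    sim$transcripts$gc_percent <- gc_percent(sim$transcripts$sequence)
  }
  if (expression_jitter_sd > 0) {
    v <- sim$expression$values
    jit <- matrix(stats::rlnorm(length(v), 0, expression_jitter_sd),
                  nrow = nrow(v))
    sim$expression$values <- v * jit
  }
  sim
}
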