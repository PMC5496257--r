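## Shared small fixtures, built in code. The moderate simulation is
## cached per test run (several files exercise it).

.fixture_cache <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.fixture_cache$sim)) {
    cfg <- sim_config(seed = 7, n_coding = 60, n_lncrna = 120,
                      n_utr_fragment = 40, n_short = 30,
                      n_low_expression = 40, n_genes = 20,
                      n_proteins = 20, n_lnc_db = 10)
    .fixture_cache$sim <- simulate_transcriptome(cfg)
  }
  .fixture_cache$sim
}

small_run <- function() {
  if (is.null(.fixture_cache$run)) {
    sim <- small_sim()
    .fixture_cache$run <- suppressMessages(run_pipeline(
      sim$transcripts, sim$expression, genes = sim$genes,
      protein_db = sim$protein_db, motifs = sim$motifs,
      lnc_db = sim$lnc_db))
  }
  .fixture_cache$run
}

## A tiny two-transcript GTF written to a temp file.
write_toy_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtf_exon_line <- function(chrom, start, end, strand, tx,
                          gene = paste0("g_", tx), category = NULL) {
  attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene, tx)
  if (!is.null(category))
    attrs <- paste0(attrs, sprintf(' category "%s";', category))
  paste(chrom, "test", "exon", start, end, ".", strand, ".", attrs,
        sep = "\t")
}

## Deterministic reverse translation (first codon of each synonym set)
## plus a stop, for building coding fixtures without touching the RNG.
reverse_translate_fixture <- function(pep) {
  gc <- Biostrings::GENETIC_CODE
  syn <- split(names(gc), unname(gc))
  ch <- strsplit(pep, "")[[1]]
  paste0(paste(vapply(ch, function(a) syn[[a]][1], character(1)),
               collapse = ""), "TAA")
}

rbind_records <- function(...) {
  out <- do.call(rbind, lapply(list(...), as.data.frame))
  class(out) <- c("transcript_set", "data.frame")
  rownames(out) <- NULL
  out
}

## Random transcript structures for round-trip properties.
random_structures <- function(n, seed) {
  set.seed(seed)
  ids <- sprintf("RT%05d", seq_len(n))
  exon_start <- vector("list", n)
  exon_end <- vector("list", n)
  chrom <- sample(paste0("chr", 1:5), n, replace = TRUE)
  strand <- sample(c("+", "-", "*"), n, replace = TRUE,
                   prob = c(0.45, 0.45, 0.1))
  for (i in seq_len(n)) {
    k <- sample(1:6, 1)
    w <- sample(30:400, k, replace = TRUE)
    gaps <- if (k > 1) sample(50:5000, k - 1, replace = TRUE) else integer(0)
    s0 <- sample(1:1e6, 1)
    st <- integer(k); en <- integer(k); pos <- s0
    for (j in seq_len(k)) {
      st[j] <- pos; en[j] <- pos + w[j] - 1L
      if (j < k) pos <- en[j] + gaps[j] + 1L
    }
    exon_start[[i]] <- st; exon_end[[i]] <- en
  }
  transcript_set(ids, chrom, strand, exon_start, exon_end,
                 category = sample(c("intergenic", "novel_I"), n, TRUE))
}
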