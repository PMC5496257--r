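test_that("simulation is byte-identical for a fixed seed", {
  cfg <- sim_config(seed = 42, n_coding = 15, n_lncrna = 30,
                    n_utr_fragment = 10, n_short = 8,
                    n_low_expression = 10, n_genes = 8,
                    n_proteins = 10, n_lnc_db = 6)
  d1 <- tempfile(); d2 <- tempfile()
  write_sim(simulate_transcriptome(cfg), d1)
  write_sim(simulate_transcriptome(cfg), d2)
  files <- list.files(d1)
  expect_gt(length(files), 5)
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  ## a different seed changes the data
  cfg2 <- sim_config(seed = 43, n_coding = 15, n_lncrna = 30,
                     n_utr_fragment = 10, n_short = 8,
                     n_low_expression = 10, n_genes = 8,
                     n_proteins = 10, n_lnc_db = 6)
  sim2 <- simulate_transcriptome(cfg2)
  sim1 <- simulate_transcriptome(cfg)
  expect_false(identical(sim1$transcripts$sequence,
                         sim2$transcripts$sequence))
})

test_that("generated classes respect their structural contracts", {
  sim <- small_sim()
  tr <- sim$transcripts
  truth <- sim$truth

  short_ids <- truth$transcript_id[truth$class == "short"]
  expect_true(all(tr$length_bp[tr$transcript_id %in% short_ids] < 200))
  other_ids <- truth$transcript_id[truth$class != "short"]
  expect_true(all(tr$length_bp[tr$transcript_id %in% other_ids] >= 200))

  ## low-expression class fails filter 1 in every configuration
  low <- truth$transcript_id[truth$class == "low_expression"]
  v <- sim$expression$values[low, , drop = FALSE]
  nex <- lengths(tr$exon_start)[match(low, tr$transcript_id)]
  expect_true(all(rowMeans(v) < 0.1 | (nex == 1 & apply(v, 1, max) < 5)))

  ## every coding transcript carries a long sense ORF matching the db
  coding <- truth$transcript_id[truth$class == "coding"]
  for (id in sample(coding, 10)) {
    orfs <- find_orfs(tr$sequence[tr$transcript_id == id], min_aa = 100)
    expect_gt(nrow(orfs), 0)
  }

  ## true lncRNA outside the rescue subset have no long ORF at all
  lnc <- truth$transcript_id[truth$class == "true_lncRNA" &
                               !truth$expected_rescue]
  for (id in sample(lnc, 10)) {
    expect_equal(nrow(find_orfs(tr$sequence[tr$transcript_id == id],
                                min_aa = 100)), 0)
  }
})

test_that("UTR fragments all sit within 1 kb same-strand of a gene", {
  sim <- small_sim()
  utr_ids <- sim$truth$transcript_id[sim$truth$class == "utr_fragment"]
  utr <- sim$transcripts[sim$transcripts$transcript_id %in% utr_ids, ]
  class(utr) <- c("transcript_set", "data.frame")
  ## verified with the quadratic interval oracle on extended spans
  ext <- extend_span(sim$genes, 1000)
  spans <- data.frame(
    chrom = utr$chrom,
    start = vapply(utr$exon_start, min, integer(1)),
    end = vapply(utr$exon_end, max, integer(1)))
  ov <- oracle_overlaps(spans, ext[, c("chrom", "start", "end")])
  strand_ok <- utr$strand[ov$a] == ext$strand[ov$b]
  expect_setequal(unique(ov$a[strand_ok]), seq_len(nrow(utr)))

  ## and the filter agrees
  out <- apply_filter4(utr, sim$genes)
  expect_equal(nrow(out$retained), 0L)
})

test_that("planted tissue-specific lncRNA are exactly the unique presences", {
  sim <- small_sim()
  planted <- sim$truth[!is.na(sim$truth$planted_tissue), ]
  expect_gt(nrow(planted), 0)
  lnc_ids <- sim$truth$transcript_id[sim$truth$class == "true_lncRNA"]
  e <- expression_matrix(
    sim$expression$values[lnc_ids, , drop = FALSE],
    sim$expression$tissues)
  up <- uniquely_present(e)
  for (k in names(up)) {
    expect_setequal(up[[k]],
                    planted$transcript_id[planted$planted_tissue == k])
  }
})

test_that("polyA capture detects fewer expressed lncRNA than rRNA depletion", {
  sim <- small_sim()
  lnc_ids <- sim$truth$transcript_id[sim$truth$class == "true_lncRNA"]
  e <- expression_matrix(sim$expression$values[lnc_ids, , drop = FALSE],
                         sim$expression$tissues)
  prep <- sim$expression$tissues
  n_expr <- vapply(prep$name, function(k) length(expressed_set(e, k)),
                   integer(1))
  expect_lt(max(n_expr[prep$library_prep == "polyA"]),
            min(n_expr[prep$library_prep == "rRNA_depleted"]))
})

test_that("infeasible configurations are rejected", {
  expect_error(sim_config(short_len = c(200, 300)), "infeasible")
  expect_error(sim_config(lnc_len = c(100, 400)), "infeasible")
  expect_error(sim_config(n_coding = -1), ">= 0")
})

test_that("perturbation at zero noise is the identity", {
  sim <- small_sim()
  expect_identical(perturb_dataset(sim, 0, 0), sim)
})

test_that("ORF mutation erodes coding-filter removals monotonically", {
  sim <- small_sim()
  coding_ids <- sim$truth$transcript_id[sim$truth$class == "coding"]
  sub <- sim$transcripts[sim$transcripts$transcript_id %in%
                           coding_ids[1:25], ]
  class(sub) <- c("transcript_set", "data.frame")
  removed <- vapply(c(0, 0.15, 0.45), function(rate) {
    mini <- sim
    mini$transcripts <- sub
    pert <- perturb_dataset(mini, mutation_rate = rate, seed = 5)
    out <- apply_filter3(pert$transcripts, sim$protein_db,
                         motifs = sim$motifs)
    nrow(out$removed)
  }, numeric(1))
  expect_equal(removed[1], 25)
  expect_true(all(diff(removed) <= 0))
  expect_lt(removed[3], removed[1])
})

test_that("expression jitter alone leaves sequence-based filters unchanged", {
  sim <- small_sim()
  pert <- perturb_dataset(sim, mutation_rate = 0,
                          expression_jitter_sd = 0.5, seed = 9)
  expect_identical(pert$transcripts$sequence, sim$transcripts$sequence)
  f2a <- apply_filter2(sim$transcripts)
  f2b <- apply_filter2(pert$transcripts)
  expect_identical(f2a$removed$transcript_id, f2b$removed$transcript_id)
})
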