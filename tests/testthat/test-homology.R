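test_that("self-alignment gives full identity and coverage", {
  set.seed(31)
  db <- random_dna_set(5, 300, 800, prefix = "D")
  h <- align_nucleotide(db[2], db)
  expect_equal(h$subject_id[1], names(db)[2])
  expect_equal(h$percent_identity[1], 100)
  expect_equal(h$percent_query_coverage[1], 100)
  expect_lt(h$evalue[1], 1e-50)

  ## query = first half of an entry: full query coverage
  q <- substr(db[[1]], 1, nchar(db[[1]]) %/% 2)
  h2 <- align_nucleotide(c(half = q), db)
  expect_equal(h2$subject_id[1], names(db)[1])
  expect_equal(h2$percent_identity[1], 100)
  expect_equal(h2$percent_query_coverage[1], 100)

  expect_warning(h3 <- align_nucleotide(c(tiny = "ACGTACGT"), db),
                 "shorter than 20")
  expect_equal(nrow(h3), 0L)
  expect_warning(h4 <- align_nucleotide(db[1], character(0)), "empty")
  expect_equal(nrow(h4), 0L)
})

test_that("random queries almost never reach e-value 1e-5", {
  set.seed(55)
  db <- random_dna_set(20, 500, 1000, prefix = "U")
  n_hit <- 0L
  for (trial in 1:100) {
    q <- setNames(paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                        collapse = ""), "q")
    h <- align_nucleotide(q, db, evalue_max = 1e-5)
    if (nrow(h)) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 1L)
})

test_that("rescue applies its thresholds strictly", {
  rec <- transcript_set(c("a", "b", "c"), "chr1", "+",
                        exon_start = list(1L, 1L, 1L),
                        exon_end = list(400L, 400L, 400L))
  mk_hit <- function(id, ident, cov, ev = 1e-6) {
    data.frame(query_id = id, subject_id = "L1",
               percent_identity = ident, percent_query_coverage = cov,
               score = 100, bitscore = 50, evalue = ev)
  }
  hits <- rbind(mk_hit("a", 76, 26),        # over both -> rescued
                mk_hit("b", 75, 90),        # identity not OVER 75
                mk_hit("c", 90, 25))        # coverage not OVER 25
  resc <- rescue_transcripts(rec, lnc_db = NULL, hits = hits)
  expect_equal(resc$transcript_id, "a")

  ## e-value must beat the cutoff too
  hits2 <- mk_hit("a", 90, 90, ev = 1e-4)
  expect_equal(nrow(rescue_transcripts(rec, NULL, hits = hits2)), 0L)
})

test_that("rescue recovers planted homologs end to end and stays a subset", {
  set.seed(88)
  lnc_db <- random_dna_set(6, 600, 1200, prefix = "L")
  ## transcript embedding a mutated 50% slice of a db entry
  seg <- substr(lnc_db[[3]], 1, 500)
  seg <- mutate_sequence(seg, 0.08)
  planted <- paste0(paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                          collapse = ""),
                    seg,
                    paste(sample(c("A", "C", "G", "T"), 250, TRUE),
                          collapse = ""))
  unrelated <- paste(sample(c("A", "C", "G", "T"), 900, TRUE), collapse = "")
  rec <- transcript_set(c("planted", "unrelated"), "chr1", "+",
                        exon_start = list(1L, 1L),
                        exon_end = list(nchar(planted), nchar(unrelated)))
  rec <- attach_sequences(rec, c(planted = planted, unrelated = unrelated))
  resc <- rescue_transcripts(rec, lnc_db)
  expect_equal(resc$transcript_id, "planted")
  expect_true(all(resc$transcript_id %in% rec$transcript_id))
  h <- attr(resc, "hits")
  expect_gt(h$percent_identity[1], 75)
  expect_gt(h$percent_query_coverage[1], 25)

  ## empty database rescues nothing
  expect_warning(none <- rescue_transcripts(rec, character(0)))
  expect_equal(nrow(none), 0L)
})

test_that("conservation curve handles the degenerate regimes", {
  set.seed(14)
  db <- random_dna_set(4, 300, 600, prefix = "H")
  ## queries identical to db entries: all scores 100, CDF a step at 100
  cc <- conservation_curve(setNames(unname(db), paste0("q", 1:4)), db)
  expect_equal(unname(cc$scores), rep(100, 4))
  expect_equal(cc$no_hit_fraction, 0)
  expect_equal(curve_at(cc, 99.9), 0)
  expect_equal(curve_at(cc, 100), 1)

  ## no query hits: curve starts (and stays) at 1
  rand <- setNames(vapply(1:5, function(i)
    paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = ""),
    character(1)), paste0("r", 1:5))
  cc2 <- conservation_curve(rand, db)
  expect_equal(cc2$no_hit_fraction, 1)
  expect_equal(unname(cc2$scores), rep(0, 5))
  expect_equal(curve_at(cc2, 0), 1)
})

test_that("conservation curve equals a direct recomputation from hits", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q2", "q4"),
    subject_id = c("s1", "s2", "s1", "s3"),
    percent_identity = c(90, 99, 50, 80),
    percent_query_coverage = c(100, 40, 80, 50),
    score = c(500, 400, 200, 300),
    bitscore = c(310, 250, 125, 190),
    evalue = c(1e-80, 1e-60, 1e-20, 1e-40))
  queries <- setNames(rep(strrep("ACGT", 30), 4), paste0("q", 1:4))
  cc <- conservation_curve(queries, NULL, hits = hits)
  ## best hit per query by bitscore: q1 -> 90*100/100, q2 -> 50*80/100,
  ## q3 -> no hit, q4 -> 80*50/100
  expect_equal(unname(cc$scores), c(90, 40, 0, 40))
  expect_equal(cc$no_hit_fraction, 0.25)
  expect_equal(cc$curve$score, c(0, 40, 90))
  expect_equal(cc$curve$cumulative_fraction, c(0.25, 0.75, 1))
  ## cumulative fraction is non-decreasing and ends at 1
  expect_true(all(diff(cc$curve$cumulative_fraction) >= 0))
  expect_equal(utils::tail(cc$curve$cumulative_fraction, 1), 1)
})
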