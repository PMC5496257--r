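expr_fixture <- function(values) {
  expression_matrix(values)
}

test_that("expressed_set is strict at the 0.1 TPM boundary", {
  v <- matrix(c(0.1, 0.11, 0), 3, 1,
              dimnames = list(c("at", "above", "zero"), "liver"))
  e <- expr_fixture(v)
  expect_equal(expressed_set(e, "liver"), "above")
  expect_error(expressed_set(e, "kidney"), "unknown tissue")
  expect_length(expressed_set(expr_fixture(
    matrix(0, 2, 1, dimnames = list(c("a", "b"), "t"))), "t"), 0)
})

test_that("unique presence is inclusive, unique absence strict", {
  v <- matrix(c(0.5, 0.01, 0.02,     # uniquely present in t1
                0.5, 0.5,  0,        # present in two -> nowhere
                0.1, 0.09, 0.09),    # at exactly 0.1 -> uniquely present
              nrow = 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("t1", "t2", "t3")))
  up <- uniquely_present(expr_fixture(v))
  expect_setequal(up$t1, c("a", "c"))
  expect_length(unlist(up[c("t2", "t3")]), 0)
  ## disjointness across tissues
  expect_equal(anyDuplicated(unlist(up)), 0L)

  v2 <- matrix(c(0.01, 0.5, 0.5,     # uniquely absent in t1
                 0.01, 0.5, 0.1),    # t3 not ABOVE 0.1 -> nowhere
               nrow = 2, byrow = TRUE,
               dimnames = list(c("x", "y"), c("t1", "t2", "t3")))
  ua <- uniquely_absent(expr_fixture(v2))
  expect_equal(ua$t1, "x")
  expect_length(unlist(ua[c("t2", "t3")]), 0)
})

test_that("one transcript can be uniquely absent and uniquely present", {
  v <- matrix(c(0.01, 5), 1, 2, dimnames = list("t", c("a", "b")))
  e <- expr_fixture(v)
  expect_equal(uniquely_absent(e)$a, "t")
  expect_equal(uniquely_present(e)$b, "t")
})

test_that("variable-transcript selection applies sum and sd thresholds", {
  v <- matrix(c(200, 0,      # sum 200, sd 141.4 -> selected
                60, 60,      # sum 120 but sd 0
                30, 30),     # neither
              nrow = 3, byrow = TRUE,
              dimnames = list(c("sel", "flat", "low"), c("t1", "t2")))
  got <- select_variable(expr_fixture(v))
  expect_equal(got, "sel")
  ## the hand-computed sample sd of (200, 0)
  expect_equal(stats::sd(c(200, 0)), 141.4214, tolerance = 1e-4)
})

test_that("bi-clustering merges identical profiles first and is deterministic", {
  v <- matrix(c(1, 2, 3, 4,
                1, 2, 3, 4,       # identical to row 1
                9, 1, 4, 0,
                2, 4, 6, 8),      # identical ranks to rows 1-2
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("tx", 1:4), paste0("ti", 1:4)))
  suppressWarnings(bc <- bicluster(expr_fixture(v)))
  m <- bc$transcript_tree$merge[1, ]
  expect_setequal(m, c(-1L, -2L))            # distance-0 pair merged first
  expect_equal(bc$transcript_tree$height[1], 0)

  bc2 <- suppressWarnings(bicluster(expr_fixture(v)))
  expect_identical(bc$transcript_order, bc2$transcript_order)
  expect_identical(bc$tissue_order, bc2$tissue_order)

  ## tissues with identical rank profiles have Spearman distance 0
  expect_equal(bc$tissue_tree$height[1], 0)
})

test_that("tissue trees match the naive average-linkage oracle", {
  set.seed(606)
  for (rep in 1:20) {
    v <- matrix(rlnorm(20 * 5, 1, 1), 20, 5,
                dimnames = list(sprintf("g%02d", 1:20), sprintf("t%d", 1:5)))
    bc <- bicluster(expr_fixture(v))
    d <- 1 - stats::cor(v, method = "spearman")
    orc <- oracle_average_linkage(d)
    expect_equal(
      as.vector(stats::cophenetic(bc$tissue_tree)),
      as.vector(stats::as.dist(orc$cophenetic)), tolerance = 1e-12)
    expect_equal(canonical_hclust_order(bc$tissue_tree), orc$order)
  }
})

test_that("zero-variance rows get maximum distance with a warning", {
  v <- matrix(c(5, 5, 5,
                1, 2, 3,
                3, 1, 9), nrow = 3, byrow = TRUE,
              dimnames = list(c("flat", "a", "b"), c("t1", "t2", "t3")))
  expect_warning(bc <- bicluster(expr_fixture(v)), "zero-variance")
  d <- stats::cophenetic(bc$transcript_tree)
  expect_equal(max(d), 2)
})

test_that("newick export writes one tree per dendrogram", {
  set.seed(2)
  v <- matrix(rlnorm(30, 1, 1), 6, 5,
              dimnames = list(paste0("g", 1:6), paste0("t", 1:5)))
  bc <- bicluster(expr_fixture(v))
  f1 <- tempfile(fileext = ".nwk"); f2 <- tempfile(fileext = ".nwk")
  write_newick(bc, f1, f2)
  t1 <- ape::read.tree(f1); t2 <- ape::read.tree(f2)
  expect_setequal(t1$tip.label, paste0("g", 1:6))
  expect_setequal(t2$tip.label, paste0("t", 1:5))
})

test_that("tissue report counts, ratios and cumulative TPM are consistent", {
  v <- matrix(c(5, 0.05,
                0.2, 0.2,
                8, 7,
                0.01, 3), nrow = 4, byrow = TRUE,
              dimnames = list(c("l1", "l2", "c1", "c2"), c("t1", "t2")))
  e <- expr_fixture(v)
  rep_ <- tissue_report(e, lnc_ids = c("l1", "l2"),
                        coding_ids = c("c1", "c2"))
  expect_equal(rep_$n_expressed_lnc, c(2, 1))
  expect_equal(rep_$n_expressed_coding, c(1, 2))
  expect_equal(rep_$ratio, c(2, 0.5))
  expect_equal(rep_$cumulative_tpm_lnc, c(5.2, 0.2))
  expect_equal(rep_$n_uniquely_present, c(1, 0))   # l1 only
  expect_equal(rep_$cum_tpm_uniquely_present, c(5, 0))

  ## permutation invariance in transcript order
  e2 <- expr_fixture(v[c(3, 1, 4, 2), ])
  rep2 <- tissue_report(e2, c("l1", "l2"), c("c1", "c2"))
  expect_equal(rep_, rep2)
})
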