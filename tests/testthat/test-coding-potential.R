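test_that("find_orfs honours the 100-aa floor and reports coordinates", {
  s <- paste0("ATG", strrep("GCT", 99), "TAA")
  orfs <- find_orfs(s, min_aa = 100)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$peptide, paste0("M", strrep("A", 99)))
  expect_equal(orfs$length_aa, 100L)
  expect_false(orfs$partial)
  ## stop codon included: span is 3 * (aa + 1)
  expect_equal(orfs$end - orfs$start + 1L, 3L * 101L)

  ## one codon short of the floor
  s2 <- paste0("ATG", strrep("GCT", 98), "TAA")
  expect_equal(nrow(find_orfs(s2, min_aa = 100)), 0L)

  ## no terminating stop: reported partial, span 3 * aa
  s3 <- paste0("ATG", strrep("GCT", 100))
  orfs3 <- find_orfs(s3, min_aa = 100)
  expect_true(orfs3$partial)
  expect_equal(orfs3$end - orfs3$start + 1L, 3L * 101L)

  ## an N codon breaks the ORF
  s4 <- paste0("ATG", strrep("GCT", 50), "NNN", strrep("GCT", 60), "TAA")
  expect_equal(nrow(find_orfs(s4, min_aa = 100)), 0L)
})

test_that("find_orfs maps antisense ORFs back to sense coordinates", {
  core <- paste0("ATG", strrep("GCT", 99), "TAA")
  s <- paste0("AAAA", as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(core))), "CC")
  orfs <- find_orfs(s, min_aa = 100)
  expect_equal(orfs$strand, "antisense")
  expect_equal(orfs$start, 5L)                 # after the AAAA leader
  expect_equal(orfs$end, 5L + 303L - 1L)
  sub <- substr(s, orfs$start, orfs$end)
  expect_equal(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(sub))), core)
})

test_that("find_orfs matches the brute-force six-frame oracle", {
  set.seed(404)
  for (rep in 1:60) {
    len <- sample(150:1500, 1)
    s <- paste(sample(c("A", "C", "G", "T", if (rep %% 5 == 0) "N"),
                      len, replace = TRUE), collapse = "")
    min_aa <- sample(c(10, 25, 40), 1)
    got <- find_orfs(s, min_aa = min_aa)
    got <- got[order(got$strand, got$frame, got$start), , drop = FALSE]
    want <- oracle_orfs(s, min_aa = min_aa)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got[, c("strand", "frame", "start", "end",
                           "peptide", "length_aa", "partial")],
                   want[, c("strand", "frame", "start", "end",
                            "peptide", "length_aa", "partial")])
    }
  }
})

test_that("protein self-search always retrieves itself", {
  set.seed(12)
  db <- setNames(
    vapply(sample(50:200, 12, replace = TRUE), function(l)
      paste0("M", paste(sample(c("A", "R", "N", "D", "C", "Q", "E", "G",
                                 "H", "I", "L", "K", "F", "P", "S", "T",
                                 "W", "Y", "V"), l - 1, TRUE), collapse = "")),
      character(1)),
    sprintf("P%02d", 1:12))
  for (id in names(db)) {
    hits <- search_protein_db(db[[id]], db)
    expect_equal(hits$subject_id[1], id)
    expect_lt(hits$evalue[1], 1e-3)
    expect_equal(hits$percent_identity[1], 100)
  }
  expect_error(search_protein_db("", db), "empty peptide")
  expect_warning(h0 <- search_protein_db("MKVLAW", character(0)),
                 "empty protein database")
  expect_equal(nrow(h0), 0L)
})

test_that("random peptides almost never hit an unrelated database", {
  set.seed(77)
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  db <- setNames(vapply(1:100, function(i)
    paste(sample(aa, 100, TRUE), collapse = ""), character(1)),
    sprintf("R%03d", 1:100))
  n_hit <- 0L
  for (trial in 1:100) {
    q <- paste(sample(aa, 100, TRUE), collapse = "")
    h <- search_protein_db(q, db)
    if (any(h$evalue < 1e-3)) n_hit <- n_hit + 1L
  }
  expect_lte(n_hit, 1L)      # >= 99% of trials hit-free
})

test_that("Prosite patterns convert to regular expressions faithfully", {
  expect_true(grepl(prosite_to_regex("C-G-H-C"), "AAACGHCAAA"))
  expect_false(grepl(prosite_to_regex("C-G-H-C"), "AAACGHAAAA"))
  expect_equal(prosite_to_regex("<M-x(2)-[DE]-{P}(1,3)-W>."),
               "^M.{2}[DE][^P]{1,3}W$")
  expect_error(prosite_to_regex("C-?-H"), "malformed")

  ## wildcard repeats agree with a direct regex oracle
  set.seed(9)
  pep <- paste(sample(c("A", "C", "D", "E", "W"), 400, TRUE), collapse = "")
  expect_equal(grepl(prosite_to_regex("W-x(2)-C"), pep),
               grepl("W.{2}C", pep))
  expect_equal(
    vapply(1:5, function(k)
      grepl(prosite_to_regex(sprintf("A-x(%d)-D", k)), pep), logical(1)),
    vapply(1:5, function(k)
      grepl(sprintf("A.{%d}D", k), pep), logical(1)))
})

test_that("match_motifs reports matches with conclusive e-value", {
  hits <- match_motifs("MAAACGHCAAA", c(zf = "C-G-H-C"))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$evalue, 0)
  expect_equal(hits$source, "motif")
  expect_equal(nrow(match_motifs("MAAA", character(0))), 0L)
})

test_that("filter 3 removes only long ORFs with protein evidence", {
  prot <- paste0("M", paste(rep(c("K", "V", "L", "A", "W", "D"), 25),
                            collapse = ""))      # 151 aa
  db <- c(ref = prot)
  mk_tx <- function(id, seq) {
    r <- transcript_set(id, "chr1", "+", list(1L), list(nchar(seq)))
    attach_sequences(r, setNames(seq, id))
  }
  with_hit <- mk_tx("hit", paste0("GGGG", reverse_translate_fixture(prot),
                                  "CCCC"))
  no_hit <- mk_tx("nohit", paste0("ATG", strrep("GGA", 150), "TAA"))
  short_orf <- mk_tx("short", paste0("ATG",
                                     reverse_translate_fixture(
                                       substr(prot, 2, 80)), "TAA"))

  out <- apply_filter3(rbind_records(with_hit, no_hit, short_orf), db)
  expect_equal(out$removed$transcript_id, "hit")
  expect_setequal(out$retained$transcript_id, c("nohit", "short"))

  ## a motif match alone is sufficient evidence
  out2 <- apply_filter3(no_hit, db = NULL, motifs = c(m = "G-G-G-G-G"))
  expect_equal(out2$removed$transcript_id, "nohit")

  ## monotonicity: removing db entries never removes more transcripts
  out3 <- apply_filter3(rbind_records(with_hit, no_hit, short_orf),
                        db = character(0))
  expect_equal(nrow(out3$removed), 0L)
})

test_that("transcripts without sequence pass filter 3 untouched", {
  rec <- transcript_set("naked", "chr1", "+", list(1L), list(500L))
  expect_message(out <- apply_filter3(rec, db = c(p = "MKVLAW")),
                 "without sequence")
  expect_equal(out$retained$transcript_id, "naked")
})
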