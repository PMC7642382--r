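# genome with a known donor context: exon ends ...CAG | intron GTAAGT...
scoring_genome <- function() {
  set.seed(61)
  g <- random_genome(3000, seed = 61)
  substr(g, 1028, 1036) <- "CAGGTAAGT" # donor window for intron start 1031
  g
}

test_that("donor 9-mers are 3 exonic + 6 intronic bases", {
  fa <- fixture_genome(scoring_genome())
  s <- extract_site_sequence(fa, "chrT", 1031, "donor", "+")
  expect_equal(nchar(s), 9L)
  expect_equal(s, "CAGGTAAGT")
})

test_that("minus-strand windows are reverse-complemented to transcript 5'->3'", {
  g <- scoring_genome()
  fa <- fixture_genome(g)
  # a minus-strand donor whose first intronic base is genomic position 1031+?
  # pick boundary 2000: window [1995, 2003] reverse-complemented
  s <- extract_site_sequence(fa, "chrT", 2000, "donor", "-")
  win <- substr(g, 1995, 2003)
  expect_equal(s, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(win))))
  expect_equal(nchar(s), 9L)
})

test_that("acceptor 23-mers end with the first three exonic bases", {
  g <- scoring_genome()
  fa <- fixture_genome(g)
  # intron ends at 1230 on the plus strand; exon starts at 1231
  s <- extract_site_sequence(fa, "chrT", 1230, "acceptor", "+")
  expect_equal(nchar(s), 23L)
  expect_equal(substr(s, 21, 23), substr(g, 1231, 1233))
  expect_equal(substr(s, 1, 20), substr(g, 1211, 1230))
})

test_that("windows beyond contig bounds raise a boundary error", {
  fa <- fixture_genome(random_genome(100, seed = 1))
  expect_error(extract_site_sequence(fa, "chrT", 2, "donor", "+"), "bounds")
  expect_error(extract_site_sequence(fa, "chrT", 99, "acceptor", "-"),
               "bounds")
})

test_that("a degenerate training set gives its 9-mer the maximum score", {
  m <- splice_site_model_from_seqs(rep("CAGGTAAGT", 100), "donor")
  smax <- glance(m)$max_score
  expect_equal(score_sequence(m, "CAGGTAAGT"), smax)
  expect_lt(score_sequence(m, "AAAAAAAAA"), smax)
})

test_that("uniform random training collapses scores towards zero", {
  set.seed(67)
  seqs <- vapply(1:10000, function(i) {
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
  }, character(1))
  m <- splice_site_model_from_seqs(seqs, "donor")
  probes <- vapply(1:50, function(i) {
    paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE), collapse = "")
  }, character(1))
  scores <- vapply(probes, function(s) score_sequence(m, s), numeric(1))
  expect_true(all(abs(scores) < 0.5))
})

test_that("trained donor model separates canonical sites from random 9-mers", {
  # synthetic annotation with GT-AG introns whose donors share a consensus
  set.seed(71)
  n_tx <- 120
  g <- random_genome(200000, seed = 71)
  exs <- list()
  for (t in seq_len(n_tx)) {
    base <- 1000 + (t - 1) * 1500
    e1 <- c(base, base + 100)
    e2 <- c(base + 401, base + 500)
    # plant a consensus-like donor at the intron start
    donor <- paste(c("CAG", "GTAAG", sample(c("T", "C"), 1)), collapse = "")
    substr(g, e1[2] - 2, e1[2] + 6) <- donor
    exs[[t]] <- tibble::tibble(chrom = "chrT", start = c(e1[1], e2[1]),
                               end = c(e1[2], e2[2]), strand = "+",
                               gene_id = paste0("G", t),
                               transcript_id = paste0("T", t))
  }
  idx <- annotation_index(dplyr::bind_rows(exs))
  fa <- fixture_genome(g, dir = tempfile("score"))
  train_jx <- idx$canonical_junctions[1:80, ]
  idx_train <- idx
  idx_train$canonical_junctions <- train_jx
  m <- train_site_model(idx_train, fa, "donor")
  held_out <- idx$canonical_junctions[81:120, ]
  pos_scores <- vapply(seq_len(nrow(held_out)), function(i) {
    score_sequence(m, extract_site_sequence(fa, "chrT",
                                            held_out$intron_start[i],
                                            "donor", "+"))
  }, numeric(1))
  neg_scores <- vapply(1:200, function(i) {
    score_sequence(m, paste(sample(c("A", "C", "G", "T"), 9, replace = TRUE),
                            collapse = ""))
  }, numeric(1))
  auc <- mean(outer(pos_scores, neg_scores, ">")) +
    0.5 * mean(outer(pos_scores, neg_scores, "=="))
  expect_gt(auc, 0.9)
})

test_that("pair scoring is deterministic, additive, and zero on identity", {
  m <- splice_site_model_from_seqs(
    c(rep("CAGGTAAGT", 30), rep("AAGGTAAGT", 10), rep("CAGGTGAGT", 10)),
    "donor")
  p <- score_site_pair(m, "CAGGTAAGT", "CAGGTAAGT")
  expect_equal(p$delta, 0)
  # identical inputs give bit-identical scores
  p2 <- score_site_pair(m, "CAGGTAAGT", "CAGGTAAGT")
  expect_identical(p$ref_score, p2$ref_score)
  # converting a non-consensus base to the consensus base raises the score
  up <- score_site_pair(m, "AAGGTAAGT", "CAGGTAAGT")
  expect_gt(up$delta, 0)
  # additivity: the delta equals the per-position log-odds difference
  expect_equal(up$delta,
               unname(m$log_odds["C", 1] - m$log_odds["A", 1]),
               tolerance = 1e-12)
  expect_error(score_sequence(m, "CAGG"), "length")
  expect_error(score_sequence(m, "CAGGTAANT"), "non-ACGT")
})

test_that("mutations inside the scored window substitute the alternate base", {
  g <- scoring_genome()
  fa <- fixture_genome(g)
  # junction (1031, 1230); mutation at 1033 (intronic position +3 of donor)
  res <- candidate_site_sequences(fa, "chrT", 1033L, substr(g, 1033, 1033),
                                  "G", 1031L, 1230L, strand = "+")
  expect_equal(res$site_type, "donor")
  expect_true(res$mutated)
  expect_equal(substr(res$mut_seq, 6, 6), "G")
  expect_equal(res$ref_seq, "CAGGTAAGT")
  # mutation far from the window leaves the sequence unchanged
  res2 <- candidate_site_sequences(fa, "chrT", 1050L, "A", "G",
                                   1031L, 1230L, strand = "+")
  expect_false(res2$mutated)
  expect_equal(res2$mut_seq, res2$ref_seq)
})

test_that("model tidiers expose per-position log-odds", {
  m <- splice_site_model_from_seqs(rep("CAGGTAAGT", 60), "donor")
  td <- tidy(m)
  expect_equal(nrow(td), 4 * 9)
  expect_equal(unique(td$base), c("A", "C", "G", "T"))
  gl <- glance(m)
  expect_equal(gl$n_sites, 60L)
  expect_s3_class(autoplot(m), "ggplot")
})
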