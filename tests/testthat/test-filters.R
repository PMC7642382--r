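test_that("exact canonical junctions are removed, shared-boundary ones kept", {
  idx <- fixture_annotation()
  cands <- dplyr::bind_rows(
    make_candidate(pos = 1195, intron_start = 1201, intron_end = 1500), # canonical
    make_candidate(pos = 1230, intron_start = 1231, intron_end = 1500), # extension-like
    make_candidate(pos = 1195, intron_start = 1201, intron_end = 1480)  # shrink-like
  )
  out <- filter_known_and_polymorphic(cands, idx)
  expect_equal(nrow(out), 2L)
  expect_false(any(out$intron_start == 1201 & out$intron_end == 1500))
})

test_that("candidates in blacklisted polymorphic regions are removed", {
  idx <- fixture_annotation()
  black <- tibble::tibble(chrom = "chrT", start = 1400L, end = 1450L)
  cands <- dplyr::bind_rows(
    make_candidate(pos = 1230, intron_start = 1231, intron_end = 1500),
    make_candidate(pos = 6205, intron_start = 6206, intron_end = 6500)
  )
  out <- filter_known_and_polymorphic(cands, idx, black)
  expect_equal(out$intron_start, 6206L)
})

test_that("blacklist/known removal agrees with a brute-force check", {
  idx <- fixture_annotation()
  black <- tibble::tibble(chrom = "chrT", start = c(1300L, 2100L),
                          end = c(1350L, 2300L))
  set.seed(21)
  cands <- dplyr::bind_rows(lapply(1:40, function(i) {
    is <- sample(1000:2600, 1); ie <- is + sample(30:400, 1)
    make_candidate(pos = is - 1L, intron_start = is, intron_end = ie)
  }))
  out <- filter_known_and_polymorphic(cands, idx, black)
  canon <- idx$canonical_junctions
  brute_keep <- vapply(seq_len(nrow(cands)), function(i) {
    known <- any(canon$chrom == cands$chrom[i] &
                   canon$intron_start == cands$intron_start[i] &
                   canon$intron_end == cands$intron_end[i])
    hit_bl <- any(black$chrom == cands$chrom[i] &
                    cands$intron_start[i] <= black$end &
                    cands$intron_end[i] >= black$start)
    !known && !hit_bl
  }, logical(1))
  expect_equal(nrow(out), sum(brute_keep))
})

test_that("the JAF filter is strict below and inclusive at the threshold", {
  cands <- dplyr::bind_rows(
    make_candidate(pos = 1, intron_start = 10, intron_end = 100, jaf = 0.04),
    make_candidate(pos = 2, intron_start = 10, intron_end = 100, jaf = 0.05),
    make_candidate(pos = 3, intron_start = 10, intron_end = 100, jaf = 0.50)
  )
  out <- jaf_filter(cands, 0.05)
  expect_equal(out$jaf, c(0.05, 0.50))
  expect_equal(nrow(jaf_filter(cands, 0)), 3L)
})

test_that("proportion-test p-values match exact tail summation", {
  tail_oracle <- function(k, n, p) {
    sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i),
               numeric(1)))
  }
  expect_equal(binomial_upper_p(0, 50, 0.05), 1)
  expect_equal(binomial_upper_p(10, 100, 0.05), 0.02818829, tolerance = 1e-6)
  set.seed(13)
  for (i in 1:30) {
    n <- sample(10:200, 1)
    k <- sample(0:n, 1)
    p <- runif(1, 0.01, 0.3)
    expect_equal(binomial_upper_p(k, n, p), tail_oracle(k, n, p),
                 tolerance = 1e-12)
  }
  expect_error(binomial_upper_p(5, 10, 0), "null_jaf")
})

test_that("proportion-test filter sets p/q and keeps q <= alpha", {
  cands <- dplyr::bind_rows(
    make_candidate(pos = 1, intron_start = 10, intron_end = 100,
                   n_supporting_reads = 30L, depth_at_site = 100L),
    make_candidate(pos = 2, intron_start = 10, intron_end = 100,
                   n_supporting_reads = 5L, depth_at_site = 100L),
    make_candidate(pos = 3, intron_start = 10, intron_end = 100,
                   n_supporting_reads = 20L, depth_at_site = 100L)
  )
  out <- proportion_test_filter(cands, null_jaf = 0.05, alpha = 0.05)
  expect_true(all(c("p_value", "q_value") %in% names(out)))
  expect_true(all(out$q_value <= 0.05))
  expect_true(all(out$n_supporting_reads %in% c(30L, 20L)))
})

test_that("BH q-values match the hand step-up computation", {
  expect_equal(bh_fdr(c(0.01, 0.04, 0.03)), c(0.03, 0.04, 0.04))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  # independent step-up oracle
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
    q <- numeric(m)
    q[o] <- pmin(q_sorted, 1)
    q
  }
  set.seed(17)
  for (i in 1:1000) {
    p <- runif(sample(1:20, 1))
    expect_lt(max(abs(bh_fdr(p) - bh_oracle(p))), 1e-14)
  }
  expect_error(bh_fdr(c(0.1, 1.2)), "0, 1")
})

test_that("case/control comparison uses a strict top-k rule with ties failing", {
  expect_true(case_control_filter(5, rep(0, 100), k = 0.05))
  expect_false(case_control_filter(5, c(rep(5, 10), rep(0, 90)), k = 0.05))
  expect_false(case_control_filter(5, c(rep(5, 5), rep(0, 95)), k = 0.05))
  expect_true(case_control_filter(5, c(rep(5, 4), rep(0, 96)), k = 0.05))
  expect_error(case_control_filter(5, integer(0)), "control")
})

test_that("apply_case_control zero-fills missing junctions and filters", {
  cands <- dplyr::bind_rows(
    make_candidate(pos = 1, intron_start = 10, intron_end = 100,
                   n_supporting_reads = 8L),
    make_candidate(pos = 2, intron_start = 200, intron_end = 300,
                   n_supporting_reads = 6L)
  )
  ctrl <- tidyr::expand_grid(
    tibble::tibble(chrom = "chrT", intron_start = 200L, intron_end = 300L),
    control_id = sprintf("C%02d", 1:20)
  )
  ctrl$count <- c(rep(9L, 3), rep(0L, 17))
  out <- apply_case_control(cands, ctrl, k = 0.05)
  # junction (200,300): 3/20 controls >= case -> fail; (10,100) zero-filled -> pass
  expect_equal(out$intron_start, 10L)
  expect_equal(out$control_ge_case, 0L)
})

test_that("relaxing thresholds never shrinks the surviving set", {
  set.seed(31)
  idx <- fixture_annotation()
  cands <- dplyr::bind_rows(lapply(1:60, function(i) {
    is <- sample(1000:2600, 1); ie <- is + sample(30:400, 1)
    depth <- sample(20:300, 1)
    supp <- sample(1:depth, 1)
    make_candidate(pos = is - 1L, intron_start = is, intron_end = ie,
                   n_supporting_reads = supp, depth_at_site = depth,
                   jaf = supp / depth)
  }))
  strict_jaf <- jaf_filter(cands, 0.10)
  loose_jaf <- jaf_filter(cands, 0.02)
  expect_true(nrow(loose_jaf) >= nrow(strict_jaf))
  strict_pt <- proportion_test_filter(cands, 0.05, 0.01)
  loose_pt <- proportion_test_filter(cands, 0.05, 0.10)
  expect_true(nrow(loose_pt) >= nrow(strict_pt))
  ctrl <- tidyr::expand_grid(
    dplyr::distinct(cands, chrom, intron_start, intron_end),
    control_id = sprintf("C%02d", 1:20)
  )
  set.seed(32)
  ctrl$count <- sample(0:40, nrow(ctrl), replace = TRUE)
  strict_cc <- apply_case_control(cands, ctrl, k = 0.05)
  loose_cc <- apply_case_control(cands, ctrl, k = 0.25)
  expect_true(nrow(loose_cc) >= nrow(strict_cc))
})
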