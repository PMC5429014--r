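# FDR machinery, candidate merging, and the exact enrichment test.

test_that("BH q-values: single p, hand example, monotonicity, q >= p", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(19)
  p <- runif(40)
  q <- bh_fdr(p)
  expect_true(all(q >= p))
  expect_true(all(diff(q[order(p)]) >= -1e-15))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("thresholding q reproduces the classical BH rejection set", {
  # independent implementation of the step-up rule
  bh_reject <- function(p, alpha) {
    n <- length(p)
    o <- order(p)
    k <- which(p[o] <= alpha * seq_len(n) / n)
    rej <- logical(n)
    if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
    rej
  }
  set.seed(23)
  for (i in 1:10) {
    p <- c(runif(15), runif(5, 0, 0.01))
    for (alpha in c(0.05, 0.2)) {
      expect_equal(bh_fdr(p) < alpha, bh_reject(p, alpha))
    }
  }
})

test_that("candidate merging follows the q and elevated-omega rules", {
  scan <- tibble::tibble(
    group_id = c("g1", "g1", "g2", "g3"),
    condition = c(1L, 3L, 1L, 2L),
    status = "tested",
    p = c(0.5, 0.001, 0.9, 0.001),
    omega_fg = c(0.1, 2.0, 0.1, 0.05),
    omega_bg = c(0.2, 0.2, 0.2, 0.2),
    q = c(0.6, 0.15, 0.95, 0.1))
  cand <- merge_candidates(scan, 0.2)
  # g1 qualifies through condition 3 only; g3 has q < 0.2 but omega_fg <
  # omega_bg and is rejected by the elevated-ratio requirement
  expect_equal(cand$group_id, "g1")
  expect_equal(cand$best_condition, 3L)
  # all q >= 0.2: no candidates
  expect_equal(nrow(merge_candidates(dplyr::mutate(scan, q = 0.5), 0.2)), 0L)
})

test_that("candidate sets are monotone in the threshold", {
  set.seed(31)
  scan <- tibble::tibble(
    group_id = rep(sprintf("g%02d", 1:20), each = 2),
    condition = rep(1:2, 20),
    status = "tested",
    p = runif(40),
    omega_fg = runif(40, 0, 3),
    omega_bg = 0.5)
  scan <- add_fdr(scan)
  for (pair in list(c(0.05, 0.2), c(0.1, 0.5))) {
    c1 <- merge_candidates(scan, pair[1])$group_id
    c2 <- merge_candidates(scan, pair[2])$group_id
    expect_true(all(c1 %in% c2))
  }
})

test_that("per-condition correction is applied within conditions", {
  scan <- tibble::tibble(
    group_id = rep(c("a", "b"), 2),
    condition = rep(1:2, each = 2),
    status = "tested",
    p = c(0.01, 0.02, 0.5, 0.6),
    omega_fg = 1, omega_bg = 0.1)
  out <- add_fdr(scan)
  expect_equal(out$q[out$condition == 1], bh_fdr(c(0.01, 0.02)))
  expect_equal(out$q[out$condition == 2], bh_fdr(c(0.5, 0.6)))
})

test_that("null-only cohorts do not exceed the nominal candidate fraction", {
  # 60 null groups x 1 condition: candidate fraction should be consistent
  # with FDR 0.2 (binomial bound at the 0.01 level)
  set.seed(57)
  n <- 60
  scan <- tibble::tibble(
    group_id = sprintf("g%02d", 1:n), condition = 1L, status = "tested",
    p = runif(n), omega_fg = runif(n, 0, 2), omega_bg = runif(n, 0, 2))
  scan <- add_fdr(scan)
  n_cand <- nrow(merge_candidates(scan, 0.2))
  expect_lte(n_cand, qbinom(0.99, n, 0.2))
})

test_that("hypergeometric enrichment matches direct summation", {
  expect_equal(enrichment_fisher(10, 5, 5, 5), 1 / 252, tolerance = 1e-12)
  expect_equal(enrichment_fisher(100, 10, 8, 0), 1)
  set.seed(41)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    K <- sample(1:(N %/% 2), 1)
    n <- sample(1:(N %/% 2), 1)
    obs <- sample(0:min(K, n), 1)
    got <- enrichment_fisher(N, n, K, obs)
    want <- if (obs == 0) 1 else oracle_hyper_upper(N, K, n, obs)
    expect_equal(got, want, tolerance = 1e-12)
  }
  expect_error(enrichment_fisher(10, 5, 20, 1))
})

test_that("storey variant never exceeds BH and stays in [0, 1]", {
  set.seed(91)
  p <- c(runif(30), runif(10, 0, 0.01))
  expect_true(all(storey_fdr(p) <= bh_fdr(p) + 1e-12))
  expect_true(all(storey_fdr(p) >= 0 & storey_fdr(p) <= 1))
})
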