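# Rate-matrix constructors: structure, reversibility, scaling, and the
# closed-form / enumeration checks.

test_that("codon rate matrix has zero row sums and respects omega = 0", {
  set.seed(1)
  pi <- runif(61); pi <- pi / sum(pi)
  m <- codon_model(kappa = 3.1, omega = c(background = 0.7), pi = pi)
  Q <- codon_rate_matrix(m)
  expect_lt(max(abs(rowSums(Q))), 1e-12)

  Q0 <- codon_rate_matrix(m, omega = 0)
  ctype <- c4scan:::.codon_tables()$ctype
  expect_true(all(Q0[ctype >= 3L] == 0))
})

test_that("codon matrix is reversible and unit-scaled for random params", {
  for (s in 1:5) {
    set.seed(s)
    pi <- runif(61, 0.1, 1); pi <- pi / sum(pi)
    m <- codon_model(kappa = runif(1, 0.5, 5),
                     omega = c(background = runif(1, 0.05, 3)), pi = pi)
    Q <- codon_rate_matrix(m)
    expect_lt(max(abs(pi * Q - t(pi * Q))), 1e-12) # diag(pi) Q symmetric
    expect_equal(-sum(pi * diag(Q)), 1, tolerance = 1e-12) # unit scaling
  }
})

test_that("uniform-pi codon matrix matches an adjacency enumeration", {
  m <- codon_model(kappa = 1, omega = c(background = 1))
  mu <- codon_model(kappa = 1, omega = c(background = 1), scaled = FALSE)
  Qu <- codon_rate_matrix(mu)
  off <- Qu[row(Qu) != col(Qu)]
  # kappa = omega = 1, uniform pi: all single-difference entries equal
  expect_equal(length(unique(round(off[off > 0], 15))), 1L)

  # scaling factor equals brute-force enumeration over codon pairs
  codons <- sense_codons()
  n_adj <- 0L
  for (i in seq_along(codons)) {
    for (j in seq_along(codons)) {
      if (i == j) next
      d <- sum(strsplit(codons[i], "")[[1]] != strsplit(codons[j], "")[[1]])
      if (d == 1L) n_adj <- n_adj + 1L
    }
  }
  expected_rate <- n_adj / 61 / 61 # sum_i pi_i sum_j!=i pi_j [adjacent]
  Qs <- codon_rate_matrix(m)
  expect_equal(Qu[2, 1] / Qs[2, 1], expected_rate, tolerance = 1e-12)
})

test_that("invalid codon frequencies are rejected", {
  expect_error(codon_model(pi = rep(1, 61)), "sum to 1")
  expect_error(codon_model(pi = c(-1, rep(2 / 60, 60))), "non-negative")
})

test_that("GTR matrix: JC limit, detailed balance, unit mean rate", {
  Q <- gtr_rate_matrix(gtr_model())
  off <- Q[row(Q) != col(Q)]
  expect_equal(length(unique(round(off, 12))), 1L) # Jukes-Cantor limit

  set.seed(7)
  for (i in 1:5) {
    exch <- runif(6, 0.2, 3)
    pi <- runif(4, 0.1, 1); pi <- pi / sum(pi)
    Qr <- gtr_rate_matrix(gtr_model(exch = exch, pi = pi))
    expect_lt(max(abs(pi * Qr - t(pi * Qr))), 1e-12) # diag(pi) Q symmetric
    expect_equal(-sum(pi * diag(Qr)), 1, tolerance = 1e-12)
  }
  expect_error(gtr_model(exch = rep(0, 6)), "positive")
})

test_that("transition matrix: identity at t = 0, JC closed form, stationarity", {
  Q <- gtr_rate_matrix(gtr_model())
  expect_equal(transition_matrix(Q, 0), diag(4), ignore_attr = TRUE)
  P <- transition_matrix(Q, 0.3)
  expect_equal(P[1, 1], 0.25 + 0.75 * exp(-0.4), tolerance = 1e-6)
  expect_equal(unname(P[1, 1]), 0.752740, tolerance = 1e-6)

  Pinf <- transition_matrix(Q, 100)
  expect_true(all(abs(Pinf - 0.25) < 1e-8))
  expect_error(transition_matrix(Q, -0.1), "non-negative")

  # Chapman-Kolmogorov for random GTR
  set.seed(3)
  Qr <- gtr_rate_matrix(gtr_model(exch = runif(6, 0.3, 2),
                                  pi = c(0.4, 0.3, 0.2, 0.1)))
  s <- 0.17; t <- 0.42
  expect_equal(transition_matrix(Qr, s) %*% transition_matrix(Qr, t),
               transition_matrix(Qr, s + t), tolerance = 1e-8)
})

test_that("gamma discretization: k = 1, unit mean, exponential case", {
  expect_equal(discretize_gamma(0.73, 1), 1.0)
  for (alpha in c(0.2, 0.8, 2.5)) {
    for (k in c(2, 4, 8)) {
      expect_equal(mean(discretize_gamma(alpha, k)), 1, tolerance = 1e-8)
    }
  }
  # alpha = 1 (exponential), k = 2: analytic segment means at median ln 2
  expect_equal(discretize_gamma(1, 2), c(1 - log(2), 1 + log(2)),
               tolerance = 1e-4)
  expect_equal(discretize_gamma(1, 2), c(0.30685, 1.69315), tolerance = 1e-4)
  expect_error(discretize_gamma(1, 0), "positive")
})
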