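# Pruning likelihood against exhaustive internal-state marginalization,
# closed forms, and structural invariants.

test_that("codon pruning equals exhaustive marginalization (4 taxa)", {
  set.seed(11)
  tr <- ape::read.tree(text = "((A:0.12,B:0.3):0.08,(C:0.2,D:0.05):0.15);")
  model <- codon_model(kappa = 2.4, omega = c(background = 0.6),
                       pi = {p <- runif(61, 0.2, 1); p / sum(p)})
  codons <- sense_codons()
  aln <- codon_alignment(c(
    A = paste0(codons[5], codons[17]),
    B = paste0(codons[5], codons[33]),
    C = paste0(codons[8], codons[17]),
    D = paste0(codons[5], codons[2])))
  ll <- prune_loglik(tr, aln, model)

  cols <- list(c(A = 5L, B = 5L, C = 8L, D = 5L),
               c(A = 17L, B = 33L, C = 17L, D = 2L))
  ll_oracle <- oracle_loglik(tr, oracle_codon_P_of(tr, model), cols, model$pi)
  expect_equal(ll, ll_oracle, tolerance = 1e-8)
})

test_that("codon pruning with branch classes matches the oracle", {
  # the foreground stem is interior, so the rooted oracle and the unrooted
  # engine parameterization agree branch-for-branch
  tr <- ape::read.tree(
    text = "(((Zm:0.1,Sb:0.2):0.1,Os:0.15):0.1,Bd:0.2);")
  tr <- label_foreground(tr)
  model <- codon_model(kappa = 1.7,
                       omega = c(background = 0.2, foreground = 3.5))
  codons <- sense_codons()
  aln <- codon_alignment(c(Zm = codons[40], Sb = codons[41],
                           Os = codons[40], Bd = codons[12]))
  ll <- prune_loglik(tr, aln, model)
  cols <- list(c(Zm = 40L, Sb = 41L, Os = 40L, Bd = 12L))
  ll_oracle <- oracle_loglik(tr, oracle_codon_P_of(tr, model), cols, model$pi)
  expect_equal(ll, ll_oracle, tolerance = 1e-8)
})

test_that("nucleotide pruning with gamma+I mixture matches the oracle", {
  tr <- ape::read.tree(text = "((A:0.25,B:0.1):0.12,(C:0.3,D:0.18):0.07);")
  model <- gtr_model(exch = c(1, 2.5, 0.8, 1.2, 3, 1),
                     pi = c(0.35, 0.2, 0.25, 0.2),
                     alpha = 0.6, p_inv = 0.25, k = 3)
  seqs <- c(A = "ACG", B = "ATG", C = "GC-", D = "ACT")
  ll <- prune_loglik(tr, seqs, model)

  Q <- gtr_rate_matrix(model)
  g <- discretize_gamma(model$alpha, model$k) / (1 - model$p_inv)
  rates <- c(0, g)
  rw <- c(model$p_inv, rep((1 - model$p_inv) / model$k, model$k))
  P_of_cat <- function(r, cat) transition_matrix(Q, tr$edge.length[r] * rates[cat])
  cols <- list(c(A = 1L, B = 1L, C = 3L, D = 1L),
               c(A = 2L, B = 4L, C = 2L, D = 2L),
               c(A = 3L, B = 3L, C = NA, D = 4L)) # gap = missing
  ll_oracle <- oracle_loglik(tr, P_of_cat, cols, model$pi, rates, rw)
  expect_equal(ll, ll_oracle, tolerance = 1e-8)
})

test_that("two-taxon JC likelihood matches the closed form", {
  tr <- ape::read.tree(text = "(A:0.15,B:0.15);")
  ll_same <- prune_loglik(tr, c(A = "A", B = "A"), gtr_model(k = 1))
  p_same <- 0.25 + 0.75 * exp(-4 / 3 * 0.3)
  expect_equal(ll_same, log(0.25 * p_same), tolerance = 1e-6)
  expect_equal(ll_same, -1.67033, tolerance = 1e-4)
})

test_that("lnL is invariant to re-rooting under a reversible model", {
  set.seed(21)
  tr <- ape::read.tree(
    text = "(((A:0.1,B:0.2):0.05,C:0.3):0.1,(D:0.2,E:0.1):0.15);")
  model <- gtr_model(exch = runif(6, 0.5, 2), pi = c(.3, .2, .3, .2),
                     alpha = 1.2, p_inv = 0.1)
  seqs <- c(A = "ACGTAC", B = "ACGTAT", C = "ACCTAC", D = "GCGTAC",
            E = "ACGAAC")
  ll1 <- prune_loglik(tr, seqs, model)
  tr2 <- ape::root(ape::unroot(tr), outgroup = "C", resolve.root = TRUE)
  ll2 <- prune_loglik(tr2, seqs, model)
  expect_equal(ll1, ll2, tolerance = 1e-9)
})

test_that("adding a column never increases the total lnL", {
  tr <- grass_species_tree()
  m <- codon_model()
  aln <- simulate_codon_alignment(tr, m, 20, seed = 400)
  mat <- as.matrix(aln)
  for (L in c(5, 10, 19)) {
    sub <- codon_alignment(apply(mat[, 1:L], 1, paste, collapse = ""))
    subp <- codon_alignment(apply(mat[, 1:(L + 1)], 1, paste, collapse = ""))
    expect_gt(prune_loglik(tr, sub, m), prune_loglik(tr, subp, m))
  }
})

test_that("alignment taxa absent from the tree are rejected", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.1);")
  expect_error(prune_loglik(tr, c(A = "A", Z = "C"), gtr_model()),
               "absent from tree")
})

test_that("GTR+Gamma+I likelihood agrees with phangorn", {
  skip_if_not_installed("phangorn")
  set.seed(5)
  tr <- ape::rtree(6)
  tr$edge.length <- runif(nrow(tr$edge), 0.05, 0.4)
  exch <- c(1, 2, 1.5, 0.8, 3, 1)
  bf <- c(0.3, 0.2, 0.3, 0.2)
  dat <- phangorn::simSeq(tr, l = 200, type = "DNA", bf = bf, Q = exch)
  fitp <- phangorn::pml(tr, dat, bf = bf, Q = exch, k = 4, shape = 0.7,
                        inv = 0.2)
  seqs <- apply(toupper(as.character(dat)), 1, paste, collapse = "")
  ll <- prune_loglik(tr, seqs,
                     gtr_model(exch = exch, pi = bf, alpha = 0.7,
                               p_inv = 0.2, k = 4))
  expect_equal(ll, as.numeric(fitp$logLik), tolerance = 1e-8)
})
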