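# Simulator: determinism, degenerate cases, stationarity, exact cohort
# allocation.

test_that("zero branch lengths copy the root draw to every tip", {
  tr <- grass_species_tree(terminal = 0, internal = 0)
  aln <- simulate_codon_alignment(tr, codon_model(), 50, seed = 1)
  expect_equal(length(unique(unclass(aln))), 1L)
})

test_that("seeds make alignments reproducible and distinct", {
  tr <- grass_species_tree()
  m <- codon_model()
  a1 <- simulate_codon_alignment(tr, m, 100, seed = 5)
  a2 <- simulate_codon_alignment(tr, m, 100, seed = 5)
  a3 <- simulate_codon_alignment(tr, m, 100, seed = 6)
  expect_identical(unclass(a1), unclass(a2))
  expect_false(identical(unclass(a1), unclass(a3)))
  expect_error(simulate_codon_alignment(tr, m, 0, seed = 1), ">= 1")
})

test_that("single-tip codon frequencies are consistent with pi", {
  tr <- ape::read.tree(text = "(A:0.0,B:0.1);") # tip A is the root draw
  set.seed(2)
  pi <- runif(61, 0.5, 1.5); pi <- pi / sum(pi)
  m <- codon_model(pi = pi)
  aln <- simulate_codon_alignment(tr, m, 50000, seed = 123)
  obs <- table(factor(c4scan:::.split_codons(unclass(aln)[["A"]]),
                      levels = sense_codons()))
  gof <- suppressWarnings(chisq.test(as.numeric(obs), p = pi))
  expect_gt(gof$p.value, 0.01)
})

test_that("cohort allocation is exact and written files round-trip", {
  cfg <- cohort_config(n_groups = 20, fraction_selected = 0.1,
                       p_duplicate = 0.2, p_loss_rice = 0.1,
                       p_loss_brachy = 0.05, discordant_fraction = 0.1,
                       n_codons = 30, seed = 77)
  dir <- tempfile("coh")
  coh <- generate_cohort(cfg, dir = dir)
  expect_equal(sum(coh$truth$selected), 2L)   # round(20 * 0.1)
  expect_equal(sum(coh$truth$pattern == "ii"), 4L)
  expect_equal(sum(coh$truth$pattern == "iii"), 2L)
  expect_equal(sum(coh$truth$pattern == "iv"), 1L)
  expect_equal(sum(coh$truth$discordant), 2L)

  # same seed: byte-identical; different seed: different sequences
  coh2 <- generate_cohort(cfg)
  expect_identical(coh$sequences, coh2$sequences)
  coh3 <- generate_cohort(cohort_config(n_groups = 20, n_codons = 30,
                                        seed = 78))
  expect_false(identical(coh$sequences$Zm[1], coh3$sequences$Zm[1]))

  # files exist and parse back
  expect_true(file.exists(coh$paths$synteny))
  syn <- read_synteny(coh$paths$synteny)
  expect_equal(nrow(syn), nrow(coh$synteny))
  fa <- c4scan:::.read_fasta(coh$paths$fasta[["Zm"]])
  expect_equal(sort(names(fa)), sort(names(coh$sequences$Zm)))
  unlink(dir, recursive = TRUE)

  # inconsistent config rejected
  expect_error(cohort_config(p_duplicate = 0.6, p_loss_rice = 0.5, seed = 1),
               "sum above 1")
})

test_that("power rises with foreground omega and drops under condition 9", {
  pw <- power_experiment(omega_fg = c(0.2, 1.5, 4.0), n_codons = 300L,
                         conditions = 1L, n_rep = 20L, seed = 515)
  r <- setNames(pw$reject_p05, pw$omega_fg)
  # nondecreasing within Monte-Carlo error
  expect_gte(r[["1.5"]], r[["0.2"]] - 0.15)
  expect_gte(r[["4"]], r[["1.5"]] - 0.15)
  expect_lte(r[["0.2"]], 0.2)   # null cell near nominal
  expect_gte(r[["4"]], 0.8)     # strong selection detected

  # removing the Setaria-Dichanthelium clade costs power
  pw2 <- power_experiment(omega_fg = 1.5, n_codons = 300L,
                          conditions = c(1L, 9L), n_rep = 20L, seed = 516)
  expect_lte(pw2$reject_p05[pw2$condition == 9],
             pw2$reject_p05[pw2$condition == 1] + 0.15)
})

test_that("omega recovery from branch-specific simulation", {
  # single replicate at 800 codons: fitted foreground omega lands in a
  # broad interval around the generating value
  tr <- label_foreground(grass_species_tree())
  m <- codon_model(kappa = 2, omega = c(background = 0.2, foreground = 3))
  aln <- simulate_codon_alignment(tr, m, 800, seed = 321)
  r <- lrt_branch_model(aln, tr)
  expect_gt(r$omega_fg, 1.2)
  expect_lt(r$omega_fg, 7.5)
  expect_gt(r$omega_bg, 0.12)
  expect_lt(r$omega_bg, 0.3)
})
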