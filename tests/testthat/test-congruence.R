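# Gene trees, quartet distances, and the congruence verdict.

test_that("third-position extraction picks nucleotide 3 of each codon", {
  aln <- codon_alignment(c(a = "ATGGCC", b = "ATGGCA"))
  th <- third_position_sites(aln)
  expect_equal(th[["a"]], "GC")
  expect_equal(th[["b"]], "GA")
  expect_equal(nchar(th[["a"]]), n_codon_columns(aln))
  # gaps map to gaps
  th2 <- third_position_sites(codon_alignment(c(a = "ATG---", b = "ATGGCA")))
  expect_equal(th2[["a"]], "G-")
})

test_that("topology enumeration counts 3, 15, 105 for 4-6 taxa", {
  expect_equal(length(c4scan:::.all_topologies(letters[1:4])), 3L)
  expect_equal(length(c4scan:::.all_topologies(letters[1:5])), 15L)
  tops6 <- c4scan:::.all_topologies(letters[1:6])
  expect_equal(length(tops6), 105L)
  # all distinct as unrooted topologies
  expect_equal(length(unique(vapply(tops6, canonical_topology,
                                    character(1)))), 105L)
})

test_that("gene-tree lnL is at least that of the species topology", {
  tr <- keep_species(grass_species_tree(), c("Zm", "Sb", "Os", "Bd"))
  aln <- simulate_codon_alignment(tr, codon_model(), 150, seed = 71)
  seqs <- setNames(as.character(unclass(aln)), names(aln))
  gt <- infer_gene_tree(seqs, extra = list(tr))
  expect_equal(attr(gt, "n_topologies"), 3L)
  # direct fit of the species topology can never beat the searched optimum
  et <- c4scan:::.engine_tree(tr, unroot = FALSE)
  emp <- c4scan:::.empirical_nuc(c4scan:::.as_nuc_matrix(seqs))
  dat <- c4scan:::.nuc_engine_data(c4scan:::.as_nuc_matrix(seqs), et$tips)
  f <- c4scan:::.cpp_fit_nuc(et$edge0, rep(0.1, nrow(et$edge0)), emp$exch,
                             emp$pi, dat$tipc, dat$patw, 1, 0.1, 4L,
                             rep(1L, nrow(et$edge0)), TRUE, TRUE, 10L,
                             1e-6, 20)
  expect_gte(attr(gt, "loglik"), f$loglik - 1e-3)
})

test_that("the generating 6-taxon topology is recovered from 500 sites", {
  tr <- grass_species_tree(terminal = 0.1, internal = 0.2)
  aln <- simulate_codon_alignment(tr, codon_model(), 167, seed = 72)
  seqs <- setNames(as.character(unclass(aln)), names(aln))
  gt <- infer_gene_tree(seqs)
  expect_equal(canonical_topology(gt), canonical_topology(tr))
})

test_that("quartet distance: worked example, identity, symmetry", {
  t1 <- ape::read.tree(text = "((((A,B),C),D),E);")
  t2 <- ape::read.tree(text = "((((A,B),D),C),E);")
  expect_equal(quartet_distance(t1, t2), 2L)
  expect_equal(quartet_distance(t1, t1), 0L)
  expect_equal(quartet_distance(t2, t1), 2L)
  t3 <- ape::read.tree(text = "((A,B),(C,D));")
  expect_error(quartet_distance(t1, t3), "same tip set")
})

test_that("quartet distance matches the split-enumeration oracle", {
  set.seed(90)
  for (i in 1:25) {
    t1 <- ape::rtree(6, tip.label = letters[1:6])
    t2 <- ape::rtree(6, tip.label = letters[1:6])
    expect_equal(quartet_distance(t1, t2), oracle_quartet_distance(t1, t2))
    expect_equal(quartet_distance(t1, t2), quartet_distance(t2, t1))
  }
})

test_that("congruence verdict implements the disjunction rule", {
  sp <- grass_species_tree()
  # concordant data: both distances 0, pass
  aln <- simulate_codon_alignment(sp, codon_model(), 300, seed = 80)
  v <- congruence_test(aln, sp)
  expect_true(v$pass)
  expect_equal(v$qdist_all, 0L)
  # discordant data: both distances > 0, exclude
  alt <- c4scan:::.discordant_tree(0.1, 0.15)
  alnd <- simulate_codon_alignment(alt, codon_model(), 300, seed = 81)
  vd <- congruence_test(alnd, sp)
  expect_false(vd$pass)
  expect_gt(vd$qdist_all, 0L)
  expect_gt(vd$qdist_third, 0L)
})

test_that("maize homeologs must form a cherry and are collapsed", {
  sp <- grass_species_tree()
  tr2 <- c4scan:::.add_homeolog_cherry(sp, "Zm", 0.05)
  aln <- simulate_codon_alignment(tr2, codon_model(), 300, seed = 82)
  v <- congruence_test(aln, sp)
  expect_true(v$pass)
  expect_equal(sort(v$tree_all$tip.label),
               sort(tr2$tip.label)) # inference kept both homeologs
})
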