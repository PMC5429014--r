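# Ortholog grouping: homeolog merging, best-hit search, pattern rules.

.syn_row <- function(gid, sp, gene) {
  tibble::tibble(group_id = gid, species = sp, gene_id = gene)
}

test_that("rows sharing all non-maize anchors merge into one homeolog pair", {
  rows <- dplyr::bind_rows(
    .syn_row("a1", "Sb", "Sb_1"), .syn_row("a1", "Zm", "Zm_A"),
    .syn_row("a2", "Sb", "Sb_1"), .syn_row("a2", "Zm", "Zm_B"))
  m <- merge_homeologs(rows)
  expect_equal(length(unique(m$group_id)), 1L)
  expect_equal(sort(m$gene_id[m$species == "Zm"]), c("Zm_A", "Zm_B"))
  expect_false(any(m$excluded))

  # idempotent
  m2 <- merge_homeologs(dplyr::select(m, -"excluded"))
  expect_equal(dplyr::select(m2, 1:3), dplyr::select(m, 1:3))

  # single maize gene: unchanged
  single <- dplyr::bind_rows(.syn_row("b1", "Sb", "Sb_9"),
                             .syn_row("b1", "Zm", "Zm_9"))
  expect_equal(nrow(merge_homeologs(single)), 2L)

  # three maize members: excluded with diagnostic flag
  tri <- dplyr::bind_rows(
    .syn_row("c1", "Sb", "Sb_2"), .syn_row("c1", "Zm", "Zm_1"),
    .syn_row("c2", "Sb", "Sb_2"), .syn_row("c2", "Zm", "Zm_2"),
    .syn_row("c3", "Sb", "Sb_2"), .syn_row("c3", "Zm", "Zm_3"))
  expect_true(all(merge_homeologs(tri)$excluded))
})

test_that("member multiset is conserved by merging", {
  set.seed(14)
  rows <- purrr::map_dfr(1:10, function(g) {
    dplyr::bind_rows(
      .syn_row(paste0("g", g), "Sb", paste0("Sb_", g)),
      .syn_row(paste0("g", g), "Zm", paste0("Zm_", g)),
      .syn_row(paste0("g", g), "Os", paste0("Os_", g)))
  })
  m <- merge_homeologs(rows)
  expect_equal(sort(m$gene_id), sort(rows$gene_id))
})

test_that("best-hit search matches the Smith-Waterman oracle", {
  q <- substr(random_cds(100, seed = 31), 1, 300)
  cands <- setNames(
    lapply(1:5, function(i) substr(random_cds(100, seed = 40 + i), 1, 300)),
    paste0("cand", 1:5))
  cands <- unlist(cands)
  hit <- best_hit_homolog(q, cands, min_score = 0)
  oracle <- vapply(cands, function(s) {
    oracle_sw_score(q, s, 2, -3, 5, 2)
  }, numeric(1))
  expect_equal(hit$score, max(oracle))
  expect_equal(hit$gene_id, names(which.max(oracle)))

  # per-candidate equality, not just the max
  for (nm in names(cands)) {
    expect_equal(
      c4scan:::.cpp_sw_score(c4scan:::.dna_int(q), c4scan:::.dna_int(cands[[nm]]),
                             2, -3, 5, 2),
      oracle[[nm]])
  }
})

test_that("best-hit returns the query's twin at maximal score and NA when empty", {
  q <- random_cds(60, seed = 9)
  cands <- c(twin = q, other = random_cds(60, seed = 10))
  hit <- best_hit_homolog(q, cands)
  expect_equal(hit$gene_id, "twin")
  expect_equal(hit$score, 2 * nchar(q)) # perfect self-match
  expect_true(is.na(best_hit_homolog(q, character(0))$gene_id))
  # below min_score: missing
  expect_true(is.na(best_hit_homolog("ACGACG",
                                     c(x = "TGTTGT"), min_score = 50)$gene_id))
})

test_that("pattern classification implements the four patterns", {
  full <- c(Zm = 1, Sb = 1, Si = 1, Do = 1, Os = 1, Bd = 1)
  expect_equal(classify_pattern(full), "i")
  expect_equal(classify_pattern(replace(full, "Zm", 2)), "ii")
  expect_equal(classify_pattern(full[names(full) != "Os"]), "iii")
  expect_equal(classify_pattern(replace(full, "Bd", 0)), "iv")
  expect_equal(classify_pattern(replace(full, "Sb", 0)), "excluded")
  # both rice and Brachypodium missing: excluded
  expect_equal(classify_pattern(full[!names(full) %in% c("Os", "Bd")]),
               "excluded")
  expect_equal(classify_pattern(replace(full, "Zm", 3)), "excluded")
})

test_that("cohort files round-trip: recovered patterns equal the truth", {
  coh <- generate_cohort(cohort_config(n_groups = 15, fraction_selected = 0,
                                       discordant_fraction = 0, seed = 33))
  grp <- build_groups(coh$synteny, coh$sequences)
  got <- setNames(grp$groups$pattern, grp$groups$group_id)
  expect_equal(unname(got[coh$truth$group_id]), coh$truth$pattern)
})
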