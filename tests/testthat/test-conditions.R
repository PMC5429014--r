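# The condition catalogue, pruning/skip rules, and foreground labeling.

test_that("the catalogue holds exactly the nine removal sets", {
  cat_tbl <- condition_catalog()
  expect_equal(nrow(cat_tbl), 9L)
  expect_equal(cat_tbl$removed, list(
    character(0), "Zm", "Sb", "Si", c("Zm", "Sb"), c("Sb", "Si"),
    c("Zm", "Si"), "Do", c("Si", "Do")))
})

test_that("pruning conserves tips and enforces the <4-taxa rule", {
  conds <- enumerate_conditions("i")
  expect_equal(nrow(conds), 9L)
  expect_true(all(conds$status == "tested")) # pattern i: all testable
  cat_tbl <- condition_catalog()
  for (r in seq_len(nrow(conds))) {
    tr <- conds$tree[[r]]
    expect_equal(sort(tr$tip.label),
                 sort(setdiff(names(c4_tags()),
                              cat_tbl$removed[[conds$condition[r]]])))
    expect_gte(conds$n_tips[r], 4L)
  }

  # pattern iii (rice absent) under condition 5 leaves 3 taxa: skipped
  c3 <- enumerate_conditions("iii")
  row5 <- c3[c3$condition == 5, ]
  expect_equal(row5$status, "skipped_min_taxa")
  expect_equal(row5$n_tips, 3L)

  # pattern ii under condition 1: homeolog cherry makes 7 tips
  c2 <- enumerate_conditions("ii")
  expect_equal(c2$n_tips[c2$condition == 1], 7L)
  expect_true(all(c("Zm.1", "Zm.2") %in% c2$tree[[1]]$tip.label))
})

test_that("stem-rule foreground sets match the transition-branch scheme", {
  fg_set <- function(tree) {
    ecl <- attr(tree, "eclass")
    lapply(which(ecl == 2L), function(r) {
      v <- tree$edge[r, 2]
      if (v <= length(tree$tip.label)) {
        tree$tip.label[v]
      } else {
        sort(ape::extract.clade(tree, v)$tip.label)
      }
    })
  }
  conds <- enumerate_conditions("i")
  # condition 1: stem of (Zm,Sb) plus the Si terminal
  fg1 <- fg_set(conds$tree[[1]])
  expect_true(list(c("Sb", "Zm")) %in% fg1 || any(
    vapply(fg1, function(x) identical(x, c("Sb", "Zm")), logical(1))))
  expect_true(any(vapply(fg1, identical, logical(1), "Si")))
  expect_equal(length(fg1), 2L)

  # condition 6 (Sb, Si removed): only the Zm terminal
  fg6 <- fg_set(conds$tree[[which(conds$condition == 6)]])
  expect_equal(fg6, list("Zm"))

  # condition 9 (Si, Do removed): the stem of (Zm,Sb)
  fg9 <- fg_set(conds$tree[[which(conds$condition == 9)]])
  expect_equal(fg9, list(c("Sb", "Zm")))
})

test_that("clade_all marks the branches inside C4-only clades too", {
  tr <- label_foreground(grass_species_tree(), "clade_all")
  st <- label_foreground(grass_species_tree(), "stem_only")
  expect_gt(sum(attr(tr, "eclass") == 2L), sum(attr(st, "eclass") == 2L))
  # foreground and background always both present
  expect_true(all(c(1L, 2L) %in% attr(tr, "eclass")))
})

test_that("foreground labeling fails on all-C4 or all-C3 tip sets", {
  expect_error(label_foreground(keep_species(grass_species_tree(),
                                             c("Zm", "Sb", "Si"))),
               "all tips are C4")
})
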