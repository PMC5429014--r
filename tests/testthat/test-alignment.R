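# Translation, progressive codon alignment, block trimming, coverage.

test_that("translation follows the universal code and flags stops", {
  expect_equal(as.character(translate_cds("ATGGCT")), "MA")
  expect_error(translate_cds("ATGGCTA"), "divisible by 3")
  # terminal stop dropped, no flag
  p <- translate_cds("ATGTAA")
  expect_equal(as.character(p), "M")
  expect_false(attr(p, "internal_stop"))
  # internal stop at codon 3 of 10: flagged
  cds <- paste0("ATGGCT", "TAA", paste(rep("GCT", 7), collapse = ""))
  p2 <- translate_cds(cds)
  expect_true(attr(p2, "internal_stop"))
  # ambiguity translates to X
  expect_equal(as.character(translate_cds("ANT")), "X")
})

test_that("identical sequences align gap-free and round-trip exactly", {
  cds <- random_cds(40, seed = 5)
  tr <- grass_species_tree()
  inputs <- setNames(rep(cds, 6), names(c4_tags()))
  aln <- codon_align(inputs, tr)
  expect_false(any(grepl("-", unclass(aln))))
  expect_equal(unclass(aln)[names(inputs)], inputs)
})

test_that("alignment only inserts gaps; ungapping returns each input CDS", {
  tr <- grass_species_tree()
  base <- simulate_codon_alignment(tr, codon_model(), 60, seed = 41)
  cds <- unclass(base)
  # introduce in-frame deletions of different sizes
  cds[["Sb"]] <- paste0(substr(cds[["Sb"]], 1, 60), substr(cds[["Sb"]], 91, 180))
  cds[["Os"]] <- substr(cds[["Os"]], 31, 180)
  aln <- codon_align(cds, tr)
  for (tx in names(cds)) {
    expect_equal(gsub("-", "", unclass(aln)[[tx]]), cds[[tx]])
  }
  # equal row lengths, divisible by 3
  expect_equal(length(unique(nchar(unclass(aln)))), 1L)
})

test_that("pairwise profile alignment score matches the DP oracle", {
  blosum <- c4scan:::.blosum()
  a <- "HEAGAWGHEE"
  b <- "PAWHEAE"
  pa <- c4scan:::.aa_profile(matrix(strsplit(a, "")[[1]], 1))
  pb <- c4scan:::.aa_profile(matrix(strsplit(b, "")[[1]], 1))
  res <- c4scan:::.cpp_profile_align(pa, pb, blosum, 10, 0.5)
  expect_equal(res$score, oracle_nw_score(a, b, blosum, 10, 0.5))
})

test_that("trimming follows the documented column/block rules", {
  # toy alignment, 4 rows x 40 aa columns: all conserved except a
  # 6-column low-identity stretch at columns 18-23.
  # Rules walkthrough: every column outside 18-23 has 4/4 identity (high
  # grade); columns 18-23 are nonconserved (max 2 of 4 rows agree) but the
  # run (6) does not exceed max_nonconserved_run (8), so the block is not
  # split; the nonconserved columns themselves are removed; flanks are
  # already highly conserved. Expected retained: 1-17 and 24-40.
  set.seed(8)
  base <- sample(sense_codons(), 40, replace = TRUE)
  rows <- list()
  variant <- c("GCT", "TGT", "GAT", "TTT") # A, C, D, F: all different
  for (i in 1:4) {
    r <- base
    r[18:23] <- variant[c(i, i %% 4 + 1, i, (i + 1) %% 4 + 1, i, i %% 4 + 1)]
    rows[[paste0("t", i)]] <- paste(r, collapse = "")
  }
  aln <- codon_alignment(unlist(rows))
  tb <- trim_blocks(aln)
  expect_equal(tb$map, c(1:17, 24:40))

  # fully conserved, gap-free: retained entirely
  same <- codon_alignment(setNames(rep(paste(base, collapse = ""), 4),
                                   paste0("t", 1:4)))
  expect_equal(trim_blocks(same)$map, 1:40)

  # a gap column is always removed (allow_gap_columns = FALSE)
  gapped <- rows
  gapped[["t1"]] <- paste(c(base[1:9], "---", base[11:40]), collapse = "")
  tg <- trim_blocks(codon_alignment(unlist(gapped)))
  expect_false(10L %in% tg$map)
})

test_that("the column map is strictly increasing with original content", {
  tr <- grass_species_tree()
  aln <- simulate_codon_alignment(tr, codon_model(), 50, seed = 300)
  tb <- trim_blocks(aln)
  expect_true(all(diff(tb$map) > 0))
  m0 <- as.matrix(aln)
  m1 <- as.matrix(tb$alignment)
  expect_equal(m1, m0[, tb$map, drop = FALSE], ignore_attr = TRUE)
})

test_that("aligned FASTA and column map round-trip through disk", {
  tr <- grass_species_tree()
  aln <- simulate_codon_alignment(tr, codon_model(), 30, seed = 63)
  tb <- trim_blocks(aln)
  fa <- tempfile(fileext = ".fa")
  write_codon_alignment(tb$alignment, fa, map = tb$map)
  back <- c4scan:::.read_fasta(fa)
  expect_equal(back, unclass(tb$alignment), ignore_attr = TRUE)
  cm <- readr::read_tsv(paste0(fa, ".colmap.tsv"), show_col_types = FALSE)
  expect_equal(cm$orig_col, tb$map)
  expect_equal(cm$aln_col, seq_along(tb$map))
  unlink(c(fa, paste0(fa, ".colmap.tsv")))
})

test_that("coverage filter discards below 30% and keeps at the boundary", {
  mk <- function(n) codon_alignment(setNames(
    rep(paste(rep("GCT", n), collapse = ""), 2), c("a", "b")))
  full <- mk(100)
  expect_false(coverage_filter(mk(29), full)$keep)
  expect_true(coverage_filter(mk(30), full)$keep)
  expect_equal(coverage_filter(mk(29), full)$coverage, 0.29)
  # empty trimmed alignment: discard
  empty <- codon_alignment(setNames(rep("", 2), c("a", "b")))
  expect_false(coverage_filter(empty, full)$keep)
  expect_false(coverage_filter(empty, empty)$keep)
})
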