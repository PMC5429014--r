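# The selection scan: one branch-model LRT per (group x applicable
# condition), with skip bookkeeping.

#' Run the branch-model selection scan
#'
#' For every QC-passed group, enumerates the applicable phylogenetic
#' conditions ([enumerate_conditions()]), subsets the alignment to each
#' condition's taxa, and runs the branch-model likelihood-ratio test
#' ([lrt_branch_model()]). Skipped conditions (fewer than four taxa) and
#' per-group failures are recorded as status rows; the batch never aborts.
#' Deterministic: identical inputs give identical tables.
#'
#' @param alignments Named list of [codon_alignment()]s keyed by group id.
#'   Taxon names are species codes (maize homeologs `Zm.1`/`Zm.2`).
#' @param patterns Tibble with `group_id`, `pattern` columns (or a named
#'   character vector of patterns).
#' @param species_tree Base species tree.
#' @param conditions Condition ids (default 1-9).
#' @param rule Foreground rule (`"stem_only"` or `"clade_all"`).
#' @param n_starts Passed to [lrt_branch_model()].
#' @return Tibble of scan records ordered by (group, condition):
#'   `group_id`, `condition`, `n_tips`, `lnL0`, `lnL1`, `stat`, `p`,
#'   `omega_fg`, `omega_bg`, `status`. Class `c4_scan`.
#' @export
run_scan <- function(alignments, patterns,
                     species_tree = grass_species_tree(),
                     conditions = 1:9, rule = "stem_only", n_starts = 1L) {
  if (is.data.frame(patterns)) {
    pat <- setNames(patterns$pattern, patterns$group_id)
  } else {
    pat <- patterns
  }
  gids <- names(alignments)
  missing_pat <- setdiff(gids, names(pat))
  if (length(missing_pat)) {
    stop("no pattern for group(s): ", paste(missing_pat, collapse = ", "))
  }

  rows <- purrr::map_dfr(gids, function(gid) {
    aln <- alignments[[gid]]
    conds <- enumerate_conditions(pat[[gid]], species_tree, conditions, rule)
    purrr::map_dfr(seq_len(nrow(conds)), function(i) {
      cid <- conds$condition[i]
      if (conds$status[i] != "tested") {
        return(tibble::tibble(
          group_id = gid, condition = cid, n_tips = conds$n_tips[i],
          lnL0 = NA_real_, lnL1 = NA_real_, stat = NA_real_, p = NA_real_,
          omega_fg = NA_real_, omega_bg = NA_real_,
          status = conds$status[i]))
      }
      tr <- conds$tree[[i]]
      sub <- .subset_alignment(aln, tr$tip.label)
      rec <- tryCatch(
        lrt_branch_model(sub, tr, rule = rule, n_starts = n_starts),
        error = function(e) e
      )
      if (inherits(rec, "error")) {
        return(tibble::tibble(
          group_id = gid, condition = cid, n_tips = conds$n_tips[i],
          lnL0 = NA_real_, lnL1 = NA_real_, stat = NA_real_, p = NA_real_,
          omega_fg = NA_real_, omega_bg = NA_real_, status = "skipped_qc"))
      }
      tibble::tibble(
        group_id = gid, condition = cid, n_tips = conds$n_tips[i],
        lnL0 = rec$lnL0, lnL1 = rec$lnL1, stat = rec$stat, p = rec$p,
        omega_fg = rec$omega_fg, omega_bg = rec$omega_bg, status = "tested")
    })
  })
  out <- dplyr::arrange(rows, .data$group_id, .data$condition)
  class(out) <- c("c4_scan", class(out))
  out
}

# subset a codon alignment to taxa present in a condition tree
.subset_alignment <- function(aln, taxa) {
  seqs <- unclass(aln)[intersect(names(aln), taxa)]
  codon_alignment(seqs)
}
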