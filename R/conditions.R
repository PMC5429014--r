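# The nine phylogenetic conditions of the selection scan: which species are
# removed before testing, pruning, the <4-taxa rule, and condition trees.

#' Catalogue of the nine phylogenetic conditions
#'
#' Condition 1 keeps the full phylogeny; conditions 2-7 remove one or two
#' C4 lineages (maize; sorghum; *S. italica*; maize-sorghum clade; sorghum +
#' *S. italica*; maize + *S. italica*); conditions 8-9 remove
#' *Dichanthelium* and the *Setaria*-*Dichanthelium* clade.
#'
#' @return Tibble with `condition` (1-9), `removed` (list of species
#'   codes), `label`.
#' @export
condition_catalog <- function() {
  tibble::tibble(
    condition = 1:9,
    removed = list(
      character(0), "Zm", "Sb", "Si", c("Zm", "Sb"), c("Sb", "Si"),
      c("Zm", "Si"), "Do", c("Si", "Do")
    ),
    label = c(
      "full phylogeny", "maize removed", "sorghum removed",
      "S. italica removed", "maize-sorghum clade removed",
      "sorghum and S. italica removed", "maize and S. italica removed",
      "Dichanthelium removed", "Setaria-Dichanthelium clade removed"
    )
  )
}

# species present for a pattern
.pattern_species <- function(pattern) {
  sp <- names(c4_tags())
  switch(pattern,
    i = sp,
    ii = sp,
    iii = setdiff(sp, "Os"),
    iv = setdiff(sp, "Bd"),
    stop("pattern must be one of i, ii, iii, iv")
  )
}

#' Enumerate testable conditions for an ortholog group
#'
#' Starts from the species tree restricted to the group's pattern (iii
#' drops rice, iv drops Brachypodium; pattern ii replaces the maize tip
#' with a homeolog cherry), removes each condition's species, suppresses
#' degree-2 nodes, and labels C4 foreground branches. Conditions leaving
#' fewer than four taxa, or no foreground branch, are emitted as skip rows.
#'
#' @param pattern Group pattern (`"i"`, `"ii"`, `"iii"`, `"iv"`).
#' @param species_tree Base six-taxon species tree.
#' @param conditions Condition ids to enumerate (default all nine).
#' @param rule Foreground rule, see [label_foreground()].
#' @param homeolog_twig Twig length for the pattern-ii maize cherry.
#' @return Tibble: `condition`, `n_tips`, `status`
#'   (`"tested"`/`"skipped_min_taxa"`), `tree` (list column; labeled
#'   `ape::phylo` or `NULL`).
#' @export
enumerate_conditions <- function(pattern,
                                 species_tree = grass_species_tree(),
                                 conditions = 1:9,
                                 rule = "stem_only",
                                 homeolog_twig = 0.05) {
  cat_tbl <- condition_catalog()
  stopifnot(all(conditions %in% cat_tbl$condition))
  base <- keep_species(species_tree,
                       intersect(species_tree$tip.label,
                                 .pattern_species(pattern)))
  if (pattern == "ii") {
    base <- .add_homeolog_cherry(base, "Zm", homeolog_twig)
  }
  purrr::map_dfr(conditions, function(cid) {
    removed <- cat_tbl$removed[[cid]]
    drop <- tree_tips_of_species(base, removed)
    keep <- setdiff(base$tip.label, drop)
    if (length(keep) < 4L) {
      return(tibble::tibble(condition = cid, n_tips = length(keep),
                            status = "skipped_min_taxa", tree = list(NULL)))
    }
    tr <- keep_species(base, keep)
    tr <- tryCatch(label_foreground(tr, rule), error = function(e) NULL)
    if (is.null(tr)) {
      return(tibble::tibble(condition = cid, n_tips = length(keep),
                            status = "skipped_min_taxa", tree = list(NULL)))
    }
    tibble::tibble(condition = cid, n_tips = length(keep),
                   status = "tested", tree = list(tr))
  })
}

#' Tips of a tree belonging to given species
#'
#' Maize homeolog tips (`Zm.1`, `Zm.2`) both belong to `Zm`.
#'
#' @param tree An `ape::phylo`.
#' @param species Species codes.
#' @return Character vector of tip labels.
#' @export
tree_tips_of_species <- function(tree, species) {
  tree$tip.label[.species_of(tree$tip.label) %in% species]
}
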