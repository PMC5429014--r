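# Tree helpers: the six-taxon grass species tree, C3/C4 tip tags,
# pruning, foreground labeling, and conversion to the C++ engine layout.

.grass_newick <- "(((Zm:%f,Sb:%f):%f,(Si:%f,Do:%f):%f):%f,(Os:%f,Bd:%f):%f);"

#' Grass species codes and photosynthetic type
#'
#' Zm (maize), Sb (sorghum) and Si (*Setaria italica*) are C4;
#' Do (*Dichanthelium oligosanthes*), Os (rice) and Bd
#' (*Brachypodium distachyon*) are C3.
#'
#' @return Named logical vector, `TRUE` for C4 species.
#' @export
c4_tags <- function() {
  c(Zm = TRUE, Sb = TRUE, Si = TRUE, Do = FALSE, Os = FALSE, Bd = FALSE)
}

# species code of a taxon label; maize homeologs carry a ".1"/".2" suffix
.species_of <- function(taxa) sub("\\..*$", "", taxa)

#' The six-taxon grass species tree
#'
#' Rooted topology `(((Zm,Sb),(Si,Do)),(Os,Bd))` with configurable terminal
#' and internal branch lengths (expected substitutions per codon for the
#' simulator's defaults).
#'
#' @param terminal,internal Branch lengths for terminal and internal branches.
#' @return An `ape::phylo` object.
#' @export
grass_species_tree <- function(terminal = 0.1, internal = 0.15) {
  txt <- sprintf(.grass_newick,
                 terminal, terminal, internal, terminal, terminal, internal,
                 internal, terminal, terminal, internal)
  ape::read.tree(text = txt)
}

#' Restrict a tree to a set of taxa
#'
#' Drops all other tips and suppresses the resulting degree-2 nodes.
#'
#' @param tree An `ape::phylo`.
#' @param taxa Tip labels to keep.
#' @return Pruned `ape::phylo`.
#' @export
keep_species <- function(tree, taxa) {
  missing <- setdiff(taxa, tree$tip.label)
  if (length(missing)) {
    stop("taxa not in tree: ", paste(missing, collapse = ", "))
  }
  ape::keep.tip(tree, taxa)
}

# replace tip `tip` by a two-tip cherry (tip.1, tip.2)
.add_homeolog_cherry <- function(tree, tip = "Zm", twig = 0.05) {
  i <- match(tip, tree$tip.label)
  stopifnot(!is.na(i))
  cherry <- ape::read.tree(
    text = sprintf("(%s.1:%f,%s.2:%f);", tip, twig, tip, twig)
  )
  ape::bind.tree(tree, cherry, where = i)
}

#' Label C4 foreground branches
#'
#' Marks as foreground the stem branch of every maximal clade whose tips are
#' all C4 (rule `"stem_only"`, the default: the branches on which the C3 to
#' C4 transitions are inferred). Rule `"clade_all"` additionally marks every
#' branch inside those clades. All other branches are background.
#'
#' @param tree Rooted `ape::phylo`; tips must be species codes (homeolog
#'   suffixes `.1`/`.2` allowed, inheriting the species tag).
#' @param rule `"stem_only"` or `"clade_all"`.
#' @return `tree` with an integer attribute `eclass` aligned to
#'   `tree$edge` rows: 1 = background, 2 = foreground.
#' @export
label_foreground <- function(tree, rule = c("stem_only", "clade_all")) {
  rule <- match.arg(rule)
  tags <- c4_tags()
  sp <- .species_of(tree$tip.label)
  unknown <- setdiff(sp, names(tags))
  if (length(unknown)) {
    stop("unknown species code(s): ", paste(unique(unknown), collapse = ", "))
  }
  is_c4_tip <- unname(tags[sp])
  if (all(is_c4_tip) || !any(is_c4_tip)) {
    stop("foreground labeling undefined: all tips are ",
         if (all(is_c4_tip)) "C4" else "C3")
  }
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  allc4 <- rep(TRUE, nnode)
  allc4[seq_len(ntip)] <- is_c4_tip
  for (r in seq_len(nrow(po$edge))) {
    p <- po$edge[r, 1]; v <- po$edge[r, 2]
    allc4[p] <- allc4[p] && allc4[v]
  }
  root <- ntip + 1L
  eclass <- rep(1L, nrow(tree$edge))
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]; v <- tree$edge[r, 2]
    if (allc4[v]) {
      maximal <- (p == root) || !allc4[p]
      if (maximal || rule == "clade_all") eclass[r] <- 2L
    }
  }
  if (!any(eclass == 2L)) stop("no foreground branch found")
  attr(tree, "eclass") <- eclass
  tree
}

# ---------------------------------------------------------------------------
# Engine layout: 0-based postorder edge matrix; rooted input trees are
# unrooted (the two root edges merged; foreground wins the merged class)
# so that the branch model matches the unrooted parameterization.
# ---------------------------------------------------------------------------
.engine_tree <- function(tree, eclass = NULL, unroot = TRUE) {
  ntip <- length(tree$tip.label)
  edge <- tree$edge
  elen <- tree$edge.length
  if (is.null(elen)) elen <- rep(0.1, nrow(edge))
  if (is.null(eclass)) eclass <- attr(tree, "eclass")
  if (is.null(eclass)) eclass <- rep(1L, nrow(edge))
  stopifnot(length(eclass) == nrow(edge))
  root <- ntip + 1L
  ch <- which(edge[, 1] == root)
  if (unroot && length(ch) == 2L && ntip > 2L) {
    c1 <- edge[ch[1], 2]; c2 <- edge[ch[2], 2]
    if (c1 <= ntip && c2 > ntip) { tmp <- c1; c1 <- c2; c2 <- tmp }
    newlen <- elen[ch[1]] + elen[ch[2]]
    newclass <- max(eclass[ch])
    keep <- setdiff(seq_len(nrow(edge)), ch)
    edge <- rbind(edge[keep, , drop = FALSE], c(c1, c2))
    elen <- c(elen[keep], newlen)
    eclass <- c(eclass[keep], newclass)
    root <- c1
  }
  ord <- .postorder_edges(edge, root)
  list(
    edge0 = edge[ord, , drop = FALSE] - 1L,
    elen = elen[ord],
    eclass0 = as.integer(eclass[ord]) - 1L,
    ntip = ntip,
    tips = tree$tip.label,
    root = root
  )
}

# DFS postorder of edge rows from the root
.postorder_edges <- function(edge, root) {
  kids <- split(seq_len(nrow(edge)), edge[, 1])
  out <- integer(0)
  visit <- function(v) {
    for (r in kids[[as.character(v)]]) {
      visit(edge[r, 2])
      out[[length(out) + 1L]] <<- r
    }
  }
  visit(root)
  unlist(out)
}

# rebuild an ape::phylo (rooted at the trifurcation) from an engine tree and
# fitted branch lengths -- used to return fitted gene trees
.engine_to_phylo <- function(et, elen = et$elen) {
  edge <- et$edge0 + 1L
  ntip <- et$ntip
  nodes <- sort(unique(c(edge)))
  internals <- setdiff(nodes, seq_len(ntip))
  # root first, then the rest: ape requires root = ntip+1
  root <- et$root
  internals <- c(root, setdiff(internals, root))
  map <- integer(max(nodes))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[internals] <- ntip + seq_along(internals)
  phy <- list(
    edge = cbind(map[edge[, 1]], map[edge[, 2]]),
    edge.length = elen,
    tip.label = et$tips,
    Nnode = length(internals)
  )
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  ape::reorder.phylo(phy, "cladewise")
}
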