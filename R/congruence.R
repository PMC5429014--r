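# Gene-tree congruence filtering: third-position extraction, exhaustive ML
# gene-tree inference under GTR+Gamma+I, quartet distance, and the
# two-tree congruence verdict.

#' Third codon positions of an alignment
#'
#' @param aln A [codon_alignment()].
#' @return Named character vector: one nucleotide per codon column (gaps
#'   map to gaps).
#' @export
third_position_sites <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  vapply(unclass(aln), function(s) {
    n <- nchar(s)
    if (n == 0L) return("")
    paste(substring(s, seq(3L, n, 3L), seq(3L, n, 3L)), collapse = "")
  }, character(1))
}

# ---------------------------------------------------------------------------
# Topology enumeration (unrooted binary trees, trifurcating root node)
# ---------------------------------------------------------------------------

# all unrooted binary topologies over `tips` (3 <= n <= 7): recursive edge
# insertion; deterministic order
.all_topologies <- function(tips) {
  n <- length(tips)
  stopifnot(n >= 3L)
  # edges as (parent, child) integer matrices; tips 1..n, internals > n
  base <- matrix(c(n + 1L, 1L, n + 1L, 2L, n + 1L, 3L),
                 ncol = 2, byrow = TRUE)
  trees <- list(list(edge = base, nextid = n + 2L))
  if (n > 3L) {
    for (tip in 4:n) {
      trees <- unlist(lapply(trees, function(tr) {
        lapply(seq_len(nrow(tr$edge)), function(r) {
          w <- tr$nextid
          u <- tr$edge[r, 1]; v <- tr$edge[r, 2]
          edge <- rbind(tr$edge[-r, , drop = FALSE],
                        c(u, w), c(w, v), c(w, tip))
          list(edge = edge, nextid = w + 1L)
        })
      }), recursive = FALSE)
    }
  }
  lapply(trees, function(tr) .edges_to_phylo(tr$edge, tips))
}

# integer edge matrix (tips 1..n) -> ape::phylo with default branch lengths
.edges_to_phylo <- function(edge, tips, elen = 0.1) {
  ntip <- length(tips)
  root <- setdiff(unique(edge[, 1]), edge[, 2])
  internals <- c(root, setdiff(sort(unique(edge[, 1])), root))
  map <- integer(max(edge))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[internals] <- ntip + seq_along(internals)
  phy <- list(edge = cbind(map[edge[, 1]], map[edge[, 2]]),
              edge.length = rep(elen, nrow(edge)),
              tip.label = tips, Nnode = length(internals))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Canonical topology string
#'
#' Label-sorted newick of the unrooted topology (no branch lengths); equal
#' strings iff equal unrooted topologies given the same tip set and a
#' deterministic internal rooting.
#'
#' @param tree An `ape::phylo`.
#' @return Character scalar.
#' @export
canonical_topology <- function(tree) {
  tree <- ape::unroot(tree)
  ntip <- length(tree$tip.label)
  # root at the internal node adjacent to the alphabetically first tip
  first <- sort(tree$tip.label)[1]
  i <- match(first, tree$tip.label)
  anchor <- tree$edge[tree$edge[, 2] == i, 1]
  phy <- .reroot_at(tree, anchor)
  kids <- split(phy$edge[, 2], phy$edge[, 1])
  lab <- function(v) {
    if (v <= ntip) return(phy$tip.label[v])
    ch <- kids[[as.character(v)]]
    paste0("(", paste(sort(vapply(ch, lab, character(1))), collapse = ","),
           ")")
  }
  lab(ntip + 1L)
}

# re-root an unrooted phylo at internal node `node` (topology only)
.reroot_at <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node == ntip + 1L) return(tree)
  edge <- tree$edge
  # orient all edges away from `node` by BFS
  adj <- vector("list", max(edge))
  for (r in seq_len(nrow(edge))) {
    a <- edge[r, 1]; b <- edge[r, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(max(edge))
  out <- matrix(0L, nrow(edge), 2)
  k <- 0L
  queue <- node
  seen[node] <- TRUE
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <- TRUE
        k <- k + 1L
        out[k, ] <- c(v, w)
        queue <- c(queue, w)
      }
    }
  }
  internals <- c(node, setdiff(sort(unique(out[, 1])), node))
  map <- integer(max(out))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[internals] <- ntip + seq_along(internals)
  phy <- list(edge = cbind(map[out[, 1]], map[out[, 2]]),
              edge.length = rep(0.1, nrow(out)),
              tip.label = tree$tip.label, Nnode = length(internals))
  class(phy) <- "phylo"
  phy
}

# ---------------------------------------------------------------------------
# Gene-tree inference
# ---------------------------------------------------------------------------

#' ML gene tree by exhaustive topology evaluation
#'
#' Enumerates all unrooted binary topologies over the alignment's taxa
#' (3, 15, 105, 945 for 4-7 taxa) under GTR+Gamma+I with empirical base
#' frequencies and mismatch-derived exchangeabilities. Alpha and the
#' invariant proportion are estimated once on a neighbor-joining starting
#' topology and held fixed while every candidate topology gets
#' branch-length optimization; the best few are then re-optimized jointly.
#' For 7 taxa the 945 topologies are prescreened by Fitch parsimony and
#' the top `parsimony_top` (plus any `extra` topologies) are ML-scored.
#' Ties break by canonical topology string.
#'
#' @param aln Named nucleotide sequences (equal length) or character
#'   matrix.
#' @param k Gamma categories.
#' @param extra List of `ape::phylo` topologies always included in the
#'   ML-scored set (e.g. the species topology).
#' @param parsimony_top Parsimony prescreen size for 7 taxa.
#' @param refine_top Number of top candidates re-optimized jointly.
#' @return `ape::phylo` (trifurcating root) with attributes `loglik`,
#'   `alpha`, `p_inv`, `n_topologies`.
#' @export
infer_gene_tree <- function(aln, k = 4L, extra = list(),
                            parsimony_top = 40L, refine_top = 3L) {
  mat <- .as_nuc_matrix(aln)
  taxa <- rownames(mat)
  n <- length(taxa)
  if (n < 4L) stop("gene-tree inference needs at least 4 taxa")
  if (n > 7L) stop("gene-tree inference supports at most 7 taxa")
  emp <- .empirical_nuc(mat)
  dat <- .nuc_engine_data(mat, taxa)

  topos <- .all_topologies(taxa)
  canon <- vapply(topos, canonical_topology, character(1))

  # starting topology for the alpha / p_inv pre-fit: neighbor joining on
  # p-distances (falls back to the first topology on degenerate data)
  tr0 <- topos[[1L]]
  dm <- tryCatch({
    idx <- matrix(match(toupper(mat), .nuc), nrow = nrow(mat))
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        ok <- !is.na(idx[i, ]) & !is.na(idx[j, ])
        d[i, j] <- d[j, i] <- if (any(ok)) mean(idx[i, ok] != idx[j, ok]) else 0
      }
    }
    dimnames(d) <- list(taxa, taxa)
    d
  }, error = function(e) NULL)
  if (!is.null(dm) && all(is.finite(dm))) {
    njt <- tryCatch(ape::nj(as.dist(dm)), error = function(e) NULL)
    if (!is.null(njt)) {
      hit <- match(canonical_topology(njt), canon)
      if (!is.na(hit)) tr0 <- topos[[hit]]
    }
  }
  et0 <- .engine_tree(tr0, unroot = FALSE)
  pre <- .cpp_fit_nuc(et0$edge0, rep(0.1, nrow(et0$edge0)), emp$exch,
                      emp$pi, dat$tipc, dat$patw, 1.0, 0.1, as.integer(k),
                      rep(1L, nrow(et0$edge0)), TRUE, TRUE, 6L, 1e-4,
                      .BLEN_MAX)
  alpha <- pre$alpha
  pinv <- pre$p_inv

  # candidate set
  cand <- seq_along(topos)
  if (n == 7L && length(topos) > parsimony_top) {
    idx <- dat$pat
    bits <- matrix(0L, nrow(idx), ncol(idx))
    bits[!is.na(idx)] <- bitwShiftL(1L, idx[!is.na(idx)] - 1L)
    pars <- vapply(topos, function(tp) {
      et <- .engine_tree(tp, unroot = FALSE)
      .cpp_fitch(et$edge0, bits[match(et$tips, taxa), , drop = FALSE],
                 dat$patw)
    }, numeric(1))
    cand <- order(pars, canon)[seq_len(parsimony_top)]
  }
  for (ex in extra) {
    hit <- match(canonical_topology(ex), canon)
    if (!is.na(hit) && !(hit %in% cand)) cand <- c(cand, hit)
  }

  screen <- vapply(cand, function(ti) {
    et <- .engine_tree(topos[[ti]], unroot = FALSE)
    fit <- .cpp_fit_nuc(et$edge0, rep(0.1, nrow(et$edge0)), emp$exch,
                        emp$pi, dat$tipc, dat$patw, alpha, pinv,
                        as.integer(k), rep(1L, nrow(et$edge0)), FALSE,
                        FALSE, 2L, 1e-3, .BLEN_MAX)
    fit$loglik
  }, numeric(1))

  top <- cand[order(-screen, canon[cand])][seq_len(min(refine_top, length(cand)))]
  fits <- lapply(top, function(ti) {
    et <- .engine_tree(topos[[ti]], unroot = FALSE)
    fit <- .cpp_fit_nuc(et$edge0, rep(0.1, nrow(et$edge0)), emp$exch,
                        emp$pi, dat$tipc, dat$patw, alpha, pinv,
                        as.integer(k), rep(1L, nrow(et$edge0)), TRUE, TRUE,
                        10L, 1e-6, .BLEN_MAX)
    list(ti = ti, fit = fit, et = et)
  })
  lls <- vapply(fits, function(f) f$fit$loglik, numeric(1))
  best <- fits[[order(-lls, canon[vapply(fits, `[[`, integer(1), "ti")])[1]]]
  out <- .engine_to_phylo(best$et, as.numeric(best$fit$elen))
  attr(out, "loglik") <- best$fit$loglik
  attr(out, "alpha") <- best$fit$alpha
  attr(out, "p_inv") <- best$fit$p_inv
  attr(out, "n_topologies") <- length(cand)
  out
}

# ---------------------------------------------------------------------------
# Quartet distance
# ---------------------------------------------------------------------------

#' Quartet distance between two trees
#'
#' Number of 4-tip subsets on which the two trees induce different
#' unrooted quartet topologies, by explicit enumeration of all `C(n, 4)`
#' subsets (four-point condition on unit-length path distances).
#'
#' @param t1,t2 `ape::phylo` trees over the same tip set.
#' @return Integer count.
#' @export
quartet_distance <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) {
    stop("trees must share the same tip set")
  }
  tips <- sort(t1$tip.label)
  n <- length(tips)
  if (n < 4L) return(0L)
  code <- function(tree) {
    tr <- tree
    tr$edge.length <- rep(1, nrow(tr$edge))
    D <- stats::cophenetic(tr)[tips, tips]
    combs <- utils::combn(n, 4L)
    apply(combs, 2, function(q) {
      a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
      s <- c(D[a, b] + D[c, d], D[a, c] + D[b, d], D[a, d] + D[b, c])
      m <- which(s == min(s))
      if (length(m) > 1L) 0L else m
    })
  }
  sum(code(t1) != code(t2))
}

# ---------------------------------------------------------------------------
# Congruence verdict
# ---------------------------------------------------------------------------

#' Gene-tree congruence test
#'
#' Infers two gene trees for a group (all nucleotide sites; third codon
#' positions only), compares each against the species topology restricted
#' to the group's taxa by quartet distance, and passes the group iff at
#' least one tree is topologically identical (distance 0). Maize homeolog
#' tips must form a cherry in a gene tree (they are then collapsed to a
#' single maize tip before comparison); a tree where they are not sisters
#' fails.
#'
#' @param aln A [codon_alignment()] (post-trimming).
#' @param species_tree Base species tree.
#' @param k Gamma categories for gene-tree inference.
#' @return List of class `c4_congruence`: `tree_all`, `tree_third`,
#'   `qdist_all`, `qdist_third`, `pass`.
#' @export
congruence_test <- function(aln, species_tree = grass_species_tree(),
                            k = 4L) {
  taxa <- names(aln)
  species <- unique(.species_of(taxa))
  ref <- keep_species(species_tree, species)
  has_homeo <- any(grepl("\\.", taxa))
  guide <- ref
  if (has_homeo) guide <- .add_homeolog_cherry(ref, "Zm")

  all_sites <- setNames(as.character(unclass(aln)), taxa)
  third <- third_position_sites(aln)

  one <- function(seqs) {
    gt <- infer_gene_tree(seqs, k = k, extra = list(guide))
    if (has_homeo) {
      if (!.is_cherry(gt, c("Zm.1", "Zm.2"))) {
        return(list(tree = gt, qdist = NA_integer_))
      }
      gt2 <- ape::drop.tip(gt, "Zm.2")
      gt2$tip.label[gt2$tip.label == "Zm.1"] <- "Zm"
      return(list(tree = gt, qdist = quartet_distance(gt2, ref)))
    }
    list(tree = gt, qdist = quartet_distance(gt, ref))
  }
  ra <- one(all_sites)
  rt <- one(third)
  out <- list(tree_all = ra$tree, tree_third = rt$tree,
              qdist_all = ra$qdist, qdist_third = rt$qdist,
              pass = isTRUE(ra$qdist == 0L) || isTRUE(rt$qdist == 0L))
  class(out) <- "c4_congruence"
  out
}

#' @export
print.c4_congruence <- function(x, ...) {
  cat("<c4_congruence> qdist(all sites) =", x$qdist_all,
      "| qdist(3rd positions) =", x$qdist_third,
      "|", if (x$pass) "PASS" else "EXCLUDE", "\n")
  invisible(x)
}

# do the two given tips form a cherry (share an internal parent)?
.is_cherry <- function(tree, tips) {
  i <- match(tips, tree$tip.label)
  if (any(is.na(i))) return(FALSE)
  p <- tree$edge[match(i, tree$edge[, 2]), 1]
  p[1] == p[2]
}
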