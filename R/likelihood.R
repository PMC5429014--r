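# Bridges between R containers and the C++ pruning engine: site-pattern
# compression, tip partial likelihoods, and the user-facing pruning
# log-likelihood.

# codon alignment -> compressed engine data, tips ordered as `taxa`
.codon_engine_data <- function(aln, taxa) {
  m <- as.matrix(aln)
  if (!all(taxa %in% rownames(m))) {
    stop("alignment is missing taxa: ",
         paste(setdiff(taxa, rownames(m)), collapse = ", "))
  }
  m <- m[taxa, , drop = FALSE]
  idx <- matrix(.codon_index(m), nrow = nrow(m))
  .compress_patterns(idx, 61L)
}

# nucleotide matrix (rows taxa, single characters) -> engine data
.nuc_engine_data <- function(mat, taxa) {
  if (!all(taxa %in% rownames(mat))) {
    stop("alignment is missing taxa: ",
         paste(setdiff(taxa, rownames(mat)), collapse = ", "))
  }
  mat <- mat[taxa, , drop = FALSE]
  idx <- matrix(match(toupper(mat), .nuc), nrow = nrow(mat))
  .compress_patterns(idx, 4L)
}

# integer state matrix (ntaxa x ncol, NA = missing) -> pattern cube + weights
.compress_patterns <- function(idx, nstate) {
  ntip <- nrow(idx)
  if (ncol(idx) == 0L) stop("alignment has no columns")
  key <- apply(idx, 2, paste, collapse = ",")
  u <- which(!duplicated(key))
  patw <- as.numeric(table(factor(key, levels = key[u])))
  pat <- idx[, u, drop = FALSE]
  npat <- ncol(pat)
  tipc <- array(0, dim = c(nstate, npat, ntip))
  for (i in seq_len(ntip)) {
    v <- pat[i, ]
    known <- which(!is.na(v))
    if (length(known)) tipc[cbind(v[known], known, i)] <- 1
    miss <- which(is.na(v))
    if (length(miss)) tipc[, miss, i] <- 1
  }
  list(tipc = tipc, patw = patw, npat = npat, pat = pat)
}

#' Pruning log-likelihood
#'
#' Computes the phylogenetic log-likelihood of an alignment on a tree by
#' Felsenstein's pruning algorithm (post-order partial likelihoods), for
#' either a codon branch-model ([codon_model()]) on a [codon_alignment()],
#' or a GTR+Gamma+I model ([gtr_model()]) on a named character vector /
#' matrix of nucleotide sequences. Gap and ambiguous states contribute
#' partial likelihood 1 for every state. With a reversible model the result
#' is invariant to the root position (the tree is unrooted internally).
#'
#' @param tree Rooted `ape::phylo` containing all alignment taxa; for a
#'   codon model with a `foreground` omega class the tree should carry the
#'   `eclass` attribute set by [label_foreground()].
#' @param alignment See description.
#' @param model A [codon_model()] or [gtr_model()].
#' @return Log-likelihood (scalar).
#' @export
prune_loglik <- function(tree, alignment, model) {
  if (inherits(model, "codon_model")) {
    aln_taxa <- names(alignment)
    if (!all(aln_taxa %in% tree$tip.label)) {
      stop("alignment taxa absent from tree: ",
           paste(setdiff(aln_taxa, tree$tip.label), collapse = ", "))
    }
    if (length(aln_taxa) < length(tree$tip.label)) {
      tree <- keep_species(tree, aln_taxa)
    }
    et <- .engine_tree(tree)
    dat <- .codon_engine_data(alignment, et$tips)
    omega <- model$omega
    nclass <- max(et$eclass0) + 1L
    if (length(omega) < nclass) {
      stop("model provides ", length(omega), " omega class(es) but tree has ",
           nclass)
    }
    .cpp_loglik_codon(et$edge0, et$elen, et$eclass0,
                      .codon_tables()$ctype, model$pi, dat$tipc, dat$patw,
                      model$kappa, unname(omega[seq_len(nclass)]))
  } else if (inherits(model, "gtr_model")) {
    mat <- .as_nuc_matrix(alignment)
    if (!all(rownames(mat) %in% tree$tip.label)) {
      stop("alignment taxa absent from tree: ",
           paste(setdiff(rownames(mat), tree$tip.label), collapse = ", "))
    }
    if (nrow(mat) < length(tree$tip.label)) {
      tree <- keep_species(tree, rownames(mat))
    }
    et <- .engine_tree(tree)
    dat <- .nuc_engine_data(mat, et$tips)
    .cpp_loglik_nuc(et$edge0, et$elen, model$exch, model$pi, dat$tipc,
                    dat$patw, model$alpha, model$p_inv, model$k)
  } else {
    stop("model must be a codon_model or gtr_model")
  }
}

# named character vector of sequences -> character matrix (rows taxa)
.as_nuc_matrix <- function(alignment) {
  if (is.matrix(alignment)) return(alignment)
  stopifnot(is.character(alignment), !is.null(names(alignment)))
  L <- unique(nchar(alignment))
  if (length(L) != 1L) stop("sequences must have equal length")
  m <- do.call(rbind, strsplit(toupper(alignment), ""))
  rownames(m) <- names(alignment)
  m
}
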