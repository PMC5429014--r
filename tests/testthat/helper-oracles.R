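# Independent brute-force oracles. These deliberately avoid the package's
# C++ engine and dynamic-programming code: likelihoods are exhaustive sums
# over internal-node states, alignments are plain R dynamic programs,
# quartet topologies come from split enumeration.

# exhaustive-marginalization log-likelihood of one site-pattern column.
# tree: rooted ape::phylo; P_of(edge_row) -> transition matrix;
# tipstate: named integer vector (NA = missing); pi: root frequencies.
oracle_column_lik <- function(tree, P_of, tipstate, pi) {
  ntip <- length(tree$tip.label)
  nstate <- length(pi)
  internals <- sort(unique(tree$edge[, 1]))
  g <- do.call(expand.grid, rep(list(seq_len(nstate)), length(internals)))
  idx_of <- function(node) match(node, internals)
  prob <- pi[g[, idx_of(ntip + 1L)]]
  for (r in seq_len(nrow(tree$edge))) {
    p <- tree$edge[r, 1]
    v <- tree$edge[r, 2]
    P <- P_of(r)
    if (v <= ntip) {
      s <- tipstate[[tree$tip.label[v]]]
      if (!is.na(s)) prob <- prob * P[cbind(g[, idx_of(p)], s)]
      # missing tip: sum_j P[.,j] = 1, factor 1
    } else {
      prob <- prob * P[cbind(g[, idx_of(p)], g[, idx_of(v)])]
    }
  }
  sum(prob)
}

# full exhaustive lnL over columns and mixture categories
oracle_loglik <- function(tree, P_of_cat, columns, pi, rates = 1, rw = 1) {
  ll <- 0
  for (col in columns) {
    lik <- 0
    for (c in seq_along(rates)) {
      lik <- lik + rw[c] * oracle_column_lik(
        tree, function(r) P_of_cat(r, c), col, pi)
    }
    ll <- ll + log(lik)
  }
  ll
}

# global affine-gap alignment score (gap of length L costs open+(L-1)*ext),
# scores from a substitution matrix; mirrors the package's convention
oracle_nw_score <- function(a, b, sub, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -open - (i - 2) * ext
  for (j in 2:(m + 1)) Y[1, j] <- -open - (j - 2) * ext
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- sub[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open,
                     Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# local Smith-Waterman score, same gap convention
oracle_sw_score <- function(a, b, match, mismatch, open, ext) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e30
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(NEG, n + 1, m + 1)
  Fm <- matrix(NEG, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      E[i, j] <- max(H[i - 1, j] - open, E[i - 1, j] - ext)
      Fm[i, j] <- max(H[i, j - 1] - open, Fm[i, j - 1] - ext)
      s <- if (A[i - 1] == B[j - 1]) match else mismatch
      H[i, j] <- max(0, H[i - 1, j - 1] + s, E[i, j], Fm[i, j])
      best <- max(best, H[i, j])
    }
  }
  best
}

# quartet distance by split enumeration (independent of the cophenetic
# four-point route used in the package)
oracle_quartet_distance <- function(t1, t2) {
  tips <- sort(t1$tip.label)
  splits_of <- function(tree) {
    tree <- ape::unroot(tree)
    ntip <- length(tree$tip.label)
    out <- list()
    for (r in seq_len(nrow(tree$edge))) {
      v <- tree$edge[r, 2]
      if (v <= ntip) next
      below <- ape::extract.clade(tree, v)$tip.label
      out[[length(out) + 1L]] <- below
    }
    out
  }
  quartet_top <- function(splits, q) {
    for (s in splits) {
      inside <- q %in% s
      if (sum(inside) == 2L) {
        # canonical form: the pair containing the smallest member
        pair <- sort(q[inside])
        if (!(min(q) %in% pair)) pair <- sort(q[!inside])
        return(paste(pair, collapse = "|"))
      }
    }
    "star"
  }
  s1 <- splits_of(t1)
  s2 <- splits_of(t2)
  combs <- utils::combn(tips, 4L)
  sum(vapply(seq_len(ncol(combs)), function(k) {
    q <- combs[, k]
    quartet_top(s1, q) != quartet_top(s2, q)
  }, logical(1)))
}

# hypergeometric upper tail by direct lchoose summation
oracle_hyper_upper <- function(N, K, n, obs) {
  k <- seq(obs, min(K, n))
  sum(exp(lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)))
}

# random in-frame CDS of n codons (sense codons only)
random_cds <- function(n, seed) {
  set.seed(seed)
  paste(sample(sense_codons(), n, replace = TRUE), collapse = "")
}

# P-matrix closure for codon models over a (possibly class-labeled) tree,
# built from the R-side matrix constructors only
oracle_codon_P_of <- function(tree, model) {
  eclass <- attr(tree, "eclass")
  if (is.null(eclass)) eclass <- rep(1L, nrow(tree$edge))
  Qs <- lapply(seq_along(model$omega), function(cl) {
    codon_rate_matrix(model, omega = model$omega[[cl]])
  })
  function(r, cat) transition_matrix(Qs[[eclass[r]]], tree$edge.length[r])
}
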