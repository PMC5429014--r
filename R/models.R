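# Substitution model parameter containers and rate-matrix constructors:
# Goldman-Yang style codon model with branch classes, and GTR+Gamma+I.

.check_freqs <- function(pi, n, what) {
  if (!is.numeric(pi) || length(pi) != n) {
    stop(what, " frequencies must be a numeric vector of length ", n)
  }
  if (any(pi < 0) || any(!is.finite(pi))) {
    stop(what, " frequencies must be finite and non-negative")
  }
  if (abs(sum(pi) - 1) > 1e-6) {
    stop(what, " frequencies must sum to 1 (got ", format(sum(pi)), ")")
  }
  pi / sum(pi)
}

#' Codon substitution model (branch-class omega)
#'
#' Parameters of a Goldman-Yang style codon model over the 61 sense codons:
#' instantaneous changes are single-nucleotide only, with rate
#' `pi_j * kappa^[transition] * omega^[nonsynonymous]`. `omega` is a named
#' vector mapping branch classes (`background`, `foreground`) to dN/dS
#' ratios; trees carry the matching branch-class labels.
#'
#' @param kappa Transition/transversion rate ratio (>= 0).
#' @param omega Named numeric vector of dN/dS per branch class; a single
#'   unnamed value is taken as `background`.
#' @param pi 61 sense-codon stationary frequencies (defaults to uniform).
#' @param scaled If `TRUE` (default) rate matrices are normalized to one
#'   expected substitution per codon per unit branch length.
#' @return Object of class `codon_model`.
#' @export
codon_model <- function(kappa = 2, omega = c(background = 0.2),
                        pi = rep(1 / 61, 61), scaled = TRUE) {
  stopifnot(is.numeric(kappa), length(kappa) == 1L, kappa >= 0)
  if (is.null(names(omega))) {
    names(omega) <- c("background", "foreground")[seq_along(omega)]
  }
  if (any(omega < 0)) stop("omega must be >= 0")
  pi <- .check_freqs(pi, 61L, "codon")
  structure(
    list(kappa = kappa, omega = omega, pi = pi, scaled = scaled),
    class = "codon_model"
  )
}

#' @export
print.codon_model <- function(x, ...) {
  cat("<codon_model> kappa =", format(x$kappa, digits = 4),
      "| omega:", paste(names(x$omega), format(x$omega, digits = 4),
                        sep = "=", collapse = ", "),
      "|", if (x$scaled) "scaled" else "unscaled", "\n")
  invisible(x)
}

#' Codon instantaneous rate matrix
#'
#' Builds the 61x61 rate matrix for one branch class. Entries between codons
#' differing at more than one nucleotide position are zero; single-nucleotide
#' changes get `pi_j`, multiplied by `kappa` for transitions and by `omega`
#' for nonsynonymous changes. The diagonal makes rows sum to zero, and when
#' `model$scaled` is set the matrix is normalized so that
#' `-sum(pi_i Q_ii) = 1`.
#'
#' @param model A [codon_model()].
#' @param omega dN/dS ratio to use; defaults to the model's first class.
#' @return 61x61 matrix with codon dimnames.
#' @export
codon_rate_matrix <- function(model, omega = NULL) {
  stopifnot(inherits(model, "codon_model"))
  if (is.null(omega)) omega <- model$omega[[1]]
  stopifnot(is.numeric(omega), length(omega) == 1L, omega >= 0)
  tab <- .codon_tables()
  pi <- model$pi
  fac <- matrix(0, 61, 61)
  fac[tab$ctype == 1L] <- 1
  fac[tab$ctype == 2L] <- model$kappa
  fac[tab$ctype == 3L] <- omega
  fac[tab$ctype == 4L] <- model$kappa * omega
  Q <- fac * rep(pi, each = 61)
  diag(Q) <- -rowSums(Q)
  if (model$scaled) {
    mu <- -sum(pi * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  dimnames(Q) <- list(tab$codons, tab$codons)
  Q
}

#' Nucleotide GTR+Gamma+I model
#'
#' @param exch Six GTR exchangeabilities in order AC, AG, AT, CG, CT, GT.
#' @param pi Base frequencies (A, C, G, T).
#' @param alpha Gamma shape for among-site rate variation (> 0).
#' @param p_inv Proportion of invariant sites in `[0, 1)`.
#' @param k Number of discrete gamma categories (>= 1).
#' @return Object of class `gtr_model`.
#' @export
gtr_model <- function(exch = rep(1, 6), pi = rep(0.25, 4), alpha = 1,
                      p_inv = 0, k = 4L) {
  stopifnot(length(exch) == 6L, all(exch >= 0), all(is.finite(exch)))
  if (all(exch == 0)) stop("at least one exchangeability must be positive")
  pi <- .check_freqs(pi, 4L, "base")
  stopifnot(alpha > 0, p_inv >= 0, p_inv < 1, k >= 1L)
  structure(
    list(exch = as.numeric(exch), pi = pi, alpha = alpha,
         p_inv = p_inv, k = as.integer(k)),
    class = "gtr_model"
  )
}

#' @export
print.gtr_model <- function(x, ...) {
  cat("<gtr_model> alpha =", format(x$alpha, digits = 4),
      "p_inv =", format(x$p_inv, digits = 4), "k =", x$k, "\n")
  invisible(x)
}

#' GTR instantaneous rate matrix
#'
#' `Q_ij = s_ij * pi_j` for `i != j`, diagonal set so rows sum to zero,
#' normalized to unit mean rate (`-sum(pi_i Q_ii) = 1`).
#'
#' @param model A [gtr_model()].
#' @return 4x4 matrix with A,C,G,T dimnames.
#' @export
gtr_rate_matrix <- function(model) {
  stopifnot(inherits(model, "gtr_model"))
  s <- model$exch
  pi <- model$pi
  # fill by explicit index to keep the AC,AG,AT,CG,CT,GT order unambiguous
  S <- matrix(0, 4, 4)
  idx <- rbind(c(1, 2, 1), c(1, 3, 2), c(1, 4, 3), c(2, 3, 4), c(2, 4, 5), c(3, 4, 6))
  for (r in seq_len(nrow(idx))) {
    S[idx[r, 1], idx[r, 2]] <- s[idx[r, 3]]
    S[idx[r, 2], idx[r, 1]] <- s[idx[r, 3]]
  }
  Q <- S * rep(pi, each = 4)
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  if (mu > 0) Q <- Q / mu
  dimnames(Q) <- list(.nuc, .nuc)
  Q
}

#' Transition probability matrix
#'
#' Matrix exponential `P = exp(Q t)`. Rows are renormalized defensively and
#' negatives below numerical noise are clamped to zero.
#'
#' @param Q Instantaneous rate matrix (rows sum to 0).
#' @param t Branch length, `t >= 0`.
#' @return Probability matrix of the same dimension.
#' @export
transition_matrix <- function(Q, t) {
  stopifnot(is.matrix(Q), nrow(Q) == ncol(Q))
  if (!is.numeric(t) || length(t) != 1L || t < 0) {
    stop("branch length t must be a single non-negative number")
  }
  e <- eigen(Q)
  P <- Re(e$vectors %*% diag(exp(e$values * t), nrow(Q)) %*% solve(e$vectors))
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- dimnames(Q)
  P
}

#' Discrete-gamma rate categories
#'
#' Splits `Gamma(alpha, alpha)` (mean 1) into `k` equal-probability segments
#' and returns the mean rate of each segment; the mean of the returned rates
#' is 1.
#'
#' @param alpha Gamma shape (> 0).
#' @param k Number of categories (>= 1).
#' @return Numeric vector of k rates.
#' @export
discretize_gamma <- function(alpha, k) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0)
  if (!is.numeric(k) || length(k) != 1L || k < 1) {
    stop("k must be a positive integer")
  }
  as.numeric(.cpp_gamma_rates(alpha, as.integer(k)))
}

#' Empirical F3x4 codon frequencies
#'
#' Position-specific nucleotide frequencies of an alignment (gaps and
#' ambiguity excluded), multiplied across the three codon positions,
#' restricted to sense codons and renormalized. Frequencies are floored at
#' 1e-8 so that codons unseen at some position keep a usable likelihood.
#'
#' @param aln A [codon_alignment()] or named character vector of in-frame
#'   sequences.
#' @return Numeric vector of 61 codon frequencies (named).
#' @export
f3x4_frequencies <- function(aln) {
  seqs <- if (inherits(aln, "codon_alignment")) unclass(aln) else aln
  tab <- .codon_tables()
  chars <- strsplit(toupper(paste(seqs, collapse = "")), "")[[1]]
  pos <- rep_len(1:3, length(chars))
  f <- matrix(0, 3, 4, dimnames = list(NULL, .nuc))
  for (p in 1:3) {
    cc <- chars[pos == p]
    cc <- cc[cc %in% .nuc]
    if (length(cc) == 0L) {
      f[p, ] <- 0.25
    } else {
      f[p, ] <- tabulate(match(cc, .nuc), 4L) / length(cc)
    }
  }
  spl <- do.call(rbind, strsplit(tab$codons, ""))
  pi <- f[1, spl[, 1]] * f[2, spl[, 2]] * f[3, spl[, 3]]
  pi <- pmax(pi, 1e-8)
  pi <- pi / sum(pi)
  names(pi) <- tab$codons
  pi
}

# empirical GTR ingredients from a nucleotide alignment matrix (rows taxa)
.empirical_nuc <- function(mat) {
  v <- mat[mat %in% .nuc]
  pi <- if (length(v)) tabulate(match(v, .nuc), 4L) / length(v) else rep(0.25, 4)
  pi <- pmax(pi, 1e-4)
  pi <- pi / sum(pi)
  # mismatch-type counts over all sequence pairs -> exchangeabilities
  n <- nrow(mat)
  cnt <- matrix(0, 4, 4)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        a <- match(mat[i, ], .nuc)
        b <- match(mat[j, ], .nuc)
        ok <- !is.na(a) & !is.na(b)
        if (any(ok)) {
          tt <- table(factor(a[ok], levels = 1:4), factor(b[ok], levels = 1:4))
          cnt <- cnt + tt + t(tt)
        }
      }
    }
  }
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  exch <- vapply(seq_len(6), function(r) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    cnt[i, j] / (pi[i] * pi[j])
  }, numeric(1))
  if (all(exch == 0)) exch <- rep(1, 6)
  exch <- exch + 0.05 * mean(exch[exch > 0])  # regularize rare types
  exch <- exch / exch[2]                      # AG = 1 reference
  list(pi = pi, exch = exch)
}
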