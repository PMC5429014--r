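# Maximum-likelihood fitting (deterministic coordinate cycling with bounded
# 1-D line searches) and the branch-model likelihood-ratio test.

.OMEGA_STARTS <- c(0.1, 0.5, 2.0)
.OMEGA_BOUNDS <- c(1e-4, 50)
.KAPPA_BOUNDS <- c(1e-3, 100)
.BLEN_MAX <- 20

#' Fit a substitution model by maximum likelihood
#'
#' Coordinate-cycling optimization: per-branch Brent line searches for
#' branch lengths, then bounded line searches for the model parameters,
#' iterated until the log-likelihood improves by less than `tol` (or
#' `max_cycles` is reached). Frequencies are always empirical, never
#' optimized. Deterministic given its inputs.
#'
#' @param tree Rooted `ape::phylo`; for codon models carry `eclass` from
#'   [label_foreground()] if a foreground omega is wanted.
#' @param alignment [codon_alignment()] (codon context) or named nucleotide
#'   sequences (GTR context).
#' @param model [codon_model()] or [gtr_model()] holding starting values.
#' @param free Parameters to optimize: subset of
#'   `c("blen", "kappa", "omega")` for codon models, `c("blen", "alpha",
#'   "p_inv")` for nucleotide models. Empty set returns the initial
#'   log-likelihood unchanged.
#' @param tol Convergence tolerance in log-likelihood units.
#' @param max_cycles Cycle cap.
#' @return Object of class `c4_fit`: `loglik`, `model` (fitted), `tree`
#'   (fitted branch lengths), `iterations`, `converged`.
#' @export
fit_model <- function(tree, alignment, model,
                      free = c("blen", "kappa", "omega"),
                      tol = 1e-6, max_cycles = 200L) {
  if (inherits(model, "codon_model")) {
    bad <- setdiff(free, c("blen", "kappa", "omega"))
    if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))
    et <- .engine_tree(tree)
    dat <- .codon_engine_data(alignment, et$tips)
    nclass <- max(et$eclass0) + 1L
    omega0 <- unname(model$omega[seq_len(nclass)])
    fit <- .cpp_fit_codon(
      et$edge0, et$elen, et$eclass0, .codon_tables()$ctype, model$pi,
      dat$tipc, dat$patw, model$kappa, omega0,
      rep(as.integer("blen" %in% free), nrow(et$edge0)),
      "kappa" %in% free, rep(as.integer("omega" %in% free), nclass),
      as.integer(max_cycles), tol, .BLEN_MAX,
      .KAPPA_BOUNDS[1], .KAPPA_BOUNDS[2], .OMEGA_BOUNDS[1], .OMEGA_BOUNDS[2]
    )
    out_model <- model
    out_model$kappa <- fit$kappa
    out_model$omega <- setNames(as.numeric(fit$omega),
                                names(model$omega)[seq_len(nclass)])
    structure(
      list(loglik = fit$loglik, model = out_model,
           tree = .engine_to_phylo(et, as.numeric(fit$elen)),
           iterations = fit$cycles, converged = fit$converged,
           loglik_initial = fit$loglik0, context = "codon"),
      class = "c4_fit"
    )
  } else if (inherits(model, "gtr_model")) {
    bad <- setdiff(free, c("blen", "alpha", "p_inv"))
    if (length(bad)) stop("unknown free parameters: ", paste(bad, collapse = ", "))
    mat <- .as_nuc_matrix(alignment)
    et <- .engine_tree(tree)
    dat <- .nuc_engine_data(mat, et$tips)
    fit <- .cpp_fit_nuc(
      et$edge0, et$elen, model$exch, model$pi, dat$tipc, dat$patw,
      model$alpha, model$p_inv, model$k,
      rep(as.integer("blen" %in% free), nrow(et$edge0)),
      "alpha" %in% free, "p_inv" %in% free,
      as.integer(max_cycles), tol, .BLEN_MAX
    )
    out_model <- model
    out_model$alpha <- fit$alpha
    out_model$p_inv <- fit$p_inv
    structure(
      list(loglik = fit$loglik, model = out_model,
           tree = .engine_to_phylo(et, as.numeric(fit$elen)),
           iterations = fit$cycles, converged = fit$converged,
           loglik_initial = fit$loglik0, context = "nucleotide"),
      class = "c4_fit"
    )
  } else {
    stop("model must be a codon_model or gtr_model")
  }
}

#' @export
print.c4_fit <- function(x, ...) {
  cat("<c4_fit> lnL =", format(x$loglik, digits = 8),
      "| cycles =", x$iterations,
      "|", if (isTRUE(x$converged)) "converged" else "not converged", "\n")
  invisible(x)
}

# distance between two sequences implied by a fitted 2-taxon tree
.tree_length <- function(fit) sum(fit$tree$edge.length)

#' Branch-model likelihood-ratio test
#'
#' Tests for a dN/dS ratio on the C4 foreground branches different from the
#' background. H0: one omega shared by all branches; Ha: an independent
#' omega for the foreground class. Both hypotheses share empirical F3x4
#' codon frequencies and independently optimized branch lengths and kappa.
#' The statistic `2(lnL1 - lnL0)` (clamped at zero) is referred to a
#' chi-square with 1 df.
#'
#' Alignments with zero variation leave omega unidentifiable: the test
#' reports `stat = 0`, `p = 1` and `NA` omegas rather than failing.
#'
#' The alternative fit chooses its foreground-omega start from the fixed
#' ladder 0.1 / 0.5 / 2.0 (plus the H0 estimate) by screening likelihoods;
#' `n_starts = 3` runs the full optimization from every ladder start
#' instead.
#'
#' @param alignment A [codon_alignment()].
#' @param tree Rooted `ape::phylo` covering the alignment taxa; foreground
#'   branches from the `eclass` attribute ([label_foreground()] is applied
#'   with `rule` if absent).
#' @param rule Foreground rule if the tree is unlabeled.
#' @param kappa_init Starting kappa.
#' @param n_starts 1 (screened start, default) or 3 (full multi-start).
#' @param tol,max_cycles Optimizer controls, see [fit_model()].
#' @return Object of class `c4_lrt`: `lnL0`, `lnL1`, `stat`, `df`, `p`,
#'   `omega_fg`, `omega_bg`, `kappa`, `converged`.
#' @export
lrt_branch_model <- function(alignment, tree, rule = "stem_only",
                             kappa_init = 2, n_starts = 1L, tol = 1e-6,
                             max_cycles = 200L) {
  stopifnot(inherits(alignment, "codon_alignment"))
  taxa <- names(alignment)
  if (!all(taxa %in% tree$tip.label)) {
    stop("alignment taxa absent from tree: ",
         paste(setdiff(taxa, tree$tip.label), collapse = ", "))
  }
  if (length(taxa) < length(tree$tip.label)) {
    cls <- attr(tree, "eclass")
    tree <- keep_species(tree, taxa)
    if (!is.null(cls)) tree <- label_foreground(tree, rule)
  }
  if (is.null(attr(tree, "eclass"))) {
    tree <- label_foreground(tree, rule)
  }
  eclass <- attr(tree, "eclass")
  if (!any(eclass == 2L) || all(eclass == 2L)) {
    stop("foreground must be a nonempty strict subset of branches")
  }

  pi <- f3x4_frequencies(alignment)
  et <- .engine_tree(tree)
  dat <- .codon_engine_data(alignment, et$tips)
  ctype <- .codon_tables()$ctype

  is_const <- apply(dat$pat, 2, function(v) {
    v <- v[!is.na(v)]
    length(unique(v)) <= 1L
  })
  if (all(is_const)) {
    # zero variation: likelihood maximized at zero branch lengths
    states <- apply(dat$pat, 2, function(v) {
      v <- v[!is.na(v)]
      if (length(v)) v[1] else NA_integer_
    })
    contrib <- ifelse(is.na(states), 0, log(pmax(pi[states], 1e-300)))
    ln <- sum(dat$patw * contrib)
    out <- list(lnL0 = ln, lnL1 = ln, stat = 0, df = 1L, p = 1,
                omega_fg = NA_real_, omega_bg = NA_real_,
                kappa = NA_real_, converged = TRUE, degenerate = TRUE)
    class(out) <- "c4_lrt"
    return(out)
  }

  free_all <- rep(1L, nrow(et$edge0))
  eclass0_h0 <- rep(0L, nrow(et$edge0))

  h0_screen <- vapply(.OMEGA_STARTS, function(w) {
    .cpp_loglik_codon(et$edge0, et$elen, eclass0_h0, ctype, pi, dat$tipc,
                      dat$patw, kappa_init, w)
  }, numeric(1))
  h0 <- .cpp_fit_codon(et$edge0, et$elen, eclass0_h0, ctype, pi, dat$tipc,
                       dat$patw, kappa_init,
                       .OMEGA_STARTS[which.max(h0_screen)],
                       free_all, TRUE, 1L, as.integer(max_cycles), tol,
                       .BLEN_MAX, .KAPPA_BOUNDS[1], .KAPPA_BOUNDS[2],
                       .OMEGA_BOUNDS[1], .OMEGA_BOUNDS[2])

  run_ha <- function(w_fg_start, elen0, kappa0, w_bg0) {
    .cpp_fit_codon(et$edge0, elen0, et$eclass0, ctype, pi, dat$tipc,
                   dat$patw, kappa0, c(w_bg0, w_fg_start),
                   free_all, TRUE, c(1L, 1L), as.integer(max_cycles), tol,
                   .BLEN_MAX, .KAPPA_BOUNDS[1], .KAPPA_BOUNDS[2],
                   .OMEGA_BOUNDS[1], .OMEGA_BOUNDS[2])
  }
  w_bg0 <- as.numeric(h0$omega)
  elen0 <- as.numeric(h0$elen)
  starts <- unique(c(.OMEGA_STARTS, w_bg0))
  if (n_starts >= 3L) {
    fits <- lapply(starts, run_ha, elen0 = elen0, kappa0 = h0$kappa,
                   w_bg0 = w_bg0)
    ha <- fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
  } else {
    screen <- vapply(starts, function(w) {
      .cpp_loglik_codon(et$edge0, elen0, et$eclass0, ctype, pi, dat$tipc,
                        dat$patw, h0$kappa, c(w_bg0, w))
    }, numeric(1))
    ha <- run_ha(starts[which.max(screen)], elen0, h0$kappa, w_bg0)
  }

  lnL0 <- h0$loglik
  lnL1 <- max(ha$loglik, lnL0) # H0 nested in Ha
  stat <- max(0, 2 * (ha$loglik - lnL0))
  out <- list(
    lnL0 = lnL0, lnL1 = lnL1, stat = stat, df = 1L,
    p = pchisq(stat, df = 1, lower.tail = FALSE),
    omega_fg = as.numeric(ha$omega[2]), omega_bg = as.numeric(ha$omega[1]),
    kappa = ha$kappa,
    converged = isTRUE(h0$converged) && isTRUE(ha$converged),
    degenerate = FALSE
  )
  class(out) <- "c4_lrt"
  out
}

#' @export
print.c4_lrt <- function(x, ...) {
  cat("<c4_lrt> 2dlnL =", format(x$stat, digits = 5),
      " p =", format(x$p, digits = 4),
      " omega_fg =", format(x$omega_fg, digits = 4),
      " omega_bg =", format(x$omega_bg, digits = 4), "\n")
  invisible(x)
}
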