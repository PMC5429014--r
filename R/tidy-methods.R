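# broom-style accessors and ggplot2 autoplot methods for the result types

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a branch-model LRT
#'
#' @param x A `c4_lrt` from [lrt_branch_model()].
#' @param ... Unused.
#' @return One-row tibble: `lnL0`, `lnL1`, `stat`, `df`, `p`, `omega_fg`,
#'   `omega_bg`, `kappa`, `converged`.
#' @export
tidy.c4_lrt <- function(x, ...) {
  tibble::tibble(lnL0 = x$lnL0, lnL1 = x$lnL1, stat = x$stat,
                 df = x$df, p = x$p, omega_fg = x$omega_fg,
                 omega_bg = x$omega_bg, kappa = x$kappa,
                 converged = x$converged)
}

#' Tidy a model fit
#'
#' @param x A `c4_fit` from [fit_model()].
#' @param ... Unused.
#' @return Tibble of fitted parameters (one row per parameter).
#' @export
tidy.c4_fit <- function(x, ...) {
  m <- x$model
  if (inherits(m, "codon_model")) {
    tibble::tibble(
      term = c("kappa", paste0("omega_", names(m$omega))),
      estimate = c(m$kappa, unname(m$omega)))
  } else {
    tibble::tibble(term = c("alpha", "p_inv"),
                   estimate = c(m$alpha, m$p_inv))
  }
}

#' Fit summary
#'
#' @param x A `c4_fit`.
#' @param ... Unused.
#' @return One-row tibble: `logLik`, `iterations`, `converged`,
#'   `tree_length`.
#' @export
glance.c4_fit <- function(x, ...) {
  tibble::tibble(logLik = x$loglik, iterations = x$iterations,
                 converged = x$converged,
                 tree_length = sum(x$tree$edge.length))
}

#' Tidy a congruence verdict
#'
#' @param x A `c4_congruence`.
#' @param ... Unused.
#' @return One-row tibble with the two quartet distances and the verdict.
#' @export
tidy.c4_congruence <- function(x, ...) {
  tibble::tibble(qdist_all = x$qdist_all, qdist_third = x$qdist_third,
                 pass = x$pass)
}

#' Heatmap of scan p-values (groups x conditions)
#'
#' @param object A `c4_scan` tibble from [run_scan()].
#' @param value Column to display (`"p"` default, or `"q"` after
#'   [add_fdr()]).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.c4_scan <- function(object, value = "p", ...) {
  df <- dplyr::filter(object, .data$status == "tested")
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$condition),
    y = stats::reorder(.data$group_id, .data[[value]]),
    fill = -log10(pmax(.data[[value]], 1e-12)))) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = paste0("-log10 ", value)) +
    ggplot2::labs(x = "phylogenetic condition", y = "ortholog group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Funnel plot of pipeline stage counts
#'
#' @param object A `c4_pipeline_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.c4_pipeline_result <- function(object, ...) {
  f <- object$funnel
  f$stage <- factor(f$stage, levels = f$stage)
  ggplot2::ggplot(f, ggplot2::aes(x = .data$stage, y = .data$n)) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.4) +
    ggplot2::labs(x = NULL, y = "ortholog groups") +
    ggplot2::theme_minimal()
}

#' Power-experiment summary plot
#'
#' @param object Tibble from [power_experiment()].
#' @param ... Unused.
#' @return A ggplot of rejection rate vs foreground omega per condition.
#' @export
plot_power <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$omega_fg, y = .data$reject_p05,
    colour = factor(.data$condition))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.05, linetype = 2) +
    ggplot2::labs(x = "foreground omega", y = "rejection rate (p < 0.05)",
                  colour = "condition") +
    ggplot2::theme_minimal()
}
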