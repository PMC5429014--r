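# Multiple-test correction (per condition), candidate merging under the
# FDR < 0.2 / elevated-omega rule, and the known-gene enrichment test.

#' Benjamini-Hochberg q-values
#'
#' Step-up q-values: `q_(i) = min_{j >= i} min(1, p_(j) * n / j)` over the
#' sorted p-values, mapped back to input order. Thresholding `q < alpha`
#' reproduces the classical BH rejection set at level `alpha`.
#'
#' @param pvalues Numeric vector in `[0, 1]` (NAs propagate).
#' @return q-values in input order.
#' @export
bh_fdr <- function(pvalues) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- stats::p.adjust(p, method = "BH")
  out
}

#' Storey pi0-adjusted q-values
#'
#' BH q-values rescaled by the Storey estimate of the null proportion,
#' `pi0 = #(p > lambda) / ((1 - lambda) n)` capped at 1.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @param lambda Tuning threshold (default 0.5).
#' @return q-values in input order.
#' @export
storey_fdr <- function(pvalues, lambda = 0.5) {
  ok <- !is.na(pvalues)
  p <- pvalues[ok]
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]")
  pi0 <- min(1, mean(p > lambda) / (1 - lambda))
  out <- rep(NA_real_, length(pvalues))
  out[ok] <- pmin(1, stats::p.adjust(p, method = "BH") * pi0)
  out
}

#' Add per-condition q-values to a scan table
#'
#' The multiple-test correction is applied separately within each
#' phylogenetic condition, over the tested records only.
#'
#' @param scan A scan tibble from [run_scan()].
#' @param method `"bh"` (default) or `"storey"`.
#' @return The scan tibble with a `q` column.
#' @export
add_fdr <- function(scan, method = c("bh", "storey")) {
  method <- match.arg(method)
  fun <- if (method == "bh") bh_fdr else storey_fdr
  scan |>
    dplyr::group_by(.data$condition) |>
    dplyr::mutate(q = ifelse(.data$status == "tested",
                             fun(ifelse(.data$status == "tested",
                                        .data$p, NA_real_)),
                             NA_real_)) |>
    dplyr::ungroup()
}

#' Merge candidates across conditions
#'
#' A group is a candidate iff some condition has `q < threshold` *and* an
#' elevated foreground ratio (`omega_fg > omega_bg`, strict) in that same
#' test. Output is sorted by minimum q (ties by group id).
#'
#' @param scan Scan tibble with a `q` column ([add_fdr()]).
#' @param threshold FDR threshold (default 0.2).
#' @return Tibble: `group_id`, `best_condition`, `min_q`, `omega_fg`,
#'   `omega_bg`, `n_significant`.
#' @export
merge_candidates <- function(scan, threshold = 0.2) {
  if (!"q" %in% names(scan)) {
    stop("scan table has no q column; run add_fdr() first")
  }
  hits <- scan |>
    dplyr::filter(.data$status == "tested", !is.na(.data$q),
                  .data$q < threshold,
                  !is.na(.data$omega_fg), !is.na(.data$omega_bg),
                  .data$omega_fg > .data$omega_bg)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(group_id = character(0),
                          best_condition = integer(0), min_q = numeric(0),
                          omega_fg = numeric(0), omega_bg = numeric(0),
                          n_significant = integer(0)))
  }
  hits |>
    dplyr::group_by(.data$group_id) |>
    dplyr::arrange(.data$q, .data$condition, .by_group = TRUE) |>
    dplyr::summarise(
      best_condition = dplyr::first(.data$condition),
      min_q = dplyr::first(.data$q),
      omega_fg = dplyr::first(.data$omega_fg),
      omega_bg = dplyr::first(.data$omega_bg),
      n_significant = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$min_q, .data$group_id)
}

#' One-sided enrichment test for known genes among candidates
#'
#' Exact hypergeometric upper tail `P(X >= observed)` for the number of
#' known genes recovered among the candidates, computed by direct
#' summation in log space.
#'
#' @param n_total Ortholog groups tested.
#' @param n_candidates Candidate groups.
#' @param n_known Known genes among the tested groups.
#' @param n_detected Known genes among the candidates.
#' @return One-sided p-value.
#' @export
enrichment_fisher <- function(n_total, n_candidates, n_known, n_detected) {
  stopifnot(n_detected >= 0, n_known >= n_detected, n_total >= n_known,
            n_candidates >= n_detected, n_total >= n_candidates)
  if (n_detected == 0) return(1)
  k <- seq(n_detected, min(n_known, n_candidates))
  lg <- stats::dhyper(k, n_known, n_total - n_known, n_candidates, log = TRUE)
  m <- max(lg)
  min(1, exp(m + log(sum(exp(lg - m)))))
}
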