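#' Two-sided p-value of a Pearson correlation
#'
#' Uses the exact null distribution of the sample correlation for bivariate
#' normal data: `t = r * sqrt((n - 2) / (1 - r^2))` referred to the t
#' distribution with `n - 2` degrees of freedom. `r = +-1` returns 0.
#'
#' @param r Correlation value(s) in `[-1, 1]`.
#' @param n Sample size(s), at least 5.
#' @return Two-sided p-value(s), vectorized over `r` and `n`.
#' @export
correlation_pvalue <- function(r, n) {
  if (any(is.na(r)) || any(abs(r) > 1 + 1e-12)) abort("|r| must be <= 1")
  if (any(n < 5)) abort("need at least 5 samples")
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  n <- rep_len(n, length(r))
  tt <- r[ok] * sqrt((n[ok] - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * pt(-abs(tt), df = n[ok] - 2)
  p
}

#' Permutation p-value of a maximized stoichiometric correlation
#'
#' The analytic p-value ignores that `r` was maximized over a grid of weight
#' tuples. This null re-maximizes: for each permutation the sample order of
#' side B alone is shuffled and the full weight search is rerun, so the
#' reference distribution carries the same selection effect. The p-value is
#' `(1 + #\{r_b >= r_obs\}) / (B + 1)`.
#'
#' @inheritParams max_stoich_correlation
#' @param n_permutations Number of permutations `B` (>= 100).
#' @param seed Integer seed; identical seeds give identical p-values.
#' @return A single p-value in `(0, 1]`.
#' @export
permutation_pvalue <- function(log_m, side_A, side_B, i_max = 4L,
                               n_permutations = 999L, seed = 1L) {
  if (n_permutations < 100L) abort("need at least 100 permutations")
  obs <- max_stoich_correlation(log_m, side_A, side_B, i_max)
  if (is.null(obs)) abort("degenerate split: no computable correlation")
  n <- nrow(log_m)
  exceed <- 0L
  rng <- local({
    set.seed(as.integer(seed))
    replicate(n_permutations, sample.int(n), simplify = FALSE)
  })
  perm_m <- log_m
  for (pm in rng) {
    perm_m[, side_B] <- log_m[pm, side_B, drop = FALSE]
    fit <- max_stoich_correlation(perm_m, side_A, side_B, i_max)
    if (!is.null(fit) && fit$r >= obs$r) exceed <- exceed + 1L
  }
  (1 + exceed) / (n_permutations + 1)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate control applied jointly across all tested
#' splits of one analysis run (pairs + triplets + quadruples form one
#' family).
#'
#' @param p Numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values (monotone, capped at 1, `p_adj >= p`).
#' @export
adjust_bh <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Filter to significant stoichiometric correlations
#'
#' Keeps records with `p_adj <= alpha` and `r >= tau` (inclusive comparisons).
#'
#' @param results An `sca_result`.
#' @param alpha FDR level (default 0.05).
#' @param tau Correlation threshold (default 0.8).
#' @return The filtered `sca_result` (attributes preserved).
#' @export
filter_significant <- function(results, alpha = 0.05, tau = 0.8) {
  keep <- results$p_adj <= alpha & results$r >= tau
  out <- results[keep, ]
  new_sca_result(out, metabolites = attr(results, "metabolites"),
                 provenance = attr(results, "provenance"),
                 skipped = attr(results, "skipped"))
}

#' Significant-split counts by category and threshold
#'
#' The layout used to compare analyses: for each correlation threshold, how
#' many significant pairs, triplet splits and quadruple splits there are, and
#' their total.
#'
#' @inheritParams filter_significant
#' @param thresholds Correlation cutoffs (default 0.8, 0.85, 0.9, 0.95).
#' @return A tibble with columns `threshold`, `pairs`, `triplets`,
#'   `quadruples`, `total`, of class `sca_counts`.
#' @export
count_by_category <- function(results, thresholds = c(0.8, 0.85, 0.9, 0.95),
                              alpha = 0.05) {
  rows <- purrr::map(thresholds, function(tau) {
    sig <- results[results$p_adj <= alpha & results$r >= tau, ]
    tibble(threshold = tau,
           pairs = sum(sig$category == "pair"),
           triplets = sum(sig$category == "triplet"),
           quadruples = sum(sig$category == "quadruple"))
  })
  out <- dplyr::bind_rows(rows) |>
    dplyr::mutate(total = .data$pairs + .data$triplets + .data$quadruples)
  class(out) <- c("sca_counts", class(out))
  out
}

#' Counts-by-threshold bar plot
#' @param object An `sca_counts` tibble.
#' @param ... Unused.
#' @return A ggplot of category counts per threshold.
#' @method autoplot sca_counts
#' @export
autoplot.sca_counts <- function(object, ...) {
  long <- tidyr::pivot_longer(as_tibble(object),
                              c("pairs", "triplets", "quadruples"),
                              names_to = "category", values_to = "count")
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$threshold), y = .data$count,
                                     fill = .data$category)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "correlation threshold", y = "significant splits", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Quintiles and ECDF of the correlation values
#'
#' @inheritParams filter_significant
#' @return A list with `quintiles` (named 0/20/40/60/80/100-percentile values
#'   of `r`) and `ecdf` (tibble of sorted support points `r` with cumulative
#'   fraction `F`).
#' @export
summarize_distribution <- function(results) {
  if (nrow(results) == 0L) abort("no records to summarize")
  r <- sort(results$r)
  q <- quantile(r, probs = seq(0, 1, 0.2), names = TRUE)
  list(quintiles = q,
       ecdf = tibble(r = r, F = seq_along(r) / length(r)))
}
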