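#' Paired MPA series
#'
#' Validated container for two paired MPA series: a reference method (the
#' full-protocol MIRD pipeline, treated as ground truth) and a comparison
#' method (e.g. the abbreviated-protocol network).
#'
#' @param labels patient identifiers.
#' @param reference_mCi,predicted_mCi positive MPA values of equal length
#'   (>= 2).
#' @return A tibble of class `paired_series` with the three columns.
#' @export
paired_series <- function(labels, reference_mCi, predicted_mCi) {
  n <- length(reference_mCi)
  if (n < 2L || length(predicted_mCi) != n || length(labels) != n) {
    stop("paired series need equal lengths >= 2", call. = FALSE)
  }
  if (any(reference_mCi <= 0) || any(predicted_mCi <= 0)) {
    stop("MPA values must be > 0", call. = FALSE)
  }
  structure(
    tibble::tibble(label = as.character(labels),
                   reference_mCi = as.numeric(reference_mCi),
                   predicted_mCi = as.numeric(predicted_mCi)),
    class = c("paired_series", class(tibble::tibble()))
  )
}

#' Paired t-test on method differences
#'
#' Classical paired t-test on `d_i = predicted_i - reference_i`, computed
#' natively: `t = mean(d) / (sd(d) / sqrt(n))` with `n - 1` degrees of
#' freedom, and the 95% confidence interval of the mean difference
#' `mean(d) +/- t_{0.975, n-1} * sd(d) / sqrt(n)`.
#'
#' @param series a [paired_series()].
#' @param conf_level confidence level for the interval (default 0.95).
#' @return One-row tibble: `mean_diff`, `statistic`, `df`, `p_value`,
#'   `ci_low`, `ci_high`. Degenerate zero-variance differences give
#'   `t = 0, p = 1` when the mean is zero, else `p = 0` with a warning.
#' @examples
#' paired_t_test(table2_fixture())
#' @export
paired_t_test <- function(series, conf_level = 0.95) {
  d <- series$predicted_mCi - series$reference_mCi
  n <- length(d)
  if (n < 2L) stop("need >= 2 pairs", call. = FALSE)
  m <- mean(d)
  s <- stats::sd(d)
  if (s < .Machine$double.eps^0.5 * max(1, abs(m))) {
    if (abs(m) < .Machine$double.eps^0.5) {
      return(tibble::tibble(mean_diff = 0, statistic = 0, df = n - 1L,
                            p_value = 1, ci_low = 0, ci_high = 0))
    }
    warning("zero-variance differences with nonzero mean: p set to 0",
            call. = FALSE)
    return(tibble::tibble(mean_diff = m, statistic = sign(m) * Inf, df = n - 1L,
                          p_value = 0, ci_low = m, ci_high = m))
  }
  se <- s / sqrt(n)
  tstat <- m / se
  tcrit <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  tibble::tibble(
    mean_diff = m,
    statistic = tstat,
    df = n - 1L,
    p_value = 2 * stats::pt(-abs(tstat), df = n - 1),
    ci_low = m - tcrit * se,
    ci_high = m + tcrit * se
  )
}

# exact null distribution of the signed-rank statistic under random signs,
# allowing midranks: generating-function recursion on doubled ranks.
# Returns P(W <= w) and P(W >= w) for the doubled-rank statistic w2.
signed_rank_exact_tail <- function(ranks2, w2) {
  total <- sum(ranks2)
  coef <- numeric(total + 1L) # index i-1 = probability weight of W2 = i-1
  coef[1L] <- 1
  for (r in ranks2) {
    shifted <- c(numeric(r), coef[seq_len(total + 1L - r)])
    coef <- (coef + shifted) / 2
  }
  w2 <- round(w2)
  list(le = sum(coef[seq_len(min(w2, total) + 1L)]),
       ge = sum(coef[(max(w2, 0) + 1L):(total + 1L)]))
}

#' Wilcoxon signed-rank test on method differences
#'
#' Two-sided signed-rank test on `d_i = predicted_i - reference_i`. Zero
#' differences are dropped; tied absolute differences receive midranks. For
#' `n <= 25` (after dropping zeros) the exact null distribution is computed by
#' the generating-function recursion on doubled midranks, which stays exact
#' under ties; above that, a normal approximation with continuity and tie
#' correction is used. The statistic `W` is the sum of ranks of positive
#' differences.
#'
#' @param series a [paired_series()].
#' @param exact_max largest `n` for which the exact null is used.
#' @return One-row tibble: `statistic` (W), `n_used` (pairs after dropping
#'   zeros), `p_value`, `method`. All-zero differences give `p = 1`.
#' @examples
#' wilcoxon_signed_rank(table2_fixture())
#' @export
wilcoxon_signed_rank <- function(series, exact_max = 25) {
  d <- series$predicted_mCi - series$reference_mCi
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    return(tibble::tibble(statistic = 0, n_used = 0L, p_value = 1,
                          method = "degenerate: all differences zero"))
  }
  r <- rank(abs(d)) # midranks for ties
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    tails <- signed_rank_exact_tail(round(2 * r), 2 * w)
    p <- min(1, 2 * min(tails$le, tails$ge))
    method <- "exact (generating function, midranks)"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    cc <- sign(w - mu) * 0.5
    z <- (w - mu - cc) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation with continuity and tie correction"
  }
  tibble::tibble(statistic = w, n_used = n, p_value = p, method = method)
}

#' Absolute percent difference relative to the reference method
#'
#' `100 * |predicted - reference| / reference` (vectorized).
#'
#' @param predicted,reference MPA values; `reference` must be > 0.
#' @return Percent differences.
#' @examples
#' percent_difference(798, 804) # ~0.75, rounds to 1%
#' percent_difference(219, 230) # ~4.78, rounds to 5%
#' @export
percent_difference <- function(predicted, reference) {
  if (any(reference <= 0)) stop("reference must be > 0", call. = FALSE)
  100 * abs(predicted - reference) / reference
}

#' The 13-patient validation series
#'
#' The published 13-patient test-set comparison of full-protocol MIRD MPAs
#' against abbreviated-protocol network predictions, embedded as a fixture
#' for reproducing the agreement analysis.
#'
#' @return A [paired_series()] of 13 pairs (reference = MIRD, predicted =
#'   network).
#' @export
table2_fixture <- function() {
  paired_series(
    labels = paste0("P", 1:13),
    reference_mCi = c(140, 791, 230, 310, 722, 625, 529, 770, 342, 762, 525, 804, 615),
    predicted_mCi = c(129, 778, 219, 275, 756, 622, 551, 754, 341, 701, 534, 798, 624)
  )
}

#' Full agreement report between two MPA series
#'
#' Per-pair differences and percent differences plus the paired t-test (with
#' 95% CI of the mean difference) and the Wilcoxon signed-rank test,
#' summarizing how well an abbreviated-protocol predictor agrees with the
#' full-protocol reference.
#'
#' @param series a [paired_series()].
#' @return A list of class `agreement_report` with `pairs` (per-patient
#'   tibble: difference, percent difference) and `summary` (one-row tibble
#'   merging both tests plus median/max absolute percent difference).
#'   Supports [generics::tidy()] (pairs), [generics::glance()] (summary) and
#'   [ggplot2::autoplot()].
#' @examples
#' glance(agreement_report(table2_fixture()))
#' @export
agreement_report <- function(series) {
  pairs <- dplyr::mutate(
    tibble::as_tibble(series),
    difference_mCi = .data$predicted_mCi - .data$reference_mCi,
    percent_difference = percent_difference(.data$predicted_mCi, .data$reference_mCi)
  )
  tt <- paired_t_test(series)
  wt <- wilcoxon_signed_rank(series)
  summary <- tibble::tibble(
    n = nrow(pairs),
    mean_diff_mCi = tt$mean_diff,
    ci95_low_mCi = tt$ci_low,
    ci95_high_mCi = tt$ci_high,
    t_statistic = tt$statistic,
    t_df = tt$df,
    t_p_value = tt$p_value,
    wilcoxon_W = wt$statistic,
    wilcoxon_p_value = wt$p_value,
    median_abs_pct_diff = stats::median(pairs$percent_difference),
    max_abs_pct_diff = max(pairs$percent_difference)
  )
  structure(list(pairs = pairs, summary = summary), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<agreement_report> n = %d\n",
           "  mean difference %.2f mCi, 95%% CI (%.2f, %.2f)\n",
           "  paired t: t = %.3f, df = %d, p = %.3f\n",
           "  Wilcoxon signed-rank: W = %.1f, p = %.3f\n",
           "  |%% difference|: median %.2f%%, max %.2f%%\n"),
    s$n, s$mean_diff_mCi, s$ci95_low_mCi, s$ci95_high_mCi,
    s$t_statistic, s$t_df, s$t_p_value,
    s$wilcoxon_W, s$wilcoxon_p_value,
    s$median_abs_pct_diff, s$max_abs_pct_diff
  ))
  invisible(x)
}

#' @export
tidy.agreement_report <- function(x, ...) x$pairs

#' @export
glance.agreement_report <- function(x, ...) x$summary

#' @export
autoplot.agreement_report <- function(object, ...) {
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$reference_mCi, y = .data$predicted_mCi)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2, colour = "steelblue") +
    ggplot2::labs(x = "reference MPA (mCi)", y = "predicted MPA (mCi)",
                  title = "Method agreement (dashed: identity)") +
    ggplot2::theme_minimal()
}
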