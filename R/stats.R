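# Group comparisons and method agreement. Two-sample comparisons are gated
# on per-sample Shapiro-Wilk normality: both samples normal-looking means
# Welch's t-test, otherwise the Mann-Whitney U test. Bland-Altman analysis
# quantifies agreement between two measurement approaches on paired data.

#' Normality-gated two-sample comparison
#'
#' Runs Shapiro-Wilk on each sample at `alpha_norm`; if both pass, an
#' unpaired two-sided Welch's t-test (unequal variances,
#' Welch-Satterthwaite degrees of freedom), otherwise a two-sided
#' Mann-Whitney U test (exact for small samples without ties, normal
#' approximation with tie and continuity correction otherwise, as
#' implemented by [stats::wilcox.test()]). A constant sample has no defined
#' normality and falls through to the Mann-Whitney branch with a warning.
#'
#' @param x,y numeric samples (each of size 3 or more).
#' @param alpha_norm significance level of the normality gate.
#' @return object of class `comparison_result`: `test_used` ("welch_t" or
#'   "mann_whitney_u"), `statistic`, `p_value`, `group_sizes`,
#'   `normality_p_values`, `alpha_norm`.
#' @export
select_and_run_test <- function(x, y, alpha_norm = 0.05) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 3 || length(y) < 3)
    stop("each sample needs at least 3 observations")
  sw <- function(v) {
    if (length(unique(v)) < 2) return(NA_real_)
    stats::shapiro.test(v)$p.value
  }
  px <- sw(x); py <- sw(y)
  if (is.na(px) || is.na(py))
    warning("constant sample: normality undefined, using Mann-Whitney U")
  normal_ok <- !is.na(px) && !is.na(py) && px >= alpha_norm && py >= alpha_norm
  if (normal_ok) {
    tt <- stats::t.test(x, y, var.equal = FALSE)
    res <- list(test_used = "welch_t",
                statistic = unname(tt$statistic),
                p_value = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = NULL,
                                              correct = TRUE))
    res <- list(test_used = "mann_whitney_u",
                statistic = unname(wt$statistic),
                p_value = wt$p.value)
  }
  structure(c(res, list(group_sizes = c(length(x), length(y)),
                        normality_p_values = c(px, py),
                        alpha_norm = alpha_norm)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: statistic %.4g, p = %.4g (n = %d vs %d)\n",
              x$test_used, x$statistic, x$p_value,
              x$group_sizes[1], x$group_sizes[2]))
  invisible(x)
}

#' Bland-Altman agreement between two paired measurement methods
#'
#' For paired measurements, computes the per-pair differences d = x - y and
#' means m = (x + y)/2, the bias (mean difference), the 95\% limits of
#' agreement bias +/- 1.96 * SD(d), and the simple proportional bias as the
#' ordinary-least-squares slope of d on m with its two-sided t-test p-value
#' (undefined when the differences or means are constant).
#'
#' @param x,y paired numeric vectors of equal length (3 or more pairs).
#' @return object of class `bland_altman_result`: `bias`, `loa_low`,
#'   `loa_high`, `proportional_bias_slope`, `slope_p`, `n`.
#' @export
bland_altman <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("paired vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y; m <- (x + y) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- 0; slope_p <- NA_real_
  if (stats::sd(m) > 0) {
    if (s > 1e-300) {
      fit <- stats::lm(d ~ m)
      cf <- suppressWarnings(summary(fit))$coefficients  # noiseless fits
      slope <- cf["m", "Estimate"]
      slope_p <- cf["m", "Pr(>|t|)"]
    } else {
      slope <- 0; slope_p <- 1  # identical differences everywhere
    }
  }
  structure(list(bias = bias,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 proportional_bias_slope = slope, slope_p = slope_p,
                 n = length(x)),
            class = "bland_altman_result")
}

#' @export
print.bland_altman_result <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (n = %d): bias %.4g, LoA [%.4g, %.4g], slope %.4g (p = %.3g)\n",
    x$n, x$bias, x$loa_low, x$loa_high, x$proportional_bias_slope,
    x$slope_p))
  invisible(x)
}
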