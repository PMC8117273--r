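#' Paired test-retest measurements
#'
#' @param x,y Paired measurements (first and second scan), equal length >= 3.
#' @param id Optional subject identifiers.
#' @param label Optional description, e.g. `"Cr/W BH1 vs BH2"`.
#' @return data.frame of class `paired_measurements`.
#' @export
paired_measurements <- function(x, y, id = seq_along(x), label = "") {
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 3) stop("need at least 3 pairs", call. = FALSE)
  if (!all(is.finite(x)) || !all(is.finite(y)))
    stop("measurements must be finite", call. = FALSE)
  out <- data.frame(id = id, x = as.numeric(x), y = as.numeric(y))
  attr(out, "label") <- label
  class(out) <- c("paired_measurements", class(out))
  out
}

as_pairs <- function(pairs) {
  if (!inherits(pairs, "paired_measurements"))
    stop("expected a paired_measurements object", call. = FALSE)
  pairs
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken first-minus-second scan (`d = x - y`); the bias is
#' their mean and the limits of agreement are `bias +/- 1.96 * SD(d)`
#' (sample SD, n - 1 denominator). Pairs falling outside the limits are
#' flagged.
#'
#' @param pairs A [paired_measurements()] object.
#' @return List with `bias`, `loa_low`, `loa_high`, `sd_diff`, `mean_xy`,
#'   `diff`, `outlier` (logical per pair) and `n`.
#' @examples
#' p <- paired_measurements(c(1, 2, 3), c(2, 4, 6))
#' bland_altman(p)$bias      # -2
#' @export
bland_altman <- function(pairs) {
  pairs <- as_pairs(pairs)
  d <- pairs$x - pairs$y
  bias <- mean(d)
  sd_d <- stats::sd(d)
  loa <- bias + c(-1, 1) * 1.96 * sd_d
  list(bias = bias, loa_low = loa[1], loa_high = loa[2], sd_diff = sd_d,
       mean_xy = (pairs$x + pairs$y) / 2, diff = d,
       outlier = d < loa[1] | d > loa[2], n = nrow(pairs))
}

#' Test-retest intraclass correlation coefficient
#'
#' Single-measurement, absolute-agreement ICC from the two-way ANOVA mean
#' squares (ICC(A,1) in the Koo & Li nomenclature, the standard test-retest
#' form): with `MSR` the between-subject, `MSC` the between-scan and `MSE`
#' the residual mean square over n subjects and k = 2 scans,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' Values are reported unclipped and classed as poor (< 0.5), moderate
#' (0.5-0.75), good (0.75-0.90) or excellent (>= 0.90).
#'
#' @param pairs A [paired_measurements()] object.
#' @return List with `icc` and `icc_class`.
#' @export
icc_test_retest <- function(pairs) {
  pairs <- as_pairs(pairs)
  n <- nrow(pairs)
  k <- 2
  long <- data.frame(value = c(pairs$x, pairs$y),
                     subject = factor(rep(seq_len(n), 2)),
                     scan = factor(rep(1:2, each = n)))
  if (stats::var(long$value) == 0) {
    # identical constant series: perfect agreement by convention
    return(list(icc = 1, icc_class = "excellent"))
  }
  ms <- summary(stats::aov(value ~ subject + scan, data = long))[[1]]
  msr <- ms["subject", "Mean Sq"]
  msc <- ms["scan", "Mean Sq"]
  mse <- ms["Residuals", "Mean Sq"]
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  cls <- if (icc < 0.5) "poor" else if (icc < 0.75) "moderate"
         else if (icc < 0.90) "good" else "excellent"
  list(icc = icc, icc_class = cls)
}

#' Linear regression and Pearson correlation of paired scans
#'
#' Ordinary least squares of the second scan on the first, with the Pearson
#' correlation coefficient and its two-sided p-value from the t distribution
#' with n - 2 degrees of freedom.
#'
#' @param pairs A [paired_measurements()] object.
#' @return List with `slope`, `intercept`, `r`, `p_value` and `n`.
#' @export
regression <- function(pairs) {
  pairs <- as_pairs(pairs)
  if (stats::var(pairs$x) == 0)
    stop("regression undefined for constant x", call. = FALSE)
  fit <- stats::lm(y ~ x, data = pairs)
  r <- stats::cor(pairs$x, pairs$y)
  n <- nrow(pairs)
  p <- if (abs(r) >= 1) 0 else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  co <- stats::coef(fit)
  list(slope = unname(co[2]), intercept = unname(co[1]), r = r,
       p_value = p, n = n)
}

#' Full repeatability report for a paired comparison
#'
#' Convenience wrapper combining [bland_altman()], [icc_test_retest()] and
#' [regression()].
#'
#' @param pairs A [paired_measurements()] object.
#' @return List of class `repeatability_report`.
#' @export
repeatability_report <- function(pairs) {
  pairs <- as_pairs(pairs)
  ba <- bland_altman(pairs)
  icc <- tryCatch(icc_test_retest(pairs),
                  error = function(e) list(icc = NA_real_, icc_class = NA_character_))
  reg <- tryCatch(regression(pairs),
                  error = function(e) list(slope = NA_real_, intercept = NA_real_,
                                           r = NA_real_, p_value = NA_real_,
                                           n = nrow(pairs)))
  out <- list(label = attr(pairs, "label"), bias = ba$bias,
              loa_low = ba$loa_low, loa_high = ba$loa_high,
              icc = icc$icc, icc_class = icc$icc_class,
              slope = reg$slope, intercept = reg$intercept,
              r = reg$r, p_value = reg$p_value, n = ba$n,
              bland_altman = ba)
  class(out) <- "repeatability_report"
  out
}

#' @export
print.repeatability_report <- function(x, ...) {
  cat(sprintf("<repeatability_report>%s n=%d\n",
              if (nzchar(x$label)) paste0(" ", x$label) else "", x$n))
  cat(sprintf("  Bland-Altman: bias %.4g, limits [%.4g, %.4g]\n",
              x$bias, x$loa_low, x$loa_high))
  cat(sprintf("  ICC %.3f (%s); regression slope %.3f, r %.3f, p %.3g\n",
              x$icc, x$icc_class, x$slope, x$r, x$p_value))
  invisible(x)
}

#' Bland-Altman plot
#'
#' @param pairs A [paired_measurements()] object.
#' @param ... Passed to [graphics::plot()].
#' @return The [bland_altman()] list, invisibly.
#' @export
plot_bland_altman <- function(pairs, ...) {
  ba <- bland_altman(as_pairs(pairs))
  graphics::plot(ba$mean_xy, ba$diff, xlab = "mean of pair",
                 ylab = "difference (first - second)",
                 main = attr(pairs, "label"), ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
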