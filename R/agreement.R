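#' Geometric mean regression
#'
#' Fits the geometric mean (reduced major axis) regression line of `y` on
#' `x`: slope = sign(r) * SD(y) / SD(x), intercept = mean(y) - slope *
#' mean(x), with `r` the Pearson correlation. Unlike ordinary least
#' squares, the fit is symmetric: swapping `x` and `y` inverts the slope.
#' Appropriate for method comparison, where both variables carry error.
#'
#' @param x,y Paired numeric vectors, at least 3 complete pairs, each with
#'   positive SD.
#' @return An object of class `ppg_gmr` with elements `slope`, `intercept`,
#'   `r`, `n` and the paired `data`; `tidy()` and `autoplot()` methods are
#'   available.
#' @examples
#' g <- gm_regression(c(1, 2, 3, 4), c(2.1, 3.9, 6.2, 7.8))
#' tidy(g)
#' @export
gm_regression <- function(x, y) {
  if (length(x) != length(y)) abort("unpaired data")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("at least 3 pairs are required")
  if (sd(x) == 0 || sd(y) == 0) abort("degenerate input")
  r <- cor(x, y)
  slope <- (if (r < 0) -1 else 1) * sd(y) / sd(x)
  structure(
    list(slope = slope, intercept = mean(y) - slope * mean(x), r = r,
         n = length(x), data = tibble::tibble(x = x, y = y)),
    class = "ppg_gmr"
  )
}

#' @export
print.ppg_gmr <- function(x, ...) {
  cat(sprintf("Geometric mean regression (n = %d)\n", x$n))
  cat(sprintf("  y = %.4g x %+.4g,  r = %.3f\n",
              x$slope, x$intercept, x$r))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ppg_gmr <- function(x, ...) {
  tibble::tibble(slope = x$slope, intercept = x$intercept, r = x$r,
                 n = x$n)
}

#' Bland-Altman agreement analysis
#'
#' Computes paired differences `y - x` (second method minus first) and
#' averages `(x + y) / 2`, the fixed bias (mean difference), the SD of the
#' differences, and agreement limits at `bias +/- limit_multiplier * SD`.
#' The default multiplier of 1 draws the M +/- 1 SD band; use
#' `limit_multiplier = 1.96` for conventional 95% limits of agreement.
#'
#' @param x,y Paired numeric vectors (reference-style ordering: differences
#'   are `y - x`), at least 3 complete pairs.
#' @param limit_multiplier Half-width of the agreement band in SD units.
#' @return An object of class `ppg_bland_altman` with `bias`, `sd_diff`,
#'   `lower`, `upper`, `limit_multiplier`, `n` and a `data` tibble of
#'   (`average`, `difference`) pairs; `tidy()` and `autoplot()` methods are
#'   available.
#' @examples
#' ba <- bland_altman(c(90, 95, 100, 104), c(92, 94, 103, 105))
#' tidy(ba)
#' @export
bland_altman <- function(x, y, limit_multiplier = 1) {
  if (length(x) != length(y)) abort("unpaired data")
  check_number(limit_multiplier, "limit_multiplier", positive = TRUE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) abort("at least 3 pairs are required")
  d <- y - x
  bias <- mean(d)
  sd_diff <- sd(d)
  structure(
    list(bias = bias, sd_diff = sd_diff,
         lower = bias - limit_multiplier * sd_diff,
         upper = bias + limit_multiplier * sd_diff,
         limit_multiplier = limit_multiplier, n = length(x),
         data = tibble::tibble(average = (x + y) / 2, difference = d)),
    class = "ppg_bland_altman"
  )
}

#' @export
print.ppg_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman analysis (n = %d)\n", x$n))
  cat(sprintf("  bias (M) = %.4g, SD = %.4g, M %+.3g SD limits [%.4g, %.4g]\n",
              x$bias, x$sd_diff, x$limit_multiplier, x$lower, x$upper))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ppg_bland_altman <- function(x, ...) {
  tibble::tibble(bias = x$bias, sd_diff = x$sd_diff, lower = x$lower,
                 upper = x$upper, limit_multiplier = x$limit_multiplier,
                 n = x$n)
}

#' Paired comparison with effect size
#'
#' Paired two-sided t-test of `b` against `a` (via [stats::t.test()];
#' positive `t` means `b` exceeds `a`) together with the pooled-SD Cohen's
#' d, \eqn{d = (\bar b - \bar a) / \sqrt{(SD_a^2 + SD_b^2)/2}}. When the
#' paired differences have zero variance and zero mean the t statistic is
#' undefined and reported as `NA`.
#'
#' @param a,b Paired numeric vectors (condition A and condition B), at
#'   least 2 complete pairs.
#' @return A one-row tibble: `mean_a`, `mean_b`, `t`, `df`, `p`, `d`, `n`.
#' @examples
#' paired_comparison(c(88, 91, 90), c(104, 107, 109))
#' @export
paired_comparison <- function(a, b) {
  if (length(a) != length(b)) abort("unpaired data")
  keep <- is.finite(a) & is.finite(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) abort("at least 2 pairs are required")
  tt <- tryCatch(t.test(b, a, paired = TRUE),
                 error = function(e) NULL)
  tibble::tibble(
    mean_a = mean(a), mean_b = mean(b),
    t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
    df = n - 1L,
    p = if (is.null(tt)) NA_real_ else tt$p.value,
    d = cohens_d(mean(a), sd(a), mean(b), sd(b)),
    n = n
  )
}

#' Pooled-SD Cohen's d from summary statistics
#'
#' Standardized mean difference
#' \eqn{d = (\bar b - \bar a) / \sqrt{(SD_a^2 + SD_b^2)/2}}, computable
#' from printed group means and SDs alone. Invariant under a common
#' positive affine transform of both groups; `0` when both means and both
#' SDs coincide; `NA` when the pooled SD is zero with unequal means.
#'
#' @param mean_a,sd_a,mean_b,sd_b Group means and (n-1 denominator) SDs.
#' @return Cohen's d as a single number.
#' @examples
#' cohens_d(90.3, 10.6, 106.1, 11.7) # about 1.42
#' @export
cohens_d <- function(mean_a, sd_a, mean_b, sd_b) {
  if (sd_a < 0 || sd_b < 0) abort("SDs must be >= 0")
  pooled <- sqrt((sd_a^2 + sd_b^2) / 2)
  if (pooled == 0) {
    return(if (mean_a == mean_b) 0 else NA_real_)
  }
  (mean_b - mean_a) / pooled
}
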