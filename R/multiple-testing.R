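# Multiple-test correction with m0 estimation
#
# Screening thousands of probes demands multiplicity control.  Besides
# Bonferroni and Benjamini-Hochberg, the number m0 of true null
# hypotheses among the m tests is estimated from the shape of the
# p-value distribution and used to sharpen the FDR: under the complete
# null, p-values are uniform, so the p-value plot (N_p, the count of
# p-values exceeding p, against 1 - p) is linear with slope m0, and the
# empirical CDF of p lies on the diagonal with area 1/2.  Deviations at
# small p betray true signals.

check_pvalues <- function(p) {
  if (!is.numeric(p) || length(p) < 1L)
    stop("p must be a non-empty numeric vector", call. = FALSE)
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1] and be non-missing", call. = FALSE)
  invisible(p)
}

#' Bonferroni correction
#' @param p numeric vector of p-values.
#' @return Adjusted p-values `min(1, m * p)`, in input order.
#' @export
bonferroni_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "bonferroni")
}

#' Benjamini-Hochberg step-up q-values
#' @param p numeric vector of p-values.
#' @return BH q-values in input order.
#' @export
bh_adjust <- function(p) {
  check_pvalues(p)
  stats::p.adjust(p, method = "BH")
}

#' m0-adjusted false discovery rate
#'
#' Benjamini-Hochberg step-up with the total test count `m` replaced by an
#' estimate of the number of true nulls:
#' `q_(i) = min_{j >= i} (m0 * p_(j) / j)`, capped at 1.  With `m0 = m`
#' this is exactly the BH procedure; a smaller `m0` yields uniformly
#' smaller (sharper) q-values.
#'
#' @param p numeric vector of p-values.
#' @param m0 estimated number of true null hypotheses (0 <= m0 <= m); an
#'   `m0_estimate` object is also accepted (its unrounded value is used).
#' @return q-values in input order.
#' @export
adjusted_fdr <- function(p, m0) {
  check_pvalues(p)
  if (inherits(m0, "m0_estimate")) m0 <- m0$m0_raw
  m <- length(p)
  if (m0 < 0 || m0 > m)
    stop("m0 must lie between 0 and the number of tests", call. = FALSE)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(m0 / (m:1) * p[o]))[ro]
}

#' P-value plot points
#'
#' The step function of Schweder-Spjotvoll type: for each distinct
#' p-value, `n_greater` is the number of p-values in the set strictly
#' greater than it, plotted against `1 - p`.  Under the complete null the
#' points fall near a line through the origin with slope m.
#'
#' @param p numeric vector of p-values (length >= 2).
#' @return Data frame with columns `p`, `x` (= 1 - p) and `n_greater`,
#'   ordered by increasing `p`.
#' @export
pvalue_plot <- function(p) {
  check_pvalues(p)
  if (length(p) < 2L) stop("need at least 2 p-values", call. = FALSE)
  sp <- sort(p)
  dp <- unique(sp)
  n_greater <- length(p) - findInterval(dp, sp)
  data.frame(p = dp, x = 1 - dp, n_greater = n_greater)
}

new_m0_estimate <- function(method, m, m0_raw, diagnostics) {
  m0_raw <- min(max(m0_raw, 0), m)
  structure(list(method = method, m = m, m0 = round(m0_raw),
                 m0_raw = m0_raw, pi0 = m0_raw / m,
                 diagnostics = diagnostics),
            class = "m0_estimate")
}

#' @export
print.m0_estimate <- function(x, ...) {
  cat(sprintf("m0 estimate (%s): m = %d, m0 = %d, pi0 = %.3f\n",
              x$method, x$m, x$m0, x$pi0))
  invisible(x)
}

#' Estimate m0 from the p-value plot
#'
#' Fits a straight line to the null-dominated (large-p) end of the
#' p-value plot and reads m0 off its slope.  The step function
#' `N_p = #\{p-values > p\}` is evaluated on a uniform grid of `grid_size`
#' p-values over \[0, 1\] and the points are taken in order from largest p
#' (x = 1 - p near 0) toward smallest.  Starting from the quarter of the
#' grid with the largest p-values, the fit region is extended one point
#' at a time for as long as the R-squared of the least-squares line does
#' not drop more than `r2_drop_tol` below its running maximum; the slope
#' of the final fit, clamped to \[0, m\], is the m0 estimate.  A region
#' with constant `N_p` has R-squared defined as 1 (a horizontal line fits
#' it perfectly).
#'
#' @param p numeric vector of at least 10 p-values.
#' @param r2_drop_tol tolerated drop in R-squared before the extension
#'   stops (default 0.005).
#' @param grid_size number of evaluation points on \[0, 1\] (default 101).
#' @return An `m0_estimate` (method `"pplot"`); `diagnostics` holds the
#'   evaluated points, the fitted region size, slope, intercept and the
#'   R-squared path.
#' @export
estimate_m0_pplot <- function(p, r2_drop_tol = 0.005, grid_size = 101L) {
  check_pvalues(p)
  m <- length(p)
  if (m < 10L) stop("m0 estimation needs at least 10 p-values", call. = FALSE)
  sp <- sort(p)
  pg <- seq(1, 0, length.out = grid_size)      # largest p first
  x <- 1 - pg
  y <- m - findInterval(pg, sp)                # strict: # p-values > pg

  if (all(y == y[1L])) {
    warning("degenerate p-value plot (constant N_p); returning m0 = m",
            call. = FALSE)
    return(new_m0_estimate("pplot", m, m,
                           list(degenerate = TRUE, points = data.frame(
                             p = pg, x = x, n_greater = y))))
  }

  # prefix regression: slope and R^2 for the first k points, k = n0..N
  n <- grid_size
  cx <- cumsum(x); cy <- cumsum(y)
  cxx <- cumsum(x^2); cyy <- cumsum(y^2); cxy <- cumsum(x * y)
  k <- seq_len(n)
  sxx <- cxx - cx^2 / k
  syy <- cyy - cy^2 / k
  sxy <- cxy - cx * cy / k
  slope_k <- ifelse(sxx > 0, sxy / sxx, 0)
  r2_k <- ifelse(syy <= .Machine$double.eps * pmax(1, cyy), 1,
                 ifelse(sxx > 0, pmin(1, sxy^2 / (sxx * syy)), 0))

  n0 <- max(3L, ceiling(0.25 * n))
  best <- r2_k[n0]
  stop_at <- n
  for (kk in (n0 + 1L):n) {
    if (r2_k[kk] < best - r2_drop_tol) { stop_at <- kk - 1L; break }
    best <- max(best, r2_k[kk])
  }
  slope <- slope_k[stop_at]
  intercept <- (cy[stop_at] - slope * cx[stop_at]) / stop_at
  new_m0_estimate("pplot", m, slope, list(
    region_size = stop_at, start_size = n0, slope = slope,
    intercept = intercept, r2 = r2_k[stop_at], r2_path = r2_k,
    points = data.frame(p = pg, x = x, n_greater = y)))
}

#' Estimate m0 from the CDF of p-values
#'
#' Under the complete null the empirical CDF of the p-values lies on the
#' diagonal, with area 1/2 below it; signal concentrated at small p
#' inflates the area.  The estimator is the ratio of the expected to the
#' observed area: `pi0 = 0.5 / A`, clamped to \[0, 1\], with `A` the
#' trapezoidal area under the empirical CDF on \[0, 1\].  Note the
#' built-in floor: even for purely alternative data `A <= 1`, so the
#' estimate never falls below 0.5.
#'
#' @param p numeric vector of at least 10 p-values.
#' @return An `m0_estimate` (method `"cdf"`); `diagnostics$area` holds `A`.
#' @export
estimate_m0_cdf <- function(p) {
  check_pvalues(p)
  m <- length(p)
  if (m < 10L) stop("m0 estimation needs at least 10 p-values", call. = FALSE)
  sp <- sort(p)
  xs <- c(0, sp, 1)
  fs <- c(0, seq_len(m) / m, 1)
  area <- sum(diff(xs) * (fs[-1L] + fs[-length(fs)]) / 2)
  pi0 <- min(1, 0.5 / area)
  new_m0_estimate("cdf", m, pi0 * m, list(area = area))
}

#' Operating characteristics over significance thresholds
#'
#' For each significance level alpha, reports the observed number of
#' significant tests `S = #\{p <= alpha\}` together with estimates derived
#' from m0: expected false positives `F = m0 * alpha`, sensitivity
#' `clamp(S - F, 0, m - m0) / (m - m0)` (undefined when m0 = m),
#' specificity `1 - alpha`, and FDR `min(1, F / S)` (defined as 0 when
#' nothing is significant).  These help choose a significance threshold
#' for a given dataset.
#'
#' @param p numeric vector of p-values.
#' @param m0 true-null count (number or `m0_estimate`); the unrounded
#'   value is used for the rates.
#' @param alphas significance levels in (0, 1); default 100 log-spaced
#'   points from 1e-4 to 0.1.
#' @return Data frame with columns `alpha`, `n_significant`,
#'   `sensitivity`, `specificity`, `fdr` (sensitivity is `NA` when
#'   m0 = m).
#' @export
operating_table <- function(p, m0,
                            alphas = 10^seq(log10(1e-4), log10(0.1),
                                            length.out = 100)) {
  check_pvalues(p)
  if (inherits(m0, "m0_estimate")) m0 <- m0$m0_raw
  m <- length(p)
  if (m0 < 0 || m0 > m) stop("m0 must lie in [0, m]", call. = FALSE)
  if (any(alphas <= 0 | alphas >= 1))
    stop("alphas must lie strictly inside (0, 1)", call. = FALSE)
  sp <- sort(p)
  s <- findInterval(alphas, sp)                 # #{p <= alpha}
  f <- m0 * alphas
  sens <- if (m0 >= m) rep(NA_real_, length(alphas)) else
    pmin(pmax(s - f, 0), m - m0) / (m - m0)
  data.frame(alpha = alphas, n_significant = s,
             sensitivity = sens, specificity = 1 - alphas,
             fdr = ifelse(s == 0, 0, pmin(1, f / s)))
}

#' Diagnostic plot data
#'
#' Plot-ready (x, y) series for the multiplicity diagnostics: the ROC
#' curve implied by the operating table (x = 1 - specificity,
#' y = sensitivity), the p-value plot, or the empirical CDF of p-values.
#'
#' @param p numeric vector of p-values.
#' @param m0 true-null count (needed for `kind = "roc"`).
#' @param kind `"roc"`, `"pplot"` or `"cdf"`.
#' @param alphas alpha grid for the ROC (see [operating_table()]).
#' @return Data frame with columns `x` and `y`, ordered by `x`.
#' @export
mtc_plot_data <- function(p, m0 = NULL, kind = c("roc", "pplot", "cdf"),
                          alphas = 10^seq(log10(1e-4), log10(0.1),
                                          length.out = 100)) {
  kind <- match.arg(kind)
  check_pvalues(p)
  if (kind == "roc") {
    if (is.null(m0)) stop("the ROC plot requires m0", call. = FALSE)
    if (inherits(m0, "m0_estimate")) m0 <- m0$m0_raw
    if (m0 >= length(p))
      stop("sensitivity is undefined when m0 = m; no ROC available",
           call. = FALSE)
    ot <- operating_table(p, m0, alphas)
    out <- data.frame(x = 1 - ot$specificity, y = ot$sensitivity)
  } else if (kind == "pplot") {
    pp <- pvalue_plot(p)
    out <- data.frame(x = pp$x, y = pp$n_greater)
  } else {
    sp <- sort(p)
    out <- data.frame(x = sp, y = seq_along(sp) / length(sp))
  }
  out[order(out$x), , drop = FALSE]
}
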