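# Small-sample outlier removal
#
# With the handful of replicates typical of short time-course designs, a
# single aberrant replicate can dominate a feature comparison.  Two
# screens are provided: an iterative mean-median discrepancy rule (the
# mean is outlier-sensitive, the median is not, so a standardized gap
# between them signals contamination) with the spread estimated by the
# sample SD or by the scaled MAD, and Dixon's extreme-value (Q) test for
# samples of 3 to 25 values, which can flag one value in each tail.

#' Mean-median discrepancy outlier screen
#'
#' Computes `D = |mean - median| / (sigma / sqrt(n))` where `sigma` is the
#' sample standard deviation (`variance_method = "sd"`) or the normal-
#' consistent scaled MAD (`"mad"`, 1.4826 * MAD).  While `D` exceeds
#' `z_threshold`, the value farthest from the median is flagged and
#' removed, stopping before the sample would shrink below 3 values.
#' Constant samples (`sigma = 0`) yield no flags.
#'
#' @param values numeric vector, length >= 3.
#' @param variance_method `"sd"` or `"mad"`.
#' @param z_threshold flagging threshold for `D` (default 1.96).
#' @return Integer vector of flagged indices into `values` (possibly
#'   empty), with attribute `"statistic"` holding the `D` value at each
#'   flagging step.
#' @export
mean_median_outliers <- function(values, variance_method = c("sd", "mad"),
                                 z_threshold = 1.96) {
  variance_method <- match.arg(variance_method)
  if (length(values) < 3L)
    stop("mean-median outlier screen needs at least 3 values", call. = FALSE)
  keep <- seq_along(values)
  flagged <- integer()
  d_at_flag <- numeric()
  repeat {
    x <- values[keep]
    n <- length(x)
    sigma <- if (variance_method == "sd") stats::sd(x) else stats::mad(x)
    d_stat <- if (sigma == 0) 0 else
      abs(mean(x) - stats::median(x)) / (sigma / sqrt(n))
    if (d_stat <= z_threshold || n - 1L < 3L) break
    worst <- which.max(abs(x - stats::median(x)))
    flagged <- c(flagged, keep[worst])
    d_at_flag <- c(d_at_flag, d_stat)
    keep <- keep[-worst]
  }
  structure(flagged, statistic = d_at_flag)
}

# Dixon r-statistic critical values (two-tailed), alpha = 0.10 / 0.05 / 0.01,
# after Rorabacher (1991).  Rows are n = 3..25; the r-family switches with n:
# r10 (3-7), r11 (8-10), r21 (11-13), r22 (14-25).
DIXON_CRITICAL <- cbind(
  `0.1` = c(0.941, 0.765, 0.642, 0.560, 0.507,
            0.554, 0.512, 0.477,
            0.575, 0.546, 0.522,
            0.546, 0.525, 0.507, 0.490, 0.475, 0.462, 0.450, 0.440, 0.430,
            0.421, 0.413, 0.406),
  `0.05` = c(0.970, 0.829, 0.710, 0.625, 0.568,
             0.608, 0.564, 0.530,
             0.619, 0.583, 0.557,
             0.586, 0.565, 0.546, 0.529, 0.514, 0.501, 0.489, 0.478, 0.468,
             0.459, 0.451, 0.443),
  `0.01` = c(0.994, 0.926, 0.821, 0.740, 0.680,
             0.717, 0.672, 0.635,
             0.709, 0.660, 0.638,
             0.670, 0.647, 0.627, 0.610, 0.594, 0.580, 0.567, 0.555, 0.544,
             0.535, 0.526, 0.517))
rownames(DIXON_CRITICAL) <- 3:25

dixon_ratios <- function(x) {
  # x sorted ascending; returns c(low tail ratio, high tail ratio)
  n <- length(x)
  span <- function(i, j) x[j] - x[i]
  if (n <= 7L) {               # r10
    lo <- span(1L, 2L) / span(1L, n)
    hi <- span(n - 1L, n) / span(1L, n)
  } else if (n <= 10L) {       # r11
    lo <- span(1L, 2L) / span(1L, n - 1L)
    hi <- span(n - 1L, n) / span(2L, n)
  } else if (n <= 13L) {       # r21
    lo <- span(1L, 3L) / span(1L, n - 1L)
    hi <- span(n - 2L, n) / span(2L, n)
  } else {                     # r22
    lo <- span(1L, 3L) / span(1L, n - 2L)
    hi <- span(n - 2L, n) / span(3L, n)
  }
  c(low = lo, high = hi)
}

#' Dixon's extreme-value (Q) test
#'
#' Flags at most one suspiciously extreme value per tail in a sample of
#' 3 to 25 values.  The r-statistic family follows standard practice for
#' the sample size (r10 for n = 3-7, r11 for 8-10, r21 for 11-13, r22 for
#' 14-25) and is compared with the embedded two-tailed critical-value
#' table (Rorabacher 1991) at `alpha` in \{0.01, 0.05, 0.10\}.  With
#' `two_tailed = FALSE` only the more extreme tail is tested.
#'
#' @param values numeric vector with 3 <= length <= 25.
#' @param alpha significance level: 0.01, 0.05 or 0.10.
#' @param two_tailed test both tails (default) or only the larger ratio.
#' @return Integer vector of flagged indices into `values`, with attribute
#'   `"statistic"` (the r ratios tested, named `low`/`high`).
#' @export
dixon_test <- function(values, alpha = 0.05, two_tailed = TRUE) {
  n <- length(values)
  if (n < 3L || n > 25L)
    stop("Dixon's test requires a sample size between 3 and 25",
         call. = FALSE)
  col <- as.character(alpha)
  if (!col %in% colnames(DIXON_CRITICAL))
    stop("alpha must be one of 0.01, 0.05, 0.10", call. = FALSE)
  crit <- DIXON_CRITICAL[as.character(n), col]
  o <- order(values)
  x <- unname(values[o])
  if (x[n] == x[1L])
    return(structure(integer(), statistic = c(low = 0, high = 0)))
  r <- dixon_ratios(x)
  flagged <- integer()
  if (two_tailed) {
    if (r["low"] > crit) flagged <- c(flagged, o[1L])
    if (r["high"] > crit) flagged <- c(flagged, o[n])
  } else {
    side <- if (r["high"] >= r["low"]) "high" else "low"
    if (r[side] > crit)
      flagged <- if (side == "high") o[n] else o[1L]
  }
  structure(flagged, statistic = r)
}

#' Run the per-probe significance screen
#'
#' For every probe, computes the chosen feature per replicate in each of
#' the two treatments, optionally screens each group for outliers, and
#' tests the surviving values.  Under the default
#' `outlier_action = "remove_gene"`, a probe with any flagged replicate is
#' excluded from the significance table and listed only in the outlier
#' report; `"remove_value"` instead drops the flagged values (for paired
#' tests, the whole pair) and tests the remainder when both groups retain
#' at least `min_group` values.
#'
#' @param dataset an `st_dataset`.
#' @param treatments character vector of exactly 2 distinct treatments.
#' @param feature `"signed_auc"`, `"slope"` or `"time_point"`.
#' @param time_params times defining the feature (see
#'   [feature_per_replicate()]).
#' @param test one of `"t"`, `"paired_t"`, `"wilcoxon_mw"`,
#'   `"wilcoxon_signed_rank"`, `"permutation_t"`, `"permutation_paired_t"`.
#' @param outlier_method `"none"`, `"sd"`, `"mad"` (mean-median screens)
#'   or `"dixon"`.
#' @param outlier_action `"remove_gene"` or `"remove_value"`.
#' @param probes probe IDs to screen (default: all).
#' @param z_threshold threshold for the mean-median screens.
#' @param dixon_alpha alpha for Dixon's test.
#' @param n_perm,seed permutation-test controls.
#' @param min_group minimum group size required to test (default 2).
#' @return An object of class `st_screen`: list with data frames `results`
#'   (probe, symbol, feature, statistic, p_value, n_a, n_b,
#'   outliers_removed), `outliers` (probe, group, replicate, method,
#'   statistic) and `skipped` (probe, reason).
#' @export
run_screen <- function(dataset, treatments, feature, time_params,
                       test = c("t", "paired_t", "wilcoxon_mw",
                                "wilcoxon_signed_rank", "permutation_t",
                                "permutation_paired_t"),
                       outlier_method = c("none", "sd", "mad", "dixon"),
                       outlier_action = c("remove_gene", "remove_value"),
                       probes = dataset$probe_ids,
                       z_threshold = 1.96, dixon_alpha = 0.05,
                       n_perm = 10000, seed = NULL, min_group = 2L) {
  test <- match.arg(test)
  outlier_method <- match.arg(outlier_method)
  outlier_action <- match.arg(outlier_action)
  if (length(treatments) != 2L || treatments[1L] == treatments[2L])
    stop("exactly two distinct treatments are required", call. = FALSE)
  missing_trt <- setdiff(treatments, dataset$treatments)
  if (length(missing_trt))
    stop("unknown treatment(s): ", paste(missing_trt, collapse = ", "),
         call. = FALSE)
  is_paired_test <- test %in% c("paired_t", "wilcoxon_signed_rank",
                                "permutation_paired_t")
  if (is_paired_test && !isTRUE(dataset$paired))
    stop("paired test requested but the dataset is unpaired", call. = FALSE)

  n_reps <- vapply(treatments, function(tr) length(dataset$index[[tr]]), 0L)
  if (any(n_reps < 3L))
    warning("fewer than 3 replicates in at least one treatment; ",
            "comparisons will have little power", call. = FALSE)

  detect <- function(x) {
    if (outlier_method == "none" || length(x) < 3L) return(integer())
    if (outlier_method == "dixon") {
      if (length(x) > 25L) return(integer())
      dixon_test(x, alpha = dixon_alpha)
    } else {
      mean_median_outliers(x, variance_method = outlier_method,
                           z_threshold = z_threshold)
    }
  }

  res_rows <- list(); out_rows <- list(); skip_rows <- list()
  for (pi in seq_along(probes)) {
    probe <- probes[pi]
    ab <- tryCatch(suppressWarnings(list(
      a = feature_per_replicate(dataset, probe, treatments[1L], feature,
                                time_params),
      b = feature_per_replicate(dataset, probe, treatments[2L], feature,
                                time_params))),
      error = function(e) conditionMessage(e))
    if (is.character(ab)) {
      skip_rows[[length(skip_rows) + 1L]] <-
        data.frame(probe = probe, reason = ab)
      next
    }
    a <- ab$a; b <- ab$b
    if (is_paired_test) {
      common <- intersect(names(a), names(b))
      a <- a[common]; b <- b[common]
    }

    fa <- detect(a); fb <- detect(b)
    if (length(fa) || length(fb)) {
      stat_of <- function(fl) {
        s <- attr(fl, "statistic")
        if (length(s)) rep_len(max(s), length(fl)) else numeric(length(fl))
      }
      if (length(fa)) out_rows[[length(out_rows) + 1L]] <- data.frame(
        probe = probe, group = treatments[1L], replicate = names(a)[fa],
        method = outlier_method, statistic = stat_of(fa))
      if (length(fb)) out_rows[[length(out_rows) + 1L]] <- data.frame(
        probe = probe, group = treatments[2L], replicate = names(b)[fb],
        method = outlier_method, statistic = stat_of(fb))
      if (outlier_action == "remove_gene") next
      if (is_paired_test) {
        drop <- union(names(a)[fa], names(b)[fb])
        keep <- setdiff(names(a), drop)
        a <- a[keep]; b <- b[keep]
      } else {
        if (length(fa)) a <- a[-fa]
        if (length(fb)) b <- b[-fb]
      }
    }
    removed <- if (length(fa) || length(fb))
      paste(c(names(ab$a)[fa], names(ab$b)[fb]), collapse = ",") else ""

    if (length(a) < min_group || length(b) < min_group) {
      skip_rows[[length(skip_rows) + 1L]] <- data.frame(
        probe = probe, reason = "fewer than min_group values after removal")
      next
    }

    ht <- tryCatch(switch(test,
      t = two_sample_test(a, b, "t"),
      wilcoxon_mw = two_sample_test(a, b, "wilcoxon_mw"),
      paired_t = paired_test(a, b, "paired_t"),
      wilcoxon_signed_rank = paired_test(a, b, "wilcoxon_signed_rank"),
      permutation_t = permutation_test(
        a, b, paired = FALSE, n_perm = n_perm,
        seed = if (!is.null(seed)) (seed + pi) %% .Machine$integer.max),
      permutation_paired_t = permutation_test(
        a, b, paired = TRUE, n_perm = n_perm,
        seed = if (!is.null(seed)) (seed + pi) %% .Machine$integer.max)),
      error = function(e) conditionMessage(e))
    if (is.character(ht)) {
      skip_rows[[length(skip_rows) + 1L]] <-
        data.frame(probe = probe, reason = ht)
      next
    }
    res_rows[[length(res_rows) + 1L]] <- data.frame(
      probe = probe,
      symbol = if (!is.null(dataset$symbols)) dataset$symbols[[probe]]
               else NA_character_,
      feature = feature, statistic = ht$statistic, p_value = ht$p_value,
      n_a = length(a), n_b = length(b), outliers_removed = removed)
  }

  empty_res <- data.frame(probe = character(), symbol = character(),
                          feature = character(), statistic = numeric(),
                          p_value = numeric(), n_a = integer(),
                          n_b = integer(), outliers_removed = character())
  empty_out <- data.frame(probe = character(), group = character(),
                          replicate = character(), method = character(),
                          statistic = numeric())
  structure(list(
    results = if (length(res_rows)) do.call(rbind, res_rows) else empty_res,
    outliers = if (length(out_rows)) do.call(rbind, out_rows) else empty_out,
    skipped = if (length(skip_rows)) do.call(rbind, skip_rows)
              else data.frame(probe = character(), reason = character()),
    treatments = treatments, feature = feature, time_params = time_params,
    test = test, outlier_method = outlier_method,
    outlier_action = outlier_action),
    class = "st_screen")
}

#' @export
print.st_screen <- function(x, ...) {
  cat(sprintf(
    "st_screen: %s on %s(%s), %s vs %s\n  %d probes tested, %d with outliers (%s), %d skipped\n",
    x$test, x$feature, paste(x$time_params, collapse = ", "),
    x$treatments[1L], x$treatments[2L], nrow(x$results),
    length(unique(x$outliers$probe)), x$outlier_method, nrow(x$skipped)))
  invisible(x)
}
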