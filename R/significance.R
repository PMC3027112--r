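# Significance screening on curve features
#
# Differential expression between two treatments is tested per probe on a
# scalar feature of each replicate's profile (signed AUC, a slope, or the
# value at one time), so that the comparison respects the time structure
# while remaining a simple two-sample problem.  Parametric (Welch /
# paired t), rank-based (Mann-Whitney U / Wilcoxon signed rank) and
# permutation t-tests are available, with optional small-sample outlier
# removal per group before testing.

SIGNIFICANCE_FEATURES <- c("signed_auc", "slope", "time_point")

#' Per-replicate feature values for one probe
#'
#' Computes the chosen significance feature once per replicate of a
#' treatment.  Replicates whose observed time range does not cover the
#' requested times are skipped with a warning; at least one replicate must
#' be usable.
#'
#' @param dataset an `st_dataset`.
#' @param probe probe ID.
#' @param treatment treatment label.
#' @param feature `"signed_auc"`, `"slope"` or `"time_point"`.
#' @param time_params numeric: `c(t_start, t_end)` for the AUC,
#'   `c(t1, t2)` for the slope, a single time for `"time_point"`.
#' @return Named numeric vector (names = replicate labels).
#' @export
feature_per_replicate <- function(dataset, probe, treatment,
                                  feature = SIGNIFICANCE_FEATURES,
                                  time_params) {
  feature <- match.arg(feature)
  need <- switch(feature, signed_auc = 2L, slope = 2L, time_point = 1L)
  if (length(time_params) != need)
    stop(sprintf("feature '%s' needs %d time parameter(s)", feature, need),
         call. = FALSE)
  lo <- min(time_params); hi <- max(time_params)
  out <- numeric(); skipped <- character()
  for (r in replicate_labels(dataset, treatment)) {
    prof <- get_profile(dataset, probe, treatment, r)
    if (!covers(prof, lo, hi)) { skipped <- c(skipped, r); next }
    out[r] <- switch(feature,
      signed_auc = signed_auc(prof, time_params[1L], time_params[2L]),
      slope = slope_between(prof, time_params[1L], time_params[2L]),
      time_point = value_at(prof, time_params[1L]))
  }
  if (length(skipped))
    warning(sprintf(
      "probe '%s', treatment '%s': replicate(s) %s do not cover the requested times and were skipped",
      probe, treatment, paste(skipped, collapse = ", ")), call. = FALSE)
  if (!length(out))
    stop(sprintf("probe '%s': no usable replicate in treatment '%s'",
                 probe, treatment), call. = FALSE)
  out
}

# Welch t statistic with explicit conventions for degenerate samples:
# both groups constant and equal -> 0; constant with different means ->
# signed infinity (difference certain relative to zero spread).
welch_t_stat <- function(a, b) {
  md <- mean(a) - mean(b)
  se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
  if (se == 0) { if (md == 0) 0 else sign(md) * Inf } else md / se
}

paired_t_stat <- function(d) {
  sdd <- stats::sd(d)
  if (sdd == 0) { if (mean(d) == 0) 0 else sign(mean(d)) * Inf }
  else mean(d) / (sdd / sqrt(length(d)))
}

#' Two-sample feature test
#'
#' Unpaired comparison of per-replicate feature values between two groups:
#' Welch's unequal-variance t-test or the Mann-Whitney U test (exact when
#' sample sizes permit and there are no ties), two-sided.  When both
#' groups have zero variance the result is flagged degenerate: p = 1 for
#' equal means, p = 0 otherwise.
#'
#' @param a,b numeric vectors of feature values (each >= 2 for the t-test,
#'   >= 1 for Mann-Whitney).
#' @param test `"t"` or `"wilcoxon_mw"`.
#' @return List: `statistic`, `p_value`, `test`, `degenerate`.
#' @export
two_sample_test <- function(a, b, test = c("t", "wilcoxon_mw")) {
  test <- match.arg(test)
  if (test == "t") {
    if (length(a) < 2L || length(b) < 2L)
      stop("the t-test needs at least 2 values per group", call. = FALSE)
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      tt <- welch_t_stat(a, b)
      return(list(statistic = tt, p_value = if (tt == 0) 1 else 0,
                  test = test, degenerate = TRUE))
    }
    ht <- stats::t.test(a, b, var.equal = FALSE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = test, degenerate = FALSE)
  } else {
    if (length(a) < 1L || length(b) < 1L)
      stop("Mann-Whitney needs at least 1 value per group", call. = FALSE)
    ht <- suppressWarnings(stats::wilcox.test(a, b))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = test, degenerate = FALSE)
  }
}

#' Paired feature test
#'
#' Paired t-test on within-replicate differences, or the Wilcoxon
#' signed-rank test (zero differences dropped).  Inputs must be matched by
#' replicate.  All-zero differences give the degenerate p = 1; constant
#' nonzero differences under the paired t give the degenerate p = 0.
#'
#' @param a,b numeric vectors of equal length, matched by replicate.
#' @param test `"paired_t"` or `"wilcoxon_signed_rank"`.
#' @return List: `statistic`, `p_value`, `test`, `degenerate`.
#' @export
paired_test <- function(a, b, test = c("paired_t", "wilcoxon_signed_rank")) {
  test <- match.arg(test)
  if (length(a) != length(b))
    stop("paired test: groups must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("paired test needs at least 2 pairs", call. = FALSE)
  d <- a - b
  if (all(d == 0))
    return(list(statistic = 0, p_value = 1, test = test, degenerate = TRUE))
  if (test == "paired_t") {
    if (stats::sd(d) == 0)
      return(list(statistic = paired_t_stat(d), p_value = 0, test = test,
                  degenerate = TRUE))
    ht <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = test, degenerate = FALSE)
  } else {
    ht <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE))
    list(statistic = unname(ht$statistic), p_value = ht$p.value,
         test = test, degenerate = FALSE)
  }
}

#' Permutation t-test (unpaired or paired)
#'
#' Uses the t statistic (Welch for unpaired data, paired t otherwise) as
#' the test statistic and builds its null distribution by relabelling.
#' When the number of distinct arrangements (group relabelings
#' `choose(n_a + n_b, n_a)`, or sign flips `2^n` for paired data) is at
#' most `exact_limit`, the full enumeration is used and
#' `p = #\{|T*| >= |T_obs|\} / n_arrangements` (the observed labelling is
#' one of them, so p >= 1/n).  Otherwise `n_perm` random arrangements are
#' drawn and `p = (#\{|T*| >= |T_obs|\} + 1) / (n_perm + 1)`.
#'
#' @param a,b numeric vectors (matched by replicate when `paired`).
#' @param paired flip signs of paired differences instead of relabelling.
#' @param n_perm number of random permutations when enumeration is not
#'   feasible (default 10000).
#' @param seed RNG seed, required for the sampled mode.
#' @param exact_limit enumeration threshold (default 20000 arrangements).
#' @return List: `statistic`, `p_value`, `test`, `exact`, `n_used`.
#' @export
permutation_test <- function(a, b, paired = FALSE, n_perm = 10000,
                             seed = NULL, exact_limit = 20000) {
  if (n_perm < 1) stop("n_perm must be at least 1", call. = FALSE)
  eps <- 1e-12
  if (paired) {
    if (length(a) != length(b))
      stop("paired permutation test: groups must have equal length",
           call. = FALSE)
    d <- a - b
    n <- length(d)
    t_obs <- paired_t_stat(d)
    thr <- abs(t_obs) * (1 - eps)
    if (2^n <= exact_limit) {
      signs <- as.matrix(expand.grid(rep(list(c(1, -1)), n)))
      stats_perm <- apply(signs, 1L, function(s) paired_t_stat(s * d))
      n_used <- 2^n
      p <- sum(abs(stats_perm) >= thr) / n_used
      exact <- TRUE
    } else {
      if (is.null(seed)) stop("seed required for sampled permutations",
                              call. = FALSE)
      count <- with_seed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
          s <- sample(c(1, -1), n, replace = TRUE)
          abs(paired_t_stat(s * d)) >= thr
        }, TRUE))
      })
      n_used <- n_perm
      p <- (count + 1) / (n_perm + 1)
      exact <- FALSE
    }
  } else {
    pooled <- c(a, b)
    na <- length(a); n <- length(pooled)
    t_obs <- welch_t_stat(a, b)
    thr <- abs(t_obs) * (1 - eps)
    if (choose(n, na) <= exact_limit) {
      idx <- utils::combn(n, na)
      stats_perm <- apply(idx, 2L, function(ii)
        welch_t_stat(pooled[ii], pooled[-ii]))
      n_used <- ncol(idx)
      p <- sum(abs(stats_perm) >= thr) / n_used
      exact <- TRUE
    } else {
      if (is.null(seed)) stop("seed required for sampled permutations",
                              call. = FALSE)
      count <- with_seed(seed, {
        sum(vapply(seq_len(n_perm), function(i) {
          ii <- sample.int(n, na)
          abs(welch_t_stat(pooled[ii], pooled[-ii])) >= thr
        }, TRUE))
      })
      n_used <- n_perm
      p <- (count + 1) / (n_perm + 1)
      exact <- FALSE
    }
  }
  list(statistic = t_obs, p_value = min(p, 1),
       test = if (paired) "permutation_paired_t" else "permutation_t",
       exact = exact, n_used = n_used)
}
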