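# Curve-summary features
#
# A short expression time course is summarised by scalar features of the
# piecewise-linear curve through its measurements: the signed area under
# the curve (net up/down change over a window), slopes (rate of change),
# the value at a chosen time, the extrema and their timing, and the
# steepest rising/falling segment.  Features handle sparsity and
# irregular sampling: replicates may be measured at different times, and
# any in-range time can be evaluated by linear interpolation.

#' Construct a time-course profile
#'
#' @param times measurement times; must be unique (sorted internally).
#' @param values log2 expression at each time.
#' @return An object of class `st_profile` with strictly increasing times.
#' @export
st_profile <- function(times, values) {
  if (length(times) != length(values))
    stop("times and values must have equal length", call. = FALSE)
  if (length(times) < 1L) stop("profile needs at least one point", call. = FALSE)
  if (anyNA(times) || anyNA(values) || any(!is.finite(times)))
    stop("profile times/values must be finite and non-missing", call. = FALSE)
  o <- order(times)
  times <- unname(times[o]); values <- unname(values[o])
  if (any(diff(times) <= 0))
    stop("profile times must be strictly increasing", call. = FALSE)
  structure(list(times = times, values = values), class = "st_profile")
}

check_in_range <- function(profile, t, what = "query time") {
  lo <- profile$times[1L]; hi <- profile$times[length(profile$times)]
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  bad <- t < lo - eps | t > hi + eps
  if (any(bad))
    stop(sprintf(
      "%s %s outside the observed range [%g, %g]; extrapolation is not supported",
      what, paste(signif(t[bad], 6), collapse = ", "), lo, hi), call. = FALSE)
  invisible(TRUE)
}

profile_values_at <- function(profile, t) {
  if (length(profile$times) == 1L) return(rep(profile$values, length(t)))
  stats::approx(profile$times, profile$values, xout = t,
                method = "linear", ties = "ordered")$y
}

#' Linearly interpolate a profile onto a time grid
#'
#' Measured times return the measured value exactly; other in-range times
#' are linearly interpolated between the bracketing measurements.  There is
#' no extrapolation.  Interpolation assumes local linearity, which becomes
#' questionable when overused, so a warning is emitted when more than 10%
#' of the requested grid had to be interpolated (a guideline, not an
#' error).
#'
#' @param profile an `st_profile`.
#' @param query_times times to evaluate, all within the observed range.
#' @return An `st_profile` on the query grid.
#' @export
interpolate_profile <- function(profile, query_times) {
  stopifnot(inherits(profile, "st_profile"))
  if (length(query_times) < 1L) stop("empty query grid", call. = FALSE)
  check_in_range(profile, query_times)
  n_interp <- sum(!query_times %in% profile$times)
  if (n_interp > 0.1 * length(query_times))
    warning(sprintf(
      "%d of %d requested time points are interpolated (> 10%%); interpolation assumes local linearity",
      n_interp, length(query_times)), call. = FALSE)
  st_profile(query_times, profile_values_at(profile, query_times))
}

#' Signed area under a profile
#'
#' Trapezoidal integral of the piecewise-linear log2 curve over
#' \[t_start, t_end\]; values below zero contribute negatively, so the
#' result measures the net change in expression over the window.
#' Endpoints inside a segment are obtained by interpolation.
#'
#' @param profile an `st_profile`.
#' @param t_start,t_end integration window, within the observed range
#'   (defaults: full observed range).
#' @return The signed area (log2 units x time units).
#' @export
signed_auc <- function(profile, t_start = NULL, t_end = NULL) {
  stopifnot(inherits(profile, "st_profile"))
  if (is.null(t_start)) t_start <- profile$times[1L]
  if (is.null(t_end)) t_end <- profile$times[length(profile$times)]
  if (t_start >= t_end)
    stop("t_start must be strictly less than t_end", call. = FALSE)
  check_in_range(profile, c(t_start, t_end), "integration limit")
  inner <- profile$times[profile$times > t_start & profile$times < t_end]
  xs <- c(t_start, inner, t_end)
  ys <- profile_values_at(profile, xs)
  sum(diff(xs) * (ys[-1L] + ys[-length(ys)]) / 2)
}

#' Slope of a profile between two times
#'
#' Rate of change `(value(t2) - value(t1)) / (t2 - t1)` with interpolated
#' values allowed at either end.
#'
#' @param profile an `st_profile`.
#' @param t1,t2 distinct in-range times.
#' @return The slope (log2 units per time unit).
#' @export
slope_between <- function(profile, t1, t2) {
  stopifnot(inherits(profile, "st_profile"))
  if (t1 == t2) stop("t1 and t2 must differ", call. = FALSE)
  check_in_range(profile, c(t1, t2))
  (profile_values_at(profile, t2) - profile_values_at(profile, t1)) / (t2 - t1)
}

#' Profile value at a single time
#' @param profile an `st_profile`.
#' @param t an in-range time.
#' @return Measured or interpolated log2 value at `t`.
#' @export
value_at <- function(profile, t) {
  stopifnot(inherits(profile, "st_profile"), length(t) == 1L)
  check_in_range(profile, t)
  profile_values_at(profile, t)
}

#' Extrema of a profile on an evaluation grid
#'
#' The profile is evaluated on `grid` (interpolating where needed) and the
#' maximum/minimum values and their times are returned.  Ties are broken
#' by the earliest time, so results are deterministic.
#'
#' @param profile an `st_profile`.
#' @param grid evaluation times within the observed range.
#' @return Named list: `max_expr`, `min_expr`, `t_of_max`, `t_of_min`.
#' @export
profile_extrema <- function(profile, grid) {
  if (length(grid) < 1L) stop("empty evaluation grid", call. = FALSE)
  ev <- interpolate_profile(profile, sort(grid))
  i_max <- which.max(ev$values)   # first index = earliest time on ties
  i_min <- which.min(ev$values)
  list(max_expr = ev$values[i_max], min_expr = ev$values[i_min],
       t_of_max = ev$times[i_max], t_of_min = ev$times[i_min])
}

#' Steepest rising and falling segment slopes
#'
#' Maximum and minimum of the consecutive-segment slopes of the
#' grid-evaluated curve.  Note that for a monotone profile the "steepest
#' negative" slot simply holds the smallest slope, which may be positive.
#'
#' @param profile an `st_profile`.
#' @param grid evaluation times (at least 2) within the observed range.
#' @return Named list: `steepest_pos_slope`, `steepest_neg_slope`.
#' @export
steepest_slopes <- function(profile, grid) {
  if (length(grid) < 2L)
    stop("steepest slopes need at least 2 grid points", call. = FALSE)
  ev <- interpolate_profile(profile, sort(grid))
  sl <- diff(ev$values) / diff(ev$times)
  list(steepest_pos_slope = max(sl), steepest_neg_slope = min(sl))
}

covers <- function(profile, lo, hi = lo) {
  eps <- 1e-9 * max(1, abs(lo), abs(hi))
  !is.null(profile) &&
    profile$times[1L] <= lo + eps &&
    profile$times[length(profile$times)] >= hi - eps
}

#' Summarize replicate profiles on a common grid
#'
#' Evaluates every replicate of `probe` under `treatment` on `grid` and
#' takes the per-time mean or median across replicates.  A replicate whose
#' observed range does not cover a given grid time is excluded at that
#' time only; if no replicate covers some grid time, that is an error.
#'
#' @param dataset an `st_dataset`.
#' @param probe probe ID.
#' @param treatment treatment label.
#' @param grid evaluation time grid.
#' @param summary `"median"` (default) or `"mean"`.
#' @return An `st_profile` on `grid`.
#' @export
summarize_replicates <- function(dataset, probe, treatment, grid,
                                 summary = c("median", "mean")) {
  summary <- match.arg(summary)
  grid <- sort(grid)
  profs <- lapply(replicate_labels(dataset, treatment),
                  function(r) get_profile(dataset, probe, treatment, r))
  profs <- Filter(Negate(is.null), profs)
  if (!length(profs))
    stop(sprintf("probe '%s' has no observed replicate in treatment '%s'",
                 probe, treatment), call. = FALSE)
  vals <- matrix(NA_real_, length(profs), length(grid))
  for (i in seq_along(profs)) {
    ok <- vapply(grid, function(t) covers(profs[[i]], t), TRUE)
    if (any(ok)) vals[i, ok] <- profile_values_at(profs[[i]], grid[ok])
  }
  n_cover <- colSums(!is.na(vals))
  if (any(n_cover == 0L))
    stop(sprintf("no replicate of probe '%s' covers time %g", probe,
                 grid[which(n_cover == 0L)[1L]]), call. = FALSE)
  agg <- if (summary == "median") {
    apply(vals, 2L, stats::median, na.rm = TRUE)
  } else {
    colMeans(vals, na.rm = TRUE)
  }
  st_profile(grid, agg)
}

#' Relative (paired-difference) profile
#'
#' For paired designs, the profile of one treatment relative to another for
#' a matched replicate: the pointwise difference of grid-interpolated log2
#' values, i.e. the log2 ratio on the raw scale.
#'
#' @param dataset a paired `st_dataset`.
#' @param probe probe ID.
#' @param treatment_a,treatment_b treatments to contrast (a minus b).
#' @param replicate replicate label present in both treatments.
#' @param grid evaluation grid within both observed ranges.
#' @return An `st_profile` of differences on `grid`.
#' @export
relative_profile <- function(dataset, probe, treatment_a, treatment_b,
                             replicate, grid) {
  if (!isTRUE(dataset$paired))
    stop("relative profiles require a paired dataset", call. = FALSE)
  grid <- sort(grid)
  pa <- get_profile(dataset, probe, treatment_a, replicate)
  pb <- get_profile(dataset, probe, treatment_b, replicate)
  if (is.null(pa) || is.null(pb))
    stop(sprintf("replicate '%s' has no data for probe '%s' in one treatment",
                 replicate, probe), call. = FALSE)
  st_profile(grid, profile_values_at(pa, {check_in_range(pa, grid); grid}) -
                   profile_values_at(pb, {check_in_range(pb, grid); grid}))
}

# feature tokens usable for clustering (raw_expression expands per grid time)
CLUSTER_FEATURES <- c("signed_auc", "slope", "raw_expression", "max_expr",
                      "min_expr", "t_of_max", "t_of_min",
                      "steepest_pos_slope", "steepest_neg_slope")

#' Build a per-probe feature matrix
#'
#' Computes the selected curve features for each probe on its
#' replicate-summarized profile (or, for paired data with `relative_to`,
#' on the summary of per-replicate difference profiles), all evaluated on
#' a common time grid.  `signed_auc` and `slope` span the full grid;
#' `raw_expression` expands to one column per grid time.  Probes whose
#' profile cannot be evaluated on the grid are excluded and recorded in
#' the `"excluded"` attribute.
#'
#' @param dataset an `st_dataset`.
#' @param probes probe IDs (default: all probes).
#' @param features subset of
#'   `c("signed_auc","slope","raw_expression","max_expr","min_expr",
#'      "t_of_max","t_of_min","steepest_pos_slope","steepest_neg_slope")`.
#' @param grid evaluation time grid (at least 2 times).
#' @param summary replicate summary, `"median"` or `"mean"`.
#' @param treatment treatment whose profiles to summarise.
#' @param relative_to optional second treatment; features are then computed
#'   on `treatment - relative_to` difference profiles (paired data only).
#' @return A numeric matrix of class `feature_matrix` (probes x features)
#'   with attributes `scaling = "raw"` and `excluded`.
#' @export
build_feature_matrix <- function(dataset, probes = dataset$probe_ids,
                                 features, grid,
                                 summary = c("median", "mean"),
                                 treatment, relative_to = NULL) {
  summary <- match.arg(summary)
  grid <- sort(grid)
  if (length(grid) < 2L) stop("grid needs at least 2 times", call. = FALSE)
  if (length(features) < 1L) stop("select at least one feature", call. = FALSE)
  unknown <- setdiff(features, CLUSTER_FEATURES)
  if (length(unknown))
    stop("unknown feature(s): ", paste(unknown, collapse = ", "),
         "; available: ", paste(CLUSTER_FEATURES, collapse = ", "),
         call. = FALSE)
  if (!is.null(relative_to) && !isTRUE(dataset$paired))
    stop("relative_to requires a paired dataset", call. = FALSE)

  col_names <- unlist(lapply(features, function(f) {
    if (f == "raw_expression") sprintf("raw_expression_t%g", grid) else f
  }))

  probe_profile <- function(probe) {
    if (is.null(relative_to))
      return(summarize_replicates(dataset, probe, treatment, grid, summary))
    reps <- intersect(replicate_labels(dataset, treatment),
                      replicate_labels(dataset, relative_to))
    diffs <- list()
    for (r in reps) {
      d <- tryCatch(relative_profile(dataset, probe, treatment, relative_to,
                                     r, grid),
                    error = function(e) NULL)
      if (!is.null(d)) diffs[[length(diffs) + 1L]] <- d$values
    }
    if (!length(diffs)) stop("no replicate pair covers the grid", call. = FALSE)
    vals <- do.call(rbind, diffs)
    agg <- if (summary == "median") apply(vals, 2L, stats::median)
           else colMeans(vals)
    st_profile(grid, agg)
  }

  rows <- vector("list", length(probes))
  excluded <- character()
  for (i in seq_along(probes)) {
    p <- probes[i]
    prof <- tryCatch(suppressWarnings(probe_profile(p)),
                     error = function(e) conditionMessage(e))
    if (is.character(prof)) { excluded[p] <- prof; next }
    ex <- profile_extrema(prof, grid)
    st <- steepest_slopes(prof, grid)
    vals <- unlist(lapply(features, function(f) switch(f,
      signed_auc = signed_auc(prof, grid[1L], grid[length(grid)]),
      slope = slope_between(prof, grid[1L], grid[length(grid)]),
      raw_expression = prof$values,
      max_expr = ex$max_expr, min_expr = ex$min_expr,
      t_of_max = ex$t_of_max, t_of_min = ex$t_of_min,
      steepest_pos_slope = st$steepest_pos_slope,
      steepest_neg_slope = st$steepest_neg_slope)))
    rows[[i]] <- vals
  }
  keep <- !vapply(rows, is.null, TRUE)
  if (!any(keep))
    stop("no probe has a usable profile on the requested grid", call. = FALSE)
  if (length(excluded))
    message(length(excluded), " probe(s) excluded from the feature matrix")
  fm <- do.call(rbind, rows[keep])
  dimnames(fm) <- list(probes[keep], col_names)
  structure(fm, class = c("feature_matrix", class(fm)),
            scaling = "raw", excluded = excluded)
}
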