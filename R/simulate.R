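# Synthetic data generation
#
# The generator emits datasets in the exact tab-delimited input formats,
# with known truth, so every analysis step can be exercised and
# calibrated without external data.  It emulates the supported data
# model: several treatments, a few replicates each, short and possibly
# irregular (jittered, thinned) time grids, i.i.d. normal noise on the
# log2 scale, optional missing cells, and a configurable fraction of
# genes whose mean profile differs between treatments by an additive
# log2 effect (constant shift, ramp, or peak), optionally organised into
# cluster templates.

effect_shape <- function(effect, times, effect_size) {
  t0 <- min(times); t1 <- max(times)
  u <- if (t1 > t0) (times - t0) / (t1 - t0) else rep(0, length(times))
  switch(effect,
         constant = rep(effect_size, length(times)),
         ramp = effect_size * u,
         peak = effect_size * (1 - abs(2 * u - 1)),
         stop("unknown effect shape '", effect, "'", call. = FALSE))
}

template_shape <- function(id, times, amplitude) {
  t0 <- min(times); t1 <- max(times)
  u <- if (t1 > t0) (times - t0) / (t1 - t0) else rep(0, length(times))
  switch(((id - 1L) %% 4L) + 1L,
         rep(0, length(times)),                     # flat
         amplitude * u,                             # up ramp
         -amplitude * u,                            # down ramp
         amplitude * (1 - abs(2 * u - 1)))          # peak
}

#' Simulate a short time-course expression dataset
#'
#' Generates matched expression and label files (as single strings in the
#' supported tab-delimited formats) plus a truth table.  Null genes share
#' their mean profile across treatments; alternative genes get an
#' additive log2 effect profile in the first treatment.  When
#' `n_templates > 0`, gene baselines follow one of up to four template
#' shapes (flat, up ramp, peak, down ramp) scaled by
#' `template_amplitude`, giving known cluster structure.
#'
#' @param n_genes number of genes.
#' @param fraction_alternative fraction of genes with a true treatment
#'   effect (in \[0, 1\]).
#' @param treatments treatment labels (default two).
#' @param n_replicates replicates per treatment.
#' @param base_times measurement time grid.
#' @param jitter per-replicate uniform time jitter, as a fraction of the
#'   smallest grid gap (0 = regular sampling).
#' @param drop_rate probability that a replicate loses each interior time
#'   point (irregular lengths; endpoints kept).
#' @param noise_sd i.i.d. normal noise SD on the log2 scale.
#' @param missing_rate probability of a missing cell (in \[0, 0.5\]).
#' @param effect effect shape for alternative genes: `"constant"`,
#'   `"ramp"` or `"peak"`.
#' @param effect_size log2 magnitude of the effect.
#' @param baseline_mean,baseline_sd distribution of gene baselines.
#' @param n_templates number of cluster templates (0 = flat baselines).
#' @param template_amplitude log2 amplitude of the template shapes.
#' @param paired mark the design as paired (replicate numbers match
#'   across treatments by construction).
#' @param seed RNG seed; the output is fully reproducible from it.
#' @return List with `expression` and `label` (single strings, the two
#'   input files), and `truth` (data frame: `probe`, `status`
#'   (null/alternative), `template`).
#' @export
simulate_dataset <- function(n_genes = 500L, fraction_alternative = 0,
                             treatments = c("treatment", "control"),
                             n_replicates = 4L,
                             base_times = c(0, 2, 8, 24),
                             jitter = 0, drop_rate = 0, noise_sd = 0.3,
                             missing_rate = 0,
                             effect = c("constant", "ramp", "peak"),
                             effect_size = 1,
                             baseline_mean = 7, baseline_sd = 1,
                             n_templates = 0L, template_amplitude = 2,
                             paired = FALSE, seed = 1L) {
  effect <- match.arg(effect)
  stopifnot(fraction_alternative >= 0, fraction_alternative <= 1,
            noise_sd >= 0, missing_rate >= 0, missing_rate <= 0.5,
            n_replicates >= 1L, length(base_times) >= 2L,
            length(treatments) >= 2L)
  base_times <- sort(base_times)
  min_gap <- min(diff(base_times))

  with_seed(seed, {
    # per-(treatment, replicate) time grids
    grids <- list()
    for (trt in treatments) for (r in seq_len(n_replicates)) {
      t <- base_times
      if (jitter > 0) {
        t <- t + stats::runif(length(t), -jitter, jitter) * min_gap
        t <- sort(t)
      }
      if (drop_rate > 0 && length(t) > 2L) {
        interior <- 2:(length(t) - 1L)
        keep <- c(1L, interior[stats::runif(length(interior)) >= drop_rate],
                  length(t))
        t <- t[keep]
      }
      grids[[paste(trt, r, sep = "\r")]] <- t
    }

    probes <- sprintf("g%04d", seq_len(n_genes))
    symbols <- sprintf("GENE%04d", seq_len(n_genes))
    n_alt <- round(fraction_alternative * n_genes)
    status <- c(rep("alternative", n_alt),
                rep("null", n_genes - n_alt))[sample.int(n_genes)]
    template <- if (n_templates > 0L)
      sample.int(n_templates, n_genes, replace = TRUE) else
      rep(NA_integer_, n_genes)
    baseline <- stats::rnorm(n_genes, baseline_mean, baseline_sd)

    arrays <- character(); trt_row <- character()
    rep_row <- integer(); time_row <- numeric()
    cols <- list()
    ai <- 0L
    for (trt in treatments) for (r in seq_len(n_replicates)) {
      t <- grids[[paste(trt, r, sep = "\r")]]
      for (tt in t) {
        ai <- ai + 1L
        arrays <- c(arrays, sprintf("A%03d", ai))
        trt_row <- c(trt_row, trt)
        rep_row <- c(rep_row, r)
        time_row <- c(time_row, tt)
      }
    }
    values <- matrix(NA_real_, n_genes, length(arrays),
                     dimnames = list(probes, arrays))
    for (j in seq_along(arrays)) {
      tt <- time_row[j]
      mu <- baseline
      if (n_templates > 0L)
        mu <- mu + vapply(template, function(id)
          template_shape(id, base_times,
                         template_amplitude)[which.min(abs(base_times - tt))],
          0)
      if (trt_row[j] == treatments[1L]) {
        eff <- effect_shape(effect, base_times, effect_size)
        mu <- mu + ifelse(status == "alternative",
                          eff[which.min(abs(base_times - tt))], 0)
      }
      values[, j] <- mu + stats::rnorm(n_genes, 0, noise_sd)
    }
    if (missing_rate > 0)
      values[stats::runif(length(values)) < missing_rate] <- NA_real_

    expr_lines <- c(
      paste(c("ID", "Symbol", arrays), collapse = "\t"),
      vapply(seq_len(n_genes), function(i)
        paste(c(probes[i], symbols[i], fmt_full(values[i, ])),
              collapse = "\t"), ""))
    label_lines <- c(
      paste(c("Array", arrays), collapse = "\t"),
      paste(c("Treatment", trt_row), collapse = "\t"),
      paste(c("Replicate", rep_row), collapse = "\t"),
      paste(c("Time", fmt_full(time_row)), collapse = "\t"))
    if (paired)
      label_lines <- c(label_lines,
                       paste(c("Paired", "yes",
                               rep("", length(arrays) - 1L)), collapse = "\t"))

    list(expression = paste0(paste(expr_lines, collapse = "\n"), "\n"),
         label = paste0(paste(label_lines, collapse = "\n"), "\n"),
         truth = data.frame(probe = probes, status = status,
                            template = template))
  })
}

#' Assemble a simulated dataset directly
#'
#' Parses the text emitted by [simulate_dataset()] through the regular
#' readers, guaranteeing that simulated data take the same path as user
#' data.
#'
#' @param sim result of [simulate_dataset()].
#' @return An `st_dataset`.
#' @export
simulated_st_dataset <- function(sim) {
  expr <- read_expression_matrix(textConnection(sim$expression))
  design <- read_design_table(textConnection(sim$label))
  assemble_dataset(expr, design)
}

#' Simulate p-values from a null/alternative mixture
#'
#' Draws `round(pi0 * m)` p-values from Uniform(0, 1) (true nulls) and
#' the remainder from a Beta(`alt_shape1`, `alt_shape2`) alternative
#' concentrated near 0, with truth labels.  A direct driver for testing
#' and calibrating the multiplicity machinery.
#'
#' @param m number of tests (>= 1).
#' @param pi0 true proportion of null hypotheses.
#' @param alt_shape1,alt_shape2 Beta parameters of the alternative
#'   (defaults 0.05 and 1).
#' @param seed RNG seed.
#' @return List: `p` (numeric vector) and `truth` (`"null"` /
#'   `"alternative"` per entry).
#' @export
simulate_pvalues <- function(m, pi0, alt_shape1 = 0.05, alt_shape2 = 1,
                             seed = 1L) {
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  if (pi0 < 0 || pi0 > 1) stop("pi0 must lie in [0, 1]", call. = FALSE)
  if (alt_shape1 <= 0 || alt_shape2 <= 0)
    stop("Beta parameters must be positive", call. = FALSE)
  with_seed(seed, {
    n0 <- round(pi0 * m)
    p <- c(stats::runif(n0), stats::rbeta(m - n0, alt_shape1, alt_shape2))
    truth <- c(rep("null", n0), rep("alternative", m - n0))
    o <- sample.int(m)
    list(p = p[o], truth = truth[o])
  })
}
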