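# Plot-ready tables and the command-line workbench
#
# The GUI-free interface to the pipeline: long-format tables ready for
# plotting, and a CLI with subcommands wiring the steps together
# (simulate -> describe/plotdata -> significance -> mtc -> cluster).
# Every output file carries a manifest header (`#` comments: command,
# parameters, seed, input checksums, package version) sufficient to
# re-run the command; results are therefore reproducible and
# self-describing.

#' Long-format profile table for plotting
#'
#' Evaluates the requested probes on a common time grid and returns a
#' long table (probe, symbol, treatment, replicate, time, value), either
#' one row per replicate measurement (`mode = "replicates"`) or the
#' median/mean summary across replicates.  With `relative = TRUE` (paired
#' data only) the first treatment is expressed relative to the second.
#'
#' @param dataset an `st_dataset`.
#' @param probes probe IDs to tabulate.
#' @param grid evaluation time grid.
#' @param mode `"replicates"`, `"median"` or `"mean"`.
#' @param treatments one or two treatment labels.
#' @param relative difference of the two treatments instead of both
#'   separately (requires a paired dataset and two treatments).
#' @return Long data frame; the `replicate` column holds the replicate
#'   label or the summary name.
#' @export
profile_table <- function(dataset, probes, grid,
                          mode = c("replicates", "median", "mean"),
                          treatments = dataset$treatments,
                          relative = FALSE) {
  mode <- match.arg(mode)
  unknown <- setdiff(probes, dataset$probe_ids)
  if (length(unknown))
    stop("unknown probe(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (relative && !isTRUE(dataset$paired))
    stop("relative profiles require a paired dataset", call. = FALSE)
  if (relative && length(treatments) != 2L)
    stop("relative profiles require exactly two treatments", call. = FALSE)
  grid <- sort(grid)
  sym <- function(p) if (!is.null(dataset$symbols)) dataset$symbols[[p]]
                     else NA_character_
  rows <- list()
  add <- function(probe, treatment, replicate, prof) {
    rows[[length(rows) + 1L]] <<- data.frame(
      probe = probe, symbol = sym(probe), treatment = treatment,
      replicate = replicate, time = prof$times, value = prof$values)
  }
  for (p in probes) {
    if (relative) {
      label <- paste(treatments[1L], "vs", treatments[2L])
      reps <- intersect(replicate_labels(dataset, treatments[1L]),
                        replicate_labels(dataset, treatments[2L]))
      if (mode == "replicates") {
        for (r in reps)
          add(p, label, r, relative_profile(dataset, p, treatments[1L],
                                            treatments[2L], r, grid))
      } else {
        mat <- do.call(rbind, lapply(reps, function(r)
          relative_profile(dataset, p, treatments[1L], treatments[2L],
                           r, grid)$values))
        agg <- if (mode == "median") apply(mat, 2L, stats::median)
               else colMeans(mat)
        add(p, label, mode, st_profile(grid, agg))
      }
    } else {
      for (trt in treatments) {
        if (mode == "replicates") {
          for (r in replicate_labels(dataset, trt)) {
            prof <- get_profile(dataset, p, trt, r)
            if (is.null(prof) || !covers(prof, grid[1L],
                                         grid[length(grid)])) next
            add(p, trt, r, interpolate_profile(prof, grid))
          }
        } else {
          add(p, trt, mode,
              summarize_replicates(dataset, p, trt, grid, mode))
        }
      }
    }
  }
  if (!length(rows))
    stop("no profile covers the requested grid", call. = FALSE)
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# CLI

cli_manifest <- function(command, opts, inputs = character()) {
  c(sprintf("stcourse %s", as.character(utils::packageVersion("stcourse"))),
    sprintf("command: %s", command),
    vapply(names(opts), function(nm)
      sprintf("param %s: %s", nm, paste(opts[[nm]], collapse = ",")), ""),
    vapply(inputs, function(f)
      sprintf("input %s: md5 %s", basename(f), unname(tools::md5sum(f))),
      ""))
}

read_result_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

parse_times <- function(s) {
  out <- suppressWarnings(as.numeric(strsplit(s, ",", fixed = TRUE)[[1L]]))
  if (anyNA(out)) stop("cannot parse time list '", s, "'", call. = FALSE)
  out
}

cli_dataset <- function(opts) {
  expr <- read_expression_matrix(opts$expr)
  design <- read_design_table(opts$labels)
  assemble_dataset(expr, design, apply_log2 = isTRUE(opts$log2))
}

cli_simulate <- function(args) {
  spec <- list(
    optparse::make_option("--genes", type = "integer", default = 500L),
    optparse::make_option("--pi0", type = "double", default = 1),
    optparse::make_option("--reps", type = "integer", default = 4L),
    optparse::make_option("--times", type = "character",
                          default = "0,2,8,24"),
    optparse::make_option("--jitter", type = "double", default = 0),
    optparse::make_option("--noise", type = "double", default = 0.3),
    optparse::make_option("--effect", type = "character",
                          default = "constant:1.0"),
    optparse::make_option("--templates", type = "integer", default = 0L),
    optparse::make_option("--missing", type = "double", default = 0),
    optparse::make_option("--paired", action = "store_true",
                          default = FALSE),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-prefix", dest = "out_prefix",
                          type = "character", default = "sim"))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                               args = args)
  eff <- strsplit(opts$effect, ":", fixed = TRUE)[[1L]]
  sim <- simulate_dataset(
    n_genes = opts$genes, fraction_alternative = 1 - opts$pi0,
    n_replicates = opts$reps, base_times = parse_times(opts$times),
    jitter = opts$jitter, noise_sd = opts$noise,
    missing_rate = opts$missing, effect = eff[1L],
    effect_size = if (length(eff) > 1L) as.numeric(eff[2L]) else 1,
    n_templates = opts$templates, paired = opts$paired, seed = opts$seed)
  write_atomically(paste0(opts$out_prefix, "_expr.tsv"), function(f)
    cat(sim$expression, file = f))
  write_atomically(paste0(opts$out_prefix, "_labels.tsv"), function(f)
    cat(sim$label, file = f))
  write_atomically(paste0(opts$out_prefix, "_truth.tsv"), function(f)
    write_results_tsv(sim$truth, f,
                      manifest = cli_manifest("simulate", opts)))
  message("wrote ", opts$out_prefix, "_{expr,labels,truth}.tsv")
  0L
}

dataset_options <- function() list(
  optparse::make_option("--expr", type = "character"),
  optparse::make_option("--labels", type = "character"),
  optparse::make_option("--log2", action = "store_true", default = FALSE))

cli_describe <- function(args) {
  opts <- optparse::parse_args(
    optparse::OptionParser(option_list = dataset_options()), args = args)
  print(cli_dataset(opts))
  0L
}

cli_plotdata <- function(args) {
  spec <- c(dataset_options(), list(
    optparse::make_option("--ids", type = "character"),
    optparse::make_option("--times", type = "character"),
    optparse::make_option("--mode", type = "character",
                          default = "replicates"),
    optparse::make_option("--treatments", type = "character",
                          default = NULL),
    optparse::make_option("--relative", action = "store_true",
                          default = FALSE),
    optparse::make_option("--out", type = "character",
                          default = "plotdata.tsv")))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                               args = args)
  ds <- cli_dataset(opts)
  probes <- strsplit(opts$ids, ",", fixed = TRUE)[[1L]]
  treatments <- if (is.null(opts$treatments)) ds$treatments
                else strsplit(opts$treatments, ",", fixed = TRUE)[[1L]]
  tab <- profile_table(ds, probes, parse_times(opts$times),
                       mode = opts$mode, treatments = treatments,
                       relative = opts$relative)
  write_atomically(opts$out, function(f)
    write_results_tsv(tab, f, manifest = cli_manifest(
      "plotdata", opts, c(opts$expr, opts$labels))))
  0L
}

cli_significance <- function(args) {
  spec <- c(dataset_options(), list(
    optparse::make_option("--treatments", type = "character"),
    optparse::make_option("--feature", type = "character",
                          default = "signed_auc"),
    optparse::make_option("--times", type = "character"),
    optparse::make_option("--test", type = "character", default = "t"),
    optparse::make_option("--outliers", type = "character",
                          default = "none"),
    optparse::make_option("--outlier-action", dest = "outlier_action",
                          type = "character", default = "remove_gene"),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--n-perm", dest = "n_perm", type = "integer",
                          default = 10000L),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "significance.tsv"),
    optparse::make_option("--outliers-out", dest = "outliers_out",
                          type = "character", default = NULL)))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                               args = args)
  ds <- cli_dataset(opts)
  treatments <- strsplit(opts$treatments, ",", fixed = TRUE)[[1L]]
  scr <- run_screen(ds, treatments, feature = opts$feature,
                    time_params = parse_times(opts$times),
                    test = opts$test, outlier_method = opts$outliers,
                    outlier_action = opts$outlier_action,
                    dixon_alpha = opts$alpha, n_perm = opts$n_perm,
                    seed = opts$seed)
  manifest <- cli_manifest("significance", opts, c(opts$expr, opts$labels))
  write_atomically(opts$out, function(f)
    write_results_tsv(scr$results, f, manifest = manifest))
  if (!is.null(opts$outliers_out) && nrow(scr$outliers))
    write_atomically(opts$outliers_out, function(f)
      write_results_tsv(scr$outliers, f, manifest = manifest))
  message(sprintf("%d probes tested, %d with outliers, %d skipped",
                  nrow(scr$results), length(unique(scr$outliers$probe)),
                  nrow(scr$skipped)))
  0L
}

cli_mtc <- function(args) {
  spec <- list(
    optparse::make_option("--pvalues", type = "character"),
    optparse::make_option("--method", type = "character",
                          default = "pplot"),
    optparse::make_option("--r2-tol", dest = "r2_tol", type = "double",
                          default = 0.005),
    optparse::make_option("--plot", type = "character", default = NULL),
    optparse::make_option("--plot-out", dest = "plot_out",
                          type = "character", default = "points.tsv"),
    optparse::make_option("--out", type = "character", default = "mtc.tsv"))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                               args = args)
  tab <- read_result_tsv(opts$pvalues)
  if (!"p_value" %in% names(tab))
    stop("input '", opts$pvalues, "' has no p_value column; ",
         "run the significance step first", call. = FALSE)
  p <- tab$p_value
  m0 <- switch(opts$method,
               pplot = estimate_m0_pplot(p, r2_drop_tol = opts$r2_tol),
               cdf = estimate_m0_cdf(p),
               bh = , bonferroni = NULL,
               stop("unknown method '", opts$method, "'", call. = FALSE))
  tab$bonferroni <- bonferroni_adjust(p)
  tab$q_bh <- bh_adjust(p)
  if (!is.null(m0)) {
    tab$q_adjusted <- adjusted_fdr(p, m0)
    message(sprintf("m = %d, estimated m0 = %d (pi0 = %.3f, %s)",
                    m0$m, m0$m0, m0$pi0, m0$method))
  }
  manifest <- c(cli_manifest("mtc", opts, opts$pvalues),
                if (!is.null(m0)) sprintf("m0: %d pi0: %.6f method: %s",
                                          m0$m0, m0$pi0, m0$method))
  write_atomically(opts$out, function(f)
    write_results_tsv(tab, f, manifest = manifest))
  if (!is.null(opts$plot)) {
    pts <- mtc_plot_data(p, m0, kind = opts$plot)
    write_atomically(opts$plot_out, function(f)
      write_results_tsv(pts, f, manifest = manifest))
  }
  0L
}

cli_cluster <- function(args) {
  spec <- c(dataset_options(), list(
    optparse::make_option("--ids", type = "character", default = NULL),
    optparse::make_option("--features", type = "character",
                          default = "signed_auc,max_expr,t_of_max"),
    optparse::make_option("--times", type = "character"),
    optparse::make_option("--summary", type = "character",
                          default = "median"),
    optparse::make_option("--treatment", type = "character"),
    optparse::make_option("--relative-to", dest = "relative_to",
                          type = "character", default = NULL),
    optparse::make_option("--algorithm", type = "character",
                          default = "pam"),
    optparse::make_option("--metric", type = "character",
                          default = "euclidean"),
    optparse::make_option("--k", type = "integer", default = NULL),
    optparse::make_option("--k-range", dest = "k_range",
                          type = "character", default = NULL),
    optparse::make_option("--no-standardize", dest = "no_standardize",
                          action = "store_true", default = FALSE),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out", type = "character",
                          default = "clusters.tsv"),
    optparse::make_option("--summary-out", dest = "summary_out",
                          type = "character", default = "clusters_summary.tsv")))
  opts <- optparse::parse_args(optparse::OptionParser(option_list = spec),
                               args = args)
  ds <- cli_dataset(opts)
  probes <- if (is.null(opts$ids)) ds$probe_ids else {
    ids <- opts$ids
    if (file.exists(ids)) readLines(ids, warn = FALSE)
    else strsplit(ids, ",", fixed = TRUE)[[1L]]
  }
  fm <- build_feature_matrix(
    ds, probes, strsplit(opts$features, ",", fixed = TRUE)[[1L]],
    grid = parse_times(opts$times), summary = opts$summary,
    treatment = opts$treatment, relative_to = opts$relative_to)
  if (!opts$no_standardize) fm <- standardize_features(fm)
  if (is.null(opts$k) && is.null(opts$k_range))
    stop("provide --k or --k-range", call. = FALSE)
  if (!is.null(opts$k_range)) {
    kr <- strsplit(opts$k_range, ":", fixed = TRUE)[[1L]]
    ks <- as.integer(kr[1L]):as.integer(kr[2L])
    ck <- choose_k(fm, ks, algorithm = opts$algorithm,
                   metric = opts$metric, seed = opts$seed)
    fit <- ck$results[[as.character(ck$best_k)]]
    message("selected k = ", ck$best_k, " by average silhouette")
  } else {
    fit <- st_cluster(fm, algorithm = opts$algorithm, metric = opts$metric,
                      k = opts$k, seed = opts$seed)
  }
  sym <- if (!is.null(ds$symbols)) ds$symbols[rownames(fm)]
         else NA_character_
  assignments <- data.frame(
    probe = rownames(fm), symbol = sym, cluster = fit$assignments,
    silhouette = if (!is.null(fit$silhouette)) fit$silhouette$sil_width
                 else NA_real_,
    neighbor_cluster = if (!is.null(fit$silhouette)) fit$silhouette$neighbor
                       else NA_integer_)
  summary_tab <- data.frame(
    k = fit$k, algorithm = fit$algorithm, metric = fit$metric,
    sizes = paste(fit$sizes, collapse = ","),
    avg_silhouette = fit$avg_silhouette, homogeneity = fit$homogeneity,
    separation = fit$separation, objective = fit$objective)
  manifest <- cli_manifest("cluster", opts, c(opts$expr, opts$labels))
  write_atomically(opts$out, function(f)
    write_results_tsv(assignments, f, manifest = manifest))
  write_atomically(opts$summary_out, function(f)
    write_results_tsv(summary_tab, f, manifest = manifest))
  0L
}

#' Command-line entry point
#'
#' Dispatches `argv` to one of the subcommands `simulate`, `describe`,
#' `plotdata`, `significance`, `mtc` or `cluster` and returns an exit
#' status (0 on success, 1 on any error, with a diagnostic on stderr).
#' Installed alongside the package as the `stcourse` Rscript under
#' `inst/cli/`; see each subcommand's `--help` for flags.
#'
#' @param argv character vector of command-line arguments (first element:
#'   the subcommand).
#' @return Integer exit status, invisibly.
#' @export
run_cli <- function(argv = commandArgs(trailingOnly = TRUE)) {
  subcommands <- c("simulate", "describe", "plotdata", "significance",
                   "mtc", "cluster")
  if (!length(argv) || !argv[1L] %in% subcommands) {
    message("usage: stcourse <", paste(subcommands, collapse = "|"),
            "> [options]")
    return(invisible(2L))
  }
  status <- tryCatch(
    switch(argv[1L],
           simulate = cli_simulate(argv[-1L]),
           describe = cli_describe(argv[-1L]),
           plotdata = cli_plotdata(argv[-1L]),
           significance = cli_significance(argv[-1L]),
           mtc = cli_mtc(argv[-1L]),
           cluster = cli_cluster(argv[-1L])),
    error = function(e) {
      message("error: ", conditionMessage(e))
      1L
    })
  invisible(status)
}
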