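# Input formats
#
# Two tab-delimited files describe an experiment.  The expression file has a
# header line (probe-ID column header, optional gene-symbol column header,
# then array names) followed by one row per probe.  The label (design) file
# is transposed: a header row of array names, then rows giving the
# treatment, replicate number and time point of each array, and an optional
# fifth row flagging the data as paired ("yes"/"no").  Array columns need
# not be in the same order in the two files.

#' Read a tab-delimited expression matrix
#'
#' Parses the expression input format: a header line with the probe-ID
#' column name, optionally a gene-symbol column name, and the array names;
#' then one line per probe with the ID, optional symbol, and one expression
#' value per array.  Empty cells or the literal `NA` (any case) denote
#' missing values.  The presence of the symbol column is auto-detected:
#' if every row's second field parses as a number (or is missing) the file
#' is taken to have no symbol column.  Pass `has_symbols` to override.
#'
#' @param source file path or text connection.
#' @param has_symbols logical or `NULL` (auto-detect).
#' @return An object of class `expr_matrix`: list with `probe_ids`,
#'   `symbols` (named character or `NULL`), `array_names`, and `values`
#'   (numeric matrix, probes x arrays, `NA` = missing).
#' @export
read_expression_matrix <- function(source, has_symbols = NULL) {
  lines <- read_tsv_lines(source)
  if (length(lines) < 2L)
    stop("expression file needs a header line and at least one probe row",
         call. = FALSE)
  fields <- split_tsv(lines)
  nf <- lengths(fields)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("line %d has %d fields, expected %d", bad, nf[bad], nf[1L]),
         call. = FALSE)
  }
  if (nf[1L] < 3L)
    stop("expression file must contain at least 2 arrays", call. = FALSE)
  header <- fields[[1L]]
  rows <- fields[-1L]

  if (is.null(has_symbols)) {
    second <- vapply(rows, `[[`, "", 2L)
    parses <- function(x) {
      x <- trimws(x)
      x == "" || toupper(x) == "NA" || !is.na(suppressWarnings(as.numeric(x)))
    }
    has_symbols <- !all(vapply(second, parses, TRUE))
  }
  skip <- if (has_symbols) 2L else 1L
  if (nf[1L] <= skip + 1L)
    stop("expression file must contain at least 2 arrays", call. = FALSE)
  array_names <- header[(skip + 1L):nf[1L]]
  if (anyDuplicated(array_names))
    stop("duplicate array names in expression header: ",
         paste(unique(array_names[duplicated(array_names)]), collapse = ", "),
         call. = FALSE)

  probe_ids <- vapply(rows, `[[`, "", 1L)
  if (anyDuplicated(probe_ids)) {
    dup <- which(duplicated(probe_ids))[1L]
    stop(sprintf("duplicate probe ID '%s' at line %d", probe_ids[dup],
                 dup + 1L), call. = FALSE)
  }
  symbols <- if (has_symbols) {
    s <- vapply(rows, `[[`, "", 2L)
    names(s) <- probe_ids
    s
  }
  values <- matrix(NA_real_, length(rows), length(array_names),
                   dimnames = list(probe_ids, array_names))
  for (i in seq_along(rows)) {
    cells <- rows[[i]][(skip + 1L):nf[1L]]
    values[i, ] <- parse_numeric_cells(cells, "expression",
                                       lines = rep(i + 1L, length(cells)))
  }
  structure(list(probe_ids = probe_ids, symbols = symbols,
                 array_names = array_names, values = values),
            class = "expr_matrix")
}

#' Read a tab-delimited design (label) table
#'
#' Parses the covariate format: a header row of array names (first field is
#' an arbitrary row label), a treatment row, a replicate-number row, a
#' time-point row, and an optional paired row ("yes"/"no",
#' case-insensitive).  When the paired row is absent, the design defaults
#' to unpaired.  The (treatment, replicate, time) triple must be unique per
#' array, and a paired design must use the same replicate numbers in every
#' treatment.
#'
#' @param source file path or text connection.
#' @return An object of class `st_design`: list with `array_names`,
#'   `treatment`, `replicate` (integer), `time` (numeric), `paired`
#'   (logical scalar).
#' @export
read_design_table <- function(source) {
  lines <- read_tsv_lines(source)
  if (length(lines) < 4L)
    stop("design file needs header, treatment, replicate and time rows",
         call. = FALSE)
  fields <- split_tsv(lines)
  arr <- fields[[1L]][-1L]
  if (anyDuplicated(arr))
    stop("duplicate array names in design header", call. = FALSE)
  n_arr <- length(arr)
  get_row <- function(i, what) {
    f <- fields[[i]]
    if (length(f) != n_arr + 1L)
      stop(sprintf("%s row has %d fields, expected %d", what,
                   length(f), n_arr + 1L), call. = FALSE)
    f[-1L]
  }
  treatment <- get_row(2L, "treatment")
  rep_raw <- get_row(3L, "replicate")
  replicate <- suppressWarnings(as.integer(rep_raw))
  if (anyNA(replicate) || any(as.numeric(rep_raw) != replicate))
    stop("replicate row must contain integers; got '",
         rep_raw[which(is.na(replicate) |
                         as.numeric(rep_raw) != replicate)[1L]], "'",
         call. = FALSE)
  time <- suppressWarnings(as.numeric(get_row(4L, "time")))
  if (anyNA(time) || any(!is.finite(time)))
    stop("time row must contain finite numbers", call. = FALSE)

  paired <- FALSE
  if (length(lines) >= 5L) {
    pval <- tolower(trimws(fields[[5L]][2L]))
    if (!pval %in% c("yes", "no"))
      stop("paired row must be 'yes' or 'no', got '", fields[[5L]][2L], "'",
           call. = FALSE)
    paired <- pval == "yes"
  }

  triple <- paste(treatment, replicate, time, sep = "\r")
  if (anyDuplicated(triple))
    stop("duplicate (treatment, replicate, time) combination for arrays: ",
         paste(arr[triple %in% triple[duplicated(triple)]], collapse = ", "),
         call. = FALSE)
  if (paired) {
    reps_by_trt <- lapply(split(replicate, treatment),
                          function(r) sort(unique(r)))
    if (length(unique(lapply(reps_by_trt, identity))) > 1L &&
        !all(vapply(reps_by_trt, identical, TRUE, y = reps_by_trt[[1L]])))
      stop("paired design: replicate numbers must match across treatments",
           call. = FALSE)
  }
  structure(list(array_names = arr, treatment = treatment,
                 replicate = replicate, time = time, paired = paired),
            class = "st_design")
}

#' Assemble an analysis-ready dataset
#'
#' Joins an expression matrix with its design metadata into the internal
#' dataset model: a log2 value matrix plus an index from
#' (treatment, replicate) to time-ordered array columns.  Values are
#' assumed to be on the log2 scale already; set `apply_log2 = TRUE` to have
#' them logged on input (all stored values are log2).  Missing cells are
#' simply absent from the per-replicate profiles; a replicate of a probe
#' with no observed value at all is dropped from downstream computations.
#'
#' @param expr an `expr_matrix`.
#' @param design an `st_design` covering exactly the same arrays.
#' @param apply_log2 log the raw values (base 2) before storage.
#' @return An object of class `st_dataset`.
#' @export
assemble_dataset <- function(expr, design, apply_log2 = FALSE) {
  stopifnot(inherits(expr, "expr_matrix"), inherits(design, "st_design"))
  only_expr <- setdiff(expr$array_names, design$array_names)
  only_design <- setdiff(design$array_names, expr$array_names)
  if (length(only_expr) || length(only_design))
    stop("array names do not match between files; only in expression: {",
         paste(only_expr, collapse = ", "), "}; only in design: {",
         paste(only_design, collapse = ", "), "}", call. = FALSE)

  values <- expr$values[, design$array_names, drop = FALSE]
  if (apply_log2) {
    if (any(values <= 0, na.rm = TRUE))
      stop("apply_log2 = TRUE but the data contain non-positive values",
           call. = FALSE)
    values <- log2(values)
  }

  treatments <- unique(design$treatment)
  index <- lapply(treatments, function(trt) {
    in_trt <- design$treatment == trt
    reps <- sort(unique(design$replicate[in_trt]))
    cols_by_rep <- lapply(reps, function(r) {
      cols <- which(in_trt & design$replicate == r)
      cols[order(design$time[cols])]
    })
    names(cols_by_rep) <- as.character(reps)
    cols_by_rep
  })
  names(index) <- treatments

  structure(list(values = values, probe_ids = expr$probe_ids,
                 symbols = expr$symbols, design = design,
                 treatments = treatments, index = index,
                 paired = design$paired),
            class = "st_dataset")
}

#' @export
print.st_dataset <- function(x, ...) {
  cat(sprintf(
    "st_dataset: %d probes, %d arrays, %d treatment(s) [%s], %s\n",
    length(x$probe_ids), ncol(x$values), length(x$treatments),
    paste(x$treatments, collapse = ", "),
    if (x$paired) "paired" else "unpaired"))
  for (trt in x$treatments) {
    reps <- x$index[[trt]]
    tp <- sort(unique(x$design$time[x$design$treatment == trt]))
    cat(sprintf("  %s: %d replicate(s), times %s\n", trt, length(reps),
                paste(signif(tp, 4), collapse = ", ")))
  }
  invisible(x)
}

#' Replicate names available for a treatment
#' @param dataset an `st_dataset`.
#' @param treatment treatment label.
#' @return Character vector of replicate labels.
#' @export
replicate_labels <- function(dataset, treatment) {
  if (!treatment %in% dataset$treatments)
    stop("unknown treatment '", treatment, "'", call. = FALSE)
  names(dataset$index[[treatment]])
}

#' Extract one replicate's time-course profile
#'
#' @param dataset an `st_dataset`.
#' @param probe probe ID.
#' @param treatment treatment label.
#' @param replicate replicate label (as in the design file).
#' @return An `st_profile`, or `NULL` when every cell of that replicate is
#'   missing for the probe.
#' @export
get_profile <- function(dataset, probe, treatment, replicate) {
  if (!probe %in% dataset$probe_ids)
    stop("unknown probe '", probe, "'", call. = FALSE)
  cols <- dataset$index[[treatment]][[as.character(replicate)]]
  if (is.null(cols))
    stop(sprintf("no replicate '%s' in treatment '%s'", replicate, treatment),
         call. = FALSE)
  vals <- dataset$values[probe, cols]
  times <- dataset$design$time[cols]
  keep <- !is.na(vals)
  if (!any(keep)) return(NULL)
  st_profile(times[keep], vals[keep])
}

# --- writers (round-trip counterparts of the readers) ----------------------

fmt_full <- function(x) ifelse(is.na(x), "", sprintf("%.17g", x))

#' Write an expression matrix in the tab-delimited input format
#' @param expr an `expr_matrix`.
#' @param destination file path or connection.
#' @export
write_expression_matrix <- function(expr, destination) {
  stopifnot(inherits(expr, "expr_matrix"))
  has_sym <- !is.null(expr$symbols)
  header <- paste(c("ID", if (has_sym) "Symbol", expr$array_names),
                  collapse = "\t")
  rows <- vapply(seq_along(expr$probe_ids), function(i) {
    paste(c(expr$probe_ids[i], if (has_sym) expr$symbols[i],
            fmt_full(expr$values[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), destination)
  invisible(destination)
}

#' Write a design table in the tab-delimited label format
#' @param design an `st_design`.
#' @param destination file path or connection.
#' @export
write_design_table <- function(design, destination) {
  stopifnot(inherits(design, "st_design"))
  lines <- c(
    paste(c("Array", design$array_names), collapse = "\t"),
    paste(c("Treatment", design$treatment), collapse = "\t"),
    paste(c("Replicate", design$replicate), collapse = "\t"),
    paste(c("Time", fmt_full(design$time)), collapse = "\t"),
    paste(c("Paired", if (design$paired) "yes" else "no",
            rep("", length(design$array_names) - 1L)), collapse = "\t"))
  writeLines(lines, destination)
  invisible(destination)
}
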