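#' @keywords internal
"_PACKAGE"

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random number stream.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Strict numeric parser: "" and NA (any case) are missing, anything else must
# parse as a plain or scientific decimal.
parse_numeric_cells <- function(x, what, lines = NULL) {
  x <- trimws(x)
  miss <- x == "" | toupper(x) == "NA"
  out <- rep(NA_real_, length(x))
  if (any(!miss)) {
    v <- suppressWarnings(as.numeric(x[!miss]))
    if (anyNA(v)) {
      bad <- which(!miss)[which(is.na(v))[1L]]
      where <- if (!is.null(lines)) sprintf(" (line %d)", lines[bad]) else ""
      stop(sprintf("non-numeric %s value '%s'%s", what, x[bad], where),
           call. = FALSE)
    }
    out[!miss] <- v
  }
  out
}

read_tsv_lines <- function(source) {
  if (inherits(source, "connection")) {
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- readLines(source, warn = FALSE)
  }
  lines <- sub("\r$", "", lines)          # accept CRLF
  while (length(lines) && !nzchar(lines[length(lines)]))
    lines <- lines[-length(lines)]        # trailing blank lines ignored
  lines
}

# strsplit drops trailing empty fields; pad with a sentinel so that a line
# ending in a tab (missing last cell) keeps its full field count.
split_tsv <- function(lines) {
  parts <- strsplit(paste0(lines, "\t\x01"), "\t", fixed = TRUE)
  lapply(parts, function(f) f[-length(f)])
}

#' Write a tabular result as TSV
#'
#' Writes any data frame of results as a tab-delimited file with a header
#' row, preserving input row order.  Numeric columns are rendered with a
#' fixed number of significant digits; missing values become empty cells.
#' Optional manifest lines (run parameters, seeds, checksums) are written
#' as `#`-prefixed comments before the header so that outputs are
#' self-describing yet still machine-readable.
#'
#' @param table data frame with at least one row.
#' @param destination file path or writable connection.
#' @param digits significant digits for numeric columns (default 6).
#' @param manifest character vector of comment lines (without the leading
#'   `"# "`), written verbatim above the header.
#' @return Invisibly, the destination.
#' @export
write_results_tsv <- function(table, destination, digits = 6,
                              manifest = character()) {
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("'table' must be a non-empty data frame", call. = FALSE)
  cols <- lapply(table, function(col) {
    if (is.double(col)) {
      out <- ifelse(is.na(col), "", as.character(signif(col, digits)))
    } else {
      out <- ifelse(is.na(col), "", as.character(col))
    }
    out
  })
  body <- do.call(paste, c(cols, sep = "\t"))
  header <- paste(names(table), collapse = "\t")
  lines <- c(if (length(manifest)) paste0("# ", manifest), header, body)
  writeLines(lines, destination)
  invisible(destination)
}

# Atomic write: assemble in a sibling temp file, then rename into place.
write_atomically <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path))
    stop(sprintf("cannot write '%s'", path), call. = FALSE)
  invisible(path)
}

#' Adjusted Rand-free agreement between two partitions
#'
#' Plain Rand index: the fraction of item pairs on which two partitions
#' agree (both together or both apart).  Used to compare recovered cluster
#' assignments with generating templates.
#'
#' @param a,b integer or factor vectors of equal length.
#' @return A number in \[0, 1\].
#' @export
rand_index <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2L)
  a <- as.integer(factor(a)); b <- as.integer(factor(b))
  n <- length(a)
  same_a <- outer(a, a, "==")[upper.tri(diag(n))]
  same_b <- outer(b, b, "==")[upper.tri(diag(n))]
  mean(same_a == same_b)
}
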