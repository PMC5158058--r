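#' Construct a trace set
#'
#' A trace set is the package's container for one experimental condition:
#' a named collection of single-cell fluorescence traces. Each trace is a
#' plain numeric vector of fluorescence values in acquisition order; the
#' cell id is its name within the set.
#'
#' @param traces named list of numeric vectors, one per cell. Every trace
#'   must have length >= 2 and contain only finite values.
#' @param name label for the set (e.g. the condition, "stage 14").
#' @param sampling_rate_hz acquisition rate in Hz, or `NA` when unknown.
#'   Metadata only; no measure in the package depends on it.
#' @return an object of class `trace_set`.
#' @examples
#' ts <- trace_set(list(c1 = c(1, 2, 1, 3), c2 = c(5, 5, 6, 4)), name = "demo")
#' length(ts)
#' @export
trace_set <- function(traces, name = "traces", sampling_rate_hz = NA_real_) {
  if (!is.list(traces) || length(traces) == 0L)
    stop("'traces' must be a non-empty list of numeric vectors", call. = FALSE)
  ids <- names(traces)
  if (is.null(ids) || any(!nzchar(ids)))
    ids <- sprintf("cell_%04d", seq_along(traces))
  if (anyDuplicated(ids))
    stop("cell ids must be unique within a trace set", call. = FALSE)
  for (i in seq_along(traces)) {
    x <- traces[[i]]
    if (!is.numeric(x) || length(x) < 2L)
      stop("trace '", ids[i], "' must be numeric with length >= 2", call. = FALSE)
    if (!all(is.finite(x)))
      stop("trace '", ids[i], "' contains non-finite values", call. = FALSE)
    traces[[i]] <- as.numeric(x)
  }
  names(traces) <- ids
  lens <- lengths(traces)
  if (length(unique(lens)) > 1L)
    warning("traces in set '", name, "' have differing lengths (",
            min(lens), "-", max(lens), "); measures are computed per trace",
            call. = FALSE)
  structure(list(name = name, traces = traces,
                 sampling_rate_hz = sampling_rate_hz),
            class = "trace_set")
}

#' @export
length.trace_set <- function(x) length(x$traces)

#' @export
print.trace_set <- function(x, ...) {
  lens <- lengths(x$traces)
  cat("Trace set '", x$name, "': ", length(x$traces), " cells, ",
      if (length(unique(lens)) == 1L) paste0(lens[1], " time points each")
      else paste0("lengths ", min(lens), "-", max(lens)),
      "\n", sep = "")
  invisible(x)
}

#' @export
`[.trace_set` <- function(x, i) {
  trace_set(x$traces[i], name = x$name, sampling_rate_hz = x$sampling_rate_hz)
}

# Tokens treated as a missing (not malformed) entry when parsing CSV cells.
.missing_tokens <- c("", "NA", "NaN", "na", "nan", "NULL")

.parse_numeric_cells <- function(chr, what) {
  # chr: character vector of one cell's values. Returns numeric vector with
  # NA for missing tokens; stops on malformed (non-numeric, non-missing) text.
  out <- suppressWarnings(as.numeric(chr))
  bad <- is.na(out) & !(trimws(chr) %in% .missing_tokens)
  if (any(bad)) {
    j <- which(bad)[1]
    stop("non-numeric value '", chr[j], "' in ", what, ", entry ", j,
         call. = FALSE)
  }
  out
}

#' Read a CSV table of calcium traces
#'
#' Reads a wide-format CSV of single-cell fluorescence time series into a
#' [trace_set]. The default layout (`orientation = "time_rows"`) has one row
#' per time point and one column per cell, the common export format of
#' imaging software; `"time_columns"` reads the transposed layout, one row
#' per cell with the cell id in the first column. Lines starting with `#`
#' (provenance headers written by this package's CLI) are skipped.
#'
#' A leading time/frame index column named `t`, `time`, `frame` or `index`
#' (case-insensitive) is dropped in `time_rows` layout. Traces containing
#' missing entries (`NA`, `NaN`, empty cells) are dropped whole, with a
#' warning; missing values are never interpolated because every measure in
#' the package assumes a complete series. Any other non-numeric content is
#' an error naming the offending cell.
#'
#' @param path path to a CSV file.
#' @param orientation `"time_rows"` (default) or `"time_columns"`.
#' @param has_header logical, or `NULL` (default) to auto-detect: the first
#'   non-comment row is treated as a header when any of its fields is
#'   non-numeric.
#' @param name label for the returned set; defaults to the file name.
#' @return a [trace_set].
#' @seealso [write_traces()], [write_results()]
#' @export
read_traces <- function(path, orientation = c("time_rows", "time_columns"),
                        has_header = NULL, name = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))

  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("'", path, "' has fewer than 2 data rows", call. = FALSE)
  cells <- strsplit(lines, ",", fixed = TRUE)
  ncol <- length(cells[[1]])
  if (any(lengths(cells) != ncol))
    stop("ragged CSV: rows of differing field counts in ", path, call. = FALSE)
  mat <- matrix(trimws(unlist(cells)), nrow = length(cells), ncol = ncol,
                byrow = TRUE)

  if (is.null(has_header)) {
    first <- suppressWarnings(as.numeric(mat[1, ]))
    has_header <- any(is.na(first) & !(mat[1, ] %in% .missing_tokens))
  }

  if (orientation == "time_rows") {
    ids <- if (has_header) mat[1, ] else sprintf("cell_%04d", seq_len(ncol))
    dat <- if (has_header) mat[-1, , drop = FALSE] else mat
    drop_time <- has_header &
      tolower(ids[1]) %in% c("t", "time", "frame", "index")
    if (drop_time) {
      ids <- ids[-1]
      dat <- dat[, -1, drop = FALSE]
    }
    cols <- lapply(seq_along(ids), function(j)
      .parse_numeric_cells(dat[, j], paste0("column '", ids[j], "'")))
    names(cols) <- ids
  } else {
    if (has_header) mat <- mat[-1, , drop = FALSE]
    first <- suppressWarnings(as.numeric(mat[, 1]))
    ids_in_col <- any(is.na(first) & !(mat[, 1] %in% .missing_tokens))
    ids <- if (ids_in_col) mat[, 1] else sprintf("cell_%04d", seq_len(nrow(mat)))
    dat <- if (ids_in_col) mat[, -1, drop = FALSE] else mat
    cols <- lapply(seq_len(nrow(dat)), function(i)
      .parse_numeric_cells(dat[i, ], paste0("row '", ids[i], "'")))
    names(cols) <- ids
  }

  incomplete <- vapply(cols, anyNA, logical(1))
  if (any(incomplete)) {
    warning("dropped ", sum(incomplete), " trace(s) with missing values: ",
            paste(names(cols)[incomplete], collapse = ", "), call. = FALSE)
    cols <- cols[!incomplete]
  }
  if (length(cols) == 0L)
    stop("no complete traces left in ", path, call. = FALSE)
  trace_set(cols, name = name)
}

#' Write a trace set to CSV
#'
#' Inverse of [read_traces()]: writes one column per cell (time_rows layout)
#' or one row per cell with ids in the first column (time_columns layout).
#' Values are written with 15 significant digits so a write/read round trip
#' preserves them to better than 1e-12 relative error.
#'
#' @param ts a [trace_set]; traces must share one length for this layout.
#' @param path output file path.
#' @param orientation as in [read_traces()].
#' @param comment optional character vector written as `#`-prefixed header
#'   lines (provenance); readers skip them.
#' @export
write_traces <- function(ts, path, orientation = c("time_rows", "time_columns"),
                         comment = NULL) {
  stopifnot(inherits(ts, "trace_set"))
  orientation <- match.arg(orientation)
  lens <- lengths(ts$traces)
  if (length(unique(lens)) > 1L)
    stop("cannot write a rectangular CSV: traces have differing lengths",
         call. = FALSE)
  fmt <- function(x) format(x, digits = 15, scientific = FALSE, trim = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  if (orientation == "time_rows") {
    writeLines(paste(names(ts$traces), collapse = ","), con)
    m <- vapply(ts$traces, fmt, character(lens[1]))
    writeLines(apply(matrix(m, nrow = lens[1]), 1, paste, collapse = ","), con)
  } else {
    rows <- vapply(seq_along(ts$traces), function(i)
      paste(c(names(ts$traces)[i], fmt(ts$traces[[i]])), collapse = ","),
      character(1))
    writeLines(c(paste(c("cell_id", paste0("t", seq_len(lens[1]))),
                       collapse = ","), rows), con)
  }
  invisible(path)
}

#' Write a per-cell results table to CSV
#'
#' Writes a table whose first column is `cell_id` and whose remaining
#' columns hold computed measures, at 15 significant digits (lossless to
#' 1e-12 through [read_results()]).
#'
#' @param table a data.frame with a `cell_id` column.
#' @param path output file path.
#' @param comment optional `#`-prefixed provenance header lines.
#' @export
write_results <- function(table, path, comment = NULL) {
  stopifnot(is.data.frame(table), "cell_id" %in% names(table))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  fmt <- function(col) {
    if (is.numeric(col)) format(col, digits = 15, scientific = TRUE, trim = TRUE)
    else as.character(col)
  }
  writeLines(paste(names(table), collapse = ","), con)
  if (nrow(table) > 0L) {
    cols <- lapply(table, fmt)
    writeLines(do.call(paste, c(cols, sep = ",")), con)
  }
  invisible(path)
}

#' Read a per-cell results table written by [write_results()]
#'
#' @param path CSV path; `#` comment lines are skipped.
#' @return a data.frame.
#' @export
read_results <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
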