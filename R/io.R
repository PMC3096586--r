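#' Read a time-course matrix from a delimited text file
#'
#' Expected layout: a header row of time labels, then one row per course with
#' the course id in the first column. Cells equal to `na_token` become missing
#' values. The reader is deliberately strict — ragged rows, duplicate ids,
#' non-numeric cells and all-missing rows are errors, not silent repairs —
#' because a malformed expression matrix should fail loudly before querying.
#'
#' @param path file path.
#' @param delimiter field separator (default tab).
#' @param na_token string marking a missing value (default `"NA"`).
#' @return a [time_course_set()].
#' @export
read_matrix <- function(path, delimiter = "\t", na_token = "NA") {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("format error: need a header row and at least one course")
  cells <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(cells)
  if (any(widths != widths[1L]))
    stop(sprintf("format error: ragged rows (row %d has %d fields, expected %d)",
                 which(widths != widths[1L])[1L], widths[widths != widths[1L]][1L],
                 widths[1L]))
  if (widths[1L] < 2L) stop("format error: no time-point columns")
  header <- cells[[1L]]
  times <- suppressWarnings(as.numeric(header[-1L]))
  if (anyNA(times)) times <- seq_len(length(header) - 1L)
  body <- cells[-1L]
  ids <- vapply(body, `[[`, "", 1L)
  vals <- vapply(body, function(row) {
    x <- row[-1L]
    x[x == na_token] <- NA_character_
    y <- suppressWarnings(as.numeric(x))
    bad <- is.na(y) & !is.na(x)
    if (any(bad)) stop("format error: non-numeric cell \"", x[bad][1L], "\"")
    y
  }, numeric(length(header) - 1L))
  values <- if (is.matrix(vals)) t(vals) else matrix(vals, ncol = 1L)
  time_course_set(values, ids = ids, times = times)
}

#' Write a time-course matrix to a delimited text file
#'
#' Values are printed with 17 significant digits so that
#' `read_matrix(write_matrix(tcs))` reproduces `tcs` exactly.
#'
#' @param tcs a [time_course_set()].
#' @param path output file path.
#' @param delimiter field separator (default tab).
#' @param na_token string written for missing values (default `"NA"`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(tcs, path, delimiter = "\t", na_token = "NA") {
  validate_tcs(tcs)
  fmt <- function(x) {
    out <- sprintf("%.17g", x)
    out[is.na(x)] <- na_token
    out
  }
  header <- paste(c("id", sprintf("%.17g", tcs$times)), collapse = delimiter)
  rows <- vapply(seq_len(n_courses(tcs)), function(i) {
    paste(c(tcs$ids[i], fmt(tcs$values[i, ])), collapse = delimiter)
  }, "")
  tryCatch(suppressWarnings(writeLines(c(header, rows), path)),
           error = function(e) stop("cannot write ", path, ": ", conditionMessage(e)))
  invisible(path)
}
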