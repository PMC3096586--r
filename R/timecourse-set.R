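#' Time-course sets
#'
#' A `TimeCourseSet` holds N labeled time courses measured at T shared time
#' points: an N x T numeric matrix in which `NA` marks a missing measurement,
#' row labels identifying the courses, and real-valued time labels for the
#' columns. Time labels are purely cosmetic (they may be unevenly spaced, as
#' microarray sampling usually is); every algorithm in the package operates on
#' the integer column indices 1..T and assumes the values are already
#' normalized/log-transformed upstream.
#'
#' @param values numeric N x T matrix; `NA` entries are treated as missing.
#' @param ids character vector of N unique, non-empty course labels. Defaults
#'   to `rownames(values)`.
#' @param times numeric vector of T strictly increasing time labels. Defaults
#'   to `colnames(values)` if numeric, else `1:T`.
#' @return an object of class `TimeCourseSet` with fields `ids`, `times`,
#'   `values` (the matrix, with `ids`/`times` as dimnames).
#' @examples
#' m <- matrix(c(1, 2, NA, 4, 0, 1, 2, 3), nrow = 2, byrow = TRUE)
#' tcs <- time_course_set(m, ids = c("g1", "g2"), times = c(0, 0.5, 2, 5))
#' data_range(tcs)
#' @seealso [read_matrix()], [filter_courses()], [data_range()]
#' @export
time_course_set <- function(values, ids = rownames(values), times = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("a TimeCourseSet needs at least one course and one time point")
  if (is.null(ids)) ids <- paste0("tc", seq_len(nrow(values)))
  if (is.null(times)) {
    times <- suppressWarnings(as.numeric(colnames(values)))
    if (is.null(colnames(values)) || anyNA(times)) times <- seq_len(ncol(values))
  }
  ids <- as.character(ids)
  times <- as.numeric(times)
  storage.mode(values) <- "double"
  rownames(values) <- ids
  colnames(values) <- format(times, trim = TRUE)
  x <- structure(list(ids = ids, times = times, values = values),
                 class = "TimeCourseSet")
  validate_tcs(x)
}

validate_tcs <- function(x) {
  v <- x$values
  n <- nrow(v); t <- ncol(v)
  if (n < 1L || t < 1L) stop("a TimeCourseSet needs at least one course and one time point")
  if (length(x$ids) != n || length(x$times) != t)
    stop("ids/times lengths inconsistent with the value matrix")
  if (anyDuplicated(x$ids)) {
    dup <- unique(x$ids[duplicated(x$ids)])
    stop("duplicate ids: ", paste(dup, collapse = ", "))
  }
  if (any(!nzchar(x$ids)) || anyNA(x$ids)) stop("ids must be non-empty strings")
  if (anyNA(x$times) || (t > 1L && any(diff(x$times) <= 0)))
    stop("time labels must be finite and strictly increasing")
  if (any(is.infinite(v))) stop("values must be finite or NA")
  all_missing <- rowSums(!is.na(v)) == 0L
  if (any(all_missing))
    stop("course(s) with all values missing: ",
         paste(x$ids[all_missing], collapse = ", "))
  x
}

#' @export
print.TimeCourseSet <- function(x, ...) {
  v <- x$values
  cat(sprintf("TimeCourseSet: %d courses x %d time points\n", nrow(v), ncol(v)))
  cat(sprintf("  time labels: %s\n", paste(format(x$times, trim = TRUE), collapse = " ")))
  cat(sprintf("  missing: %d/%d values\n", sum(is.na(v)), length(v)))
  r <- data_range(x)
  cat(sprintf("  value range: [%g, %g]\n", r[1], r[2]))
  invisible(x)
}

#' Number of courses / time points
#'
#' @param tcs a [time_course_set()].
#' @return `n_courses`: N, the number of time courses; `n_times`: T, the
#'   number of time points.
#' @export
n_courses <- function(tcs) nrow(tcs$values)

#' @rdname n_courses
#' @export
n_times <- function(tcs) ncol(tcs$values)

#' Data value range
#'
#' Minimum and maximum over all non-missing values. This is the support given
#' to the uniform emissions of the waiting states inserted by [compile_hmm()].
#'
#' @param tcs a [time_course_set()].
#' @return numeric length-2 vector `c(x_min, x_max)`.
#' @export
data_range <- function(tcs) {
  r <- range(tcs$values, na.rm = TRUE)
  names(r) <- c("x_min", "x_max")
  r
}

#' Filter out sparse and flat time courses
#'
#' Drops courses whose missing fraction exceeds `max_missing_fraction` or
#' whose dynamic range (max minus min over non-missing values) falls below
#' `min_range`. This mirrors the usual pre-query cleanup of expression
#' matrices: courses that are mostly absent or essentially constant carry no
#' queryable temporal signal. The default thresholds are conventional for
#' log-scale data, not calibrated to any particular dataset; override freely.
#'
#' @param tcs a [time_course_set()].
#' @param max_missing_fraction keep courses with missing fraction <= this
#'   (in \[0, 1\]).
#' @param min_range keep courses whose value range >= this (expression units).
#' @return the filtered `TimeCourseSet`, original course order preserved.
#' @export
filter_courses <- function(tcs, max_missing_fraction = 0.25, min_range = 1.0) {
  stopifnot(max_missing_fraction >= 0, max_missing_fraction <= 1, min_range >= 0)
  v <- tcs$values
  miss_frac <- rowMeans(is.na(v))
  rng <- apply(v, 1L, function(row) {
    ok <- !is.na(row)
    diff(range(row[ok]))
  })
  keep <- miss_frac <= max_missing_fraction & rng >= min_range
  if (!any(keep)) stop("empty after filtering: no course passes the thresholds")
  time_course_set(v[keep, , drop = FALSE], ids = tcs$ids[keep], times = tcs$times)
}
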