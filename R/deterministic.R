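#' Deterministic timebox membership for a single course
#'
#' The classic all-points-inside semantics: the course satisfies the box iff
#' at every integer time point within the box's span its value is present and
#' lies in the closed band `[x_lo, x_hi]`. A missing value inside the span
#' fails the box — an absent measurement cannot be shown to lie in the band.
#' This strictness (one outlier or one missing value vetoes a course) is
#' precisely the brittleness the probabilistic engine is designed to fix.
#'
#' @param values numeric vector, one course (`NA` = missing).
#' @param b a [timebox()].
#' @return `TRUE` or `FALSE`.
#' @export
satisfies_box <- function(values, b) {
  idx <- covered_points(b, length(values))
  if (length(idx) == 0L) return(TRUE)   # vacuous span
  v <- values[idx]
  all(!is.na(v) & v >= b$x_lo & v <= b$x_hi)
}

#' Run a deterministic timebox query
#'
#' A course is a member iff it satisfies every box (set intersection over
#' boxes). An empty result is a legal outcome, not an error.
#'
#' @param spec a [query_spec()] with `mode = "deterministic"`.
#' @param tcs a [time_course_set()].
#' @return an object of class `DeterministicResult`: list with `member_ids`
#'   (in input order) and `n_queried`.
#' @export
run_deterministic <- function(spec, tcs) {
  stopifnot(inherits(spec, "QuerySpec"), inherits(tcs, "TimeCourseSet"))
  if (spec$mode != "deterministic")
    stop("run_deterministic() needs a spec with mode = \"deterministic\"")
  spec <- validate_query(spec, n_times(tcs))
  keep <- vapply(seq_len(n_courses(tcs)), function(i) {
    all(vapply(spec$boxes, function(b) satisfies_box(tcs$values[i, ], b), TRUE))
  }, TRUE)
  structure(list(member_ids = tcs$ids[keep], n_queried = n_courses(tcs)),
            class = "DeterministicResult")
}

#' @export
print.DeterministicResult <- function(x, ...) {
  cat(sprintf("DeterministicResult: %d of %d courses match\n",
              length(x$member_ids), x$n_queried))
  if (length(x$member_ids))
    cat(" ", paste(utils::head(x$member_ids, 10L), collapse = " "),
        if (length(x$member_ids) > 10L) "..." else "", "\n")
  invisible(x)
}
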