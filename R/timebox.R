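#' Timeboxes
#'
#' A timebox is a rectangle in (time, value) space: it asks that a trajectory
#' lie within the value band `[x_lo, x_hi]` during the time span
#' `[t_lo, t_hi]`. Time coordinates live on the continuous index axis of the
#' queried matrix (point 1 is the first column, point T the last), so a box
#' may start at, say, t = 1.5; measurements are still only compared at integer
#' indices, the box geometry parameterizes expected state durations in the
#' probabilistic interpretation.
#'
#' Boxes must be at least 1.0 time unit wide: the data carry no interpolation
#' model, so expecting a behavior to last less than one sampling unit is not
#' meaningful, and sub-unit boxes would force near-zero self-transition
#' probabilities (overfitting in time).
#'
#' @param t_lo,t_hi continuous time-index span, `t_hi - t_lo >= 1`.
#' @param x_lo,x_hi value band, `x_lo < x_hi`.
#' @return an object of class `Timebox`.
#' @examples
#' timebox(1, 3, 0, 2)
#' @export
timebox <- function(t_lo, t_hi, x_lo, x_hi) {
  co <- c(t_lo = t_lo, t_hi = t_hi, x_lo = x_lo, x_hi = x_hi)
  if (anyNA(co) || any(!is.finite(co))) stop("timebox coordinates must be finite")
  if (x_lo >= x_hi)
    stop(sprintf("degenerate height: x_lo (%g) must be < x_hi (%g)", x_lo, x_hi))
  if (t_hi - t_lo < 1)
    stop(sprintf("sub-unit duration: box [%g, %g] is %g wide; boxes need a minimum expected duration of 1.0",
                 t_lo, t_hi, t_hi - t_lo))
  structure(as.list(co), class = "Timebox")
}

#' @export
print.Timebox <- function(x, ...) {
  cat(sprintf("Timebox t:[%g, %g] x:[%g, %g]\n", x$t_lo, x$t_hi, x$x_lo, x$x_hi))
  invisible(x)
}

#' Query specifications
#'
#' Bundles an ordered list of time-disjoint [timebox()]es with the query mode
#' and, for probabilistic mode, the stringency `m` — how many top-ranked
#' courses the query returns. Boxes are stored sorted by `t_lo`; abutting
#' boxes (one ends exactly where the next starts) are legal and compile with
#' no waiting state between them.
#'
#' @param boxes a list of [timebox()] objects (any order; sorted internally).
#' @param mode `"probabilistic"` or `"deterministic"`.
#' @param m stringency: number of courses a probabilistic query returns
#'   (integer >= 1). Ignored in deterministic mode.
#' @return an object of class `QuerySpec`.
#' @seealso [validate_query()], [parse_query()]
#' @export
query_spec <- function(boxes, mode = c("probabilistic", "deterministic"), m = NULL) {
  mode <- match.arg(mode)
  if (inherits(boxes, "Timebox")) boxes <- list(boxes)
  if (!is.list(boxes) || length(boxes) < 1L ||
      !all(vapply(boxes, inherits, TRUE, "Timebox")))
    stop("`boxes` must be a non-empty list of Timebox objects")
  if (mode == "probabilistic") {
    if (is.null(m)) stop("probabilistic queries need a stringency `m`")
    if (!is.numeric(m) || length(m) != 1L || is.na(m) || m < 1 || m != floor(m))
      stop("`m` must be a single integer >= 1")
    m <- as.integer(m)
  } else {
    m <- NULL
  }
  boxes <- boxes[order(vapply(boxes, `[[`, 0, "t_lo"))]
  check_disjoint(boxes)
  structure(list(boxes = boxes, mode = mode, m = m), class = "QuerySpec")
}

check_disjoint <- function(boxes) {
  q <- length(boxes)
  if (q < 2L) return(invisible(boxes))
  for (j in seq_len(q - 1L)) {
    if (boxes[[j]]$t_hi > boxes[[j + 1L]]$t_lo)
      stop(sprintf("overlapping boxes: box %d ends at t=%g after box %d starts at t=%g",
                   j, boxes[[j]]$t_hi, j + 1L, boxes[[j + 1L]]$t_lo))
  }
  invisible(boxes)
}

#' Validate a query against a data set's time axis
#'
#' Re-checks every box invariant (width >= 1, positive height, pairwise
#' time-disjointness) and additionally that all boxes lie within `[1, T]` —
#' boxes may not extend beyond the measured time range. Idempotent: a valid
#' spec is returned unchanged (boxes canonically sorted by `t_lo`).
#'
#' @param spec a [query_spec()].
#' @param T number of time points of the data set to be queried.
#' @return the validated `QuerySpec`.
#' @export
validate_query <- function(spec, T) {
  stopifnot(inherits(spec, "QuerySpec"))
  spec <- query_spec(spec$boxes, mode = spec$mode, m = spec$m)
  for (j in seq_along(spec$boxes)) {
    b <- spec$boxes[[j]]
    if (b$t_lo < 1 || b$t_hi > T)
      stop(sprintf("out of range: box %d spans t:[%g, %g] but the data cover t:[1, %d]",
                   j, b$t_lo, b$t_hi, T))
    if (length(covered_points(b, T)) == 0L)
      warning(sprintf("box %d covers no integer time point; it is vacuous for deterministic queries", j))
  }
  spec
}

#' @export
print.QuerySpec <- function(x, ...) {
  cat(sprintf("QuerySpec (%s%s), %d box(es):\n", x$mode,
              if (!is.null(x$m)) paste0(", m = ", x$m) else "", length(x$boxes)))
  for (b in x$boxes) print(b)
  invisible(x)
}

#' Read a query specification from JSON or YAML
#'
#' The document must contain `mode` (`"probabilistic"` or `"deterministic"`),
#' `boxes` (a list of objects with fields `t_lo`, `t_hi`, `x_lo`, `x_hi`) and,
#' for probabilistic mode, `m`. YAML input requires the `yaml` package.
#'
#' @param path file path; format chosen by extension (`.json` vs
#'   `.yaml`/`.yml`), defaulting to JSON.
#' @return a [query_spec()].
#' @export
parse_query <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("YAML query files need the `yaml` package; use JSON instead")
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  }
  if (is.null(doc$mode)) stop("query document: missing field `mode`")
  if (is.null(doc$boxes) || length(doc$boxes) == 0L)
    stop("query document: missing or empty field `boxes`")
  bx <- doc$boxes
  if (is.data.frame(bx)) bx <- lapply(seq_len(nrow(bx)), function(i) as.list(bx[i, ]))
  boxes <- lapply(seq_along(bx), function(i) {
    b <- bx[[i]]
    need <- c("t_lo", "t_hi", "x_lo", "x_hi")
    miss <- setdiff(need, names(b))
    if (length(miss))
      stop(sprintf("query document: boxes[%d] missing field(s) %s",
                   i, paste(miss, collapse = ", ")))
    timebox(b$t_lo, b$t_hi, b$x_lo, b$x_hi)
  })
  query_spec(boxes, mode = doc$mode, m = doc[["m"]])
}

#' Write a query specification to JSON
#'
#' @param spec a [query_spec()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_query <- function(spec, path) {
  stopifnot(inherits(spec, "QuerySpec"))
  doc <- list(mode = spec$mode,
              boxes = lapply(spec$boxes, function(b) b[c("t_lo", "t_hi", "x_lo", "x_hi")]))
  if (!is.null(spec$m)) doc$m <- spec$m
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Integer time indices a box constrains: t with ceil(t_lo) <= t <= floor(t_hi),
# clipped to 1..T.
covered_points <- function(b, T) {
  lo <- max(1L, as.integer(ceiling(b$t_lo - 1e-9)))
  hi <- min(as.integer(T), as.integer(floor(b$t_hi + 1e-9)))
  if (lo > hi) integer(0) else lo:hi
}
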