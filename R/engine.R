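#' Score every course under a probabilistic query
#'
#' Compiles the query once and runs the forward algorithm over all N courses
#' (total cost O(N * K * T)). The returned table is in input order; sorting it
#' by score and truncating reproduces [run_probabilistic()] exactly, and it is
#' the right object for threshold-style analyses (likelihood histograms,
#' user-chosen cutoffs).
#'
#' @param spec a [query_spec()] with `mode = "probabilistic"`.
#' @param tcs a [time_course_set()].
#' @param support_pad passed to [compile_hmm()].
#' @return a `data.frame` with columns `id` and `log_likelihood` (input
#'   order). Attribute `n_forward_evals` counts forward evaluations (one per
#'   course), the unit in which query cost scales.
#' @export
score_table <- function(spec, tcs, support_pad = 0) {
  stopifnot(inherits(tcs, "TimeCourseSet"))
  hmm <- compile_hmm(spec, tcs, support_pad = support_pad)
  ll <- forward_all(hmm, tcs$values)
  out <- data.frame(id = tcs$ids, log_likelihood = ll, stringsAsFactors = FALSE)
  attr(out, "n_forward_evals") <- n_courses(tcs)
  out
}

#' Run a probabilistic timebox query
#'
#' Ranks all courses by forward log-likelihood under the compiled model and
#' returns the top `m` (the query stringency). Setting `m = N` returns every
#' course; `m = 1` returns the single best. Ties are broken by input order,
#' so results are reproducible and top-m results are nested in m. Courses
#' scoring `-Inf` (impossible under the model) are used only to pad the
#' result up to `m` and are flagged by the `impossible` column.
#'
#' @param spec a [query_spec()] with `mode = "probabilistic"`.
#' @param tcs a [time_course_set()].
#' @param m override the spec's stringency (default `spec$m`).
#' @param support_pad passed to [compile_hmm()].
#' @return an object of class `RankedResult`: a `data.frame` with columns
#'   `rank`, `id`, `log_likelihood`, `impossible`, plus attributes
#'   `m_requested` and `n_scored`.
#' @export
run_probabilistic <- function(spec, tcs, m = spec$m, support_pad = 0) {
  stopifnot(inherits(spec, "QuerySpec"))
  if (spec$mode != "probabilistic")
    stop("run_probabilistic() needs a spec with mode = \"probabilistic\"")
  if (is.null(m)) stop("no stringency m given")
  tab <- score_table(spec, tcs, support_pad = support_pad)
  n <- nrow(tab)
  if (m > n)
    warning(sprintf("m = %d exceeds the %d available courses; returning all", m, n))
  ord <- order(-tab$log_likelihood, seq_len(n))   # stable: ties by input order
  top <- utils::head(ord, min(m, n))
  out <- data.frame(rank = seq_along(top),
                    id = tab$id[top],
                    log_likelihood = tab$log_likelihood[top],
                    impossible = !is.finite(tab$log_likelihood[top]),
                    stringsAsFactors = FALSE)
  structure(out, m_requested = as.integer(m), n_scored = n,
            class = c("RankedResult", "data.frame"))
}

#' @export
print.RankedResult <- function(x, ...) {
  cat(sprintf("RankedResult: top %d of %d courses (m = %d requested)\n",
              nrow(x), attr(x, "n_scored"), attr(x, "m_requested")))
  print.data.frame(utils::head(x, 15L), row.names = FALSE)
  if (nrow(x) > 15L) cat(sprintf("  ... %d more rows\n", nrow(x) - 15L))
  invisible(x)
}

#' Run a query in whichever mode it specifies
#'
#' Dispatches to [run_deterministic()] or [run_probabilistic()]; both modes
#' run on identical inputs, so deterministic and probabilistic answers to the
#' same boxes can be compared directly.
#'
#' @param spec a [query_spec()].
#' @param tcs a [time_course_set()].
#' @param ... passed on to the mode-specific engine.
#' @return a `DeterministicResult` or `RankedResult`.
#' @export
run_query <- function(spec, tcs, ...) {
  if (spec$mode == "deterministic") run_deterministic(spec, tcs)
  else run_probabilistic(spec, tcs, ...)
}
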