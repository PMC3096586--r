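#' Synthetic time-course generator configuration
#'
#' Describes a two-population world: "signal" courses follow a
#' piecewise-constant template (a sequence of expression levels held for given
#' numbers of time points) distorted by the nuisances real expression time
#' courses show — per-course phase shift, per-segment speed variation,
#' measurement noise and sporadic single-point outliers; "background" courses
#' are pure measurement noise around the template's global mean. Piecewise
#' -constant templates are the matched generator for timebox queries, which
#' themselves model trajectories as levels held for geometric durations.
#'
#' Defaults describe a small log2-ratio microarray experiment: ten time
#' points, an up-then-down template at +/- 1.5 log2 units, replicate noise
#' sd 0.5, a 5% chance per measurement of a clear 2-log2-unit spike, phase
#' shifts and speed changes of up to one sampling step, and a 1:4
#' signal:background mix (30 vs 120 courses).
#'
#' @param n_signal,n_background course counts for the two populations.
#' @param segment_means `data.frame` with columns `length` (time points) and
#'   `level` (expression units): the signal template. Lengths must sum to `T`.
#' @param T number of time points; defaults to the template length.
#' @param noise_sd measurement noise sd (expression units).
#' @param outlier_prob per-measurement probability of an outlier.
#' @param outlier_magnitude outlier displacement (expression units, sign
#'   random).
#' @param max_shift maximum phase shift, in time steps (per course, uniform
#'   on `-max_shift..max_shift`).
#' @param speed_jitter maximum per-segment length perturbation, in time steps.
#' @param seed RNG seed; generation is fully deterministic given the config.
#' @return an object of class `GeneratorConfig`.
#' @export
generator_config <- function(n_signal = 30L, n_background = 120L,
                             segment_means = data.frame(length = c(5L, 5L),
                                                        level = c(1.5, -1.5)),
                             T = sum(segment_means$length),
                             noise_sd = 0.5, outlier_prob = 0.05,
                             outlier_magnitude = 2.0,
                             max_shift = 1L, speed_jitter = 1L, seed = 1L) {
  stopifnot(is.data.frame(segment_means),
            all(c("length", "level") %in% names(segment_means)),
            nrow(segment_means) >= 1L, all(segment_means$length >= 1L),
            noise_sd >= 0, outlier_prob >= 0, outlier_prob <= 1,
            outlier_magnitude >= 0, max_shift >= 0L, speed_jitter >= 0L,
            n_signal >= 0L, n_background >= 0L, n_signal + n_background >= 1L)
  if (sum(segment_means$length) != T)
    stop("segment lengths must sum to T")
  structure(list(n_signal = as.integer(n_signal),
                 n_background = as.integer(n_background),
                 segment_means = segment_means, T = as.integer(T),
                 noise_sd = noise_sd, outlier_prob = outlier_prob,
                 outlier_magnitude = outlier_magnitude,
                 max_shift = as.integer(max_shift),
                 speed_jitter = as.integer(speed_jitter),
                 seed = as.integer(seed)),
            class = "GeneratorConfig")
}

# Uniform draw from an integer range, safe for single-element ranges.
draw_int <- function(lo, hi) {
  v <- lo:hi
  v[sample.int(length(v), 1L)]
}

#' Generate a synthetic time-course set with truth labels
#'
#' Signal courses: the template level sequence, with per-segment lengths
#' jittered by up to `speed_jitter` steps (re-drawn internally if a length
#' would drop below 1, then truncated/padded to T), shifted in phase by up to
#' `max_shift` steps, plus i.i.d. Gaussian noise and sporadic outliers.
#' Background courses: Gaussian noise around the template's global mean.
#' Output is deterministic given `cfg` (the seed is part of the config); the
#' caller's RNG state is left untouched.
#'
#' @param cfg a [generator_config()].
#' @return list with `tcs` (a [time_course_set()]) and `truth` (a
#'   `data.frame` with columns `id`, `label` in `"signal"`/`"background"`).
#' @export
generate <- function(cfg) {
  stopifnot(inherits(cfg, "GeneratorConfig"))
  old_seed <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(cfg$seed)

  T <- cfg$T
  lens <- cfg$segment_means$length
  levels <- cfg$segment_means$level
  nseg <- length(lens)
  template_mean <- sum(lens * levels) / T

  make_signal <- function() {
    l <- lens
    if (cfg$speed_jitter > 0L) {
      repeat {
        l <- lens + vapply(seq_len(nseg), function(j)
          draw_int(-cfg$speed_jitter, cfg$speed_jitter), 0L)
        if (all(l >= 1L)) break
      }
    }
    lev <- rep(levels, l)
    lev <- if (length(lev) >= T) lev[seq_len(T)] else c(lev, rep(lev[length(lev)], T - length(lev)))
    s <- if (cfg$max_shift > 0L) draw_int(-cfg$max_shift, cfg$max_shift) else 0L
    x <- lev[pmin(pmax(seq_len(T) - s, 1L), T)]
    x <- x + stats::rnorm(T, 0, cfg$noise_sd)
    hit <- stats::runif(T) < cfg$outlier_prob
    if (any(hit)) {
      sign <- sample(c(-1, 1), T, replace = TRUE)
      x[hit] <- x[hit] + sign[hit] * cfg$outlier_magnitude
    }
    x
  }

  n <- cfg$n_signal + cfg$n_background
  values <- matrix(NA_real_, n, T)
  for (i in seq_len(cfg$n_signal)) values[i, ] <- make_signal()
  for (i in seq_len(cfg$n_background))
    values[cfg$n_signal + i, ] <- stats::rnorm(T, template_mean, cfg$noise_sd)

  ids <- c(sprintf("signal_%03d", seq_len(cfg$n_signal)),
           sprintf("background_%03d", seq_len(cfg$n_background)))
  list(tcs = time_course_set(values, ids = ids, times = seq_len(T)),
       truth = data.frame(id = ids,
                          label = rep(c("signal", "background"),
                                      c(cfg$n_signal, cfg$n_background)),
                          stringsAsFactors = FALSE))
}

#' Ground-truth query for a generator template
#'
#' Builds the query a user would draw to recover the template: one box per
#' segment, centered on the segment level with half-height `box_halfheight`,
#' spanning the segment's time range. Segment boundaries are placed midway
#' between the last point of one segment and the first of the next; the first
#' box starts at t = 1 and the last ends at t = T, so a single-segment
#' template compiles to a one-state chain with no waiting states. With
#' `box_halfheight = 2 * noise_sd` the compiled emission sd equals the
#' generator's noise sd exactly (sigma = height/4) — the matched-model case.
#'
#' @param cfg a [generator_config()].
#' @param box_halfheight half the box height, expression units.
#' @param mode query mode for the returned spec.
#' @param m stringency; defaults to the number of planted signal courses.
#' @return a [query_spec()].
#' @export
template_query <- function(cfg, box_halfheight = 1.0,
                           mode = c("probabilistic", "deterministic"),
                           m = cfg$n_signal) {
  stopifnot(inherits(cfg, "GeneratorConfig"), box_halfheight > 0)
  mode <- match.arg(mode)
  lens <- cfg$segment_means$length
  levels <- cfg$segment_means$level
  nseg <- length(lens)
  cuts <- c(1, cumsum(lens)[-nseg] + 0.5, cfg$T)
  boxes <- lapply(seq_len(nseg), function(j)
    timebox(cuts[j], cuts[j + 1L],
            levels[j] - box_halfheight, levels[j] + box_halfheight))
  query_spec(boxes, mode = mode, m = if (mode == "probabilistic") m else NULL)
}
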