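#' HMM states
#'
#' A state of the linear chain. `normal` states come from user boxes: they
#' emit from N(mu, sigma) where mu is the box mid-height and sigma a quarter
#' of the box height, so the box band spans mu +/- 2*sigma and carries
#' 2*pnorm(2) - 1 (about 95.5%) of the emission mass. `uniform` states are
#' the automatically inserted waiting states covering time ranges with no box:
#' they emit uniformly over the data's value range, i.e. any observation is
#' equally likely while waiting.
#'
#' The number of consecutive emissions a state produces is geometric with
#' self-transition probability `p`, so the expected duration is `1/(1 - p)`;
#' states are constructed from the duration, `p = 1 - 1/d`, and a duration of
#' exactly 1 gives `p = 0` (the state emits exactly once).
#'
#' @param kind `"normal"` or `"uniform"`.
#' @param expected_duration expected number of emissions, >= 1.
#' @param mu,sigma normal emission parameters (`sigma > 0`); normal only.
#' @param lo,hi uniform emission support (`lo < hi`); uniform only.
#' @return an object of class `HmmState` with an additional `self_prob` field.
#' @export
hmm_state <- function(kind = c("normal", "uniform"), expected_duration,
                      mu = NULL, sigma = NULL, lo = NULL, hi = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(expected_duration) || expected_duration < 1)
    stop("expected_duration must be >= 1 (a state emits at least once)")
  if (kind == "normal") {
    if (is.null(mu) || is.null(sigma) || sigma <= 0)
      stop("normal states need mu and sigma > 0")
    lo <- hi <- NULL
  } else {
    if (is.null(lo) || is.null(hi) || lo >= hi)
      stop("uniform states need support lo < hi")
    mu <- sigma <- NULL
  }
  structure(list(kind = kind, expected_duration = as.numeric(expected_duration),
                 self_prob = 1 - 1 / as.numeric(expected_duration),
                 mu = mu, sigma = sigma, lo = lo, hi = hi),
            class = "HmmState")
}

#' Compile one timebox into a normal-emission state
#'
#' The translation at the core of the probabilistic interpretation:
#' `mu = (x_lo + x_hi)/2`, `sigma = (x_hi - x_lo)/4`,
#' `expected_duration = t_hi - t_lo`, `self_prob = 1 - 1/duration`.
#'
#' @param b a [timebox()].
#' @return an `HmmState` of kind `"normal"`.
#' @export
box_to_state <- function(b) {
  stopifnot(inherits(b, "Timebox"))
  hmm_state("normal",
            expected_duration = b$t_hi - b$t_lo,
            mu = (b$x_lo + b$x_hi) / 2,
            sigma = (b$x_hi - b$x_lo) / 4)
}

#' Linear hidden Markov models
#'
#' A left-to-right chain of [hmm_state()]s: from state k the only moves are
#' staying (probability `self_prob[k]`) or advancing to k + 1 (the
#' complement). Paths start in state 1 and a course is scored by the forward
#' mass sitting in the final state at the last time point.
#'
#' @param states list of `HmmState` objects, in chain order.
#' @return an object of class `LinearHMM`.
#' @seealso [compile_hmm()], [forward_loglik()]
#' @export
linear_hmm <- function(states) {
  if (length(states) < 1L || !all(vapply(states, inherits, TRUE, "HmmState")))
    stop("`states` must be a non-empty list of HmmState objects")
  kinds <- vapply(states, `[[`, "", "kind")
  if (any(kinds[-1L] == "uniform" & kinds[-length(kinds)] == "uniform"))
    stop("two adjacent uniform states: waiting ranges must be separated by a box")
  structure(list(states = states, K = length(states)), class = "LinearHMM")
}

#' @export
print.LinearHMM <- function(x, ...) {
  cat(sprintf("LinearHMM with %d state(s):\n", x$K))
  for (k in seq_len(x$K)) {
    s <- x$states[[k]]
    if (s$kind == "normal")
      cat(sprintf("  %d. normal  mu=%.4g sigma=%.4g  d=%.4g p=%.4g\n",
                  k, s$mu, s$sigma, s$expected_duration, s$self_prob))
    else
      cat(sprintf("  %d. uniform [%.4g, %.4g]  d=%.4g p=%.4g\n",
                  k, s$lo, s$hi, s$expected_duration, s$self_prob))
  }
  invisible(x)
}

#' Compile a probabilistic query into a linear HMM
#'
#' Each box becomes a normal state (see [box_to_state()]). Uniform waiting
#' states, supported on the data's value range, are inserted automatically
#' wherever the query leaves time uncovered: between two boxes separated by a
#' positive gap (duration = the gap length), before the first box if it starts
#' after t = 1 (duration = `t_lo(b1) - 1`), and after the last box if it ends
#' before t = T (duration = `T - t_hi(bq)`). A positive duration below 1 is
#' clamped to 1 — every state emits at least once.
#'
#' Expected durations are then normalized to sum to T (the shared course
#' length): a single global rescale, with any duration pushed below 1 clamped
#' to 1 and the remainder redistributed over the other states, iterated to a
#' fixpoint. Self-transition probabilities are recomputed from the final
#' durations.
#'
#' @param spec a [query_spec()] with `mode = "probabilistic"`.
#' @param tcs a [time_course_set()]; supplies T and the uniform support.
#' @param support_pad widen the uniform support by this much on each side
#'   (useful when scoring data other than the compile-time set, whose values
#'   may exceed the compiled range and would otherwise score -Inf).
#' @return a [linear_hmm()].
#' @export
compile_hmm <- function(spec, tcs, support_pad = 0) {
  stopifnot(inherits(spec, "QuerySpec"), inherits(tcs, "TimeCourseSet"))
  if (spec$mode != "probabilistic")
    stop("compile_hmm() needs a spec with mode = \"probabilistic\"")
  T <- n_times(tcs)
  spec <- validate_query(spec, T)
  rng <- unname(data_range(tcs)) + c(-support_pad, support_pad)
  if (rng[1] >= rng[2]) rng <- rng + c(-0.5, 0.5)  # constant-valued data
  boxes <- spec$boxes
  q <- length(boxes)

  states <- list()
  add_uniform <- function(d) {
    states[[length(states) + 1L]] <<- hmm_state("uniform", max(1, d),
                                                lo = rng[1], hi = rng[2])
  }
  if (boxes[[1L]]$t_lo > 1) add_uniform(boxes[[1L]]$t_lo - 1)
  for (j in seq_len(q)) {
    states[[length(states) + 1L]] <- box_to_state(boxes[[j]])
    if (j < q) {
      gap <- boxes[[j + 1L]]$t_lo - boxes[[j]]$t_hi
      if (gap > 0) add_uniform(gap)
    }
  }
  if (boxes[[q]]$t_hi < T) add_uniform(T - boxes[[q]]$t_hi)

  d <- vapply(states, `[[`, 0, "expected_duration")
  if (length(d) > T)
    stop(sprintf("query compiles to %d states but the data have only %d time points",
                 length(d), T))
  d <- normalize_durations(d, T)
  for (k in seq_along(states)) {
    states[[k]]$expected_duration <- d[k]
    states[[k]]$self_prob <- 1 - 1 / d[k]
  }
  linear_hmm(states)
}

# Rescale durations to sum to `total`, clamping at the 1.0 floor and
# redistributing the excess over the unclamped states, iterated to a fixpoint.
normalize_durations <- function(d, total) {
  stopifnot(all(d >= 1), length(d) <= total)
  free <- rep(TRUE, length(d))
  repeat {
    target <- total - sum(d[!free])
    d[free] <- d[free] * target / sum(d[free])
    newly <- free & d < 1
    if (!any(newly)) break
    d[newly] <- 1
    free <- free & !newly
    if (!any(free)) break
  }
  if (abs(sum(d) - total) > 1e-9)
    stop("duration normalization failed to reach the target length")
  d
}

#' Emission log-density of a state
#'
#' Normal states use the closed-form normal log-density; uniform states give
#' `log(1/(hi - lo))` inside their support and `-Inf` outside. A missing
#' observation contributes `log(1) = 0`: it is marginalized out rather than
#' imputed, the standard HMM treatment of missing data.
#'
#' @param s an [hmm_state()].
#' @param x numeric vector of observations (`NA` = missing).
#' @return numeric vector of log-densities.
#' @export
emission_logdensity <- function(s, x) {
  stopifnot(inherits(s, "HmmState"))
  out <- if (s$kind == "normal") {
    stats::dnorm(x, mean = s$mu, sd = s$sigma, log = TRUE)
  } else {
    ifelse(x >= s$lo & x <= s$hi, -log(s$hi - s$lo), -Inf)
  }
  out[is.na(x)] <- 0
  out
}

#' Forward-algorithm log-likelihood of one course
#'
#' Computes `log P(o | model)` by the forward recursion in log space
#' (log-sum-exp; no underflow for any realistic T). Paths start in state 1 at
#' the first time point and must occupy the final state K at the last time
#' point; a course too short to traverse the chain (T < K), or one emitting
#' outside a uniform support, scores `-Inf`, which is a legal value meaning
#' "impossible under this model". Cost O(K*T).
#'
#' @param hmm a [linear_hmm()].
#' @param values numeric vector, one course (`NA` = missing).
#' @return log-likelihood (scalar; possibly `-Inf`).
#' @export
forward_loglik <- function(hmm, values) {
  stopifnot(inherits(hmm, "LinearHMM"))
  drop(forward_all(hmm, matrix(values, nrow = 1L)))
}

# Vectorized forward pass over all rows of a values matrix at once.
# Returns the length-N vector of log-likelihoods log alpha_K(T).
forward_all <- function(hmm, values) {
  K <- hmm$K
  N <- nrow(values); T <- ncol(values)
  log_p <- log(vapply(hmm$states, `[[`, 0, "self_prob"))     # log(0) = -Inf ok
  log_q <- log1p(-vapply(hmm$states, `[[`, 0, "self_prob"))
  # emission log-densities: list over states, each an N x T matrix
  E <- lapply(hmm$states, function(s) {
    e <- emission_logdensity(s, values)
    matrix(e, nrow = N, ncol = T)
  })
  alpha <- matrix(-Inf, N, K)
  alpha[, 1L] <- E[[1L]][, 1L]
  if (T > 1L) for (t in 2:T) {
    new <- matrix(-Inf, N, K)
    new[, 1L] <- alpha[, 1L] + log_p[1L]
    if (K > 1L) for (k in 2:K) {
      new[, k] <- logsumexp2(alpha[, k] + log_p[k], alpha[, k - 1L] + log_q[k - 1L])
    }
    alpha <- new + vapply(E, function(e) e[, t], numeric(N))
    if (N == 1L) alpha <- matrix(alpha, 1L, K)
  }
  alpha[, K]
}

# Elementwise log(exp(a) + exp(b)) robust to -Inf.
logsumexp2 <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[m == -Inf] <- -Inf
  out
}

#' Export / import a compiled model as JSON
#'
#' For inspection and regression testing of compiled queries; the JSON lists
#' each state's kind, emission parameters, expected duration and
#' self-transition probability.
#'
#' @param hmm a [linear_hmm()].
#' @param path file path.
#' @return `write_hmm`: `path`, invisibly. `read_hmm`: a `LinearHMM`.
#' @export
write_hmm <- function(hmm, path) {
  stopifnot(inherits(hmm, "LinearHMM"))
  doc <- list(states = lapply(hmm$states, function(s)
    Filter(Negate(is.null),
           s[c("kind", "expected_duration", "self_prob", "mu", "sigma", "lo", "hi")])))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  linear_hmm(lapply(doc$states, function(s)
    hmm_state(s$kind, s$expected_duration,
              mu = s$mu, sigma = s$sigma, lo = s$lo, hi = s$hi)))
}
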