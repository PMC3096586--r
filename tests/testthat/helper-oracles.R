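# Independent oracles and fixture builders. Nothing here calls the forward
# recursion or the deterministic engine under test.

# Exhaustive-path forward oracle: sum over all monotone state paths that start
# in state 1 and end in state K at time T, i.e. over duration compositions
# (n_1, ..., n_K), n_k >= 1, sum n_k = T. Emissions computed from first
# principles (dnorm / uniform density), not via emission_logdensity().
enum_forward <- function(hmm, values) {
  K <- hmm$K
  T <- length(values)
  if (K > T) return(-Inf)
  st <- hmm$states
  emit <- function(k, x) {
    if (is.na(x)) return(0)
    s <- st[[k]]
    if (s$kind == "normal") {
      -0.5 * log(2 * pi * s$sigma^2) - (x - s$mu)^2 / (2 * s$sigma^2)
    } else {
      if (x >= s$lo && x <= s$hi) -log(s$hi - s$lo) else -Inf
    }
  }
  p <- vapply(st, `[[`, 0, "self_prob")
  path_logps <- c()
  recurse <- function(k, remaining, acc) {
    if (k == K) {
      lp <- acc + (remaining - 1) * log(p[K]) +
        sum(vapply((T - remaining + 1):T, function(t) emit(K, values[t]), 0))
      path_logps <<- c(path_logps, lp)
      return(invisible(NULL))
    }
    max_n <- remaining - (K - k)          # leave >= 1 step per later state
    start_t <- T - remaining + 1
    for (n in seq_len(max_n)) {
      lp <- acc + (n - 1) * log(p[k]) + log(1 - p[k]) +
        sum(vapply(start_t:(start_t + n - 1), function(t) emit(k, values[t]), 0))
      recurse(k + 1L, remaining - n, lp)
    }
  }
  recurse(1L, T, 0)
  m <- max(path_logps)
  if (m == -Inf) return(-Inf)
  m + log(sum(exp(path_logps - m)))
}

# Brute-force deterministic membership: explicit double loop over boxes and
# integer time points.
brute_member <- function(values, boxes) {
  for (b in boxes) {
    lo <- ceiling(b$t_lo - 1e-9); hi <- floor(b$t_hi + 1e-9)
    ts <- seq_len(length(values))
    ts <- ts[ts >= lo & ts <= hi]
    for (t in ts) {
      v <- values[t]
      if (is.na(v) || v < b$x_lo || v > b$x_hi) return(FALSE)
    }
  }
  TRUE
}

# Small random fixtures -------------------------------------------------------

rand_tcs <- function(n = 5, T = 6, missing_prob = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  v <- matrix(rnorm(n * T), n, T)
  if (missing_prob > 0) {
    v[runif(n * T) < missing_prob] <- NA
    # keep the at-least-one-value invariant
    for (i in seq_len(n)) if (all(is.na(v[i, ]))) v[i, 1] <- rnorm(1)
  }
  time_course_set(v, ids = sprintf("g%02d", seq_len(n)), times = seq_len(T))
}

rand_hmm <- function(K = 3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  kinds <- character(K)
  for (k in seq_len(K)) {
    kinds[k] <- if (k > 1 && kinds[k - 1] == "uniform") "normal"
                else sample(c("normal", "uniform"), 1)
  }
  states <- lapply(kinds, function(kind) {
    d <- 1 + runif(1, 0, 3)
    if (kind == "normal") hmm_state("normal", d, mu = rnorm(1), sigma = runif(1, 0.3, 1.5))
    else hmm_state("uniform", d, lo = -3, hi = 3)
  })
  linear_hmm(states)
}

rand_boxes <- function(T, q = 2, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  # q disjoint boxes with integer-ish bounds inside [1, T]
  cuts <- sort(sample(seq(1, T), q + 1, replace = FALSE))
  lapply(seq_len(q), function(j) {
    lo <- cuts[j]; hi <- max(cuts[j + 1], lo + 1)
    x0 <- rnorm(1)
    timebox(lo, hi, x0 - runif(1, 0.2, 1.5), x0 + runif(1, 0.2, 1.5))
  })
}
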