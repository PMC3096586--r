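test_that("box_to_state applies the midpoint / quarter-height / width rules", {
  s <- box_to_state(timebox(1, 3, 0, 2))
  expect_equal(s$mu, 1)
  expect_equal(s$sigma, 0.5)
  expect_equal(s$expected_duration, 2)
  expect_equal(s$self_prob, 0.5)          # E[geometric duration] = 1/(1-p) = 2
  # width exactly 1: the state emits exactly once
  expect_equal(box_to_state(timebox(4, 5, -1, 1))$self_prob, 0)
  # the box band mu +/- 2*sigma carries 2*pnorm(2) - 1 of the emission mass
  s2 <- box_to_state(timebox(1, 4, -0.7, 1.9))
  mass <- pnorm(s2$mu + 2 * s2$sigma, s2$mu, s2$sigma) -
          pnorm(s2$mu - 2 * s2$sigma, s2$mu, s2$sigma)
  expect_equal(mass, 2 * pnorm(2) - 1)
  expect_equal(pnorm(1.9, s2$mu, s2$sigma) - pnorm(-0.7, s2$mu, s2$sigma), mass)
})

test_that("hmm_state keeps duration and self-probability consistent", {
  s <- hmm_state("uniform", 3.5, lo = -2, hi = 2)
  expect_equal(s$self_prob, 1 - 1 / 3.5)
  expect_error(hmm_state("normal", 0.5, mu = 0, sigma = 1), "at least once")
  expect_error(hmm_state("normal", 2, mu = 0, sigma = 0), "sigma")
  expect_error(hmm_state("uniform", 2, lo = 1, hi = 1), "lo < hi")
  expect_error(linear_hmm(list(hmm_state("uniform", 2, lo = 0, hi = 1),
                               hmm_state("uniform", 2, lo = 0, hi = 1))),
               "adjacent uniform")
})

test_that("compile_hmm inserts waiting states and normalizes durations to T", {
  tcs <- time_course_set(matrix(rnorm(5 * 7), 5, 7))
  rng <- data_range(tcs)

  # one box at [3,5] with T = 7: uniform / normal / uniform chain
  spec <- query_spec(timebox(3, 5, -1, 1), "probabilistic", m = 3)
  hmm <- compile_hmm(spec, tcs)
  expect_equal(hmm$K, 3L)
  expect_equal(vapply(hmm$states, `[[`, "", "kind"),
               c("uniform", "normal", "uniform"))
  d <- vapply(hmm$states, `[[`, 0, "expected_duration")
  expect_equal(sum(d), 7, tolerance = 1e-9)
  expect_equal(d, rep(7 / 3, 3))           # raw durations 2,2,2 rescaled
  expect_equal(hmm$states[[1]]$lo, unname(rng[1]))
  expect_equal(hmm$states[[3]]$hi, unname(rng[2]))

  # two abutting boxes covering [1,T] exactly: K = 2, no uniform states
  spec2 <- query_spec(list(timebox(1, 4, 0, 1), timebox(4, 7, -1, 0)),
                      "probabilistic", m = 3)
  hmm2 <- compile_hmm(spec2, tcs)
  expect_equal(hmm2$K, 2L)
  expect_equal(vapply(hmm2$states, `[[`, "", "kind"), c("normal", "normal"))
  expect_equal(sum(vapply(hmm2$states, `[[`, 0, "expected_duration")), 7,
               tolerance = 1e-9)

  # a single box spanning [1,T] compiles to one state with p = 1 - 1/T
  spec3 <- query_spec(timebox(1, 7, -1, 1), "probabilistic", m = 3)
  hmm3 <- compile_hmm(spec3, tcs)
  expect_equal(hmm3$K, 1L)
  expect_equal(hmm3$states[[1]]$self_prob, 1 - 1 / 7)
})

test_that("compile invariants hold over random queries", {
  set.seed(77)
  for (rep in 1:20) {
    T <- sample(5:12, 1)
    tcs <- rand_tcs(n = 4, T = T)
    spec <- query_spec(rand_boxes(T, q = sample(1:3, 1)), "probabilistic", m = 2)
    hmm <- compile_hmm(spec, tcs)
    d <- vapply(hmm$states, `[[`, 0, "expected_duration")
    p <- vapply(hmm$states, `[[`, 0, "self_prob")
    expect_equal(sum(d), T, tolerance = 1e-9)
    expect_true(all(d >= 1 - 1e-12))
    expect_equal(p + 1 / d, rep(1, hmm$K), tolerance = 1e-12)  # rows sum to 1
    kinds <- vapply(hmm$states, `[[`, "", "kind")
    expect_false(any(kinds[-1] == "uniform" & kinds[-length(kinds)] == "uniform"))
  }
})

test_that("sub-unit gaps and boundary ranges are clamped to duration 1", {
  tcs <- time_course_set(matrix(rnorm(3 * 8), 3, 8))
  # leading range of 0.5 and a gap of 0.5: both become duration-1 states
  spec <- query_spec(list(timebox(1.5, 3, 0, 1), timebox(3.5, 8, -1, 0)),
                     "probabilistic", m = 1)
  hmm <- compile_hmm(spec, tcs)
  expect_equal(vapply(hmm$states, `[[`, "", "kind"),
               c("uniform", "normal", "uniform", "normal"))
  d <- vapply(hmm$states, `[[`, 0, "expected_duration")
  expect_equal(sum(d), 8, tolerance = 1e-9)
  expect_true(all(d >= 1 - 1e-12))
})

test_that("emission_logdensity: closed forms, support, and missing data", {
  n <- hmm_state("normal", 2, mu = 0, sigma = 1)
  expect_equal(emission_logdensity(n, 0), log(1 / sqrt(2 * pi)))
  u <- hmm_state("uniform", 2, lo = 0, hi = 2)
  expect_equal(emission_logdensity(u, 1), log(0.5))
  expect_equal(emission_logdensity(u, 3), -Inf)
  expect_equal(emission_logdensity(u, c(0, 2)), rep(log(0.5), 2))  # closed support
  # missing observations are marginalized out
  expect_equal(emission_logdensity(n, NA), 0)
  expect_equal(emission_logdensity(u, c(NA, 1)), c(0, log(0.5)))
})

test_that("forward_loglik matches hand computations on tiny chains", {
  # K = 1, T = 1: just the emission density
  h1 <- linear_hmm(list(hmm_state("normal", 1, mu = 2, sigma = 0.5)))
  expect_equal(forward_loglik(h1, 2), dnorm(2, 2, 0.5, log = TRUE))

  # K = 1 spanning T steps: product of densities times p^(T-1)
  h2 <- linear_hmm(list(hmm_state("normal", 4, mu = 0, sigma = 1)))
  o <- c(0.1, -0.2, 0.3, 0)
  expect_equal(forward_loglik(h2, o),
               sum(dnorm(o, 0, 1, log = TRUE)) + 3 * log(0.75))

  # K = 2, T = 3: two monotone paths (112 and 122), summed by hand
  hA <- hmm_state("normal", 2, mu = 1, sigma = 0.5)   # p = 0.5
  hB <- hmm_state("normal", 3, mu = -1, sigma = 1)    # p = 2/3
  h3 <- linear_hmm(list(hA, hB))
  o3 <- c(0.8, 0.1, -0.9)
  e <- function(s, x) dnorm(x, s$mu, s$sigma, log = TRUE)
  p112 <- e(hA, o3[1]) + log(0.5) + e(hA, o3[2]) + log(0.5) + e(hB, o3[3])
  p122 <- e(hA, o3[1]) + log(0.5) + e(hB, o3[2]) + log(2 / 3) + e(hB, o3[3])
  expect_equal(forward_loglik(h3, o3), log(exp(p112) + exp(p122)),
               tolerance = 1e-12)

  # uniform-only chain: T * log(1/w) + (T-1) * log(p)
  h4 <- linear_hmm(list(hmm_state("uniform", 5, lo = -2, hi = 2)))
  expect_equal(forward_loglik(h4, rep(0, 5)), 5 * log(1 / 4) + 4 * log(0.8))
})

test_that("forward_loglik equals the exhaustive path-enumeration oracle", {
  set.seed(303)
  for (rep in 1:40) {
    K <- sample(1:4, 1)
    T <- sample(K:6, 1)
    hmm <- rand_hmm(K)
    o <- rnorm(T, sd = 2)
    if (runif(1) < 0.3) o[sample(T, 1)] <- NA
    got <- forward_loglik(hmm, o)
    want <- enum_forward(hmm, o)
    if (is.finite(want)) expect_equal(got, want, tolerance = 1e-9)
    else expect_identical(got, -Inf)
  }
})

test_that("courses that cannot traverse the chain score -Inf", {
  hmm <- linear_hmm(list(hmm_state("normal", 2, mu = 0, sigma = 1),
                         hmm_state("uniform", 2, lo = -3, hi = 3),
                         hmm_state("normal", 2, mu = 0, sigma = 1)))
  expect_identical(forward_loglik(hmm, c(0, 0)), -Inf)       # T < K
  # emission outside a uniform support kills every path through it
  expect_identical(forward_loglik(hmm, c(0, 9, 0)), -Inf)
})

test_that("shifting data and boxes together preserves likelihood differences", {
  set.seed(404)
  tcs <- rand_tcs(n = 10, T = 8)
  spec <- query_spec(list(timebox(2, 4, -0.5, 1), timebox(5, 8, -1, 0.5)),
                     "probabilistic", m = 5)
  base <- score_table(spec, tcs)$log_likelihood
  cshift <- 3.7
  tcs2 <- time_course_set(tcs$values + cshift, ids = tcs$ids, times = tcs$times)
  spec2 <- query_spec(lapply(spec$boxes, function(b)
    timebox(b$t_lo, b$t_hi, b$x_lo + cshift, b$x_hi + cshift)),
    "probabilistic", m = 5)
  shifted <- score_table(spec2, tcs2)$log_likelihood
  expect_equal(diff(base), diff(shifted), tolerance = 1e-9)
})

test_that("write_hmm / read_hmm round-trips a compiled model", {
  tcs <- rand_tcs(n = 3, T = 9, seed = 11)
  spec <- query_spec(list(timebox(2, 4, 0, 1), timebox(6, 8, -1, 0)),
                     "probabilistic", m = 2)
  hmm <- compile_hmm(spec, tcs)
  f <- withr::local_tempfile(fileext = ".json")
  write_hmm(hmm, f)
  back <- read_hmm(f)
  expect_equal(back, hmm)
  o <- rnorm(9)
  expect_equal(forward_loglik(back, o), forward_loglik(hmm, o))
})
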