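fac0 <- correction_factors(0, 1)

test_that("largest_change_point finds exact steps and rejects flat series", {
  x <- c(rep(10, 100), rep(0, 100))
  cp <- largest_change_point(x)
  expect_equal(cp$index, 100L)
  expect_equal(cp$step, -10)
  expect_null(largest_change_point(rep(5, 50)))
  expect_error(largest_change_point(1:3), "too short")
})

test_that("change point equals exhaustive SSE minimization (oracle)", {
  set.seed(8)
  for (i in 1:20) {
    n <- sample(20:500, 1)
    k <- sample(5:(n - 5), 1)
    x <- c(rnorm(k, 10), rnorm(n - k, 0))
    expect_identical(largest_change_point(x, min_effect = 0)$index,
                     oracle_change_point(x))
  }
})

test_that("noisy change points localize within 2 frames in >= 95% of runs", {
  set.seed(9)
  hits <- vapply(1:100, function(i) {
    x <- c(rnorm(100, 10, 1), rnorm(100, 0, 1))
    abs(largest_change_point(x)$index - 100L) <= 2L
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("fret_efficiency applies alpha and gamma corrections", {
  expect_equal(fret_efficiency(50, 50, fac0), 0.5)
  expect_equal(fret_efficiency(100, 10, correction_factors(0.1, 1)), 0)
  expect_equal(fret_efficiency(100, 60, correction_factors(0.1, 1)), 1 / 3)
  # non-positive denominator flagged invalid
  expect_true(is.na(fret_efficiency(0, 0, fac0)))
})

test_that("segment_states forms censored dwells at the threshold", {
  E <- c(rep(0.8, 5), rep(0.2, 3), rep(0.8, 4))
  seg <- segment_states(E, threshold = 0.48, dt = 10)
  expect_equal(seg$dwells$state, c("high_fret_wrapped", "low_fret_unwrapped",
                                   "high_fret_wrapped"))
  expect_equal(seg$dwells$duration_s, c(50, 30, 40))
  expect_equal(seg$dwells$censored, c(TRUE, FALSE, TRUE))

  const <- segment_states(rep(0.9, 10), dt = 10)
  expect_equal(nrow(const$dwells), 1L)
  expect_true(const$dwells$censored)
  expect_equal(const$dwells$state, "high_fret_wrapped")

  # tie rule: E exactly at threshold is high
  tie <- segment_states(c(0.48, 0.48, 0.2, 0.2), threshold = 0.48, dt = 1)
  expect_equal(tie$states[1:2], c(TRUE, TRUE))
})

test_that("segmentation is invariant under monotone transforms of E", {
  set.seed(10)
  E <- runif(200)
  a <- segment_states(E, threshold = 0.48, dt = 2)
  b <- segment_states(E^3, threshold = 0.48^3, dt = 2)
  expect_identical(a$dwells, b$dwells)
})

test_that("exponential MLE equals the closed-form mean (oracle)", {
  f1 <- fit_exponential(10, min_dwells = 1L)
  expect_equal(f1$tau, 10)
  expect_equal(f1$half_life, 10 * log(2))
  expect_equal(f1$rate, 1 / (10 * log(2)))
  expect_equal(f1$rate * f1$half_life, 1)

  set.seed(11)
  d <- rexp(1000, 1 / 10)
  f2 <- fit_exponential(d)
  expect_equal(f2$tau, mean(d))                  # MLE == mean, exactly
  expect_lt(abs(f2$tau - 10), 10 * 3 / sqrt(1000))

  expect_equal(fit_exponential(rep(7, 20))$tau, 7)
  # right-censored MLE: total time over uncensored count
  f3 <- fit_exponential(c(5, 5, 9), censored = c(FALSE, FALSE, TRUE),
                        censoring = "include", min_dwells = 2L)
  expect_equal(f3$tau, 19 / 2)
  expect_error(fit_exponential(c(1, 2), min_dwells = 10L), "too few")
})

test_that("qc_trace accepts a clean trace and finds both bleach points", {
  tr <- fixture_trace(rep(c("H", "L"), times = c(8, 6)), noise_sd = 5)
  ft <- qc_trace(tr, fac0)
  expect_equal(ft$qc_status, "accepted")
  expect_equal(ft$acceptor_bleach_frame, 14L)
  expect_equal(ft$donor_bleach_frame, 24L)
  expect_equal(length(ft$efficiency), 14L)
  expect_equal(mean(ft$efficiency[1:8]), 0.75, tolerance = 0.05)
})

test_that("qc_trace rejects donor-only and multi-step traces with reasons", {
  # donor-only: no acceptor signal at the start
  n <- 30L
  dono <- data.frame(molecule_id = "m", frame_index = 0:(n - 1),
                     time_s = (0:(n - 1)) * 10,
                     donor = c(rep(1000, 20), rep(0, 10)) + rnorm(n, 0, 5),
                     acceptor = rnorm(n, 0, 5))
  expect_equal(qc_trace(dono, fac0)$qc_status, "rejected:no_acceptor")

  # two-step acceptor bleach dents the corrected total intensity
  tr <- fixture_trace(rep("H", 14), noise_sd = 5)
  dip <- 8:14
  tr$acceptor[dip] <- tr$acceptor[dip] * 0.5
  expect_equal(qc_trace(tr, fac0)$qc_status, "rejected:multiple_bleach")

  # donor dies without a preceding acceptor bleach: no bleach step on the
  # acceptor channel, hence no recovery to certify
  tr2 <- fixture_trace(rep("H", 14), post_accept = 0, noise_sd = 5)
  expect_equal(qc_trace(tr2, fac0)$qc_status, "rejected:no_acceptor_bleach")
})

test_that("QC labels agree with the synthetic generator's classes", {
  sim <- simulate_fret_traces(fret_preset("WT", n_molecules = 80, seed = 12))
  res <- fret_dwell_pipeline(sim$traces, correction_factors(0.1, 1))
  t <- merge(res$qc, sim$truth)
  donly <- t[t$class == "donor_only", ]
  expect_true(all(donly$status == "rejected:no_acceptor"))
  expect_false(any(t$status[t$class == "multi_step"] == "accepted"))
})

test_that("dwell_kinetics fits satisfy the rate/half-life identities", {
  sim <- simulate_fret_traces(fret_preset("D159A", n_molecules = 60, seed = 13))
  res <- fret_dwell_pipeline(sim$traces, correction_factors(0.1, 1))
  for (f in list(res$fits$low, res$fits$high)) {
    expect_equal(f$half_life / f$tau, log(2))
    expect_equal(f$rate * f$half_life, 1)
  }
})

test_that("compare_replicates is a classical pooled-variance t-test", {
  same <- compare_replicates(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  jit <- c(-0.01, 0, 0.01)
  sep <- compare_replicates(16.4 + jit, 9.19 + jit)
  expect_lt(sep$p_value, 0.01)
  expect_error(compare_replicates(1, c(1, 2)), ">= 2 replicate")
  # cross-check against stats::t.test on a generic case
  set.seed(14)
  a <- rnorm(5, 1); b <- rnorm(6, 2)
  ours <- compare_replicates(a, b)
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ours$t, unname(ref$statistic))
  expect_equal(ours$p_value, ref$p.value)
})
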