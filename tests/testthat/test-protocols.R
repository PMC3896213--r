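test_that("default protocol enumerates 75 indexed simulations", {
  p <- stimulus_protocol()
  expect_equal(nrow(p$table), 75)
  expect_equal(length(unique(p$table$stim_id)), 15)
  expect_equal(max(table(p$table$stim_id)), 5)
  expect_error(stimulus_protocol(depths = c(0.005, 0.2)), "depths")
})

test_that("ramp and static rates count spikes in the right windows", {
  stim <- make_ramp_hold(0.36, 1143, hold = 5)   # ramp 25.1 ms
  train <- spike_train(c(5, 12, 20, 3000, 4000))
  expect_equal(ramp_rate(train, stim), 3 / (stim$ramp_ms / 1000))
  expect_equal(ramp_rate(train, stim), 119.5, tolerance = 1e-2)

  # static window is the final 2.5 s of the hold
  t_end <- stim$ramp_ms + 5000
  early <- spike_train(t_end - 2500 - 100 - 10 * (10:1))   # all before window
  expect_equal(static_rate(early, stim), 0)
  inside <- spike_train(t_end - 2500 + 10 * (1:10))
  expect_equal(static_rate(inside, stim), 4)

  hold_only <- spike_train(c(200, 300))
  expect_equal(ramp_rate(hold_only, stim), 0)
  expect_equal(ramp_rate(spike_train(numeric(0)), stim), 0)
  expect_error(static_rate(train, make_ramp_hold(0.1, 100, hold = 2)),
               "static window")
  expect_error(ramp_rate(train, make_ramp_hold(0, 100)), "zero ramp")

  # uniform 5 Hz train: one-count quantization around 5 Hz
  unif <- spike_train(seq(0, t_end, by = 200))
  expect_equal(static_rate(unif, stim), 5, tolerance = 0.1)
})

test_that("first-spike latency reports the first spike or NA", {
  stim <- make_ramp_hold(0.2, 81)
  expect_equal(first_spike_latency(spike_train(c(12, 40)), stim), 12)
  expect_true(is.na(first_spike_latency(spike_train(numeric(0)), stim)))
})

test_that("exponential displacement-response fit recovers generating parameters", {
  D <- c(0.04, 0.12, 0.20, 0.28, 0.36)
  fit <- fit_displacement_response(D, 2 * exp(5 * D))
  expect_equal(fit$Y0, 2, tolerance = 1e-4)
  expect_equal(fit$kappa, 5, tolerance = 1e-4)
  expect_gt(fit$r_squared, 0.9999)

  flat <- fit_displacement_response(D, rep(7, 5))
  expect_equal(flat$kappa, 0, tolerance = 1e-6)
  expect_equal(flat$Y0, 7, tolerance = 1e-6)
  expect_error(fit_displacement_response(c(0.1, 0.2), c(1, 2)), "3 distinct")
})

test_that("kappa is recovered within 10% under 5% multiplicative noise", {
  D <- rep(c(0.04, 0.12, 0.20, 0.28, 0.36), each = 15)
  set.seed(123)
  err <- replicate(60, {
    r <- 2 * exp(5 * D) * (1 + rnorm(length(D), 0, 0.05))
    abs(fit_displacement_response(D, r)$kappa - 5) / 5
  })
  expect_gt(mean(err < 0.10), 0.95)
})

test_that("extra sum-of-squares F test separates different kappas and not identical data", {
  D <- rep(c(0.04, 0.12, 0.20, 0.28, 0.36), each = 15)
  set.seed(9)
  rA <- 2 * exp(7.7 * D) * (1 + rnorm(length(D), 0, 0.1))
  same <- compare_exponential_fits(D, rA, D, rA, share = "kappa")
  expect_lt(same$F, 1e-6)
  expect_gt(same$p_value, 0.999)

  # power: kappa 7.7 vs 5.0 at the published sample size
  set.seed(10)
  hits <- replicate(25, {
    a <- 2 * exp(7.7 * D) * (1 + rnorm(length(D), 0, 0.1))
    b <- 3 * exp(5.0 * D) * (1 + rnorm(length(D), 0, 0.1))
    compare_exponential_fits(D, a, D, b, share = "kappa")$p_value < 0.05
  })
  expect_gte(mean(hits), 0.8)
})

test_that("percent firing-rate change follows the summed-rate definition", {
  a <- rep(10, 75)
  expect_equal(percent_fr_change(a, a), 0)
  expect_equal(percent_fr_change(a, 2 * a), 100)
  expect_equal(percent_fr_change(2 * a, a), 100)          # order-invariant
  expect_equal(percent_fr_change(rep(10, 5), rep(8, 5)), 25)
  expect_equal(percent_fr_change(rep(8, 5), rep(10, 5), signed = TRUE), -25)
  expect_error(percent_fr_change(a, rep(0, 75)), "zero")
  expect_error(percent_fr_change(a, a[-1]), "equal length")
})

test_that("normalized ISI pooling has unit mean and the expected dispersion", {
  # regular trains: point mass at 1
  reg <- list(rep(100, 20), rep(40, 12))
  ni <- normalized_isi(reg)
  expect_true(all(abs(ni - 1) < 1e-12))

  # unit mean holds for arbitrary per-stimulus interval sets of equal count
  set.seed(5)
  eq <- lapply(1:10, function(i) rexp(30, rate = runif(1, 0.01, 1)))
  expect_equal(mean(normalized_isi(eq)), 1, tolerance = 1e-12)

  # Poisson trains: normalized-ISI coefficient of variation near 1
  pois <- lapply(1:200, function(i) rexp(50, rate = 0.05))
  np <- normalized_isi(pois)
  expect_equal(stats::sd(np) / mean(np), 1, tolerance = 0.05)
  expect_error(normalized_isi(list()), "no interspike")
})
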