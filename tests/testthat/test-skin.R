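test_that("ramp-and-hold trajectory follows the constant-acceleration closed form", {
  stim <- make_ramp_hold(0.36, 1143, hold = 5)
  expect_equal(stim$ramp_ms, sqrt(2 * 0.36 / 1143) * 1000, tolerance = 1e-12)
  expect_equal(stim$ramp_ms, 25.1, tolerance = 1e-2)
  # d(t) = a t^2 / 2 during the ramp
  k <- 10
  t_s <- stim$time_ms[k] / 1000
  expect_equal(stim$displacement_mm[k], 0.5 * 1143 * t_s^2)
  expect_equal(stim$displacement_mm[length(stim$displacement_mm)], 0.36)

  slow <- make_ramp_hold(0.2, 20)
  expect_equal(slow$ramp_ms, sqrt(2 * 0.2 / 20) * 1000, tolerance = 1e-12)
  expect_equal(slow$ramp_ms, 141.4, tolerance = 1e-2)

  zero <- make_ramp_hold(0, 1143)
  expect_true(all(zero$displacement_mm == 0))
  expect_equal(zero$ramp_ms, 0)
})

test_that("invalid stimuli are rejected", {
  expect_error(make_ramp_hold(-0.1, 100), "depth")
  expect_error(make_ramp_hold(0.1, 0), "acceleration")
  expect_error(make_ramp_hold(0.1, 100, hold = 0), "hold")
  expect_error(make_ramp_hold(0.7, 100), "depth")
})

test_that("instantaneous SED matches Mooney-Rivlin limits", {
  sp <- skin_parameters()
  expect_equal(instantaneous_sed(0, sp), 0)
  # small-strain effective modulus of the tissue column: W ~ E_eff e^2 / 2
  # with E_eff = 6 (C10 + C01); recover via finite differences using a
  # near-rigid substrate so the tissue takes the whole depth
  rigid <- skin_parameters(substrate_modulus = 1e15)
  h_t <- rigid$tissue_thickness / 1000
  d <- 1e-5
  e <- d / h_t
  E_eff <- 2 * instantaneous_sed(d, rigid) / e^2
  expect_equal(E_eff, 6 * (14847 + 41410), tolerance = 1e-3)
  # rigid substrate: doubling depth ~ quadruples small-strain SED
  expect_equal(instantaneous_sed(2 * d, rigid) / instantaneous_sed(d, rigid),
               4, tolerance = 1e-3)
  # strictly increasing in depth
  W <- instantaneous_sed(seq(0.02, 0.36, by = 0.02), sp)
  expect_true(all(diff(W) > 0))
})

test_that("QLV reduces to identity in the elastic limit and relaxes a step to g_inf", {
  elastic <- skin_parameters(prony_g1 = 0, prony_g2 = 0)
  W <- c(0, cumsum(runif(99)))
  expect_equal(qlv_convolve(W, elastic), W, tolerance = 1e-12)

  sp <- skin_parameters()
  n <- 60001                      # 60 s at 1000 Hz >> tau2 = 9.371 s
  Wstep <- c(0, rep(1000, n - 1))
  eps <- qlv_convolve(Wstep, sp)
  expect_equal(eps[2] / 1000, 1, tolerance = 2e-3)          # instant response
  expect_equal(eps[n] / 1000, 1 - 0.391 - 0.226, tolerance = 1e-3)
  expect_equal(eps[n] / 1000, 0.383, tolerance = 1e-3)
})

test_that("recursive Prony update matches the direct hereditary-integral oracle", {
  sp <- skin_parameters()
  # smooth loading history (continuous derivative) so the trapezoidal
  # quadrature of the oracle is accurate
  t <- seq(0, 3, by = 1e-3)
  W <- 1e4 * ifelse(t < 1, (1 - cos(pi * t)) / 2, 1)
  fast <- qlv_convolve(W, sp, fs = 1000)
  slow <- qlv_trapezoid_oracle(W, sp, fs = 1000)
  expect_lt(max(abs(fast - slow)) / max(slow), 1e-3)
  # ramp-and-hold input (derivative jump at the hold): agreement within the
  # O(dt) smear of the quadrature at the kink
  stim <- make_ramp_hold(0.2, 81, hold = 3)
  Wr <- instantaneous_sed(stim$displacement_mm, sp)
  fr <- qlv_convolve(Wr, sp, fs = 1000)
  sr <- qlv_trapezoid_oracle(Wr, sp, fs = 1000)
  expect_lt(max(abs(fr - sr)) / max(sr), 0.05)
})

test_that("QLV agrees across grid resolutions on a smooth ramp", {
  sp <- skin_parameters()
  t1 <- seq(0, 1, by = 1e-3)
  t4 <- seq(0, 1, by = 2.5e-4)
  W1 <- 1e4 * t1^2
  W4 <- 1e4 * t4^2
  e1 <- qlv_convolve(W1, sp, fs = 1000)
  e4 <- qlv_convolve(W4, sp, fs = 4000)
  expect_lt(abs(e1[length(e1)] - e4[length(e4)]) / e4[length(e4)], 1e-3)
})

test_that("SED traces relax during the hold and grow with depth", {
  sp <- skin_parameters()
  traces <- lapply(c(0.12, 0.2, 0.36),
                   function(d) sed_trace(make_ramp_hold(d, 81, hold = 5), sp))
  peaks <- vapply(traces, function(tr) max(tr$sed_pa), numeric(1))
  finals <- vapply(traces, function(tr) tr$sed_pa[length(tr$sed_pa)],
                   numeric(1))
  expect_true(all(diff(peaks) > 0))
  expect_true(all(diff(finals) > 0))
  # relaxation: non-increasing during the hold, bounded below by
  # g_inf * W(depth)
  tr <- traces[[3]]
  stim <- tr$stimulus
  hold_idx <- which(tr$time_ms > stim$ramp_ms + 1)
  expect_true(all(diff(tr$sed_pa[hold_idx]) <= 1e-9))
  W_depth <- instantaneous_sed(0.36, sp)
  expect_true(all(tr$sed_pa[hold_idx] >= sp$g_inf * W_depth - 1e-6))
  expect_true(all(tr$sed_pa >= 0))
})

test_that("SED trace CSV round-trips and rejects malformed files", {
  tr <- sed_trace(make_ramp_hold(0.12, 1143, hold = 1))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sed_trace(tr, path)
  back <- read_sed_trace(path)
  expect_equal(back$time_ms, tr$time_ms)
  expect_equal(back$sed_pa, tr$sed_pa)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time_ms,sed_pa", "0,1", "1,-5"), bad)
  expect_error(read_sed_trace(bad), "negative SED at row 2")
  writeLines(c("time_ms,sed_pa", "0,1", "1,2", "5,3"), bad)
  expect_error(read_sed_trace(bad), "non-uniform")
  writeLines("time_ms,sed_pa", bad)
  expect_error(read_sed_trace(bad), "empty")
  writeLines(c("t,x", "0,1"), bad)
  expect_error(read_sed_trace(bad), "columns")
})
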