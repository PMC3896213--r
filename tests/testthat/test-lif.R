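test_that("constant subthreshold drive never fires; suprathreshold matches the closed form", {
  lp <- lif_parameters()
  # R I < threshold: no spikes
  sub <- integrate_afferent(matrix(5.9e-8, 3000, 1), lp)
  expect_equal(nrow(sub), 0L)

  # at the default 1-ms step, spike times are grid-quantized: the ISI can
  # be off by at most one step
  for (I in c(6.2e-8, 6.5e-8, 7.0e-8)) {
    train <- integrate_afferent(matrix(I, 5000, 1), lp)
    isi <- diff(train$time_ms)
    expect_true(all(abs(isi - lif_isi_exact(I, lp)) <= 1))
  }
  # with 0.1-ms substeps the relative ISI error drops below 2%
  fine01 <- lif_parameters(step = 0.1)
  for (I in c(6.2e-8, 6.5e-8, 7.0e-8)) {
    train <- integrate_afferent(matrix(I, 5000, 1), fine01)
    exact <- lif_isi_exact(I, fine01)
    expect_lt(abs(mean(diff(train$time_ms)) - exact) / exact, 0.02)
  }

  # 3x rheobase (RI = 90 mV): fine substeps recover the short ISI
  fine <- lif_parameters(step = 0.05)
  train <- integrate_afferent(matrix(1.8e-7, 2000, 1), fine)
  isi <- diff(train$time_ms)
  expect_lt(abs(mean(isi) - lif_isi_exact(1.8e-7, fine)) /
              lif_isi_exact(1.8e-7, fine), 0.02)
})

test_that("antidromic resetting makes the strongest zone the driver", {
  lp <- lif_parameters()
  t_max <- 4000
  drives <- list(c(7e-8, 6.4e-8), c(6.6e-8, 6.5e-8, 6.2e-8))
  for (I in drives) {
    cur <- matrix(rep(I, each = t_max), t_max, length(I))
    merged <- integrate_afferent(cur, lp)
    solo <- integrate_afferent(matrix(max(I), t_max, 1), lp)
    # merged rate equals the strongest zone's solo rate
    expect_equal(nrow(merged), nrow(solo), tolerance = 0.02)
    # and matches the continuous-time event oracle within grid quantization
    oracle <- lif_event_oracle(I, lp, t_max)
    expect_lt(abs(nrow(merged) - length(oracle$time_ms)) /
                length(oracle$time_ms), 0.03)
    expect_true(all(merged$zone == which.max(I)))
  }
})

test_that("adding a weaker zone never raises the merged steady rate", {
  lp <- lif_parameters()
  strong <- matrix(6.8e-8, 4000, 1)
  alone <- nrow(integrate_afferent(strong, lp))
  for (weak in c(6.0e-8, 6.3e-8, 6.6e-8)) {
    both <- nrow(integrate_afferent(cbind(strong, rep(weak, 4000)), lp))
    expect_lte(both, alone + 1)   # one count of grid slack
  }
})

test_that("refractory spacing holds even under intense noisy drive", {
  lp <- lif_parameters()
  set.seed(99)
  cur <- matrix(6e-8 + noise_series(8000, noise_config(sigma = 2e-8)),
                4000, 2)
  train <- integrate_afferent(cur, lp)
  expect_gt(nrow(train), 10)
  expect_true(all(diff(train$time_ms) >= lp$refractory - 1e-9))
})

test_that("offset-current subthreshold gate reproduces the printed arithmetic", {
  chk <- baseline_subthreshold_check(lif_parameters(),
                                     transduction_parameters(beta = 5.643e-8))
  expect_true(chk$pass)
  expect_equal(chk$drive_mV, 28.215, tolerance = 1e-6)

  chk0 <- baseline_subthreshold_check(lif_parameters(),
                                      transduction_parameters(beta = 0))
  expect_equal(chk0$margin_mV, 30)

  chk_hot <- baseline_subthreshold_check(lif_parameters(),
                                         transduction_parameters(beta = 1e-7))
  expect_false(chk_hot$pass)
  expect_equal(chk_hot$drive_mV, 50)
})

test_that("spike trains validate ordering and round-trip through CSV", {
  expect_error(spike_train(c(3, 2, 5)), "increasing")
  expect_error(spike_train(c(1, 1.5), refractory = 1), "refractory")
  tr <- spike_train(c(10, 12, 20), c(1L, 2L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_spike_train(tr, path)
  back <- read_spike_train(path)
  expect_equal(back$time_ms, tr$time_ms)
  expect_equal(back$zone, tr$zone)
})
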