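test_that("band splitting passes in-band and rejects out-of-band content", {
  fs <- 25000
  t <- seq(0, 2, by = 1 / fs)
  s1k <- sin(2 * pi * 1000 * t)
  out <- preprocess_traces(s1k, fs)
  expect_equal(out$lfp$fs, fs / 8)
  expect_equal(sd(out$mua) / sd(s1k), 1, tolerance = 0.01)
  expect_equal(sd(out$lfp$samples) / sd(s1k), 1, tolerance = 0.01)
  # 5 kHz attenuated by > 20 dB in the LFP output
  s5k <- sin(2 * pi * 5000 * t)
  out5 <- preprocess_traces(s5k, fs)
  expect_lt(20 * log10(sd(out5$lfp$samples) / sd(s5k)), -20)
  # DC removed from MUA by the 0.3 kHz high-pass edge
  dc <- rep(1, length(t))
  expect_lt(max(abs(preprocess_traces(dc, fs)$mua[5000:45000])), 1e-6)
  expect_error(preprocess_traces(s1k, 4000), class = "raphemap_config_error")
  expect_length(out$lfp$provenance, 3)
})

test_that("wavelet ridges sit at the input frequencies with input amplitudes", {
  fs <- 250
  t <- seq(0, 20, by = 1 / fs)
  ws <- wavelet_amplitude(sin(2 * pi * 2 * t), fs = fs)
  mid <- seq(500, 4500)
  ridge <- ws$frequencies[apply(ws$amplitude[, mid], 2, which.max)]
  nearest <- ws$frequencies[which.min(abs(ws$frequencies - 2))]
  expect_true(all(ridge == nearest))
  # two components: amplitude ratio preserved within 5%
  x2 <- sin(2 * pi * 2 * t) + 0.5 * sin(2 * pi * 40 * t)
  ws2 <- wavelet_amplitude(x2, fs = fs, frequencies = c(2, 40))
  amps <- rowMeans(ws2$amplitude[, 2000:3000])
  expect_equal(amps[1] / amps[2], 2, tolerance = 0.05)
  # zero trace -> zero spectrum
  ws0 <- wavelet_amplitude(numeric(5000), fs = fs)
  expect_equal(max(ws0$amplitude), 0)
  expect_error(wavelet_amplitude(x2, fs = fs, frequencies = c(0.1, 200)),
               class = "raphemap_config_error")
})

test_that("white-noise wavelet power is flat after kernel-energy correction", {
  set.seed(1)
  wn <- rnorm(1000 * 400)
  ws <- wavelet_amplitude(wn, fs = 1000,
                          frequencies = exp(seq(log(4), log(100),
                                                length.out = 8)))
  pw <- rowMeans(ws$amplitude^2) / ws$kernel_energy
  expect_lt(max(abs(pw / mean(pw) - 1)), 0.10)
})

test_that("trial-averaged z spectrum obeys the normalisation contract", {
  p <- short_protocol()
  set.seed(2)
  ws <- wavelet_amplitude(rnorm(250 * 720), fs = 250,
                          frequencies = exp(seq(log(1), log(50),
                                                length.out = 10)))
  z <- trial_average_z(ws, p, baseline_s = 10)
  expect_equal(z$units, "z")
  base_cols <- z$times < 0
  expect_lt(max(abs(rowMeans(z$amplitude[, base_cols]))), 1e-9)
  expect_lt(max(abs(z$amplitude), na.rm = TRUE), 6)  # stationary input
  expect_error(trial_average_z(ws, p, baseline_s = 45),
               class = "raphemap_config_error")
})

test_that("z transform is invariant to adding a constant offset", {
  p <- short_protocol()
  set.seed(3)
  x <- rnorm(250 * 720)
  fr <- exp(seq(log(1), log(20), length.out = 6))
  z1 <- trial_average_z(wavelet_amplitude(x, fs = 250, frequencies = fr), p)
  z2 <- trial_average_z(wavelet_amplitude(x + 100, fs = 250, frequencies = fr), p)
  expect_equal(z1$amplitude, z2$amplitude, tolerance = 1e-6)
})

test_that("delta suppression maps to the analytic fractional power change", {
  p <- short_protocol()
  tr <- synth_truth("control")       # amplitude suppression to 50%
  pr <- simulate_probe(p, tr, seed = 5, fs_raw = 2000, n_channels = 1)
  ws <- wavelet_amplitude(as_lfp(pr$traces[1, ], 2000))
  fc <- fractional_band_change(ws, p, band = c(1, 4))
  expect_equal(fc$fractional_change, 0.5^2 - 1, tolerance = 0.05)
  # suppressed delta shows strongly negative z during stimulation
  z <- trial_average_z(ws, p, baseline_s = 10)
  rows <- ws$frequencies >= 1 & ws$frequencies <= 4
  stim_cols <- z$times >= tr$lfp_lag_s + 2 & z$times < 20
  expect_lt(mean(z$amplitude[rows, stim_cols]), -1)
  # amplitude measure: (0.5 - 1) = -0.5
  fca <- fractional_band_change(ws, p, c(1, 4), measure = "amplitude")
  expect_equal(fca$fractional_change, -0.5, tolerance = 0.05)
})

test_that("fractional change is ~0 without modulation and out of band", {
  p <- short_protocol()
  tr1 <- synth_truth("control", delta_suppression = 1, burst_suppression = 1)
  pr1 <- simulate_probe(p, tr1, seed = 2, fs_raw = 2000, n_channels = 1)
  ws <- wavelet_amplitude(as_lfp(pr1$traces[1, ], 2000))
  fc <- fractional_band_change(ws, p, c(1, 4))
  expect_lt(abs(fc$fractional_change), 0.05)
  # band far from any oscillatory content: white noise only, still ~0
  # (spike-free trace; rare large spike transients would dominate the
  # band's variance and widen the sampling error, not bias it)
  tr0 <- synth_truth("control", delta_suppression = 1, burst_suppression = 1,
                     n_units = 0, burst_rate_hz = 1e-3)
  pr0 <- simulate_probe(p, tr0, seed = 2, fs_raw = 2000, n_channels = 1)
  ws0 <- wavelet_amplitude(as_lfp(pr0$traces[1, ], 2000))
  fc2 <- fractional_band_change(ws0, p, c(10, 20))
  expect_lt(abs(fc2$fractional_change), 0.05)
  expect_error(fractional_band_change(ws, p, c(400, 500)),
               class = "raphemap_config_error")
})

test_that("fractional change is invariant to global amplitude rescaling", {
  p <- short_protocol()
  tr <- synth_truth("control")
  pr <- simulate_probe(p, tr, seed = 6, fs_raw = 2000, n_channels = 1)
  f1 <- fractional_band_change(
    wavelet_amplitude(as_lfp(pr$traces[1, ], 2000)), p, c(1, 4))
  f3 <- fractional_band_change(
    wavelet_amplitude(as_lfp(3 * pr$traces[1, ], 2000)), p, c(1, 4))
  expect_equal(f1$fractional_change, f3$fractional_change, tolerance = 1e-9)
})

test_that("burst statistics recover the generator's rate suppression", {
  p <- short_protocol()
  tr <- synth_truth("control")
  # detected rates match the realised ground-truth rates once the
  # burst-run merging dead time (~burst width + merge gap) is accounted for
  pr <- simulate_probe(p, tr, seed = 5, fs_raw = 2000, n_channels = 1)
  bs <- burst_statistics(ground_truth_spikes(pr), p)
  cents <- seq(0.05, 719.95, by = 0.1)
  msk <- raphemap:::epoch_masks(cents, p, 5)
  idx <- round((pr$burst_times - 0.05) / 0.1) + 1
  true_stim <- sum(msk$stim[idx]) / (sum(msk$stim) * 0.1)
  true_base <- sum(msk$base[idx]) / (sum(msk$base) * 0.1)
  dead <- 0.3   # 0.1 s burst + <0.2 s merge gap
  expect_equal(bs$base_rate_hz, true_base / (1 + true_base * dead),
               tolerance = 0.2)
  expect_equal(bs$stim_rate_hz, true_stim / (1 + true_stim * dead),
               tolerance = 0.35)   # ~18 stim-epoch bursts: wide Poisson band
  # averaged over seeds the fractional change settles near -0.5
  fr <- vapply(1:5, function(s) {
    prs <- simulate_probe(p, tr, seed = s, fs_raw = 2000, n_channels = 1)
    burst_statistics(ground_truth_spikes(prs), p)$fractional_change
  }, numeric(1))
  expect_lt(abs(mean(fr) - (-0.5)), 0.15)
})

test_that("constant burst rate gives ~0 change; degenerate inputs error", {
  p <- short_protocol()
  tr <- synth_truth("control", burst_suppression = 1, burst_rate_hz = 1.5)
  pr <- simulate_probe(p, tr, seed = 9, fs_raw = 2000, n_channels = 1)
  bs <- burst_statistics(ground_truth_spikes(pr), p)
  expect_lt(abs(bs$fractional_change), 0.25)
  p0 <- p; p0$block_onsets <- numeric(0)
  expect_error(burst_statistics(c(1, 2, 3), p0),
               class = "raphemap_config_error")
})
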