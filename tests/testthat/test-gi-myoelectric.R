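test_that("planar averaging is a pointwise mean", {
  m <- matrix(rnorm(400), 100, 4)
  same <- matrix(m[, 1], 100, 4)
  expect_equal(planar_average(same), m[, 1])
  cancel <- cbind(m[, 1], -m[, 1], m[, 1], -m[, 1])
  expect_equal(planar_average(cancel), rep(0, 100))
  expect_equal(planar_average(m), rowMeans(m))
  expect_error(planar_average(m[, 1:3]), "4")
})

test_that("cascaded-biquad Butterworth matches the reference design", {
  skip_if_not_installed("signal")
  # benign cutoff where the polynomial form is stable: compare both routes
  fs <- 100; fc <- 5
  set.seed(2); x <- rnorm(2000)
  mine <- vagsel:::.sosfilt(butter_sos(4, fc, fs), x)
  bw <- signal::butter(4, fc / (fs / 2))
  ref <- as.numeric(signal::filter(bw, x))
  expect_equal(mine, ref, tolerance = 1e-8)
})

test_that("the filter chain has the predicted Butterworth magnitudes", {
  fs <- 250
  t <- seq(0, 420 - 1 / fs, by = 1 / fs)
  # 9.6 cpm: zero-phase chain attenuates by |H1|^2 |H2|^2
  f0 <- 9.6 / 60
  x <- sin(2 * pi * f0 * t)
  y <- gi_preprocess(x, fs)
  h1 <- 1 / (1 + (f0 / 2.5)^8)                 # |H|^2 of 4th-order at 2.5 Hz
  h2 <- 1 / (1 + (f0 / 0.3)^4)                 # |H|^2 of 2nd-order at 0.3 Hz
  gain <- max(abs(y[100:(length(y) - 100)]))
  expect_equal(gain, h1 * h2, tolerance = 0.01)
  # 2 Hz interference: attenuated by more than 40 dB
  x2 <- sin(2 * pi * 2 * t)
  y2 <- gi_preprocess(x2, fs)
  expect_lt(max(abs(y2[100:(length(y2) - 100)])), 10^(-40 / 20))
  # DC gain is exactly 1
  yc <- gi_preprocess(rep(3, length(t)), fs)
  expect_equal(yc, rep(3, length(yc)), tolerance = 1e-6)
  # linearity
  xa <- x + 0.3 * x2
  expect_equal(gi_preprocess(2 * xa, fs), 2 * gi_preprocess(xa, fs),
               tolerance = 1e-10)
  expect_error(gi_preprocess(x, 251), "integer multiple")
})

test_that("segmentation yields the 6 s hop layout and a 0.1 cpm grid", {
  x <- sin(2 * pi * 9.6 / 60 * seq(0, 120 - 0.1, by = 0.1))
  sg <- segment_spectra(x, fs_hz = 10)
  expect_equal(ncol(sg$power), 11)             # floor((120-60)/6)+1
  expect_equal(sg$starts_s, seq(0, 60, by = 6))
  expect_equal(diff(sg$freq_cpm)[1], 0.1)
  peaks <- apply(sg$power, 2, function(p) sg$freq_cpm[which.max(p)])
  expect_true(all(abs(peaks - 9.6) <= 0.05))
  z <- segment_spectra(rep(0, 1200), fs_hz = 10)
  expect_true(all(z$power == 0))
  expect_error(segment_spectra(rep(0, 100), fs_hz = 10), "shorter")
})

test_that("dominant frequency is recovered and calibrated against white noise", {
  t <- seq(0, 300 - 0.1, by = 0.1)
  set.seed(9)
  x <- sin(2 * pi * 9.6 / 60 * t) + rnorm(length(t), sd = 0.3)
  dom <- dominant_frequency(segment_spectra(x, 10))
  expect_equal(dom$dominant_cpm, 9.6, tolerance = 0.1)
  expect_true(dom$significant)
  # pure white noise: flagged significant in at most a seed or two
  nsig <- 0
  for (s in 1:10) {
    set.seed(s)
    w <- rnorm(3000)
    nsig <- nsig + dominant_frequency(segment_spectra(w, 10))$significant
  }
  expect_lte(nsig, 1)
  # exact ties resolve to the lower-frequency bin
  sg <- segment_spectra(rep(0, 1200), 10)
  sg$power[c(71, 121), ] <- 5                  # 7.0 and 12.0 cpm, equal power
  expect_equal(dominant_frequency(sg)$dominant_cpm, 7.0)
})

test_that("normogastric fraction has the band-ratio limits", {
  t <- seq(0, 300 - 0.1, by = 0.1)
  sg <- segment_spectra(sin(2 * pi * 9.6 / 60 * t), 10)
  f <- normogastric_fraction(rowMeans(sg$power), sg$freq_cpm)
  expect_gte(f, 0.9)   # rectangular-window leakage of a 9.6-cycle segment
  sg5 <- segment_spectra(sin(2 * pi * 5 / 60 * t), 10)
  expect_lte(normogastric_fraction(rowMeans(sg5$power), sg5$freq_cpm), 0.05)
  # uniform power: fraction equals the (discrete, inclusive) bandwidth ratio
  freq <- sg$freq_cpm
  expect_equal(normogastric_fraction(rep(1, length(freq)), freq), 31 / 146)
  expect_equal(31 / 146, 3 / 14.5, tolerance = 0.03)
  expect_error(normogastric_fraction(rep(0, length(freq)), freq), "zero total")
})

test_that("epoch comparison exposes slow-wave suppression", {
  r0 <- analyze_gi_recording(simulate_gi_session(
    gi_sim_config(suppression_factor = 0, n_electrodes = 1), seed = 14))[[1]]
  expect_lt(r0$comparison$stimulation_fraction,
            0.1 * r0$comparison$baseline_fraction)
  r1 <- analyze_gi_recording(simulate_gi_session(
    gi_sim_config(suppression_factor = 1, n_electrodes = 1), seed = 14))[[1]]
  expect_gt(r1$comparison$ratio, 0.8)
  expect_lt(r1$comparison$ratio, 1.25)
  expect_equal(r1$baseline$dominant_cpm, 9.6, tolerance = 0.1)
  expect_true(r1$baseline$significant)
})

test_that("a delayed suppression onset shows up in the waterfall series", {
  rec <- simulate_gi_session(
    gi_sim_config(suppression_factor = 0, suppression_onset_s = 25,
                  n_electrodes = 1), seed = 15)
  res <- analyze_gi_recording(rec)[[1]]
  s <- res$comparison$stimulation_series
  # early stimulation segments still overlap unsuppressed signal; segments
  # fully past the onset have collapsed band power
  late <- s$band_power[s$start_s >= 30]
  early <- s$band_power[s$start_s == 0]
  expect_lt(max(late), 0.5 * early)
})
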