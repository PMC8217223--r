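test_that("artifact blanking interpolates supra-threshold runs", {
  # isolated spike on a flat signal is replaced by the flat level
  x <- rep(0, 50); x[20:24] <- 10000
  expect_equal(blank_artifacts(x), rep(0, 50))
  # sub-threshold signals pass through untouched
  y <- sin(seq(0, 10, length.out = 100)) * 7000
  expect_identical(blank_artifacts(y), y)
  # hand-computed chord between the boundary samples
  z <- c(1000, 12000, 9000, 2000)
  expect_equal(blank_artifacts(z),
               c(1000, 1000 + 1000 / 3, 1000 + 2000 / 3, 2000))
  # runs touching an edge extend the nearest clean value
  e <- c(9000, 9000, 500, 300)
  expect_equal(blank_artifacts(e), c(500, 500, 500, 300))
  # idempotence on a noisy signal with artifacts
  set.seed(1)
  w <- rnorm(500, sd = 100); w[c(40:45, 300)] <- 12000
  expect_identical(blank_artifacts(blank_artifacts(w)), blank_artifacts(w))
})

test_that("sliding RMS has the closed-form responses", {
  expect_equal(sliding_rms(rep(-3, 100)), rep(3, 24))    # constant -> |c|
  imp <- rep(0, 100); imp[50] <- 1
  r <- sliding_rms(imp)
  hit <- which(r > 0)
  expect_equal(r[hit], rep(sqrt(1 / 30), 10))            # 10 windows hold it
  expect_equal(hit, 8:17)
  t <- seq(0, 0.02, by = 1 / 30000)
  s <- 5 * sin(2 * pi * 5000 * t)                        # window >> period
  expect_equal(median(sliding_rms(s)), 5 / sqrt(2), tolerance = 0.02)
  expect_equal(sliding_rms(-s), sliding_rms(s))          # sign-flip invariant
  expect_error(sliding_rms(rep(0, 10)), "shorter")
})

test_that("stimulus-triggered average recovers repeated deflections and obeys the CLT", {
  pop <- manual_population(1.5, 7)
  train <- stim_train(stim_pulse(500, 0.5), 5, cuff_pair = "1:2")
  rec <- simulate_sta_experiment(pop, train, no_noise(), seed = 2)
  sta <- stimulus_triggered_average(rec)
  # zero noise: the average equals any single-trial window
  w1 <- rec$samples[(rec$stim_events[1] + sta$params$offset):
                      (rec$stim_events[1] + sta$params$end_off), ]
  expect_equal(sta$avg, unname(w1))
  expect_gt(max(abs(sta$avg[, 7])), 1)
  # pure noise, 120 events: averaging shrinks the SD by sqrt(120)
  quiet <- make_population(1, 0, seed = 1)
  recn <- simulate_sta_experiment(
    quiet, stim_train(stim_pulse(0, 0.5), 120, cuff_pair = "1:2"),
    noise_model(gaussian_sd_uV = 3), seed = 3)
  stan <- stimulus_triggered_average(recn)
  expect_equal(sd(stan$avg[, 5]), 3 / sqrt(120), tolerance = 0.2)
})

test_that("deflections earlier than the 30 m/s latency are outside the window", {
  g <- mea_geometry()
  x <- matrix(0, 30000 * 3, 32)
  ev <- c(30000, 60000)
  x[ev + 90, 4] <- 50                     # 3 ms post-stimulus; window opens at 5 ms
  rec <- mea_recording(x, 30000, ev, g, 0.15,
                       stim_train(stim_pulse(500, 0.5), 2, cuff_pair = "1:2"))
  sta <- stimulus_triggered_average(rec)
  expect_equal(sum(abs(sta$avg)), 0)
})

test_that("baseline noise estimate matches the ensemble-average statistics", {
  quiet <- make_population(1, 0, seed = 1)
  rec <- simulate_sta_experiment(
    quiet, stim_train(stim_pulse(0, 0.5), 120, cuff_pair = "1:2"),
    noise_model(gaussian_sd_uV = 2), seed = 4)
  base <- estimate_baseline_noise(rec)
  expect_equal(median(base$sd), 2 / sqrt(120), tolerance = 0.2)
  expect_lt(max(abs(base$mean)), 3 * 2 / sqrt(120))
  base2 <- estimate_baseline_noise(rec)
  expect_identical(base, base2)                      # seeded draws
  # all-zero signal -> (0, 0)
  rec0 <- simulate_sta_experiment(
    quiet, stim_train(stim_pulse(0, 0.5), 3, cuff_pair = "1:2"),
    no_noise(), seed = 1)
  base0 <- estimate_baseline_noise(rec0)
  expect_equal(base0$mean, rep(0, 32))
  expect_equal(base0$sd, rep(0, 32))
})

test_that("an embedded CAP is detected in the right CV bin and class", {
  pop <- manual_population(1.5, 9, cap_amplitude_uV = 8)
  train <- stim_train(stim_pulse(500, 0.5), 60, cuff_pair = "1:2")
  rec <- simulate_sta_experiment(pop, train, noise_model(gaussian_sd_uV = 3),
                                 seed = 6)
  resp <- detect_recording(rec)
  expect_equal(responding_channels(resp), 9)
  ev <- resp$events[resp$events$channel == 9, ]
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cv_mps, 1.5, tolerance = 0.02)
  expect_equal(ev$cv_bin, 3L)                        # bin [1.5, 2.0)
  expect_equal(ev$fiber_class, "C")
  expect_equal(ev$latency_ms, 100, tolerance = 1)
})

test_that("two crossings inside one CV bin yield a single event", {
  pop <- manual_population(c(1.9, 1.6), c(9, 9))     # same channel, same bin
  rec <- simulate_sta_experiment(
    pop, stim_train(stim_pulse(500, 0.5), 3, cuff_pair = "1:2"),
    no_noise(), seed = 1)
  resp <- detect_recording(rec, detector_config(n_baseline_windows = 120))
  ev <- resp$events
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cv_bin, 3L)
  expect_equal(ev$cv_mps, 1.9, tolerance = 0.02)     # first crossing wins
})

test_that("pure-noise channels rarely cross the calibrated threshold", {
  quiet <- make_population(1, 0, seed = 1)
  hits <- trials <- 0
  for (s in 1:5) {
    rec <- simulate_sta_experiment(
      quiet, stim_train(stim_pulse(0, 0.5), 20, cuff_pair = "1:2"),
      noise_model(gaussian_sd_uV = 5), seed = s)
    det <- detect_recording(rec)
    hits <- hits + length(responding_channels(det))
    trials <- trials + 32
  }
  expect_lt(hits / trials, 0.10)
})

test_that("fiber classification uses the 3 m/s boundary", {
  expect_equal(classify_fiber(1.2), "C")
  expect_equal(classify_fiber(10), "Adelta")
  expect_equal(classify_fiber(3.0), "Adelta")        # boundary -> A-delta
  expect_equal(classify_fiber(30), "Adelta")
  expect_error(classify_fiber(0), "outside")
  expect_error(classify_fiber(31), "outside")
})

test_that("detection is monotone in CAP amplitude for a fixed noise draw", {
  base_pop <- manual_population(1.2, 11, cap_amplitude_uV = 1)
  detected <- vapply(c(0.5, 1, 2, 4, 8, 16), function(scale) {
    pop <- base_pop
    pop$fibers$cap_amplitude_uV <- scale
    rec <- simulate_sta_experiment(
      pop, stim_train(stim_pulse(500, 0.5), 30, cuff_pair = "1:2"),
      noise_model(gaussian_sd_uV = 4), seed = 12)
    11 %in% responding_channels(detect_recording(rec))
  }, TRUE)
  expect_true(all(diff(detected) >= 0))              # once in, stays in
  expect_false(detected[1])
  expect_true(detected[6])
})

test_that("gain calibration picks the smallest acceptable gain with a full ROC", {
  # cleanly separable synthetic trials: positives cross at any grid gain
  neg <- lapply(1:8, function(s) {
    set.seed(s); list(rms = abs(rnorm(100, 1, 0.05)), mean = 1, sd = 0.5,
                      truth = FALSE)
  })
  pos <- lapply(1:8, function(s) {
    set.seed(100 + s); list(rms = c(abs(rnorm(99, 1, 0.05)), 10), mean = 1,
                            sd = 0.5, truth = TRUE)
  })
  cal <- calibrate_gain(c(pos, neg))
  expect_equal(cal$gain, 2.4)
  expect_true(all(c("gain", "tpr", "fpr") %in% names(cal$roc)))
  expect_equal(cal$roc$fpr, rep(0, 3))
  expect_equal(cal$roc$tpr, rep(1, 3))
  expect_error(calibrate_gain(pos), "no negatives")
  # inseparable negatives: no gain passes, error carries the ROC table
  bad <- lapply(1:6, function(s) list(rms = rep(100, 10), mean = 1, sd = 0.5,
                                      truth = FALSE))
  err <- tryCatch(calibrate_gain(c(pos, bad)), error = identity)
  expect_s3_class(err, "vagsel_roc_error")
  expect_true(is.data.frame(err$roc))
})
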