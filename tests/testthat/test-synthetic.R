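test_that("Weiss strength-duration law has the closed form and monotonicity", {
  pop <- manual_population(1.5, 5, rheobase_uA = 200, chronaxie_ms = 0.5)
  expect_equal(recruitment_threshold(pop, "1:2", 0.5), 400)   # rb(1 + 0.5/0.5)
  expect_equal(recruitment_threshold(pop, "1:2", 1.0), 300)
  rpop <- make_population(10, 5, seed = 4)
  for (pair in cuff_pairs()) {
    t01 <- recruitment_threshold(rpop, pair, 0.1)
    t05 <- recruitment_threshold(rpop, pair, 0.5)
    t10 <- recruitment_threshold(rpop, pair, 1.0)
    expect_true(all(t01 > t05 & t05 > t10))
    # approaches rheobase for long pulses
    rb <- if (pair == "1:2") rpop$fibers$rheobase_12 else rpop$fibers$rheobase_34
    expect_equal(recruitment_threshold(rpop, pair, 1e6), rb, tolerance = 1e-4)
  }
})

test_that("population generation respects counts, classes, and determinism", {
  pop <- make_population(18, 2, seed = 7)
  expect_equal(nrow(pop$fibers), 20)
  expect_equal(sum(pop$fibers$cv_mps < 3), 18)
  expect_true(all(pop$fibers$cv_mps > 0.3 & pop$fibers$cv_mps < 30))
  expect_true(all(pop$fibers$rheobase_12 > 0 & pop$fibers$chronaxie_12 > 0))
  expect_identical(make_population(18, 2, seed = 7)$fibers, pop$fibers)
  expect_false(identical(make_population(18, 2, seed = 8)$fibers, pop$fibers))
  expect_error(make_population(0, 0, seed = 1), "zero fibers")
})

test_that("full clustering segregates the channels preferred by the pairs", {
  pop <- make_population(24, 6, clustering = 1, seed = 3)
  ch12 <- pop$fibers$channel[pop$fibers$pref_pair == "1:2"]
  ch34 <- pop$fibers$channel[pop$fibers$pref_pair == "3:4"]
  expect_length(intersect(ch12, ch34), 0)
  cols <- pop$geometry$col
  expect_true(all(cols[ch12] <= 4) && all(cols[ch34] >= 5))
})

test_that("ground-truth responses are exact and monotone in amplitude", {
  pop <- make_population(12, 3, seed = 21)
  pw <- 0.5
  thr <- sort(recruitment_threshold(pop, "1:2", pw))
  expect_equal(nrow(ground_truth_responses(pop, stim_pulse(0, pw), "1:2")$events), 0)
  # amplitude between the two cheapest fibers recruits exactly the cheaper one
  mid <- mean(thr[1:2])
  one <- ground_truth_responses(pop, stim_pulse(mid, pw), "1:2")
  cheap <- pop$fibers[which.min(recruitment_threshold(pop, "1:2", pw)), ]
  expect_equal(responding_channels(one), cheap$channel)
  # above all thresholds every fiber inside the observable latency range
  # responds (the last RMS window ends ~1 ms before 498 ms, hence the margin)
  all_resp <- ground_truth_responses(pop, stim_pulse(3000, pw), "1:2")
  surely <- pop$fibers$cv_mps >= 0.15 / 0.4965 &
    recruitment_threshold(pop, "1:2", pw) <= 3000
  expect_true(all(unique(pop$fibers$channel[surely]) %in%
                    responding_channels(all_resp)))
  expect_true(all(responding_channels(all_resp) %in% pop$fibers$channel))
  # responding channels nest over the amplitude grid, both pairs
  for (pair in cuff_pairs()) {
    prev <- integer(0)
    for (amp in seq(0, 3000, by = 250)) {
      cur <- responding_channels(
        ground_truth_responses(pop, stim_pulse(amp, pw), pair))
      expect_true(all(prev %in% cur))
      prev <- cur
    }
  }
})

test_that("simulated trials are seed-reproducible and stimulus-locked", {
  pop <- manual_population(1.5, 7)
  train <- stim_train(stim_pulse(500, 0.5), 3, cuff_pair = "1:2")
  rec1 <- simulate_sta_experiment(pop, train, noise_model(gaussian_sd_uV = 2),
                                  seed = 5)
  rec2 <- simulate_sta_experiment(pop, train, noise_model(gaussian_sd_uV = 2),
                                  seed = 5)
  expect_identical(rec1$samples, rec2$samples)
  # noise-free: deflection exactly at 100 ms (0.15 m / 1.5 m/s) on channel 7
  rec0 <- simulate_sta_experiment(pop, train, no_noise(), seed = 5)
  on <- rec0$stim_events + round(0.100 * 30000)
  expect_true(all(abs(rec0$samples[on, 7]) > 1))
  expect_true(all(rec0$samples[rec0$stim_events + 100, 7] == 0))  # pre-arrival
  expect_equal(sum(abs(rec0$samples[, -7])), 0)
  # amplitude below every threshold leaves pure noise
  quiet <- simulate_sta_experiment(pop, stim_train(stim_pulse(10, 0.5), 3,
                                                   cuff_pair = "1:2"),
                                   no_noise(), seed = 5)
  expect_equal(sum(abs(quiet$samples)), 0)
})

test_that("artifact excursions exceed the blanking threshold when enabled", {
  pop <- manual_population(1.5, 7)
  rec <- simulate_sta_experiment(
    pop, stim_train(stim_pulse(0, 0.5), 3, cuff_pair = "1:2"),
    noise_model(gaussian_sd_uV = 2, artifact_rate_per_s = 2), seed = 8)
  expect_true(max(abs(rec$samples)) > 8000)
})

test_that("GI simulation is reproducible and planar averaging raises SNR", {
  cfg <- gi_sim_config(fs_hz = 50, n_electrodes = 1, white_sd_uV = 12)
  g1 <- simulate_gi_session(cfg, baseline_s = 70, stim_s = 65, seed = 3)
  g2 <- simulate_gi_session(cfg, baseline_s = 70, stim_s = 65, seed = 3)
  expect_identical(g1$contacts, g2$contacts)
  # contacts = common signal + independent white noise: the planar average
  # retains the common part and quarters the noise variance (mean of 4), so
  # the variance drop from a single contact to the average is 3/4 sigma^2
  m <- g1$contacts[[1]]
  sig2_hat <- var(m[, 1] - m[, 2]) / 2
  expect_equal(sig2_hat, 144, tolerance = 0.15)
  drop <- mean(apply(m, 2, var)) - var(rowMeans(m))
  expect_equal(drop, 0.75 * 144, tolerance = 0.15)
})

test_that("unseeded stochastic generation is rejected", {
  expect_error(make_population(3, 1), "seed")
  expect_error(simulate_gi_session(gi_sim_config(fs_hz = 50),
                                   baseline_s = 70, stim_s = 65),
               "seed")
})
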