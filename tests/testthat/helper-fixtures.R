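# Shared fixture builders. All fixtures are generated in code; populations
# used for detector checks draw CAP amplitudes well clear of the noise floor.

# A population whose two cuff pairs recruit cleanly separated fiber sets
# inside a designed amplitude window (tight rheobases, no shared fibers).
designed_population <- function(seed, n_c = 16, n_adelta = 4, clustering = 1) {
  make_population(n_c, n_adelta, clustering = clustering, seed = seed,
                  overlap = 0, rheobase_uA = c(150, 250),
                  nonpref_factor = c(4, 6))
}

# A population with hand-set fibers (bypasses the random draws) for tests
# that need exact conduction velocities / channels.
manual_population <- function(cv_mps, channel, cap_amplitude_uV = 6,
                              rheobase_uA = 200, chronaxie_ms = 0.5,
                              geometry = mea_geometry()) {
  pop <- make_population(length(cv_mps), 0, geometry = geometry, seed = 1)
  pop$fibers <- data.frame(
    id = seq_along(cv_mps),
    fiber_class = ifelse(cv_mps < 3, "C", "Adelta"),
    cv_mps = cv_mps, channel = channel, pref_pair = "1:2",
    rheobase_12 = rheobase_uA, rheobase_34 = rheobase_uA,
    chronaxie_12 = chronaxie_ms, chronaxie_34 = chronaxie_ms,
    cap_amplitude_uV = cap_amplitude_uV, latency_jitter_ms = 0,
    stringsAsFactors = FALSE)
  pop
}

# Response set holding just a channel list (for set-algebra tests).
channel_set <- function(channels, amplitude_uA = 500, pair = "1:2") {
  ev <- if (length(channels))
    data.frame(channel = channels, latency_ms = 100, cv_mps = 1.5,
               cv_bin = 3L, fiber_class = "C")
  else NULL
  response_set(ev, stim_pulse(amplitude_uA, 0.5), pair)
}

no_noise <- function() noise_model(gaussian_sd_uV = 0)
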