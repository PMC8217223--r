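# Synthetic MEA / GI data with known ground truth. The generator emulates the
# statistical structure the analysis assumes: stimulus-locked CAP deflections
# at latencies set by conduction velocity and cuff-to-ganglion distance,
# per-fiber recruitment thresholds obeying a strength-duration law that
# differs between cuff pairs, Gaussian background noise with optional large
# artifact excursions, and gastric slow waves whose amplitude is suppressed
# during stimulation.

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) stop("unseeded stochastic stage: a seed is required")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Background-noise model for synthetic MEA recordings
#'
#' @param gaussian_sd_uV Standard deviation of white background noise (uV).
#' @param line_freq_hz,line_amplitude_uV Optional mains interference.
#' @param artifact_rate_per_s Rate of large transient excursions (EMG-like);
#'   each excursion exceeds the 8 mV blanking threshold.
#' @param artifact_amplitude_mV Peak amplitude of artifact excursions (mV).
#' @param artifact_duration_ms Duration of each excursion.
#' @param dropout_rate_per_s Rate of packet-loss gaps (signal forced to zero).
#' @param dropout_duration_ms Duration of each gap.
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gaussian_sd_uV = 5, line_freq_hz = 60,
                        line_amplitude_uV = 0, artifact_rate_per_s = 0,
                        artifact_amplitude_mV = 10, artifact_duration_ms = 2,
                        dropout_rate_per_s = 0, dropout_duration_ms = 10) {
  stopifnot(gaussian_sd_uV >= 0, artifact_rate_per_s >= 0,
            dropout_rate_per_s >= 0, line_amplitude_uV >= 0)
  structure(as.list(environment()), class = "noise_model")
}

#' Synthetic fiber population with per-pair recruitment thresholds
#'
#' Draws a labelled population of vagal afferents: unmyelinated C fibers with
#' conduction velocities in (0.3, 3) m/s and thinly myelinated A-delta fibers
#' in \[3, 30) m/s (C fibers dominate the abdominal vagus). Each fiber carries
#' a strength-duration threshold (rheobase + chronaxie) for each cuff pair,
#' drawn so that the two pairs preferentially - not exclusively - recruit
#' different fiber subsets, a home MEA channel, and a CAP amplitude below
#' 10 uV peak to peak.
#'
#' `clustering` controls the spatial segregation of the channels favoured by
#' the two cuff pairs: 0 assigns channels uniformly (no somatotopy), 1 places
#' the fibers preferring pair 1:2 in the left half-columns of the grid and
#' pair 3:4 in the right half (fully segregated blocks).
#'
#' @param n_c,n_adelta Number of C and A-delta fibers (total >= 1).
#' @param geometry An [mea_geometry()].
#' @param clustering Spatial clustering in \[0, 1\].
#' @param seed RNG seed (required; generation is deterministic given the seed).
#' @param overlap Fraction of fibers whose two per-pair rheobases are nearly
#'   equal (recruited by both pairs at similar amplitudes).
#' @param rheobase_uA Range the preferred-pair rheobase is drawn from.
#' @param chronaxie_ms Range chronaxies are drawn from.
#' @param nonpref_factor Range of the multiplier applied to the rheobase for
#'   the non-preferred pair (when the fiber is not in the overlap set).
#' @param cap_amplitude_uV Range of single-fiber CAP template amplitudes.
#' @param latency_jitter_ms Per-pulse latency jitter SD (default 0: the
#'   analysis operates on stimulus-triggered averages).
#' @return An object of class `fiber_population`: a list with `fibers` (one
#'   data-frame row per fiber) and the generation parameters.
#' @export
make_population <- function(n_c, n_adelta, geometry = mea_geometry(),
                            clustering = 0.5, seed = NULL, overlap = 0.2,
                            rheobase_uA = c(100, 600),
                            chronaxie_ms = c(0.2, 0.8),
                            nonpref_factor = c(2, 6),
                            cap_amplitude_uV = c(4, 8),
                            latency_jitter_ms = 0) {
  n <- n_c + n_adelta
  if (n < 1) stop("zero fibers: n_c + n_adelta must be >= 1")
  stopifnot(clustering >= 0, clustering <= 1)
  fibers <- .with_seed(seed, {
    cv <- c(runif(n_c, 0.3, 3), runif(n_adelta, 3, 30))
    pref <- sample(cuff_pairs(), n, replace = TRUE)
    # channel blocks: pair 1:2 prefers the left half-columns, 3:4 the right
    left <- which(geometry$col <= geometry$n_cols / 2)
    right <- setdiff(seq_len(geometry$n_channels), left)
    in_block <- runif(n) < clustering
    channel <- integer(n)
    for (i in seq_len(n)) {
      pool <- if (!in_block[i]) seq_len(geometry$n_channels)
              else if (pref[i] == "1:2") left else right
      channel[i] <- pool[sample.int(length(pool), 1L)]
    }
    rheo_pref <- runif(n, rheobase_uA[1], rheobase_uA[2])
    shared <- runif(n) < overlap
    fac <- ifelse(shared, runif(n, 0.9, 1.1),
                  runif(n, nonpref_factor[1], nonpref_factor[2]))
    chron <- runif(n, chronaxie_ms[1], chronaxie_ms[2])
    amp <- runif(n, cap_amplitude_uV[1], cap_amplitude_uV[2])
    data.frame(
      id = seq_len(n),
      fiber_class = rep(c("C", "Adelta"), c(n_c, n_adelta)),
      cv_mps = cv, channel = channel, pref_pair = pref,
      rheobase_12 = ifelse(pref == "1:2", rheo_pref, rheo_pref * fac),
      rheobase_34 = ifelse(pref == "3:4", rheo_pref, rheo_pref * fac),
      chronaxie_12 = chron, chronaxie_34 = chron,
      cap_amplitude_uV = amp,
      latency_jitter_ms = latency_jitter_ms,
      stringsAsFactors = FALSE
    )
  })
  structure(list(fibers = fibers, clustering = clustering, seed = seed,
                 geometry = geometry),
            class = "fiber_population")
}

#' @export
print.fiber_population <- function(x, ...) {
  cat(sprintf("Fiber population: %d fibers (%d C, %d Adelta), clustering %.2f\n",
              nrow(x$fibers), sum(x$fibers$fiber_class == "C"),
              sum(x$fibers$fiber_class == "Adelta"), x$clustering))
  invisible(x)
}

#' Strength-duration recruitment threshold (Weiss law)
#'
#' Threshold amplitude as a function of pulse width for each fiber, using the
#' hyperbolic Weiss law I(PW) = rheobase * (1 + chronaxie / PW): strictly
#' decreasing in pulse width and approaching rheobase for long pulses.
#'
#' @param pop A [make_population()] result.
#' @param pair Cuff pair, `"1:2"` or `"3:4"`.
#' @param pulse_width_ms Pulse width in ms (> 0).
#' @return Numeric vector of thresholds (uA), one per fiber.
#' @export
recruitment_threshold <- function(pop, pair = c("1:2", "3:4"), pulse_width_ms) {
  pair <- match.arg(pair)
  stopifnot(pulse_width_ms > 0)
  f <- pop$fibers
  if (pair == "1:2") f$rheobase_12 * (1 + f$chronaxie_12 / pulse_width_ms)
  else               f$rheobase_34 * (1 + f$chronaxie_34 / pulse_width_ms)
}

#' Ground-truth response set for a stimulus
#'
#' The exact set of evoked responses a noise-free measurement of this
#' population yields: a fiber responds iff the pulse amplitude reaches its
#' strength-duration threshold for the stimulated pair, and is observable iff
#' its arrival latency (distance / CV) falls inside the post-stimulus analysis
#' window (which runs from the 30 m/s latency to 498 ms, so fibers slower than
#' distance/0.498 s are invisible by construction). Latencies are quantized to
#' the detector's RMS output grid (window-start convention) so that conduction
#' velocities and CV bins are expressed on the same measurement scale the
#' detector reports; responses of fibers whose CAP footprints on that grid are
#' not separated by a sub-threshold gap merge into a single event, and at most
#' one event is kept per (channel, CV bin).
#'
#' @param pop A [make_population()] result.
#' @param pulse A [stim_pulse()].
#' @param pair Cuff pair delivering the pulse.
#' @param distance_m Cuff-to-MEA conduction distance (m).
#' @param fs_hz Sampling rate of the emulated recording.
#' @param cfg A [detector_config()] (supplies the window and bin layout).
#' @return A `response_set` (see [detect_responses()]).
#' @export
ground_truth_responses <- function(pop, pulse, pair = c("1:2", "3:4"),
                                   distance_m = 0.15, fs_hz = 30000,
                                   cfg = detector_config()) {
  pair <- match.arg(pair)
  stopifnot(inherits(pulse, "stim_pulse"))
  thr <- recruitment_threshold(pop, pair, pulse$pulse_width_ms)
  f <- pop$fibers[pulse$amplitude_uA >= thr, , drop = FALSE]
  p <- .sta_params(distance_m, fs_hz, cfg)
  tlen <- length(.cap_template(fs_hz, 1))
  events <- NULL
  if (nrow(f) > 0) {
    n0 <- round(distance_m / f$cv_mps * fs_hz)   # onset sample, rel. stimulus
    r0 <- n0 - p$offset                          # rel. analysis window start
    k0 <- pmax(0L, as.integer(ceiling((r0 - p$win + 1) / p$step)))
    vis <- r0 >= 0 & k0 <= p$n_out - 1L
    f <- f[vis, , drop = FALSE]; r0 <- r0[vis]; k0 <- k0[vis]
    if (nrow(f) > 0) {
      rend <- pmin(r0 + tlen - 1, p$len - 1)     # last template sample in window
      rows <- vector("list", nrow(f))
      for (ch in unique(f$channel)) {
        idx <- which(f$channel == ch)
        idx <- idx[order(r0[idx])]
        prev_end <- -Inf
        for (i in idx) {
          # a fiber yields its own threshold transition only if the RMS window
          # preceding its onset window is clear of earlier CAP footprints
          if (k0[i] == 0 || (k0[i] - 1) * p$step > prev_end) {
            lat <- (p$offset + k0[i] * p$step) / fs_hz
            cv <- distance_m / lat
            rows[[i]] <- data.frame(
              channel = ch, latency_ms = lat * 1000, cv_mps = cv,
              cv_bin = .cv_bin(cv, cfg), fiber_class = .classify_cv(cv, cfg),
              cv_true_mps = f$cv_mps[i], stringsAsFactors = FALSE)
          }
          prev_end <- max(prev_end, rend[i])
        }
      }
      events <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
      if (!is.null(events) && nrow(events) > 0) {
        events <- events[order(events$channel, events$latency_ms), , drop = FALSE]
        events <- events[!duplicated(events[, c("channel", "cv_bin")]), , drop = FALSE]
        rownames(events) <- NULL
      }
    }
  }
  response_set(events, pulse = pulse, pair = pair,
               n_channels = pop$geometry$n_channels,
               distance_m = distance_m)
}

# Stereotyped biphasic CAP template, ~2 ms, sharp onset. Edge samples are kept
# well away from zero so that on noise-free data the first RMS window that
# overlaps the onset crosses any realistic detection threshold.
.cap_template <- function(fs_hz, amplitude_uV, dur_ms = 2) {
  n <- round(dur_ms * 1e-3 * fs_hz)
  n1 <- n %/% 2
  c(amplitude_uV * sin(pi * seq(0.15, 0.95, length.out = n1)),
    -0.7 * amplitude_uV * sin(pi * seq(0.10, 0.90, length.out = n - n1)))
}

#' Simulate a stimulus-triggered-averaging trial
#'
#' Generates a multichannel MEA recording for one pulse train: every recruited
#' fiber adds a stereotyped biphasic CAP template on its channel at latency
#' distance / CV after each pulse (plus optional per-pulse jitter), on top of
#' the configured background noise, mains interference, large artifact
#' excursions and packet-loss gaps. Deterministic given `seed`.
#'
#' @param pop A [make_population()] result.
#' @param train A [stim_train()].
#' @param noise A [noise_model()].
#' @param distance_m Cuff-to-MEA conduction distance (m).
#' @param fs_hz Sampling rate (Hz).
#' @param duration_s Recording length; defaults to the train plus margins.
#' @param seed RNG seed (required).
#' @return An [mea_recording()].
#' @export
simulate_sta_experiment <- function(pop, train, noise = noise_model(),
                                    distance_m = 0.15, fs_hz = 30000,
                                    duration_s = NULL, seed = NULL) {
  stopifnot(inherits(train, "stim_train"))
  geom <- pop$geometry
  if (is.null(duration_s))
    duration_s <- 0.1 + (train$n_pulses - 1) / train$rate_hz + 0.6
  n <- round(duration_s * fs_hz)
  events <- round((0.1 + (seq_len(train$n_pulses) - 1) / train$rate_hz) * fs_hz) + 1L
  if (max(events) + round(0.498 * fs_hz) > n)
    stop("train does not fit in duration_s")
  thr <- recruitment_threshold(pop, train$cuff_pair, train$pulse$pulse_width_ms)
  rec <- pop$fibers[train$pulse$amplitude_uA >= thr, , drop = FALSE]
  x <- .with_seed(seed, {
    x <- if (noise$gaussian_sd_uV > 0)
      matrix(stats::rnorm(n * geom$n_channels, sd = noise$gaussian_sd_uV),
             n, geom$n_channels)
    else matrix(0, n, geom$n_channels)
    if (noise$line_amplitude_uV > 0)
      x <- x + noise$line_amplitude_uV *
        sin(2 * pi * noise$line_freq_hz * seq_len(n) / fs_hz)
    if (nrow(rec) > 0) {
      for (i in seq_len(nrow(rec))) {
        tpl <- .cap_template(fs_hz, rec$cap_amplitude_uV[i])
        jit <- if (rec$latency_jitter_ms[i] > 0)
          stats::rnorm(length(events), sd = rec$latency_jitter_ms[i] / 1000) else 0
        n0 <- round((distance_m / rec$cv_mps[i] + jit) * fs_hz)
        for (j in seq_along(events)) {
          at <- events[j] + n0[min(j, length(n0))]
          span <- at:min(at + length(tpl) - 1L, n)
          if (length(span) > 0 && span[1] >= 1)
            x[span, rec$channel[i]] <- x[span, rec$channel[i]] +
              tpl[seq_along(span)]
        }
      }
    }
    if (noise$artifact_rate_per_s > 0) {
      n_art <- stats::rpois(1, noise$artifact_rate_per_s * duration_s)
      if (n_art > 0) {
        at <- sample.int(n, n_art, replace = TRUE)
        ch <- sample.int(geom$n_channels, n_art, replace = TRUE)
        sgn <- sample(c(-1, 1), n_art, replace = TRUE)
        w <- round(noise$artifact_duration_ms * 1e-3 * fs_hz)
        for (i in seq_len(n_art)) {
          span <- at[i]:min(at[i] + w - 1L, n)
          x[span, ch[i]] <- sgn[i] * noise$artifact_amplitude_mV * 1000
        }
      }
    }
    if (noise$dropout_rate_per_s > 0) {
      n_gap <- stats::rpois(1, noise$dropout_rate_per_s * duration_s)
      if (n_gap > 0) {
        at <- sample.int(n, n_gap, replace = TRUE)
        w <- round(noise$dropout_duration_ms * 1e-3 * fs_hz)
        for (i in seq_len(n_gap)) x[at[i]:min(at[i] + w - 1L, n), ] <- 0
      }
    }
    x
  })
  mea_recording(x, fs_hz, events, geom, distance_m, train)
}

#' Gastric slow-wave simulator configuration
#'
#' Defaults describe a normogastric preparation: a ~9.6 cpm slow wave with a
#' weak second harmonic, riding on low-frequency (1/f-type) drift plus white
#' instrument noise, and strong suppression of the slow wave during
#' stimulation. Serosal baselines are drift-dominated, so most noise power
#' sits below the normogastric band.
#'
#' @param slow_wave_cpm Slow-wave frequency in cycles per minute.
#' @param harmonics List of `c(multiple, relative_amplitude)` pairs.
#' @param amplitude_uV Slow-wave amplitude.
#' @param pink_sd_uV,pink_exponent 1/f^exponent drift noise (common to the
#'   four contacts of a planar electrode).
#' @param white_sd_uV Independent white noise per contact.
#' @param suppression_factor Multiplier applied to the slow-wave amplitude
#'   during stimulation (0 = abolished, 1 = unchanged).
#' @param suppression_onset_s Delay between stimulation onset and suppression.
#' @param fs_hz Simulation sampling rate; any rate with an integer decimation
#'   to 10 Hz works.
#' @param n_electrodes Number of planar electrodes.
#' @return An object of class `gi_sim_config`.
#' @export
gi_sim_config <- function(slow_wave_cpm = 9.6, harmonics = list(c(2, 0.2)),
                          amplitude_uV = 200, pink_sd_uV = 40,
                          pink_exponent = 1.5, white_sd_uV = 10,
                          suppression_factor = 0.1, suppression_onset_s = 0,
                          fs_hz = 250, n_electrodes = 4) {
  stopifnot(suppression_factor >= 0, suppression_factor <= 1,
            slow_wave_cpm > 0, fs_hz > 0)
  structure(as.list(environment()), class = "gi_sim_config")
}

# 1/f^a noise by spectral synthesis, scaled to the requested SD.
.pink_noise <- function(n, sd, exponent) {
  if (sd <= 0) return(numeric(n))
  nf <- n %/% 2
  amp <- (seq_len(nf))^(-exponent / 2)
  ph <- stats::runif(nf, 0, 2 * pi)
  spec <- complex(modulus = c(0, amp, rep(0, n - nf - 1)),
                  argument = c(0, ph, rep(0, n - nf - 1)))
  x <- Re(stats::fft(spec, inverse = TRUE))
  x * sd / stats::sd(x)
}

#' Simulate a gastric myoelectric session
#'
#' A baseline epoch followed by a stimulation epoch, recorded on
#' `n_electrodes` planar electrodes of four contacts each. The four contacts
#' of an electrode see correlated copies of the same physiological signal
#' (slow wave + drift) plus independent white noise, so planar averaging
#' raises SNR. From `suppression_onset_s` after stimulation onset, the
#' slow-wave (and harmonic) amplitude is multiplied by `suppression_factor`.
#' Deterministic given `seed`.
#'
#' @param cfg A [gi_sim_config()].
#' @param baseline_s,stim_s Epoch durations in seconds (protocol: 300 and 120).
#' @param seed RNG seed (required).
#' @return A [gi_recording()].
#' @export
simulate_gi_session <- function(cfg = gi_sim_config(), baseline_s = 300,
                                stim_s = 120, seed = NULL) {
  stopifnot(baseline_s > 0, stim_s > 0)
  fs <- cfg$fs_hz
  n <- round((baseline_s + stim_s) * fs)
  t <- (seq_len(n) - 1) / fs
  gate <- rep(1, n)
  gate[t >= baseline_s + cfg$suppression_onset_s] <- cfg$suppression_factor
  f0 <- cfg$slow_wave_cpm / 60
  contacts <- .with_seed(seed, {
    lapply(seq_len(cfg$n_electrodes), function(e) {
      ph <- stats::runif(1, 0, 2 * pi)
      sw <- cfg$amplitude_uV * sin(2 * pi * f0 * t + ph)
      for (h in cfg$harmonics)
        sw <- sw + cfg$amplitude_uV * h[2] * sin(2 * pi * f0 * h[1] * t + ph * h[1])
      common <- sw * gate + .pink_noise(n, cfg$pink_sd_uV, cfg$pink_exponent)
      m <- matrix(stats::rnorm(n * 4, sd = cfg$white_sd_uV), n, 4)
      m + common
    })
  })
  gi_recording(contacts, fs, baseline_s, stim_s,
               meta = list(slow_wave_cpm = cfg$slow_wave_cpm,
                           suppression_factor = cfg$suppression_factor,
                           suppression_onset_s = cfg$suppression_onset_s))
}
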