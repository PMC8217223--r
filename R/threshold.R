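# Binary-search amplitude thresholding and threshold-table aggregation.

#' Binary-search configuration
#'
#' @param amp_min_uA,amp_max_uA Search range in microamperes.
#' @param resolution_uA Target resolution: the search stops once the bracket
#'   between the highest non-responding and lowest responding amplitude is no
#'   wider than this (protocol: 20 uA).
#' @return An object of class `search_config`.
#' @export
search_config <- function(amp_min_uA = 0, amp_max_uA = 3000,
                          resolution_uA = 20) {
  stopifnot(amp_min_uA < amp_max_uA, resolution_uA > 0)
  structure(list(amp_min_uA = amp_min_uA, amp_max_uA = amp_max_uA,
                 resolution_uA = resolution_uA), class = "search_config")
}

#' Find the response threshold by bisection
#'
#' Finds the minimum stimulation amplitude that evokes a response (the
#' predicate turning TRUE), to within `resolution_uA`. The first probe is at
#' `amp_max_uA`: if even the maximum amplitude evokes nothing the condition
#' is flagged NR (no response) after a single trial. Otherwise the bracket
#' (highest amplitude without a response, lowest with one) is halved -- each
#' midpoint rounded to the 1 uA hardware lattice -- until it is within the
#' resolution; the threshold is the low end's first responding amplitude.
#' With the default 0-3000 uA range and 20 uA resolution at most
#' ceil(log2(3000/20)) + 1 = 9 predicate evaluations are needed.
#'
#' If the tested amplitudes reveal a non-monotone predicate (a response below
#' some amplitude without one) a warning is issued and the record flagged.
#'
#' @param predicate Function of one amplitude (uA) returning TRUE if a
#'   response is detected on any channel in a full stimulation trial.
#' @param cfg A [search_config()].
#' @return An object of class `threshold_record`: list with `threshold_uA`
#'   (NA if NR), `nr`, `tested` (data frame of amplitude/detected in test
#'   order), `n_calls`, `monotone`.
#' @export
binary_search_threshold <- function(predicate, cfg = search_config()) {
  tested_amp <- numeric(0)
  tested_det <- logical(0)
  probe <- function(a) {
    det <- isTRUE(predicate(a))
    tested_amp <<- c(tested_amp, a)
    tested_det <<- c(tested_det, det)
    det
  }
  hi <- round(cfg$amp_max_uA)
  if (!probe(hi)) {
    return(structure(list(threshold_uA = NA_real_, nr = TRUE,
                          tested = data.frame(amplitude_uA = tested_amp,
                                              detected = tested_det),
                          n_calls = 1L, monotone = TRUE),
                     class = "threshold_record"))
  }
  lo <- round(cfg$amp_min_uA)          # amp_min is assumed non-responding
  while (hi - lo > cfg$resolution_uA) {
    mid <- round((lo + hi) / 2)
    if (probe(mid)) hi <- mid else lo <- mid
  }
  pos <- tested_amp[tested_det]
  neg <- tested_amp[!tested_det]
  monotone <- length(neg) == 0 || length(pos) == 0 || min(pos) > max(neg)
  if (!monotone)
    warning("non-monotone predicate: a response at ", min(pos),
            " uA but none at ", max(neg), " uA; returning bracket anyway")
  structure(list(threshold_uA = hi, nr = FALSE,
                 tested = data.frame(amplitude_uA = tested_amp,
                                     detected = tested_det),
                 n_calls = length(tested_amp), monotone = monotone),
            class = "threshold_record")
}

#' @export
print.threshold_record <- function(x, ...) {
  if (x$nr) cat("Threshold: NR (no response at any tested amplitude)\n")
  else cat(sprintf("Threshold: %g uA (%d predicate calls)\n",
                   x$threshold_uA, x$n_calls))
  invisible(x)
}

#' Mean threshold across animals and cuff pairs at one pulse width
#'
#' Arithmetic mean of the threshold amplitudes at a pulse width over all
#' testable entries: each cuff pair counts separately, and NR (no response up
#' to the maximum amplitude) / NT (not tested) entries are excluded.
#'
#' @param records Data frame with columns `pulse_width_ms`, `threshold_uA`
#'   and `flag` (`""`, `"NR"` or `"NT"`), e.g. from
#'   [reference_thresholds()] or [run_threshold_campaign()].
#' @param pulse_width_ms Pulse width to aggregate.
#' @return Mean threshold in uA.
#' @export
mean_threshold_by_pulse_width <- function(records, pulse_width_ms) {
  flag_ok <- if (is.null(records$flag)) TRUE
             else is.na(records$flag) | records$flag == ""
  sel <- records$pulse_width_ms == pulse_width_ms & flag_ok &
    is.finite(records$threshold_uA)
  if (!any(sel)) stop("no testable thresholds at pulse width ", pulse_width_ms)
  mean(records$threshold_uA[sel])
}

#' Reference cuff-stimulation threshold table
#'
#' The bundled threshold table from abdominal vagus nerve mapping experiments
#' in six ferrets: the minimum stimulation amplitude (uA) that evoked an MEA
#' response, per animal, cuff contact pair and pulse width. Flags: NR = no
#' response at any amplitude up to 3 mA; NT = pulse width not tested.
#'
#' @return Data frame with columns `animal`, `vagus_trunk`, `pair`,
#'   `pulse_width_ms`, `threshold_uA` (NA where flagged), `flag`.
#' @export
reference_thresholds <- function() {
  path <- system.file("extdata", "reference_thresholds.csv", package = "vagsel",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(flag = "character"))
}

#' Run a threshold-search campaign over conditions
#'
#' Drives [binary_search_threshold()] across cuff pairs and pulse widths. By
#' default each predicate call simulates a full stimulation trial from the
#' fiber population and runs the CAP detector on it (`method = "simulate"`);
#' `method = "ground_truth"` uses the noise-free recruitment oracle instead
#' (fast, for design studies). Detected response sets for every tested
#' amplitude are cached and returned so that post-hoc selectivity analysis
#' can reuse the amplitudes sampled by the search, as in the experimental
#' protocol.
#'
#' @param pop A [make_population()].
#' @param pulse_widths_ms Pulse widths to test.
#' @param pairs Cuff pairs to test.
#' @param cfg A [search_config()].
#' @param detector A [detector_config()].
#' @param noise A [noise_model()] for simulated trials.
#' @param n_pulses,rate_hz Stimulation train parameters.
#' @param distance_m,fs_hz Recording parameters.
#' @param method `"simulate"` (full pipeline) or `"ground_truth"`.
#' @param seed Base seed for the simulated trials.
#' @return A list with `table` (data frame: pair, pulse_width_ms,
#'   threshold_uA, flag, n_calls), `records` (threshold_record list), and
#'   `response_sets` (nested list `[[pair]][[pulse width]][[amplitude]]`).
#' @export
run_threshold_campaign <- function(pop, pulse_widths_ms = c(0.1, 0.5, 1.0),
                                   pairs = cuff_pairs(),
                                   cfg = search_config(),
                                   detector = detector_config(),
                                   noise = noise_model(),
                                   n_pulses = 120L, rate_hz = 2,
                                   distance_m = 0.15, fs_hz = 30000,
                                   method = c("simulate", "ground_truth"),
                                   seed = 1L) {
  method <- match.arg(method)
  rows <- list(); records <- list(); sets <- list()
  for (pair in pairs) {
    sets[[pair]] <- list()
    for (pw in pulse_widths_ms) {
      key <- as.character(pw)
      sets[[pair]][[key]] <- list()
      predicate <- function(amp) {
        pulse <- stim_pulse(amp, pw, max_amplitude_uA = cfg$amp_max_uA)
        resp <- if (method == "ground_truth") {
          ground_truth_responses(pop, pulse, pair, distance_m, fs_hz, detector)
        } else {
          train <- stim_train(pulse, n_pulses, rate_hz, pair)
          rec <- simulate_sta_experiment(
            pop, train, noise, distance_m, fs_hz,
            seed = (seed + round(amp) + round(1000 * pw)) %% 2147483647)
          detect_recording(rec, detector)
        }
        sets[[pair]][[key]][[as.character(amp)]] <<- resp
        length(responding_channels(resp)) > 0
      }
      recd <- binary_search_threshold(predicate, cfg)
      records[[paste(pair, pw)]] <- recd
      rows[[paste(pair, pw)]] <- data.frame(
        pair = pair, pulse_width_ms = pw,
        threshold_uA = recd$threshold_uA,
        flag = if (recd$nr) "NR" else "", n_calls = recd$n_calls,
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(table = tab, records = records, response_sets = sets)
}
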