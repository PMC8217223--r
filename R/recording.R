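#' Stimulation pulse description
#'
#' A single charge-balanced stimulation pulse. Amplitude is capped at a
#' configured maximum (hardware compliance limit, default 3000 uA) and pulse
#' width must be positive.
#'
#' @param amplitude_uA Pulse amplitude in microamperes (>= 0).
#' @param pulse_width_ms Phase width in milliseconds (> 0).
#' @param shape Pulse shape; only biphasic symmetric pulses are modelled.
#' @param max_amplitude_uA Largest deliverable amplitude.
#' @return An object of class `stim_pulse`.
#' @export
stim_pulse <- function(amplitude_uA, pulse_width_ms,
                       shape = "biphasic_symmetric",
                       max_amplitude_uA = 3000) {
  shape <- match.arg(shape)
  if (!is.numeric(amplitude_uA) || length(amplitude_uA) != 1 || amplitude_uA < 0)
    stop("amplitude_uA must be a nonnegative scalar")
  if (amplitude_uA > max_amplitude_uA)
    stop("amplitude_uA exceeds configured maximum of ", max_amplitude_uA, " uA")
  if (!is.numeric(pulse_width_ms) || length(pulse_width_ms) != 1 || pulse_width_ms <= 0)
    stop("pulse_width_ms must be a positive scalar")
  structure(list(amplitude_uA = amplitude_uA, pulse_width_ms = pulse_width_ms,
                 shape = shape),
            class = "stim_pulse")
}

#' Cuff pair labels
#'
#' The stimulating cuff carries two longitudinal bipolar contact pairs,
#' conventionally labelled 1:2 and 3:4. Their designation is arbitrary
#' (cuff rotation is not controlled).
#' @export
cuff_pairs <- function() c("1:2", "3:4")

#' Stimulation train
#'
#' A train of identical pulses delivered through one bipolar cuff pair. The
#' inter-pulse interval must strictly exceed the post-stimulus analysis window
#' (498 ms), so that consecutive responses do not overlap: at the protocol rate
#' of 2 Hz the interval is 500 ms.
#'
#' @param pulse A [stim_pulse()].
#' @param n_pulses Number of pulses (default 120, the threshold-trial protocol).
#' @param rate_hz Pulse rate in Hz (default 2).
#' @param cuff_pair Which bipolar pair delivers the train, `"1:2"` or `"3:4"`.
#' @param window_end_ms Analysis window end used to validate the rate.
#' @return An object of class `stim_train`.
#' @export
stim_train <- function(pulse, n_pulses = 120L, rate_hz = 2,
                       cuff_pair = c("1:2", "3:4"), window_end_ms = 498) {
  stopifnot(inherits(pulse, "stim_pulse"))
  cuff_pair <- match.arg(cuff_pair)
  if (n_pulses < 1 || n_pulses != round(n_pulses)) stop("n_pulses must be a positive integer")
  if (rate_hz <= 0) stop("rate_hz must be positive")
  if (1000 / rate_hz <= window_end_ms)
    stop("inter-pulse interval (", 1000 / rate_hz,
         " ms) must exceed the analysis window end (", window_end_ms, " ms)")
  structure(list(pulse = pulse, n_pulses = as.integer(n_pulses),
                 rate_hz = rate_hz, cuff_pair = cuff_pair),
            class = "stim_train")
}

#' Multichannel MEA recording
#'
#' Container for a stimulation trial: per-channel sampled voltage (uV), the
#' stimulation event times (sample indices), the array geometry, and the
#' conduction distance from the stimulating cuff to the recording site, which
#' converts response latencies into conduction velocities.
#'
#' @param samples Numeric matrix, samples x channels, in microvolts.
#' @param fs_hz Sampling rate in Hz (acquisition standard: 30000).
#' @param stim_events Strictly increasing sample indices of stimulus onsets.
#' @param geometry An [mea_geometry()].
#' @param cuff_distance_m Cuff-to-recording conduction distance in metres (> 0).
#' @param stim The [stim_train()] delivered.
#' @param validate Run [validate_recording()] on construction.
#' @return An object of class `mea_recording`.
#' @export
mea_recording <- function(samples, fs_hz, stim_events, geometry,
                          cuff_distance_m, stim, validate = TRUE) {
  samples <- as.matrix(samples)
  rec <- structure(
    list(samples = samples, fs_hz = fs_hz,
         stim_events = as.integer(stim_events), geometry = geometry,
         cuff_distance_m = cuff_distance_m, stim = stim),
    class = "mea_recording"
  )
  if (validate) validate_recording(rec) else rec
}

#' @export
print.mea_recording <- function(x, ...) {
  cat(sprintf(
    "MEA recording: %d channels x %.2f s at %g Hz, %d stim events (pair %s, %g uA, %g ms)\n",
    ncol(x$samples), nrow(x$samples) / x$fs_hz, x$fs_hz, length(x$stim_events),
    x$stim$cuff_pair, x$stim$pulse$amplitude_uA, x$stim$pulse$pulse_width_ms))
  invisible(x)
}

#' Validate an MEA recording
#'
#' Checks the container invariants: stimulation events strictly increasing,
#' every event's full post-stimulus analysis window (498 ms) inside the
#' recording, positive conduction distance, and a sample matrix matching the
#' geometry.
#'
#' @param rec An [mea_recording()].
#' @param window_end_ms Post-stimulus window end that must fit (default 498).
#' @return `rec`, unchanged, if all invariants hold; otherwise an error.
#' @export
validate_recording <- function(rec, window_end_ms = 498) {
  stopifnot(inherits(rec, "mea_recording"))
  if (!is.matrix(rec$samples) || !is.numeric(rec$samples))
    stop("samples must be a numeric matrix (samples x channels)")
  if (ncol(rec$samples) != rec$geometry$n_channels)
    stop("samples has ", ncol(rec$samples), " channels but geometry declares ",
         rec$geometry$n_channels)
  if (!is.numeric(rec$fs_hz) || rec$fs_hz <= 0) stop("missing or invalid sampling rate")
  ev <- rec$stim_events
  if (length(ev) == 0) stop("recording has no stimulation events")
  if (any(diff(ev) <= 0)) stop("events not increasing")
  if (any(ev < 1)) stop("stimulation event before start of recording")
  win <- round(window_end_ms / 1000 * rec$fs_hz)
  if (max(ev) + win > nrow(rec$samples))
    stop("window overrun: last stimulation event's ", window_end_ms,
         " ms analysis window extends past the end of the recording")
  if (!is.numeric(rec$cuff_distance_m) || rec$cuff_distance_m <= 0)
    stop("cuff_distance_m must be positive")
  rec
}

#' Gastric myoelectric recording
#'
#' Serosal planar-electrode session: each planar electrode carries four
#' contacts whose waveforms are later averaged into one signal per electrode.
#' The session is annotated with a baseline epoch followed by a stimulation
#' epoch.
#'
#' @param contacts A list with one element per planar electrode; each element a
#'   numeric matrix, samples x 4 contacts, in microvolts.
#' @param fs_hz Sampling rate in Hz.
#' @param baseline_s,stim_s Durations (s) of the baseline and stimulation
#'   epochs; baseline starts at time 0 and stimulation follows immediately.
#' @param meta Optional named list of protocol metadata (stimulation rate,
#'   amplitude, pulse width, ...), echoed into outputs.
#' @return An object of class `gi_recording`.
#' @export
gi_recording <- function(contacts, fs_hz, baseline_s, stim_s, meta = list()) {
  stopifnot(is.list(contacts), length(contacts) >= 1)
  for (m in contacts) {
    if (!is.matrix(m) || ncol(m) != 4)
      stop("each planar electrode must have exactly 4 contact waveforms")
    if (nrow(m) != nrow(contacts[[1]])) stop("contact waveform length mismatch")
  }
  if (!is.numeric(fs_hz) || fs_hz <= 0) stop("missing or invalid sampling rate")
  if (baseline_s <= 0 || stim_s <= 0) stop("epoch durations must be positive")
  n_need <- round((baseline_s + stim_s) * fs_hz)
  if (nrow(contacts[[1]]) < n_need)
    stop("recording shorter than declared baseline + stimulation epochs")
  structure(list(contacts = contacts, fs_hz = fs_hz,
                 baseline_s = baseline_s, stim_s = stim_s, meta = meta),
            class = "gi_recording")
}

#' @export
print.gi_recording <- function(x, ...) {
  cat(sprintf("GI recording: %d planar electrodes x 4 contacts, %.1f min at %g Hz (baseline %g s, stimulation %g s)\n",
              length(x$contacts), nrow(x$contacts[[1]]) / x$fs_hz / 60, x$fs_hz,
              x$baseline_s, x$stim_s))
  invisible(x)
}

# ---- container I/O ---------------------------------------------------------

.CONTAINER_FORMAT <- "vagsel-container"
.CONTAINER_VERSION <- 1L

#' Write recordings to a container file
#'
#' Serializes one or both recording kinds into a single R-native container
#' file. The round trip through [read_container()] is bit-exact for all fields
#' (voltages, event indices, geometry, metadata).
#'
#' @param path Output file path.
#' @param mea An [mea_recording()], or `NULL`.
#' @param gi A [gi_recording()], or `NULL`.
#' @export
write_container <- function(path, mea = NULL, gi = NULL) {
  if (is.null(mea) && is.null(gi)) stop("nothing to write")
  if (!is.null(mea)) stopifnot(inherits(mea, "mea_recording"))
  if (!is.null(gi)) stopifnot(inherits(gi, "gi_recording"))
  obj <- list(format = .CONTAINER_FORMAT, version = .CONTAINER_VERSION,
              mea = unclass(mea), gi = unclass(gi))
  if (!is.null(obj$mea)) obj$mea$geometry <- unclass(obj$mea$geometry)
  saveRDS(obj, path)
  invisible(path)
}

.rebuild_geometry <- function(g) {
  for (k in c("n_rows", "n_cols", "pitch_um"))
    if (is.null(g[[k]])) stop("malformed container: geometry lacks ", k)
  mea_geometry(g$n_rows, g$n_cols, g$pitch_um)
}

#' Read recordings from a container file
#'
#' @param path Container file written by [write_container()].
#' @return A list with elements `mea` (an [mea_recording()] or `NULL`) and
#'   `gi` (a [gi_recording()] or `NULL`).
#' @export
read_container <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) stop("malformed container: ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, .CONTAINER_FORMAT))
    stop("malformed container: not a ", .CONTAINER_FORMAT, " file")
  out <- list(mea = NULL, gi = NULL)
  if (!is.null(obj$mea)) {
    m <- obj$mea
    if (is.null(m$fs_hz)) stop("missing sampling rate")
    for (k in c("samples", "stim_events", "geometry", "cuff_distance_m", "stim"))
      if (is.null(m[[k]])) stop("malformed container: MEA group lacks ", k)
    stim <- m$stim
    class(stim$pulse) <- "stim_pulse"
    class(stim) <- "stim_train"
    out$mea <- mea_recording(m$samples, m$fs_hz, m$stim_events,
                             .rebuild_geometry(m$geometry),
                             m$cuff_distance_m, stim)
  }
  if (!is.null(obj$gi)) {
    g <- obj$gi
    if (is.null(g$fs_hz)) stop("missing sampling rate")
    for (k in c("contacts", "baseline_s", "stim_s"))
      if (is.null(g[[k]])) stop("malformed container: GI group lacks ", k)
    out$gi <- gi_recording(g$contacts, g$fs_hz, g$baseline_s, g$stim_s,
                           meta = if (is.null(g$meta)) list() else g$meta)
  }
  out
}
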