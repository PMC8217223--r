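# End-to-end orchestration of the synthetic study: simulate populations,
# search thresholds with the detector in the loop, optimize selectivity over
# the amplitudes the search visited, quantify somatotopy, and run the GI
# spectral pipeline. One global seed fans out deterministically to per-stage
# seeds.

#' Derive per-stage seeds from one global seed
#'
#' Splitting rule: seed_i = (a * seed + b * i) mod (2^31 - 1) with fixed
#' multipliers, so one knob reproduces the whole study and stages stay
#' decorrelated.
#'
#' @param seed Global integer seed.
#' @param n Number of stage seeds.
#' @return Integer vector of `n` seeds, each below 2^31.
#' @export
split_seed <- function(seed, n) {
  if (is.null(seed)) stop("unseeded stochastic stage: a global seed is required")
  as.integer((7919 * as.numeric(seed) + 104729 * seq_len(n)) %% 2147483647)
}

#' Configuration of the full synthetic study
#'
#' Defaults describe a scaled-down version of the mapping protocol that a
#' desktop run completes in minutes: 3 synthetic animals, 20 fibers each
#' (C-dominated), thresholds searched per cuff pair at 0.1 / 0.5 / 1.0 ms
#' with the detector in the loop, 12-pulse trains with noise scaled to keep
#' the post-average SNR of the 120-pulse / ~5 uV regime, and one GI session
#' per suppression condition.
#'
#' @param seed Global seed (required).
#' @param out_dir Output directory for the report CSVs.
#' @param n_animals Number of synthetic animals.
#' @param n_c,n_adelta Fibers per animal.
#' @param clustering Spatial clustering of the populations.
#' @param pulse_widths_ms Pulse widths searched.
#' @param n_pulses Pulses per trial.
#' @param noise_sd_uV Background noise SD.
#' @param distance_m Cuff-to-MEA distance.
#' @param fs_hz MEA sampling rate.
#' @param overlap_limit Largest tolerated channel overlap in the optimizer.
#' @param gi_suppression Suppression factors for the two GI conditions
#'   (cuff pair 1:2 and 3:4).
#' @return An object of class `study_config`.
#' @export
study_config <- function(seed, out_dir = tempfile("vagsel_study_"),
                         n_animals = 3, n_c = 16, n_adelta = 4,
                         clustering = 0.5,
                         pulse_widths_ms = c(0.1, 0.5, 1.0),
                         n_pulses = 12L, noise_sd_uV = 1.5,
                         distance_m = 0.15, fs_hz = 30000,
                         overlap_limit = 3,
                         gi_suppression = c(`1:2` = 1, `3:4` = 0.1)) {
  if (missing(seed) || is.null(seed)) stop("unseeded stochastic stage: provide seed")
  structure(as.list(environment()), class = "study_config")
}

.write_report_csv <- function(df, dir, name) {
  path <- file.path(dir, name)
  utils::write.csv(format(df, trim = TRUE, digits = 10), path,
                   row.names = FALSE, quote = FALSE)
  path
}

#' Run the full synthetic study
#'
#' Chains every stage of the pipeline on synthetic data and writes the
#' report tables to `cfg$out_dir`: per-animal thresholds
#' (`thresholds.csv`), mean thresholds by pulse width
#' (`threshold_means.csv`), SI optimization (`selectivity.csv`), selective
#' channel counts at overlap allowances 0 and 3 (`selective_counts.csv`),
#' nearest-neighbor distances (`nn_distances.csv`), centroid separations
#' and the condition comparison (`centroids.csv`), fiber-class proportions
#' (`fiber_classes.csv`), GI epoch summaries (`gi_summary.csv`) and
#' waterfall series (`gi_waterfall.csv`), plus a `manifest.json` recording
#' the configuration hash, seeds and per-stage runtimes. Byte-identical
#' CSVs across runs with the same configuration.
#'
#' @param cfg A [study_config()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_full_synthetic_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- split_seed(cfg$seed, cfg$n_animals + 2L)
  gi_seed <- seeds[cfg$n_animals + 1L]
  t_start <- proc.time()[["elapsed"]]
  runtimes <- c()
  detector <- detector_config()
  noise <- noise_model(gaussian_sd_uV = cfg$noise_sd_uV)

  # --- per-animal threshold campaigns (detector in the loop) ---------------
  t0 <- proc.time()[["elapsed"]]
  animals <- lapply(seq_len(cfg$n_animals), function(a) {
    pop <- make_population(cfg$n_c, cfg$n_adelta, clustering = cfg$clustering,
                           seed = seeds[a])
    camp <- run_threshold_campaign(
      pop, cfg$pulse_widths_ms, cuff_pairs(), search_config(), detector,
      noise, n_pulses = cfg$n_pulses, distance_m = cfg$distance_m,
      fs_hz = cfg$fs_hz, method = "simulate", seed = seeds[a])
    list(id = sprintf("S%02d", a), pop = pop, campaign = camp)
  })
  thresholds <- do.call(rbind, lapply(animals, function(an)
    cbind(animal = an$id, an$campaign$table)))
  runtimes["thresholds"] <- proc.time()[["elapsed"]] - t0

  means <- do.call(rbind, lapply(cfg$pulse_widths_ms, function(pw) {
    m <- tryCatch(mean_threshold_by_pulse_width(thresholds, pw),
                  error = function(e) NA_real_)
    data.frame(pulse_width_ms = pw, mean_threshold_uA = m)
  }))

  # --- selectivity over the amplitudes the searches visited ----------------
  t0 <- proc.time()[["elapsed"]]
  sel_rows <- list(); count_rows <- list(); nn_rows <- list()
  cent_a <- list(); cent_b <- list(); class_rows <- list()
  for (an in animals) {
    for (pw in cfg$pulse_widths_ms) {
      key <- as.character(pw)
      g12 <- an$campaign$response_sets[["1:2"]][[key]]
      g34 <- an$campaign$response_sets[["3:4"]][[key]]
      if (length(g12) == 0 || length(g34) == 0) next
      opt <- optimize_selectivity(g12, g34, cfg$overlap_limit)
      sel_rows[[paste(an$id, pw)]] <- data.frame(
        animal = an$id, pulse_width_ms = pw, feasible = opt$feasible,
        si = opt$si, amp_12 = opt$amplitude_pair[1],
        amp_34 = opt$amplitude_pair[2],
        t12 = if (opt$feasible) opt$counts$t12 else NA,
        t34 = if (opt$feasible) opt$counts$t34 else NA,
        ts = if (opt$feasible) opt$counts$ts else NA)
      if (!opt$feasible) next
      r12 <- opt$response_sets[["1:2"]]; r34 <- opt$response_sets[["3:4"]]
      for (al in c(0, cfg$overlap_limit)) {
        cnt <- selective_channel_summary(r12, r34, al)
        count_rows[[paste(an$id, pw, al)]] <- data.frame(
          animal = an$id, pulse_width_ms = pw, allowance = al,
          n_12 = cnt[["1:2"]], n_34 = cnt[["3:4"]])
      }
      ev <- rbind(r12$events, r34$events)
      if (nrow(ev) > 0)
        class_rows[[paste(an$id, pw)]] <- data.frame(
          animal = an$id, pulse_width_ms = pw,
          frac_c = mean(ev$fiber_class == "C"), n_events = nrow(ev))
      # somatotopy needs selective responses on both pairs
      if (length(opt$selective_12) > 0 && length(opt$selective_34) > 0) {
        nn <- nearest_neighbor_analysis(r12, r34, an$pop$geometry)
        if (length(nn$same_pair_distances))
          nn_rows[[paste(an$id, pw, "same")]] <- data.frame(
            animal = an$id, pulse_width_ms = pw, category = "same",
            distance_um = nn$same_pair_distances)
        if (length(nn$cross_pair_distances))
          nn_rows[[paste(an$id, pw, "cross")]] <- data.frame(
            animal = an$id, pulse_width_ms = pw, category = "cross",
            distance_um = nn$cross_pair_distances)
        # centroid separation at max SI vs at the maximum tested amplitude
        max12 <- g12[[which.max(as.numeric(names(g12)))]]
        max34 <- g34[[which.max(as.numeric(names(g34)))]]
        if (length(responding_channels(max12)) > 0 &&
            length(responding_channels(max34)) > 0) {
          cent_a[[paste(an$id, pw)]] <- data.frame(
            animal = an$id, pulse_width_ms = pw,
            separation_um = centroid_separation(r12, r34, an$pop$geometry))
          cent_b[[paste(an$id, pw)]] <- data.frame(
            animal = an$id, pulse_width_ms = pw,
            separation_um = centroid_separation(max12, max34, an$pop$geometry))
        }
      }
    }
  }
  runtimes["selectivity"] <- proc.time()[["elapsed"]] - t0

  selectivity <- do.call(rbind, sel_rows)
  counts <- do.call(rbind, count_rows)
  nn <- do.call(rbind, nn_rows)
  classes <- do.call(rbind, class_rows)
  centroids <- NULL; centroid_test <- NULL
  if (length(cent_a) >= 2) {
    ca <- do.call(rbind, cent_a); cb <- do.call(rbind, cent_b)
    centroids <- merge(ca, cb, by = c("animal", "pulse_width_ms"),
                       suffixes = c("_si_max", "_max_amp"))
    wt <- centroid_shift_analysis(centroids$separation_um_si_max,
                                  centroids$separation_um_max_amp)
    centroid_test <- data.frame(n_pairs = wt$n_used, statistic = wt$statistic,
                                p_value = wt$p_value)
  }

  # --- GI sessions: one per cuff pair / suppression condition --------------
  t0 <- proc.time()[["elapsed"]]
  gi_rows <- list(); wf_rows <- list()
  for (i in seq_along(cfg$gi_suppression)) {
    pair <- names(cfg$gi_suppression)[i]
    rec <- simulate_gi_session(
      gi_sim_config(suppression_factor = cfg$gi_suppression[[i]]),
      seed = (gi_seed + i) %% 2147483647)
    res <- analyze_gi_recording(rec)[[1]]   # first planar electrode
    gi_rows[[pair]] <- data.frame(
      pair = pair, suppression_factor = cfg$gi_suppression[[i]],
      baseline_dominant_cpm = res$baseline$dominant_cpm,
      baseline_significant = res$baseline$significant,
      baseline_fraction = res$comparison$baseline_fraction,
      stimulation_fraction = res$comparison$stimulation_fraction,
      ratio = res$comparison$ratio)
    wf <- rbind(cbind(epoch = "baseline", res$comparison$baseline_series),
                cbind(epoch = "stimulation", res$comparison$stimulation_series))
    wf_rows[[pair]] <- cbind(pair = pair, wf)
  }
  gi_summary <- do.call(rbind, gi_rows)
  waterfall <- do.call(rbind, wf_rows)
  runtimes["gi"] <- proc.time()[["elapsed"]] - t0

  # --- write report --------------------------------------------------------
  files <- c(
    .write_report_csv(thresholds, cfg$out_dir, "thresholds.csv"),
    .write_report_csv(means, cfg$out_dir, "threshold_means.csv"),
    .write_report_csv(selectivity, cfg$out_dir, "selectivity.csv"),
    if (!is.null(counts)) .write_report_csv(counts, cfg$out_dir, "selective_counts.csv"),
    if (!is.null(nn)) .write_report_csv(nn, cfg$out_dir, "nn_distances.csv"),
    if (!is.null(centroids)) .write_report_csv(centroids, cfg$out_dir, "centroids.csv"),
    if (!is.null(centroid_test)) .write_report_csv(centroid_test, cfg$out_dir, "centroid_test.csv"),
    if (!is.null(classes)) .write_report_csv(classes, cfg$out_dir, "fiber_classes.csv"),
    .write_report_csv(gi_summary, cfg$out_dir, "gi_summary.csv"),
    .write_report_csv(waterfall, cfg$out_dir, "gi_waterfall.csv"))
  manifest <- version_and_manifest(cfg, seeds, runtimes, files)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(animals = animals, thresholds = thresholds, means = means,
                 selectivity = selectivity, counts = counts, nn = nn,
                 centroids = centroids, centroid_test = centroid_test,
                 gi_summary = gi_summary, waterfall = waterfall,
                 manifest = manifest, files = files))
}

#' Build the study manifest
#'
#' Records the package version, a digest of the configuration, the derived
#' stage seeds, per-stage runtimes and digests of the written report files.
#'
#' @param cfg A [study_config()].
#' @param seeds Stage seeds used.
#' @param runtimes Named numeric vector of stage runtimes (s).
#' @param files Report file paths.
#' @return A list (serializable as JSON).
#' @export
version_and_manifest <- function(cfg, seeds = NULL, runtimes = NULL,
                                 files = character()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  cfg_plain <- unclass(cfg)
  cfg_plain$out_dir <- NULL          # the hash covers the science, not paths
  saveRDS(cfg_plain, tf, version = 2)
  list(
    tool = "vagsel",
    version = as.character(utils::packageVersion("vagsel")),
    config_hash = unname(tools::md5sum(tf)),
    global_seed = cfg$seed,
    stage_seeds = seeds,
    runtimes_s = if (is.null(runtimes)) NULL else as.list(round(runtimes, 2)),
    outputs = lapply(files, function(f)
      list(file = basename(f), md5 = unname(tools::md5sum(f)))))
}
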