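# Structural objects shared by the whole pipeline: the optode montage, the
# walk/rest block design, per-subject metadata and cohort scenario configs.

#' Build the default 48-channel motor-cortex montage
#'
#' Constructs the abstract channel layout used throughout the package: 16
#' sources and 16 detectors paired into 48 measurement channels (24 per
#' hemisphere) over the primary motor (M1/SMC) and premotor (PM) cortices,
#' with a uniform 3 cm source-detector separation. No scalp coordinates are
#' attached: no downstream computation needs geometry beyond the separation
#' and the hemisphere label.
#'
#' Channel ordering is stable: left-hemisphere channels L01..L24 first, then
#' right-hemisphere channels R01..R24. Within each hemisphere the first 12
#' channels are labelled M1 (primary motor / sensorimotor) and the last 12 PM
#' (premotor); the region split is a documented convention, the headline
#' biomarker only uses hemispheres.
#'
#' @param separation_m Source-detector separation in meters (default 0.03).
#' @return A data.frame of class `nirs_montage` with columns `channel`,
#'   `source`, `detector`, `hemisphere`, `region`, `separation_m`.
#' @export
build_default_montage <- function(separation_m = 0.03) {
  hemi_block <- function(prefix, src_offset, det_offset) {
    # 8 sources x 3 neighbouring detectors each = 24 channels per hemisphere
    src <- rep(seq_len(8), each = 3)
    det <- ((src - 1) + rep(0:2, times = 8)) %% 8 + 1
    data.frame(
      channel = sprintf("%s%02d", prefix, seq_len(24)),
      source = src + src_offset,
      detector = det + det_offset,
      hemisphere = if (prefix == "L") "left" else "right",
      region = rep(c("M1", "PM"), each = 12),
      separation_m = separation_m,
      stringsAsFactors = FALSE
    )
  }
  m <- rbind(hemi_block("L", 0, 0), hemi_block("R", 8, 8))
  class(m) <- c("nirs_montage", "data.frame")
  validate_montage(m)
  m
}

#' Validate a montage object
#'
#' @param montage A `nirs_montage` data.frame.
#' @return The montage, invisibly, if valid; otherwise an error of class
#'   `invalid_montage`.
#' @export
validate_montage <- function(montage) {
  if (!is.data.frame(montage) ||
      !all(c("channel", "hemisphere", "region", "separation_m") %in%
           names(montage))) {
    nw_stop("montage must have channel/hemisphere/region/separation_m columns",
            "invalid_montage")
  }
  if (anyDuplicated(montage$channel)) {
    nw_stop("montage channel ids must be unique", "invalid_montage")
  }
  if (!all(montage$hemisphere %in% c("left", "right"))) {
    nw_stop("hemisphere labels must be 'left' or 'right'", "invalid_montage")
  }
  if (any(montage$separation_m <= 0)) {
    nw_stop("channel separations must be positive", "invalid_montage")
  }
  invisible(montage)
}

#' Build a block task design
#'
#' Describes the walking task: a pre-task standing baseline followed by
#' `cycles` repetitions of (walk, rest). Defaults match the treadmill
#' protocol: 3.46 Hz sampling, 4 cycles of 30 s walking + 30 s standing
#' rest, preceded by a 30 s baseline used as the optical-density reference
#' and to let filters settle.
#'
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param cycles Number of walk/rest cycles (>= 1).
#' @param walk_s Walking-block duration in seconds.
#' @param rest_s Rest-block duration in seconds.
#' @param baseline_s Pre-task baseline duration in seconds.
#' @return A list of class `nirs_design` with fields `sampling_rate`,
#'   `cycles`, `walk_s`, `rest_s`, `baseline_s`, `onsets` (walk-block onsets
#'   in seconds), `total_s`, and `n_samples`.
#' @export
build_task_design <- function(sampling_rate = 3.46, cycles = 4L,
                              walk_s = 30, rest_s = 30, baseline_s = 30) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    nw_stop("sampling_rate must be a positive number", "invalid_design")
  }
  if (!is.numeric(cycles) || length(cycles) != 1 || cycles < 1 ||
      cycles != round(cycles)) {
    nw_stop("cycles must be an integer >= 1", "invalid_design")
  }
  if (any(c(walk_s, rest_s, baseline_s) < 0)) {
    nw_stop("durations must be non-negative", "invalid_design")
  }
  cycles <- as.integer(cycles)
  sampling_rate <- as.numeric(sampling_rate)
  walk_s <- as.numeric(walk_s)
  rest_s <- as.numeric(rest_s)
  baseline_s <- as.numeric(baseline_s)
  onsets <- baseline_s + (seq_len(cycles) - 1) * (walk_s + rest_s)
  total_s <- baseline_s + cycles * (walk_s + rest_s)
  d <- list(
    sampling_rate = sampling_rate, cycles = cycles, walk_s = walk_s,
    rest_s = rest_s, baseline_s = baseline_s, onsets = onsets,
    total_s = total_s, n_samples = as.integer(round(total_s * sampling_rate))
  )
  class(d) <- "nirs_design"
  d
}

#' Sample times of a task design
#'
#' @param design A `nirs_design`.
#' @return Numeric vector of sample times in seconds (first sample at t = 0).
#' @export
design_times <- function(design) {
  (seq_len(design$n_samples) - 1) / design$sampling_rate
}

#' Serialize a montage or design to JSON
#'
#' Round-trips exactly: `montage_from_json(montage_to_json(m))` reproduces
#' `m`, and likewise for designs (onsets are recomputed from the stored
#' fields, so the round trip is exact by construction).
#'
#' @param montage A `nirs_montage`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written to a file).
#' @export
montage_to_json <- function(montage, path = NULL) {
  js <- jsonlite::toJSON(as.data.frame(montage), digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname montage_to_json
#' @param x JSON string or file path produced by [montage_to_json()].
#' @export
montage_from_json <- function(x) {
  m <- as.data.frame(jsonlite::fromJSON(x))
  class(m) <- c("nirs_montage", "data.frame")
  validate_montage(m)
  m
}

#' @rdname montage_to_json
#' @param design A `nirs_design`.
#' @export
design_to_json <- function(design, path = NULL) {
  keep <- c("sampling_rate", "cycles", "walk_s", "rest_s", "baseline_s")
  js <- jsonlite::toJSON(design[keep], digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' @rdname montage_to_json
#' @export
design_from_json <- function(x) {
  f <- jsonlite::fromJSON(x)
  build_task_design(f$sampling_rate, f$cycles, f$walk_s, f$rest_s, f$baseline_s)
}

#' Construct subject metadata
#'
#' Per-subject clinical and demographic record. Patients (cohort "PwMS")
#' carry an EDSS disability score, an MS phenotype and a more-impaired limb
#' side, and are scheduled at timepoints T0/T1/T2; healthy controls are
#' measured at T0 only and their "side" is the dominant limb.
#'
#' @param subject_id Character id.
#' @param cohort "PwMS" or "healthy".
#' @param treatment "RAGT", "OW" or "none".
#' @param timepoints Character subset of c("T0","T1","T2").
#' @param edss EDSS score (0-10 in 0.5 steps; NA for healthy).
#' @param phenotype "primary progressive", "secondary progressive" or "none".
#' @param side More-impaired limb side for patients, dominant limb side for
#'   healthy subjects: "left" or "right".
#' @param age Age in years.
#' @param sex "M" or "F".
#' @param t25fw_speed Named numeric: T25FW gait speed (m/s) per timepoint.
#' @param mwd6 Named numeric: 6-minute walking distance (m) per timepoint.
#' @param bbs Named numeric: Berg Balance Scale (0-56) per timepoint.
#' @return A list of class `subject_meta`.
#' @export
subject_meta <- function(subject_id, cohort, treatment = "none",
                         timepoints = "T0", edss = NA_real_,
                         phenotype = "none", side, age = NA_real_,
                         sex = NA_character_, t25fw_speed = NULL,
                         mwd6 = NULL, bbs = NULL) {
  if (!cohort %in% c("PwMS", "healthy")) {
    nw_stop("cohort must be 'PwMS' or 'healthy'", "invalid_metadata")
  }
  if (!treatment %in% c("RAGT", "OW", "none")) {
    nw_stop("treatment must be 'RAGT', 'OW' or 'none'", "invalid_metadata")
  }
  if (!all(timepoints %in% c("T0", "T1", "T2"))) {
    nw_stop("timepoints must be within T0/T1/T2", "invalid_metadata")
  }
  if (cohort == "healthy" && !identical(sort(timepoints), "T0")) {
    nw_stop("healthy subjects are measured at T0 only", "invalid_metadata")
  }
  if (missing(side) || !side %in% c("left", "right")) {
    nw_stop("side must be 'left' or 'right'", "invalid_metadata")
  }
  if (!is.na(edss) && (edss < 0 || edss > 10 || (edss * 2) %% 1 != 0)) {
    nw_stop("edss must lie in [0,10] in 0.5 steps", "invalid_metadata")
  }
  structure(list(
    subject_id = subject_id, cohort = cohort, treatment = treatment,
    timepoints = timepoints, edss = edss, phenotype = phenotype,
    side = side, age = age, sex = sex,
    t25fw_speed = t25fw_speed, mwd6 = mwd6, bbs = bbs
  ), class = "subject_meta")
}

#' Cohort scenario configuration for the synthetic generator
#'
#' Parameterizes [simulate_cohort()]: group sizes, per-cohort per-hemisphere
#' oxy-Hb activation amplitude distributions, longitudinal effect multipliers
#' per treatment arm and timepoint, the optical noise model, the bad-channel
#' probability, and the scenario seed. Every stochastic draw in the
#' generator descends from `seed`, so a scenario is fully reproducible.
#'
#' Amplitudes are response-plateau oxy-Hb changes in micromolar. Defaults
#' state a world in which patients activate roughly an order of magnitude
#' more than healthy controls, more so in the hemisphere controlling the
#' more impaired limb, and in which robot-assisted training lowers
#' activation over time while overground training raises it.
#'
#' @param n_ragt,n_ow,n_healthy Group sizes (patients per arm, controls).
#' @param amp_mean Named list: `pwms` and `healthy`, each c(maff=, laff=)
#'   mean channel amplitude in uM.
#' @param subject_cv Between-subject lognormal coefficient of variation of
#'   the overall activation level, per cohort (named c(pwms=, healthy=)).
#' @param channel_cv Within-subject between-channel amplitude CV.
#' @param multipliers Named list per arm of longitudinal multipliers at
#'   T0/T1/T2 applied to patient amplitudes.
#' @param mult_jitter_sd Lognormal SD of the per-subject multiplier jitter
#'   at T1/T2.
#' @param rti_coupling Slope tying the RAGT T2 multiplier to the subject's
#'   relative training intensity (lower-intensity training gives a larger
#'   activation decrease); 0 disables the coupling.
#' @param noise A [noise_model()] object.
#' @param bad_channel_prob Per-channel probability of injecting a bad
#'   channel (gain or noise violation).
#' @param hbr_ratio Deoxy-Hb amplitude as a fraction of the oxy-Hb
#'   amplitude (typically negative).
#' @param seed Scenario seed (integer).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_ragt = 12L, n_ow = 12L, n_healthy = 5L,
                            amp_mean = list(
                              pwms = c(maff = 0.25, laff = 0.19),
                              healthy = c(maff = 0.030, laff = 0.018)),
                            subject_cv = c(pwms = 0.45, healthy = 0.20),
                            channel_cv = 0.30,
                            multipliers = list(
                              RAGT = c(T0 = 1, T1 = 0.8, T2 = 0.6),
                              OW = c(T0 = 1, T1 = 1.3, T2 = 1.6)),
                            mult_jitter_sd = 0.20,
                            rti_coupling = 0.6,
                            noise = noise_model(),
                            bad_channel_prob = 0.05,
                            hbr_ratio = -1 / 3,
                            seed = 20210609L) {
  if (any(c(n_ragt, n_ow, n_healthy) < 0)) {
    nw_stop("group sizes must be non-negative", "invalid_scenario")
  }
  if (bad_channel_prob < 0 || bad_channel_prob > 1) {
    nw_stop("bad_channel_prob must lie in [0,1]", "invalid_scenario")
  }
  if (any(subject_cv < 0) || channel_cv < 0) {
    nw_stop("coefficients of variation must be >= 0", "invalid_scenario")
  }
  structure(list(
    n_ragt = as.integer(n_ragt), n_ow = as.integer(n_ow),
    n_healthy = as.integer(n_healthy), amp_mean = amp_mean,
    subject_cv = subject_cv, channel_cv = channel_cv,
    multipliers = multipliers, mult_jitter_sd = mult_jitter_sd,
    rti_coupling = rti_coupling, noise = noise,
    bad_channel_prob = bad_channel_prob, hbr_ratio = hbr_ratio,
    seed = as.integer(seed)
  ), class = "scenario_config")
}

#' Study-like cohort scenario
#'
#' The default scenario: 12 robot-assisted + 12 overground patients followed
#' at T0/T1/T2 plus 5 healthy controls at T0, with patient activation well
#' above healthy activation, a decreasing longitudinal multiplier in the
#' RAGT arm and an increasing one in the OW arm.
#'
#' @param seed Scenario seed.
#' @return A `scenario_config`.
#' @export
scenario_study_like <- function(seed = 20210609L) {
  scenario_config(seed = seed)
}

#' Null cohort scenario
#'
#' All groups share one amplitude distribution and all longitudinal
#' multipliers are 1, so every downstream group contrast is a true null;
#' used to calibrate type-I error of the statistical battery.
#'
#' @param seed Scenario seed.
#' @return A `scenario_config`.
#' @export
scenario_null <- function(seed = 20210609L) {
  amp <- c(maff = 0.12, laff = 0.12)
  scenario_config(
    amp_mean = list(pwms = amp, healthy = amp),
    subject_cv = c(pwms = 0.45, healthy = 0.45),
    multipliers = list(RAGT = c(T0 = 1, T1 = 1, T2 = 1),
                       OW = c(T0 = 1, T1 = 1, T2 = 1)),
    mult_jitter_sd = 0.20, rti_coupling = 0,
    seed = seed
  )
}
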