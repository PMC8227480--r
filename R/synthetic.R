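# Synthetic dual-wavelength fNIRS generator with known ground truth.
# Forward model: per-channel concentration time courses (walk-block boxcar
# convolved with a canonical double-gamma hemodynamic response) are mapped
# to optical density by the forward Beer-Lambert model and to detector
# intensity by I = I0 * 10^(-OD), with physiological noise, drift, spikes
# and baseline shifts added in the OD domain (so the inversion sees them as
# additive disturbances).

#' Canonical double-gamma hemodynamic response function
#'
#' Standard double-gamma impulse response (peak 6 s, undershoot centred at
#' 16 s, undershoot ratio 1/6), used to shape the walking-block response.
#'
#' @param t Time in seconds (>= 0).
#' @param peak Time-to-peak of the positive lobe (s).
#' @param undershoot Time-to-peak of the undershoot (s).
#' @param ratio Undershoot amplitude as a fraction of the peak.
#' @return HRF values at `t` (unnormalized).
#' @export
canonical_hrf <- function(t, peak = 6, undershoot = 16, ratio = 1 / 6) {
  g <- function(t, a) t^(a - 1) * exp(-t) / gamma(a)
  h <- g(pmax(t, 0), peak) - ratio * g(pmax(t, 0), undershoot)
  h[t < 0] <- 0
  h
}

#' Noise-free task response of one channel
#'
#' Boxcar over the walking blocks convolved with the canonical HRF, scaled
#' so the plateau of a sustained response equals 1; multiply by a channel's
#' amplitude (uM) to obtain its concentration time course.
#'
#' @param design A `nirs_design`.
#' @return Numeric vector of length `design$n_samples`.
#' @export
task_response <- function(design) {
  t <- design_times(design)
  box <- rep(0, design$n_samples)
  for (on in design$onsets) box[t >= on & t < on + design$walk_s] <- 1
  kern_t <- seq(0, 32, by = 1 / design$sampling_rate)
  h <- canonical_hrf(kern_t)
  h <- h / sum(h)  # plateau of a long boxcar response = 1
  y <- stats::convolve(box, rev(h), type = "open")
  y[seq_len(design$n_samples)]
}

#' Optical noise model
#'
#' Amplitudes are in optical-density units. Components: cardiac (~1.1 Hz),
#' respiratory (~0.25 Hz) and Mayer-wave (~0.1 Hz) sinusoids with random
#' per-channel phases; a Gaussian random-walk drift; white measurement
#' noise; sporadic single-sample spikes; and sporadic sustained baseline
#' shifts. `bad_white_sd` is the inflated white-noise level given to
#' injected "snr"-bad channels, chosen to push the intensity CV well above
#' the QC threshold.
#'
#' @param cardiac_hz,cardiac_amp Cardiac frequency (Hz; must stay below the
#'   Nyquist frequency) and OD amplitude.
#' @param resp_hz,resp_amp Respiratory component.
#' @param mayer_hz,mayer_amp Mayer-wave component.
#' @param drift_sd Per-sample SD of the random-walk drift.
#' @param white_sd White-noise SD.
#' @param spike_rate Spikes per minute.
#' @param spike_mag Spike OD magnitude.
#' @param shift_rate Baseline shifts per minute.
#' @param shift_mag Baseline-shift OD magnitude.
#' @param bad_white_sd White-noise SD of injected snr-bad channels.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(cardiac_hz = 1.1, cardiac_amp = 0.002,
                        resp_hz = 0.25, resp_amp = 0.001,
                        mayer_hz = 0.1, mayer_amp = 8e-4,
                        drift_sd = 5e-5, white_sd = 1.5e-3,
                        spike_rate = 1, spike_mag = 0.03,
                        shift_rate = 0.2, shift_mag = 0.05,
                        bad_white_sd = 0.3) {
  vals <- c(cardiac_amp, resp_amp, mayer_amp, drift_sd, white_sd,
            spike_rate, spike_mag, shift_rate, shift_mag, bad_white_sd)
  if (any(vals < 0)) nw_stop("noise amplitudes/rates must be >= 0",
                             "invalid_noise")
  structure(list(cardiac_hz = cardiac_hz, cardiac_amp = cardiac_amp,
                 resp_hz = resp_hz, resp_amp = resp_amp,
                 mayer_hz = mayer_hz, mayer_amp = mayer_amp,
                 drift_sd = drift_sd, white_sd = white_sd,
                 spike_rate = spike_rate, spike_mag = spike_mag,
                 shift_rate = shift_rate, shift_mag = shift_mag,
                 bad_white_sd = bad_white_sd),
            class = "noise_model")
}

#' Silent noise model
#'
#' All noise components zero; used for exact-recovery tests.
#' @return A `noise_model`.
#' @export
noise_none <- function() {
  noise_model(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0, drift_sd = 0,
              white_sd = 0, spike_rate = 0, spike_mag = 0, shift_rate = 0,
              shift_mag = 0, bad_white_sd = 0)
}

#' Ground truth for one simulated subject recording
#'
#' @param montage A `nirs_montage`.
#' @param hbo_amp Per-channel oxy-Hb plateau amplitude in uM (length =
#'   number of channels, montage order).
#' @param hbr_ratio Deoxy-Hb amplitude as a fraction of `hbo_amp`.
#' @param bad_channels Character vector of channel ids injected as bad.
#' @param bad_reason Named character ("gain", "snr" or "gain+snr") per bad
#'   channel; defaults to "gain" for all.
#' @return A list of class `ground_truth`.
#' @export
ground_truth <- function(montage, hbo_amp, hbr_ratio = -1 / 3,
                         bad_channels = character(0), bad_reason = NULL) {
  if (length(hbo_amp) != nrow(montage)) {
    nw_stop("hbo_amp must have one value per montage channel",
            "configuration_error")
  }
  if (!all(is.finite(hbo_amp))) {
    nw_stop("amplitudes must be finite", "configuration_error")
  }
  if (!all(bad_channels %in% montage$channel)) {
    nw_stop("bad_channels must be a subset of montage channels",
            "configuration_error")
  }
  if (is.null(bad_reason)) {
    bad_reason <- stats::setNames(rep("gain", length(bad_channels)),
                                  bad_channels)
  }
  structure(list(hbo_amp = stats::setNames(hbo_amp, montage$channel),
                 hbr_amp = stats::setNames(hbo_amp * hbr_ratio,
                                           montage$channel),
                 hbr_ratio = hbr_ratio,
                 bad_channels = bad_channels, bad_reason = bad_reason),
            class = "ground_truth")
}

#' Simulate one raw dual-wavelength recording
#'
#' Reproducible forward simulation for one subject at one timepoint: the
#' output is a pure function of the inputs and `seed`. Injected bad
#' channels receive hardware gain 8 (reason "gain") and/or inflated white
#' noise (reason "snr"), so they violate the default QC thresholds by
#' construction; all other channels have gain 1.
#'
#' @param montage A `nirs_montage`.
#' @param design A `nirs_design`.
#' @param truth A [ground_truth()] object (channel set must match the
#'   montage).
#' @param noise A [noise_model()].
#' @param seed Integer seed.
#' @param subject_id,timepoint Metadata carried on the recording.
#' @param i0 Baseline detector intensity (arbitrary detector units).
#' @param mbll An [mbll_params()] object for the forward model.
#' @return A list of class `nirs_recording`: `montage`, `design`,
#'   `wavelengths`, `intensity` (named list of n x channels matrices, one
#'   per wavelength), `gains`, `sampling_rate`, `subject_id`, `timepoint`,
#'   `seed`.
#' @export
simulate_subject_recording <- function(montage, design, truth,
                                       noise = noise_model(), seed,
                                       subject_id = "S01", timepoint = "T0",
                                       i0 = 1.0, mbll = mbll_params()) {
  if (!identical(names(truth$hbo_amp), montage$channel)) {
    nw_stop("ground truth channels do not match the montage",
            "configuration_error")
  }
  set.seed(seed)
  n <- design$n_samples
  nc <- nrow(montage)
  t <- design_times(design)
  resp <- task_response(design)
  hbo <- outer(resp, unname(truth$hbo_amp))
  hbr <- outer(resp, unname(truth$hbr_amp))
  od <- hemoglobin_to_od(hbo, hbr, mbll)

  gains <- rep(1L, nc)
  white <- rep(noise$white_sd, nc)
  for (ch in truth$bad_channels) {
    i <- match(ch, montage$channel)
    reasons <- strsplit(truth$bad_reason[[ch]], "+", fixed = TRUE)[[1]]
    if ("gain" %in% reasons) gains[i] <- 8L
    if ("snr" %in% reasons) white[i] <- noise$bad_white_sd
  }

  dur_min <- design$total_s / 60
  make_noise <- function(ch) {
    osc <- noise$cardiac_amp * sin(2 * pi * noise$cardiac_hz * t +
                                     runif(1, 0, 2 * pi)) +
      noise$resp_amp * sin(2 * pi * noise$resp_hz * t + runif(1, 0, 2 * pi)) +
      noise$mayer_amp * sin(2 * pi * noise$mayer_hz * t + runif(1, 0, 2 * pi))
    drift <- if (noise$drift_sd > 0) cumsum(rnorm(n, 0, noise$drift_sd)) else 0
    wn <- if (white[ch] > 0) rnorm(n, 0, white[ch]) else 0
    x <- osc + drift + wn
    n_spk <- if (noise$spike_rate > 0) rpois(1, noise$spike_rate * dur_min)
             else 0
    if (n_spk > 0) {
      pos <- sample.int(n, n_spk)
      x[pos] <- x[pos] + noise$spike_mag * sample(c(-1, 1), n_spk, TRUE) *
        runif(n_spk, 0.8, 1.5)
    }
    n_shift <- if (noise$shift_rate > 0) rpois(1, noise$shift_rate * dur_min)
               else 0
    if (n_shift > 0) {
      pos <- sample(seq(10, n - 10), n_shift)
      for (p in pos) {
        x[p:n] <- x[p:n] + noise$shift_mag * sample(c(-1, 1), 1) *
          runif(1, 0.8, 1.5)
      }
    }
    x
  }

  intensity <- list()
  for (w in c("od_760", "od_850")) {
    wl <- if (w == "od_760") "760" else "850"
    m <- od[[w]]
    for (ch in seq_len(nc)) m[, ch] <- m[, ch] + make_noise(ch)
    intensity[[wl]] <- i0 * 10^(-m)
  }

  structure(list(
    montage = montage, design = design, wavelengths = c(760, 850),
    intensity = intensity, gains = gains,
    sampling_rate = design$sampling_rate,
    subject_id = subject_id, timepoint = timepoint, seed = seed
  ), class = "nirs_recording")
}

# ---- cohort scenario machinery --------------------------------------------

# Lognormal multiplier with mean 1 and coefficient of variation cv.
rlnorm_mean1 <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw one subject's profile (side, clinical covariates per timepoint,
# training log, per-channel baseline amplitudes). Shared by the full raw
# generator and the fast table-level generator so both state the same world.
draw_subject_profile <- function(scenario, montage, cohort, arm, id) {
  healthy <- cohort == "healthy"
  side <- if (healthy) sample(c("right", "left"), 1, prob = c(0.9, 0.1))
          else sample(c("left", "right"), 1)
  mapping <- assign_affected_hemisphere(side)
  amp_mean <- if (healthy) scenario$amp_mean$healthy else scenario$amp_mean$pwms
  subj_scale <- rlnorm_mean1(1, unname(
    scenario$subject_cv[[if (healthy) "healthy" else "pwms"]]))
  ch_scale <- rlnorm_mean1(nrow(montage), scenario$channel_cv)
  hemi_amp <- ifelse(montage$hemisphere == mapping[["MAff"]],
                     amp_mean[["maff"]], amp_mean[["laff"]])
  base_amp <- hemi_amp * subj_scale * ch_scale

  if (healthy) {
    clin <- list(
      edss = NA_real_, phenotype = "none",
      age = round(clip(rnorm(1, 56, 10), 25, 75)),
      sex = sample(c("M", "F"), 1),
      t25fw = c(T0 = clip(rnorm(1, 1.4, 0.2), 0.8, 2.2)),
      mwd6 = c(T0 = clip(rnorm(1, 550, 80), 300, 800)),
      bbs = c(T0 = round(clip(rnorm(1, 55, 1.5), 45, 56)))
    )
    training <- NULL
  } else {
    ragt <- arm == "RAGT"
    t0_speed <- clip(rnorm(1, if (ragt) 0.50 else 0.65,
                           if (ragt) 0.20 else 0.40), 0.1, 1.8)
    t0_mwd <- clip(rnorm(1, if (ragt) 118 else 171,
                         if (ragt) 55 else 124), 20, 550)
    t0_bbs <- round(clip(rnorm(1, if (ragt) 32 else 36, 13), 3, 56))
    # functional gains over rehabilitation (both arms improve; no
    # between-arm difference), half realized by mid-treatment
    sp_gain <- clip(rnorm(1, 0.09, 0.10), -0.1, 0.35)
    mw_gain <- clip(rnorm(1, 0.14, 0.12), -0.1, 0.45)
    bb_gain <- round(clip(rnorm(1, 2, 2), -2, 7))
    clin <- list(
      edss = clip(round(rnorm(1, 6.3, 0.3) * 2) / 2, 6.0, 7.0),
      phenotype = sample(c("primary progressive", "secondary progressive"),
                         1, prob = if (ragt) c(0.5, 0.5) else c(0.33, 0.67)),
      age = round(clip(rnorm(1, 56, 10), 25, 70)),
      sex = sample(c("M", "F"), 1,
                   prob = if (ragt) c(0.42, 0.58) else c(0.67, 0.33)),
      t25fw = c(T0 = t0_speed, T1 = t0_speed * (1 + sp_gain / 2),
                T2 = t0_speed * (1 + sp_gain)),
      mwd6 = c(T0 = t0_mwd, T1 = t0_mwd * (1 + mw_gain / 2),
               T2 = t0_mwd * (1 + mw_gain)),
      bbs = c(T0 = t0_bbs, T1 = round(clip(t0_bbs + bb_gain / 2, 0, 56)),
              T2 = round(clip(t0_bbs + bb_gain, 0, 56)))
    )
    n_sessions <- 12L
    if (ragt) {
      training <- training_log(
        speeds = clip(rnorm(n_sessions, 0.45, 0.08), 0.15, 0.8),
        bws = clip(rnorm(n_sessions, 0.40, 0.08), 0.2, 0.5),
        arm = "RAGT", reference_speed = t0_speed)
    } else {
      training <- training_log(
        speeds = clip(t0_speed * 0.85 * rnorm(n_sessions, 1, 0.15),
                      0.05, 2.5),
        arm = "OW", reference_speed = t0_speed)
    }
  }
  list(id = id, cohort = cohort, arm = arm, side = side, mapping = mapping,
       base_amp = base_amp, clin = clin, training = training)
}

# Per-timepoint amplitude multiplier for one patient. The RAGT arm's
# end-of-treatment multiplier is (optionally) coupled to training
# intensity: subjects trained at lower relative intensity decrease more.
timepoint_multiplier <- function(scenario, arm, timepoint, rti = NULL) {
  m <- scenario$multipliers[[arm]][[timepoint]]
  if (timepoint != "T0") {
    m <- m * exp(rnorm(1, 0, scenario$mult_jitter_sd))
    if (arm == "RAGT" && scenario$rti_coupling > 0 && !is.null(rti)) {
      m <- m + scenario$rti_coupling * (rti - 0.5) *
        (if (timepoint == "T2") 1 else 0.5)
    }
  }
  max(m, 0.02)
}

#' Simulate a full cohort of raw recordings
#'
#' Generates one raw recording per subject per scheduled timepoint
#' (patients at T0/T1/T2, healthy controls at T0 only) together with
#' subject metadata, per-recording ground truth and per-patient training
#' logs. Patient amplitudes are drawn above healthy amplitudes and are
#' larger in the more affected hemisphere; longitudinal multipliers are
#' applied at T1/T2 per treatment arm.
#'
#' @param scenario A [scenario_config()].
#' @param montage,design Structural objects (defaults used when `NULL`).
#' @return A list with elements `recordings` (list of `nirs_recording`),
#'   `meta` (list of `subject_meta`), `truths` (named by
#'   "subject.timepoint"), `training` (named list of training logs),
#'   `scenario`.
#' @export
simulate_cohort <- function(scenario = scenario_study_like(),
                            montage = NULL, design = NULL) {
  montage <- montage %||% build_default_montage()
  design <- design %||% build_task_design()
  set.seed(scenario$seed)

  subjects <- c(
    if (scenario$n_ragt > 0)
      lapply(seq_len(scenario$n_ragt), function(i)
        list(id = sprintf("R%02d", i), cohort = "PwMS", arm = "RAGT")),
    if (scenario$n_ow > 0)
      lapply(seq_len(scenario$n_ow), function(i)
        list(id = sprintf("O%02d", i), cohort = "PwMS", arm = "OW")),
    if (scenario$n_healthy > 0)
      lapply(seq_len(scenario$n_healthy), function(i)
        list(id = sprintf("H%02d", i), cohort = "healthy", arm = "none"))
  )

  recordings <- list()
  truths <- list()
  meta <- list()
  training <- list()
  for (s in subjects) {
    prof <- draw_subject_profile(scenario, montage, s$cohort, s$arm, s$id)
    tps <- if (s$cohort == "healthy") "T0" else c("T0", "T1", "T2")
    rti <- if (!is.null(prof$training)) {
      compute_rti(prof$training)
    } else NULL
    meta[[s$id]] <- subject_meta(
      subject_id = s$id, cohort = s$cohort, treatment = s$arm,
      timepoints = tps, edss = prof$clin$edss,
      phenotype = prof$clin$phenotype, side = prof$side,
      age = prof$clin$age, sex = prof$clin$sex,
      t25fw_speed = prof$clin$t25fw, mwd6 = prof$clin$mwd6,
      bbs = prof$clin$bbs)
    if (!is.null(prof$training)) training[[s$id]] <- prof$training
    for (tp in tps) {
      mult <- timepoint_multiplier(scenario, s$arm, tp, rti)
      bad <- montage$channel[runif(nrow(montage)) < scenario$bad_channel_prob]
      reason <- stats::setNames(
        sample(c("gain", "snr", "gain+snr"), length(bad), TRUE,
               prob = c(0.45, 0.45, 0.1)), bad)
      truth <- ground_truth(montage, prof$base_amp * mult,
                            hbr_ratio = scenario$hbr_ratio,
                            bad_channels = bad, bad_reason = reason)
      key <- paste(s$id, tp, sep = ".")
      rec_seed <- sample.int(.Machine$integer.max - 1, 1)
      truths[[key]] <- truth
      recordings[[key]] <- simulate_subject_recording(
        montage, design, truth, scenario$noise, seed = rec_seed,
        subject_id = s$id, timepoint = tp)
    }
  }
  list(recordings = recordings, meta = meta, truths = truths,
       training = training, scenario = scenario)
}

#' Noise-free pipeline response per unit amplitude
#'
#' The walking-block AUC (mean over blocks, in uM-samples) produced by the
#' full noise-free pipeline for a channel of unit (1 uM) amplitude. Because
#' every pipeline stage is linear, a channel with amplitude `a` yields AUC
#' `a * unit_channel_auc(...)`; the fast cohort-table generator uses this
#' to map sampled amplitudes to biomarker values without re-simulating
#' optics.
#'
#' @param design A `nirs_design`.
#' @param filtered Apply the default bandpass (TRUE, the pipeline default)
#'   or bypass it.
#' @param band Band edges in Hz.
#' @return Scalar unit AUC (uM-samples per uM of amplitude).
#' @export
unit_channel_auc <- function(design = build_task_design(), filtered = TRUE,
                             band = c(0.01, 0.20)) {
  r <- task_response(design)
  if (filtered) r <- bandpass_filter(r, band[1], band[2],
                                     design$sampling_rate)
  w <- segment_blocks(design, design$n_samples)
  mean_block_auc(vapply(w, function(ix) block_auc(r, ix), numeric(1)))
}

#' Fast subject-level cohort table generator
#'
#' Draws the same subject-level quantities as [simulate_cohort()] (channel
#' amplitudes, clinical covariates, training logs) but maps amplitudes to
#' biomarker values through the deterministic noise-free pipeline response
#' ([unit_channel_auc()]) instead of simulating raw optics, making large
#' replicate counts affordable for calibration studies of the statistical
#' battery. Bad channels are not injected on this path.
#'
#' @param scenario A [scenario_config()].
#' @param au_scale Arbitrary-unit scale, see [compute_activation()].
#' @param filtered Use the filtered pipeline response.
#' @return A cohort table data.frame (one row per subject x timepoint) with
#'   the schema required by [analyze_cohort()].
#' @export
simulate_cohort_table <- function(scenario = scenario_study_like(),
                                  au_scale = 1000, filtered = TRUE) {
  montage <- build_default_montage()
  design <- build_task_design()
  u <- unit_channel_auc(design, filtered = filtered)
  set.seed(scenario$seed)

  subjects <- c(
    if (scenario$n_ragt > 0)
      lapply(seq_len(scenario$n_ragt), function(i)
        list(id = sprintf("R%02d", i), cohort = "PwMS", arm = "RAGT")),
    if (scenario$n_ow > 0)
      lapply(seq_len(scenario$n_ow), function(i)
        list(id = sprintf("O%02d", i), cohort = "PwMS", arm = "OW")),
    if (scenario$n_healthy > 0)
      lapply(seq_len(scenario$n_healthy), function(i)
        list(id = sprintf("H%02d", i), cohort = "healthy", arm = "none"))
  )

  rows <- list()
  for (s in subjects) {
    prof <- draw_subject_profile(scenario, montage, s$cohort, s$arm, s$id)
    tps <- if (s$cohort == "healthy") "T0" else c("T0", "T1", "T2")
    rti <- if (!is.null(prof$training)) compute_rti(prof$training) else
      NA_real_
    maff_ch <- montage$hemisphere == prof$mapping[["MAff"]]
    for (tp in tps) {
      mult <- timepoint_multiplier(scenario, s$arm, tp,
                                   if (is.na(rti)) NULL else rti)
      amp <- prof$base_amp * mult
      maff <- sum(amp[maff_ch]) * u * au_scale
      laff <- sum(amp[!maff_ch]) * u * au_scale
      rows[[length(rows) + 1]] <- data.frame(
        subject = s$id, cohort = s$cohort, treatment = s$arm,
        timepoint = tp, tot_auc = maff + laff, maff_auc = maff,
        laff_auc = laff, edss = prof$clin$edss, age = prof$clin$age,
        sex = prof$clin$sex, phenotype = prof$clin$phenotype,
        t25fw_speed = unname(prof$clin$t25fw[tp]),
        mwd6 = unname(prof$clin$mwd6[tp]), bbs = unname(prof$clin$bbs[tp]),
        rti = rti, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  tab$rti_category <- NA_character_
  for (arm in c("RAGT", "OW")) {
    sel <- tab$treatment == arm
    if (any(sel)) {
      arm_rti <- unique(tab[sel, c("subject", "rti")])$rti
      tab$rti_category[sel] <- vapply(
        tab$rti[sel], function(r) dichotomize_rti(arm_rti, r), character(1))
    }
  }
  tab
}
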