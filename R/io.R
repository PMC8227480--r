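# File formats and the pipeline driver. Recordings live in an open text
# format: a wide tab-separated table (time, then <channel>_<wavelength>
# intensity columns, 17 significant digits) plus a JSON sidecar carrying
# montage, design, gains, wavelengths and provenance.

#' Write / read a raw recording
#'
#' `write_recording()` produces `<path>.tsv` (wide intensity table) and
#' `<path>.json` (sidecar). `read_recording()` reverses it; the round trip
#' reproduces every series to full double precision and all metadata.
#'
#' @param rec A `nirs_recording`.
#' @param path Output path stem (without extension).
#' @return `write_recording`: the path stem, invisibly. `read_recording`:
#'   a `nirs_recording`.
#' @export
write_recording <- function(rec, path) {
  t <- design_times(rec$design)
  cols <- list(time = sprintf("%.17g", t))
  for (wl in names(rec$intensity)) {
    m <- rec$intensity[[wl]]
    for (i in seq_len(ncol(m))) {
      cols[[paste0(rec$montage$channel[i], "_", wl)]] <-
        sprintf("%.17g", m[, i])
    }
  }
  df <- as.data.frame(cols, check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", row.names = FALSE,
                     quote = FALSE)
  sidecar <- list(
    montage = as.data.frame(rec$montage),
    design = rec$design[c("sampling_rate", "cycles", "walk_s", "rest_s",
                          "baseline_s")],
    wavelengths = rec$wavelengths,
    gains = rec$gains,
    sampling_rate = rec$sampling_rate,
    subject_id = rec$subject_id,
    timepoint = rec$timepoint,
    seed = rec$seed
  )
  writeLines(jsonlite::toJSON(sidecar, digits = NA, auto_unbox = TRUE),
             paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  if (!file.exists(json)) {
    nw_stop(paste("missing sidecar:", json), "format_error")
  }
  if (!file.exists(tsv)) nw_stop(paste("missing table:", tsv), "format_error")
  side <- jsonlite::fromJSON(readLines(json))
  montage <- side$montage
  class(montage) <- c("nirs_montage", "data.frame")
  validate_montage(montage)
  design <- build_task_design(side$design$sampling_rate, side$design$cycles,
                              side$design$walk_s, side$design$rest_s,
                              side$design$baseline_s)
  tab <- utils::read.delim(tsv, check.names = FALSE)
  if (is.unsorted(tab$time, strictly = TRUE)) {
    nw_stop(paste("non-monotone time column in", tsv), "format_error")
  }
  wls <- as.character(side$wavelengths)
  intensity <- list()
  for (wl in wls) {
    want <- paste0(montage$channel, "_", wl)
    absent <- setdiff(want, names(tab))
    if (length(absent)) {
      nw_stop(paste0("column(s) missing from ", tsv, ": ",
                     paste(absent, collapse = ", ")), "format_error")
    }
    intensity[[wl]] <- as.matrix(tab[want])
    dimnames(intensity[[wl]]) <- NULL
  }
  structure(list(
    montage = montage, design = design, wavelengths = side$wavelengths,
    intensity = intensity, gains = side$gains,
    sampling_rate = side$sampling_rate,
    subject_id = side$subject_id, timepoint = side$timepoint,
    seed = side$seed
  ), class = "nirs_recording")
}

#' Process one raw recording to hemoglobin concentration changes
#'
#' The single-subject pipeline: channel QC, conversion to optical-density
#' changes against the baseline reference, artifact cleaning
#' (discontinuities then spikes, applied in the OD domain where motion
#' artifacts are additive), zero-phase bandpass filtering, and
#' Beer-Lambert inversion.
#' Excluded channels carry NA concentration series. Cleaning and filtering
#' can be bypassed for exact-recovery analyses.
#'
#' @param raw A `nirs_recording`.
#' @param thresholds QC thresholds ([qc_thresholds()]).
#' @param mbll [mbll_params()] used for the inversion.
#' @param band Bandpass edges in Hz; `NULL` bypasses the filter.
#' @param clean Apply artifact cleaning.
#' @return A list of class `nirs_hemo`: `hbo`, `hbr` (n x channels, uM),
#'   `montage`, `design`, `retained`, `qc`, `subject_id`, `timepoint`.
#'   When the subject fails QC the `hbo`/`hbr` fields are `NULL` and
#'   `excluded` is TRUE.
#' @export
process_recording <- function(raw, thresholds = qc_thresholds(),
                              mbll = mbll_params(), band = c(0.01, 0.20),
                              clean = TRUE) {
  qc <- qc_channels(raw, thresholds)
  if (attr(qc, "subject_status") == "excluded") {
    return(structure(list(hbo = NULL, hbr = NULL, montage = raw$montage,
                          design = raw$design, retained = qc_retained(qc),
                          qc = qc, excluded = TRUE,
                          subject_id = raw$subject_id,
                          timepoint = raw$timepoint),
                     class = "nirs_hemo"))
  }
  retained <- qc_retained(qc)
  n <- nrow(raw$intensity[[1]])
  nc <- ncol(raw$intensity[[1]])
  od <- list()
  for (wl in names(raw$intensity)) {
    m <- raw$intensity[[wl]]
    refs <- baseline_reference(m, raw$design)
    odm <- intensity_to_od(m[, retained, drop = FALSE], refs[retained])
    if (clean) for (i in seq_len(ncol(odm))) odm[, i] <- clean_series(odm[, i])
    if (!is.null(band)) {
      odm <- bandpass_filter(odm, band[1], band[2], raw$sampling_rate)
    }
    full <- matrix(NA_real_, n, nc)
    full[, retained] <- odm
    od[[wl]] <- full
  }
  hb <- od_to_hemoglobin(od[["760"]], od[["850"]], mbll)
  structure(list(hbo = hb$hbo, hbr = hb$hbr, montage = raw$montage,
                 design = raw$design, retained = retained, qc = qc,
                 excluded = FALSE, subject_id = raw$subject_id,
                 timepoint = raw$timepoint),
            class = "nirs_hemo")
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with validated defaults.
#'
#' @param scenario A [scenario_config()] driving the simulation.
#' @param thresholds QC thresholds.
#' @param mbll Beer-Lambert parameters.
#' @param band Bandpass edges (Hz) or `NULL`.
#' @param clean Apply artifact cleaning.
#' @param rescale_missing See [aggregate_activation()].
#' @param au_scale See [compute_activation()].
#' @param bws_correction See [compute_rti()].
#' @param alpha Significance level of the statistical report.
#' @param out_dir Optional output directory for the cohort table and
#'   reports.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = scenario_study_like(),
                            thresholds = qc_thresholds(),
                            mbll = mbll_params(), band = c(0.01, 0.20),
                            clean = TRUE, rescale_missing = FALSE,
                            au_scale = 1000,
                            bws_correction = "load_fraction",
                            alpha = 0.05, out_dir = NULL) {
  if (!inherits(scenario, "scenario_config")) {
    nw_stop("scenario must be a scenario_config", "invalid_config")
  }
  structure(list(scenario = scenario, thresholds = thresholds, mbll = mbll,
                 band = band, clean = clean,
                 rescale_missing = rescale_missing, au_scale = au_scale,
                 bws_correction = bws_correction, alpha = alpha,
                 out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Simulate (or accept) a cohort, then for every recording: QC, artifact
#' cleaning, bandpass, Beer-Lambert inversion, and the walking-block AUC
#' biomarker; assemble the cohort table (subjects failing QC at any
#' timepoint are excluded and logged), score relative training intensity
#' and dichotomize it within each treatment arm, and run the statistical
#' battery. Fully deterministic under the scenario seed.
#'
#' @param config A [pipeline_config()].
#' @param cohort Optional pre-simulated output of [simulate_cohort()]
#'   (bypasses simulation).
#' @return A list: `table` (cohort table), `report` (statistical report, or
#'   `NULL` when the table is too small), `exclusions` (data.frame),
#'   `activations` (named list of `nirs_activation`), `qc` (named list of
#'   QC reports), `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL) {
  sim <- cohort %||% simulate_cohort(config$scenario)
  qc_reports <- list()
  activations <- list()
  exclusions <- list()
  excluded_subjects <- character(0)

  for (key in names(sim$recordings)) {
    raw <- sim$recordings[[key]]
    hemo <- process_recording(raw, config$thresholds, config$mbll,
                              config$band, config$clean)
    qc_reports[[key]] <- hemo$qc
    if (hemo$excluded) {
      excluded_subjects <- union(excluded_subjects, raw$subject_id)
      exclusions[[length(exclusions) + 1]] <- data.frame(
        subject = raw$subject_id, timepoint = raw$timepoint,
        bad_channels = attr(hemo$qc, "bad_count"),
        reason = sprintf("more than %d low-quality channels",
                         config$thresholds$max_bad),
        stringsAsFactors = FALSE)
      next
    }
    meta <- sim$meta[[raw$subject_id]]
    activations[[key]] <- compute_activation(
      hemo, meta$side, hemo$qc, config$rescale_missing, config$au_scale)
  }

  rti_vals <- vapply(sim$training, compute_rti, numeric(1),
                     bws_correction = config$bws_correction)

  rows <- list()
  for (key in names(activations)) {
    act <- activations[[key]]
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    sid <- parts[1]
    tp <- parts[2]
    if (sid %in% excluded_subjects) next
    meta <- sim$meta[[sid]]
    rows[[length(rows) + 1]] <- data.frame(
      subject = sid, cohort = meta$cohort, treatment = meta$treatment,
      timepoint = tp, tot_auc = act$tot_auc, maff_auc = act$maff_auc,
      laff_auc = act$laff_auc, edss = meta$edss, age = meta$age,
      sex = meta$sex, phenotype = meta$phenotype,
      t25fw_speed = unname(meta$t25fw_speed[tp]),
      mwd6 = unname(meta$mwd6[tp]), bbs = unname(meta$bbs[tp]),
      rti = if (sid %in% names(rti_vals)) rti_vals[[sid]] else NA_real_,
      maff_retained = act$retained_per_hemisphere[["MAff"]],
      laff_retained = act$retained_per_hemisphere[["LAff"]],
      stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab)) {
    tab$rti_category <- NA_character_
    for (arm in c("RAGT", "OW")) {
      sel <- tab$treatment == arm & !is.na(tab$rti)
      if (any(sel)) {
        arm_rti <- rti_vals[unique(tab$subject[sel])]
        tab$rti_category[sel] <- vapply(
          tab$rti[sel], function(r) dichotomize_rti(arm_rti, r),
          character(1))
      }
    }
  }
  exclusions <- if (length(exclusions)) do.call(rbind, exclusions) else
    data.frame(subject = character(0), timepoint = character(0),
               bad_channels = integer(0), reason = character(0))

  report <- NULL
  if (!is.null(tab) && sum(tab$cohort == "PwMS" & tab$timepoint == "T0") >= 3) {
    report <- tryCatch(analyze_cohort(tab, config$alpha),
                       nirswalk_error = function(e) NULL)
  }

  if (!is.null(config$out_dir) && !is.null(tab)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(tab, file.path(config$out_dir, "cohort_table.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(report)) {
      utils::write.table(report, file.path(config$out_dir, "stats_report.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      writeLines(jsonlite::toJSON(report, digits = NA, auto_unbox = TRUE),
                 file.path(config$out_dir, "stats_report.json"))
    }
    utils::write.table(exclusions, file.path(config$out_dir, "exclusions.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }

  list(table = tab, report = report, exclusions = exclusions,
       activations = activations, qc = qc_reports, config = config)
}
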