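# Relative training intensity (RTI): mean training speed relative to the
# subject's reference gait speed, corrected for body-weight support in the
# robot-assisted arm, and dichotomized at the treatment-arm median.

#' Construct a training log
#'
#' @param speeds Per-session mean walking speed (m/s, >= 0; >= 1 session).
#' @param bws Per-session body-weight-support fraction in [0, 1]
#'   (robot-assisted arm only; `NULL` otherwise).
#' @param arm Treatment arm: "RAGT" or "OW".
#' @param reference_speed Reference gait speed (m/s): the baseline timed
#'   25-foot walk speed, or a declared highest attainable speed.
#' @return A list of class `training_log`.
#' @export
training_log <- function(speeds, bws = NULL, arm, reference_speed) {
  if (length(speeds) < 1 || any(speeds < 0)) {
    nw_stop("need >= 1 session with non-negative speeds", "invalid_input")
  }
  if (!arm %in% c("RAGT", "OW")) {
    nw_stop("arm must be 'RAGT' or 'OW'", "invalid_input")
  }
  if (!is.null(bws)) {
    if (length(bws) != length(speeds) || any(bws < 0 | bws > 1)) {
      nw_stop("bws must match sessions and lie in [0,1]", "invalid_input")
    }
  }
  structure(list(speeds = speeds, bws = bws, arm = arm,
                 reference_speed = reference_speed),
            class = "training_log")
}

#' Compute relative training intensity
#'
#' RTI = mean session speed / reference speed. For the robot-assisted arm
#' the ratio is corrected for body-weight support; with the default
#' `"load_fraction"` correction it is multiplied by the mean carried-load
#' fraction (1 - BWS), so more support means lower intensity (at 50%
#' support both conventions multiply by 0.50). The overground arm has no
#' correction.
#'
#' @param log A [training_log()].
#' @param bws_correction "load_fraction" (default) multiplies by
#'   mean(1 - BWS); "support_fraction" multiplies by mean(BWS).
#' @return RTI, a dimensionless non-negative scalar.
#' @export
compute_rti <- function(log, bws_correction = c("load_fraction",
                                                "support_fraction")) {
  bws_correction <- match.arg(bws_correction)
  if (!is.numeric(log$reference_speed) || log$reference_speed <= 0) {
    nw_stop("reference speed must be positive", "invalid_input")
  }
  rti <- mean(log$speeds) / log$reference_speed
  if (log$arm == "RAGT" && !is.null(log$bws)) {
    corr <- if (bws_correction == "load_fraction") mean(1 - log$bws)
            else mean(log$bws)
    rti <- rti * corr
  }
  rti
}

#' Dichotomize an RTI value at the cohort median
#'
#' Two-quantile split with the median as the cutoff: "low" below the
#' median, "high" at or above it (ties at the median are classified high).
#' The median of an even-sized cohort is the midpoint of the two central
#' order statistics. Dichotomization is intended per treatment arm.
#'
#' @param cohort_rtis RTI values of the subject's treatment arm (non-empty).
#' @param subject_rti The subject's RTI.
#' @return "high" or "low".
#' @export
dichotomize_rti <- function(cohort_rtis, subject_rti) {
  if (length(cohort_rtis) == 0) nw_stop("empty cohort", "invalid_input")
  if (subject_rti < stats::median(cohort_rtis)) "low" else "high"
}
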