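# Modified Beer-Lambert law: raw intensity -> optical density changes ->
# oxy-/deoxy-hemoglobin concentration changes.

#' Modified Beer-Lambert law parameters
#'
#' Holds the 2x2 molar extinction coefficient matrix (rows = wavelengths
#' 760/850 nm, columns = HbO/HbR, units cm^-1 (mol/L)^-1, defaults from the
#' standard compiled hemoglobin spectra), the differential pathlength factor
#' per wavelength, and the source-detector separation. The forward
#' simulator and the inversion share this object, so round trips are exact
#' by construction.
#'
#' @param extinction 2x2 numeric matrix, rows wavelengths, cols c(HbO, HbR).
#' @param dpf Differential pathlength factor per wavelength (length 2).
#' @param separation_cm Source-detector separation in cm.
#' @param wavelengths Wavelengths in nm (metadata only).
#' @return A list of class `mbll_params`.
#' @export
mbll_params <- function(extinction = matrix(c(586, 1548.52,
                                              1058, 691.32),
                                            nrow = 2, byrow = TRUE,
                                            dimnames = list(c("760", "850"),
                                                            c("HbO", "HbR"))),
                        dpf = c(6.0, 6.0), separation_cm = 3.0,
                        wavelengths = c(760, 850)) {
  if (!is.matrix(extinction) || any(dim(extinction) != 2)) {
    nw_stop("extinction must be a 2x2 matrix", "invalid_mbll")
  }
  if (abs(det(extinction)) < .Machine$double.eps * max(abs(extinction))^2) {
    nw_stop("extinction matrix is singular", "invalid_mbll")
  }
  if (any(dpf <= 0) || separation_cm <= 0) {
    nw_stop("dpf and separation must be positive", "invalid_mbll")
  }
  structure(list(extinction = extinction, dpf = dpf,
                 separation_cm = separation_cm, wavelengths = wavelengths),
            class = "mbll_params")
}

#' Convert intensity to optical-density change
#'
#' dOD(t) = log10(reference / I(t)). The reference is conventionally the
#' mean intensity over the pre-task baseline window (see
#' [baseline_reference()]); with no baseline the whole-recording mean is
#' used.
#'
#' @param intensity Positive numeric vector or matrix (series per column).
#' @param reference Positive scalar, or one reference per column.
#' @return Optical-density change, same shape as `intensity`.
#' @export
intensity_to_od <- function(intensity, reference) {
  if (any(intensity <= 0)) {
    bad <- which(intensity <= 0)[1]
    nw_stop(sprintf("non-positive intensity at sample %d", bad),
            "invalid_signal")
  }
  if (any(reference <= 0)) nw_stop("reference must be positive", "invalid_signal")
  if (is.matrix(intensity) && length(reference) > 1) {
    log10(matrix(reference, nrow(intensity), ncol(intensity), byrow = TRUE) /
            intensity)
  } else {
    log10(reference / intensity)
  }
}

#' Baseline reference intensity
#'
#' Mean intensity over the pre-task baseline window (t < baseline_s); falls
#' back to the whole-recording mean when the design has no baseline.
#'
#' @param intensity Numeric vector or matrix (series per column).
#' @param design A `nirs_design`.
#' @return Scalar (vector input) or one reference per column.
#' @export
baseline_reference <- function(intensity, design) {
  m <- as.matrix(intensity)
  t <- (seq_len(nrow(m)) - 1) / design$sampling_rate
  idx <- if (design$baseline_s > 0) which(t < design$baseline_s) else
    seq_len(nrow(m))
  refs <- colMeans(m[idx, , drop = FALSE])
  if (is.matrix(intensity)) refs else unname(refs)
}

#' Invert optical density to hemoglobin concentration changes
#'
#' Solves, per sample, E %*% c(dHbO, dHbR) = c(dOD760/(d*DPF760),
#' dOD850/(d*DPF850)) with the exact 2x2 inverse; outputs are in micromolar.
#'
#' @param od_760,od_850 Equal-shape OD series (vector or matrix, series per
#'   column).
#' @param params An [mbll_params()] object.
#' @return List with `hbo` and `hbr` (uM), same shape as the inputs.
#' @export
od_to_hemoglobin <- function(od_760, od_850, params = mbll_params()) {
  if (length(od_760) != length(od_850)) {
    nw_stop("OD series must have equal length", "invalid_input")
  }
  E <- params$extinction
  Einv <- solve(E)
  d <- params$separation_cm
  r1 <- od_760 / (d * params$dpf[1])
  r2 <- od_850 / (d * params$dpf[2])
  hbo <- (Einv[1, 1] * r1 + Einv[1, 2] * r2) * 1e6
  hbr <- (Einv[2, 1] * r1 + Einv[2, 2] * r2) * 1e6
  list(hbo = hbo, hbr = hbr)
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (uM) to optical-density changes at
#' both wavelengths; the exact inverse of [od_to_hemoglobin()] under the
#' same parameters. Used by the synthetic generator.
#'
#' @param hbo,hbr Concentration series in uM (vector or matrix).
#' @param params An [mbll_params()] object.
#' @return List with `od_760` and `od_850`.
#' @export
hemoglobin_to_od <- function(hbo, hbr, params = mbll_params()) {
  E <- params$extinction
  d <- params$separation_cm
  list(
    od_760 = (E[1, 1] * hbo + E[1, 2] * hbr) * 1e-6 * d * params$dpf[1],
    od_850 = (E[2, 1] * hbo + E[2, 2] * hbr) * 1e-6 * d * params$dpf[2]
  )
}
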