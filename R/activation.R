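# The oxyhemoglobin walking-block AUC biomarker: per-channel block sums,
# mean of blocks, hemispheric aggregation into MAff/LAff/Tot.

#' Walking-block sample windows
#'
#' One half-open window [onset, onset + walk_s) per cycle, realized as the
#' sample indices k (0-based times k/fs) with onset <= k/fs < onset +
#' walk_s. A sample landing exactly on a boundary belongs to the next
#' phase. Returned indices are 1-based.
#'
#' @param design A `nirs_design`.
#' @param n_samples Recording length in samples.
#' @param fs Sampling rate (defaults to the design's).
#' @return List of integer index vectors, one per walking block.
#' @export
segment_blocks <- function(design, n_samples, fs = design$sampling_rate) {
  eps <- 1e-9
  t <- (seq_len(n_samples) - 1) / fs
  windows <- lapply(design$onsets, function(on) {
    which(t >= on - eps & t < on + design$walk_s - eps)
  })
  if (any(vapply(windows, length, integer(1)) == 0)) {
    nw_stop("empty walking-block window (degenerate design)",
            "invalid_design")
  }
  last_needed <- design$onsets[length(design$onsets)] + design$walk_s
  if ((n_samples - 1) / fs + 1 / fs < last_needed - eps) {
    nw_stop("walking block extends past the end of the recording",
            "invalid_design")
  }
  windows
}

#' Area under the curve of one walking block
#'
#' Plain sample sum of the oxy-Hb trace over the window (no time-step
#' weighting; sign preserved, so negative AUCs are legal). Units follow the
#' trace ("a.u.").
#'
#' @param series Numeric series.
#' @param window Integer sample indices.
#' @return Scalar AUC.
#' @export
block_auc <- function(series, window) {
  if (length(window) == 0) nw_stop("empty window", "invalid_input")
  if (any(window < 1 | window > length(series))) {
    nw_stop("window indices outside the series", "invalid_input")
  }
  sum(series[window])
}

#' Mean of per-block AUCs
#'
#' @param per_block_aucs Numeric vector (>= 1 value).
#' @return Arithmetic mean.
#' @export
mean_block_auc <- function(per_block_aucs) {
  if (length(per_block_aucs) == 0) nw_stop("no block AUCs", "invalid_input")
  mean(per_block_aucs)
}

#' Map limb side to more/less affected hemisphere
#'
#' The hemisphere contralateral to the more impaired limb (patients) or to
#' the dominant limb (healthy controls) is the more affected (MAff)
#' hemisphere; the other is the less affected (LAff).
#'
#' @param side "left" or "right": the more-impaired (or dominant) limb.
#' @return Named character vector c(MAff = ..., LAff = ...).
#' @export
assign_affected_hemisphere <- function(side) {
  if (length(side) != 1 || is.na(side) || !side %in% c("left", "right")) {
    nw_stop("limb side must be 'left' or 'right'", "invalid_metadata")
  }
  maff <- if (side == "right") "left" else "right"
  c(MAff = maff, LAff = setdiff(c("left", "right"), maff))
}

#' Aggregate per-channel AUCs into the hemispheric biomarker
#'
#' Hemisphere AUC = sum over retained channels of the channel mean-of-block
#' AUCs in that hemisphere; Tot = MAff + LAff exactly. With
#' `rescale_missing`, each hemisphere sum is multiplied by (channels per
#' hemisphere) / (retained channels in that hemisphere) to compensate for
#' QC-excluded channels (default off: the biomarker is defined over all 48
#' channels).
#'
#' @param channel_aucs Named numeric vector of per-channel mean AUCs
#'   (montage order, names = channel ids).
#' @param montage A `nirs_montage`.
#' @param mapping Output of [assign_affected_hemisphere()].
#' @param qc A `nirs_qc` report (optional: `NULL` retains all channels).
#' @param rescale_missing Rescale hemisphere sums for excluded channels.
#' @param block_aucs Optional per-channel x per-block AUC matrix carried on
#'   the result.
#' @return A list of class `nirs_activation` with fields `channel_aucs`,
#'   `block_aucs`, `maff_auc`, `laff_auc`, `tot_auc`, `mapping`,
#'   `retained_per_hemisphere`, `rescaled`.
#' @export
aggregate_activation <- function(channel_aucs, montage, mapping, qc = NULL,
                                 rescale_missing = FALSE,
                                 block_aucs = NULL) {
  if (!is.null(qc) && attr(qc, "subject_status") == "excluded") {
    nw_stop("subject failed quality control", "invalid_subject")
  }
  retained <- if (is.null(qc)) rep(TRUE, nrow(montage)) else qc_retained(qc)
  hemi_sum <- function(h) {
    sel <- montage$hemisphere == h & retained
    n_ret <- sum(sel)
    if (n_ret == 0) {
      nw_stop(sprintf("no retained channels in %s hemisphere", h),
              "invalid_subject")
    }
    s <- sum(channel_aucs[montage$channel[sel]])
    if (rescale_missing) s <- s * sum(montage$hemisphere == h) / n_ret
    list(sum = s, n = n_ret)
  }
  maff <- hemi_sum(mapping[["MAff"]])
  laff <- hemi_sum(mapping[["LAff"]])
  structure(list(
    channel_aucs = channel_aucs, block_aucs = block_aucs,
    maff_auc = maff$sum, laff_auc = laff$sum,
    tot_auc = maff$sum + laff$sum, mapping = mapping,
    retained_per_hemisphere = c(MAff = maff$n, LAff = laff$n),
    rescaled = rescale_missing
  ), class = "nirs_activation")
}

#' Compute the activation biomarker from a hemoglobin recording
#'
#' Per channel: AUC of the oxy-Hb trace over each walking block (plain
#' sample sum), averaged over the blocks; then hemispheric aggregation via
#' [aggregate_activation()]. Traces are converted from micromolar to the
#' package's arbitrary units (a.u. = nM-samples) with `au_scale` before
#' summation; the scale is a pure unit convention and cancels from every
#' ratio or test statistic downstream.
#'
#' @param hemo A `nirs_hemo` recording (see [process_recording()]).
#' @param side More-impaired (or dominant) limb side.
#' @param qc The recording's `nirs_qc` report (optional).
#' @param rescale_missing See [aggregate_activation()].
#' @param au_scale Arbitrary-unit scale applied to the uM traces
#'   (default 1000).
#' @return A `nirs_activation` result.
#' @export
compute_activation <- function(hemo, side, qc = NULL,
                               rescale_missing = FALSE, au_scale = 1000) {
  windows <- segment_blocks(hemo$design, nrow(hemo$hbo))
  nc <- ncol(hemo$hbo)
  retained <- if (is.null(qc)) rep(TRUE, nc) else qc_retained(qc)
  blocks <- matrix(NA_real_, nc, length(windows),
                   dimnames = list(hemo$montage$channel, NULL))
  for (ch in which(retained)) {
    trace <- hemo$hbo[, ch] * au_scale
    blocks[ch, ] <- vapply(windows, function(w) block_auc(trace, w),
                           numeric(1))
  }
  channel_aucs <- stats::setNames(rowMeans(blocks), hemo$montage$channel)
  aggregate_activation(channel_aucs, hemo$montage,
                       assign_affected_hemisphere(side), qc,
                       rescale_missing, block_aucs = blocks)
}

#' @export
print.nirs_activation <- function(x, ...) {
  cat("fNIRS walking-block activation (a.u.)\n")
  cat(sprintf("  MAff-Oxy_AUC: %.1f\n  LAff-Oxy_AUC: %.1f\n  Tot-Oxy_AUC:  %.1f\n",
              x$maff_auc, x$laff_auc, x$tot_auc))
  cat(sprintf("  retained channels: MAff %d, LAff %d%s\n",
              x$retained_per_hemisphere[["MAff"]],
              x$retained_per_hemisphere[["LAff"]],
              if (x$rescaled) " (rescaled)" else ""))
  invisible(x)
}
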