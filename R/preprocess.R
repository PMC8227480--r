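# Channel quality control, artifact removal and bandpass filtering.

#' Channel quality-control thresholds
#'
#' A channel is rejected when its hardware gain reaches `gain` (default 7)
#' or when its raw-intensity coefficient of variation (SD/mean, computed per
#' wavelength, worst wavelength taken) exceeds `cv`. A subject is excluded
#' when strictly more than `max_bad` channels (default 8 of 48) are
#' rejected. The CV criterion operationalizes "excessively noisy channel":
#' it is the standard NIRS proxy for poor optode coupling.
#'
#' @param gain Gain exclusion threshold (channel excluded when gain >= this).
#' @param cv Intensity coefficient-of-variation threshold.
#' @param max_bad Maximum tolerated number of rejected channels per subject.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(gain = 7, cv = 0.15, max_bad = 8L) {
  if (gain <= 0 || cv <= 0) nw_stop("thresholds must be positive", "invalid_qc")
  if (max_bad < 0 || max_bad != round(max_bad)) {
    nw_stop("max_bad must be a non-negative integer", "invalid_qc")
  }
  structure(list(gain = gain, cv = cv, max_bad = as.integer(max_bad)),
            class = "qc_thresholds")
}

#' Quality-control a raw recording
#'
#' Applies the channel rejection rule (gain >= threshold OR worst-wavelength
#' intensity CV > threshold) and the subject exclusion rule (more than
#' `max_bad` rejected channels). QC is deterministic and idempotent.
#'
#' @param raw A `nirs_recording` (see [simulate_subject_recording()]).
#' @param thresholds A [qc_thresholds()] object.
#' @return A data.frame of class `nirs_qc` with one row per channel
#'   (`channel`, `gain`, per-wavelength CVs, `status`, `reason`) and
#'   attributes `subject_status` ("included"/"excluded"), `bad_count`,
#'   `thresholds`.
#' @export
qc_channels <- function(raw, thresholds = qc_thresholds()) {
  if (is.null(raw$intensity) || length(raw$intensity) == 0 ||
      nrow(raw$intensity[[1]]) == 0) {
    nw_stop("empty recording", "invalid_input")
  }
  wl <- names(raw$intensity)
  cvs <- vapply(raw$intensity, function(m) {
    apply(m, 2, function(x) stats::sd(x) / mean(x))
  }, numeric(ncol(raw$intensity[[1]])))
  if (!is.matrix(cvs)) cvs <- matrix(cvs, nrow = 1)
  colnames(cvs) <- wl
  worst_cv <- apply(cvs, 1, max)
  bad_gain <- raw$gains >= thresholds$gain
  bad_snr <- worst_cv > thresholds$cv
  status <- ifelse(bad_gain | bad_snr, "excluded", "retained")
  reason <- mapply(function(g, s) {
    paste(c(if (g) "gain", if (s) "snr"), collapse = "+")
  }, bad_gain, bad_snr)
  rep <- data.frame(
    channel = raw$montage$channel, gain = raw$gains,
    status = status, reason = reason, stringsAsFactors = FALSE
  )
  for (w in wl) rep[[paste0("cv_", w)]] <- cvs[, w]
  bad_count <- sum(status == "excluded")
  attr(rep, "bad_count") <- bad_count
  attr(rep, "subject_status") <-
    if (bad_count > thresholds$max_bad) "excluded" else "included"
  attr(rep, "thresholds") <- thresholds
  class(rep) <- c("nirs_qc", "data.frame")
  rep
}

#' Retained-channel mask from a QC report
#'
#' @param qc A `nirs_qc` report.
#' @return Logical vector, TRUE for retained channels (montage order).
#' @export
qc_retained <- function(qc) qc$status == "retained"

#' Serialize a QC report to JSON
#'
#' @param qc A `nirs_qc` report.
#' @param path Optional output path.
#' @return JSON string (invisibly if written).
#' @export
qc_to_json <- function(qc, path = NULL) {
  obj <- list(
    subject_status = attr(qc, "subject_status"),
    bad_count = attr(qc, "bad_count"),
    thresholds = unclass(attr(qc, "thresholds")),
    channels = as.data.frame(qc)
  )
  js <- jsonlite::toJSON(obj, digits = NA, auto_unbox = TRUE)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}

#' Remove spike artifacts from a series
#'
#' Samples whose first-difference robust z-score
#' |dx - median(dx)| / (1.4826 * MAD(dx)) exceeds `z_threshold` mark spike
#' samples; both the sample the large difference enters and the one it
#' leaves are replaced by linear interpolation between the nearest retained
#' neighbours (endpoints extend the nearest retained value). If the MAD of
#' the differences is zero on a non-constant series, the SD is used instead;
#' a constant series is returned unchanged.
#'
#' @param x Numeric series (length >= 5).
#' @param z_threshold Robust z threshold (default 5).
#' @return Cleaned series, same length.
#' @export
remove_spikes <- function(x, z_threshold = 5) {
  if (length(x) < 5) nw_stop("series must have length >= 5", "invalid_input")
  d <- diff(x)
  s <- stats::mad(d)
  if (s == 0) {
    s <- stats::sd(d)
    if (is.na(s) || s == 0) return(x)  # constant (or constant-step) series
  }
  z <- abs(d - stats::median(d)) / s
  big <- which(z > z_threshold)
  if (length(big) == 0) return(x)
  flag <- unique(pmin(length(x), c(big, big + 1L)))
  keep <- setdiff(seq_along(x), flag)
  if (length(keep) < 2) return(x)
  interp <- stats::approx(keep, x[keep], xout = flag, rule = 2)$y
  x[flag] <- interp
  x
}

#' Remove sustained baseline discontinuities from a series
#'
#' Detects first differences exceeding `step_threshold` whose surrounding
#' segment medians also differ by more than the threshold (distinguishing a
#' sustained level shift from an isolated spike), and subtracts the step
#' offset from all subsequent samples. The offset is estimated as the
#' difference of the post- and pre-step segment medians, which is robust to
#' a spike landing next to the step. Within-segment waveforms are preserved
#' exactly: output first differences equal input first differences
#' everywhere except at corrected steps.
#'
#' @param x Numeric series (length >= 5).
#' @param step_threshold Absolute step size treated as a discontinuity; when
#'   `NULL` (default) it is set to 8 robust SDs (1.4826 * MAD) of the first
#'   differences.
#' @param window Number of samples used for the pre/post segment medians.
#' @return Corrected series, same length.
#' @export
remove_discontinuities <- function(x, step_threshold = NULL, window = 10L) {
  if (length(x) < 5) nw_stop("series must have length >= 5", "invalid_input")
  d <- diff(x)
  if (is.null(step_threshold)) {
    s <- stats::mad(d)
    if (s == 0) s <- stats::sd(d)
    if (is.na(s) || s == 0) return(x)
    step_threshold <- 8 * s
  }
  cand <- which(abs(d) > step_threshold)
  if (length(cand) == 0) return(x)
  # A level shift riding on noise can spread its rise over a few samples:
  # group candidate diffs separated by < 3 samples into one transition
  # event, estimated from segment medians strictly outside the event (and
  # not crossing neighbouring events). An isolated spike forms one event
  # whose pre/post levels agree, so the offset gate rejects it; the
  # mid-transition samples keep large diffs and are left to
  # remove_spikes().
  grp <- cumsum(c(1L, diff(cand) >= 3L))
  first <- as.integer(tapply(cand, grp, min))
  last <- as.integer(tapply(cand, grp, max))
  for (j in seq_along(first)) {
    k0 <- first[j]
    k1 <- last[j]
    pre_from <- max(if (j > 1) last[j - 1] + 1L else 1L, k0 - window + 1L)
    post_to <- min(if (j < length(first)) first[j + 1] else length(x),
                   k1 + window)
    if (k0 - pre_from + 1L < 3L || post_to - k1 < 3L) next
    offset <- stats::median(x[(k1 + 1L):post_to]) -
      stats::median(x[pre_from:k0])
    if (abs(offset) > step_threshold) {
      x[(k1 + 1L):length(x)] <- x[(k1 + 1L):length(x)] - offset
    }
  }
  x
}

# --- Butterworth bandpass design (analog prototype + bilinear transform) ----
# The `signal` package is not a dependency; the design below reproduces the
# standard digital Butterworth bandpass (verified against an independent
# reference implementation to machine precision).

poly_from_roots <- function(r) {
  p <- complex(real = 1)
  for (ri in r) p <- c(p, 0 + 0i) - c(0 + 0i, ri * p)
  p
}

butter_bandpass <- function(order, low_hz, high_hz, fs) {
  fs2 <- 2 * fs
  w1 <- fs2 * tan(pi * low_hz / fs)   # prewarped analog edges
  w2 <- fs2 * tan(pi * high_hz / fs)
  w0 <- sqrt(w1 * w2)
  bw <- w2 - w1
  k <- seq_len(order)
  p_lp <- exp(1i * pi * (2 * k + order - 1) / (2 * order))
  p_bp <- complex(0)
  for (p in p_lp) {
    disc <- sqrt((p * bw)^2 - 4 * w0^2)
    p_bp <- c(p_bp, (p * bw + disc) / 2, (p * bw - disc) / 2)
  }
  z_p <- (fs2 + p_bp) / (fs2 - p_bp)
  z_z <- c(rep(1 + 0i, order), rep(-1 + 0i, order))
  kz <- bw^order * Re(fs2^order / prod(fs2 - p_bp))
  list(b = Re(kz * poly_from_roots(z_z)), a = Re(poly_from_roots(z_p)))
}

# Steady-state initial filter conditions (direct form II transposed), so a
# step input produces no start-up transient.
lfilter_zi <- function(b, a) {
  n <- length(a)
  A <- rbind(-a[-1], cbind(diag(n - 2), 0))
  B <- b[-1] - a[-1] * b[1]
  solve(diag(n - 1) - t(A), B)
}

# IIR filter in direct form II transposed; x may be a matrix (one series per
# column, filtered simultaneously). zi: one initial state per column
# (matrix nz x ncol) or NULL for zero state.
lfilter <- function(b, a, x, zi = NULL) {
  xm <- as.matrix(x)
  n <- length(b)
  nz <- n - 1
  m <- ncol(xm)
  z <- if (is.null(zi)) matrix(0, nz, m) else zi
  y <- matrix(0, nrow(xm), m)
  for (t in seq_len(nrow(xm))) {
    xt <- xm[t, ]
    yt <- b[1] * xt + z[1, ]
    if (nz > 1) {
      z[1:(nz - 1), ] <- outer(b[2:nz], xt) + z[2:nz, , drop = FALSE] -
        outer(a[2:nz], yt)
    }
    z[nz, ] <- b[n] * xt - a[n] * yt
    y[t, ] <- yt
  }
  if (is.matrix(x)) y else drop(y)
}

filtfilt_bp <- function(b, a, x) {
  xm <- as.matrix(x)
  n <- nrow(xm)
  padlen <- 3 * max(length(a), length(b))
  if (n <= padlen) {
    nw_stop("series too short for zero-phase filtering", "invalid_input")
  }
  odd_ext <- function(m) {
    top <- 2 * m[rep(1, padlen), , drop = FALSE] - m[(padlen + 1):2, , drop = FALSE]
    bot <- 2 * m[rep(n, padlen), , drop = FALSE] -
      m[(n - 1):(n - padlen), , drop = FALSE]
    rbind(top, m, bot)
  }
  ext <- odd_ext(xm)
  zi <- lfilter_zi(b, a)
  y <- lfilter(b, a, ext, zi %o% ext[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  y <- lfilter(b, a, y, zi %o% y[1, ])
  y <- y[nrow(y):1, , drop = FALSE]
  out <- y[(padlen + 1):(padlen + n), , drop = FALSE]
  if (is.matrix(x)) out else drop(out)
}

#' Zero-phase Butterworth bandpass filter
#'
#' Order-3 Butterworth bandpass applied forward and backward (zero phase;
#' effective magnitude response squared). Defaults pass the task's block
#' fundamental (1/60 s = 0.0167 Hz, kept within 3%) while strongly rejecting
#' cardiac (~1.1 Hz), respiratory (~0.25 Hz) and slow-drift components.
#'
#' @param x Numeric vector, or matrix with one series per column.
#' @param low_hz,high_hz Band edges in Hz (0 < low < high < fs/2).
#' @param fs Sampling rate in Hz.
#' @param order Filter order (default 3).
#' @return Filtered series, same shape as `x`.
#' @export
bandpass_filter <- function(x, low_hz = 0.01, high_hz = 0.20, fs = 3.46,
                            order = 3L) {
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < fs / 2)) {
    nw_stop("need 0 < low_hz < high_hz < fs/2", "invalid_band")
  }
  ba <- butter_bandpass(order, low_hz, high_hz, fs)
  filtfilt_bp(ba$b, ba$a, x)
}

#' Magnitude response of the zero-phase bandpass
#'
#' Evaluates the effective (forward-backward, i.e. squared) magnitude
#' response of the filter used by [bandpass_filter()] at given frequencies.
#'
#' @inheritParams bandpass_filter
#' @param f Frequencies (Hz) at which to evaluate the response.
#' @return Numeric vector of gains.
#' @export
bandpass_response <- function(f, low_hz = 0.01, high_hz = 0.20, fs = 3.46,
                              order = 3L) {
  ba <- butter_bandpass(order, low_hz, high_hz, fs)
  vapply(f, function(fi) {
    z <- exp(-1i * 2 * pi * fi / fs)
    h <- sum(ba$b * z^(seq_along(ba$b) - 1)) /
      sum(ba$a * z^(seq_along(ba$a) - 1))
    Mod(h)^2
  }, numeric(1))
}

#' Clean one intensity series
#'
#' Applies the documented cleaning order: discontinuity correction, then
#' spike removal. Series length is never changed.
#'
#' @param x Numeric series.
#' @param z_threshold Spike threshold, see [remove_spikes()].
#' @param step_threshold Step threshold, see [remove_discontinuities()].
#' @return Cleaned series.
#' @export
clean_series <- function(x, z_threshold = 5, step_threshold = NULL) {
  remove_spikes(remove_discontinuities(x, step_threshold), z_threshold)
}
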