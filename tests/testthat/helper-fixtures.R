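# Shared fixtures: all built in code at test time.

default_montage <- build_default_montage()
default_design <- build_task_design()

# A raw recording built directly (no simulation): constant intensity i0
# everywhere unless overridden, gains all 1 unless overridden.
make_flat_recording <- function(montage = default_montage,
                                design = default_design, i0 = 1,
                                gains = NULL) {
  n <- design$n_samples
  nc <- nrow(montage)
  m <- matrix(i0, n, nc)
  structure(list(
    montage = montage, design = design, wavelengths = c(760, 850),
    intensity = list("760" = m, "850" = m),
    gains = gains %||% rep(1L, nc),
    sampling_rate = design$sampling_rate,
    subject_id = "T01", timepoint = "T0", seed = 0L
  ), class = "nirs_recording")
}

# Distinct positive per-channel amplitudes for recovery tests.
graded_amps <- function(n = 48, lo = 0.02, hi = 0.4) {
  seq(lo, hi, length.out = n)
}
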