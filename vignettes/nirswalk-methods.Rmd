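---
title: "Methods: block-design fNIRS activation analysis for gait rehabilitation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: block-design fNIRS activation analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirswalk)
```

## The measurement and the biomarker

During a treadmill task alternating 30 s of walking with 30 s of standing
rest (4 cycles, preceded by a 30 s baseline), a dual-wavelength continuous
NIRS system (760/850 nm, 3.46 Hz) records light attenuation over 48
source–detector channels — 24 per hemisphere over motor and premotor
cortex, with ~3 cm separations. Task-locked increases in oxyhemoglobin
(HbO) indicate cortical activation.

The biomarker is the walking-block area under the HbO curve:

* per channel and walking block, the **plain sum of HbO samples** over the
  half-open window `[onset, onset + 30 s)`;
* averaged over the four blocks;
* summed over the 24 channels of each hemisphere, yielding
  `MAff-Oxy_AUC` (hemisphere controlling the more impaired limb — the
  hemisphere *contralateral* to it) and `LAff-Oxy_AUC` (the other side);
* `Tot-Oxy_AUC = MAff + LAff` holds exactly by construction. This
  channel-sum reading is the one under which published hemisphere/total
  triplets are exactly additive, which is why it was adopted over the
  alternative "AUC of the channel-mean trace".

Units are arbitrary. The package's convention is **a.u. = nM·sample**
(`au_scale = 1000` converts µM traces before summation). This is a pure
unit choice — every ratio, correlation and test statistic downstream is
invariant to it — selected so that the study-like synthetic scenario
produces totals of the same order (1e5) as published tables while keeping
concentrations physiological. No per-block baseline is subtracted before
summation: the bandpass filter has already removed the DC component, so a
separate zero-reference would be redundant (the alternative is noted as an
open interpretation of the source software's behaviour).

## From light to hemoglobin

Optical-density changes are computed against the pre-task baseline:
`ΔOD(t) = log10(ref / I(t))`, ref = mean intensity over the 30 s baseline
(whole-recording mean if the design has no baseline). The modified
Beer–Lambert law then gives, per sample,

```
E · [ΔHbO; ΔHbR] = [ΔOD760/(d·DPF760); ΔOD850/(d·DPF850)]
```

solved by the exact 2×2 inverse. `E` defaults to the standard compiled
molar extinction coefficients (cm⁻¹ M⁻¹): HbO 586 / HbR 1548.52 at 760 nm,
HbO 1058 / HbR 691.32 at 850 nm; DPF = 6.0 at both wavelengths; d = 3 cm.
None of these constants is fixed by the study protocol — all are
overridable in `mbll_params()` — and the forward simulator shares the same
parameter object, so simulation/inversion round trips are exact by
construction (verified to ≤1e-9 relative error, in practice ~1e-16).

A number worth keeping in mind: with these coefficients the inversion maps
1 unit of OD noise to ≈77 µM of HbO-equivalent noise. OD-domain noise
magnitudes must be read through that gain.

## Quality control

* **Channel rejection**: hardware gain ≥ 7, or raw-intensity coefficient
  of variation (SD/mean per wavelength, worst wavelength) > 0.15. The
  protocol's phrase "excessive signal-to-noise ratio" is read as
  *excessive noise* (the sentence as printed is self-contradictory); the
  intensity CV is the standard NIRS proxy for poor optode coupling. Both
  thresholds are configurable (`qc_thresholds()`).
* **Subject exclusion**: strictly more than 8 rejected channels of 48
  (9+ excludes, 8 does not).

QC is deterministic and idempotent, and excluded channels propagate: their
concentration columns are NA and hemispheric aggregation skips them. By
default hemisphere sums are **not** rescaled for missing channels
(`rescale_missing = FALSE`), matching the definition of the biomarker over
all 48 channels; the rescaling option (×24/retained) is exposed for
sensitivity analyses.

## Artifact cleaning and filtering

Cleaning operates in the OD domain, where motion artifacts are additive
(a multiplicative intensity step is an additive OD step), in the
documented order *discontinuities → spikes → bandpass*:

* **Discontinuities**: first differences above a threshold (default: 8
  robust SDs of the diffs) are grouped into transition events (gaps < 3
  samples); each event's offset is estimated as the difference of post-
  and pre-event segment medians, computed strictly outside the event and
  never crossing a neighbouring event, and subtracted from all subsequent
  samples. Segment medians — rather than the raw first difference — are
  used because a shift riding on noise spreads its rise over 2–3 samples
  and a spike landing next to a shift corrupts any single-sample estimate;
  isolated spikes fail the offset gate naturally (their pre/post levels
  agree). Within-segment waveforms are preserved exactly.
* **Spikes**: samples whose first-difference robust z-score
  (|Δx − median Δx| / (1.4826·MAD)) exceeds 5 are replaced by linear
  interpolation between the nearest retained neighbours; if MAD = 0 on a
  non-constant series the plain SD substitutes. Note the SD fallback can
  mask a single impulse on a short flat series (the impulse inflates the
  SD); at realistic series lengths (≥100 samples) the rule behaves as
  intended.
* **Bandpass**: zero-phase (forward–backward) order-3 Butterworth,
  0.01–0.20 Hz at 3.46 Hz sampling. The protocol names no cutoffs, only a
  "wide bandpass"; the band was chosen so the block fundamental
  (1/60 s ≈ 0.0167 Hz) is preserved (gain 0.97) while cardiac (~1.1 Hz)
  is attenuated >100 dB and respiratory (~0.25 Hz) and slow drift are
  rejected. The design was validated coefficient-for-coefficient against
  an independent reference implementation. Because the Beer–Lambert
  inversion is linear, filtering before or after the inversion is
  mathematically equivalent; the pipeline filters OD.

## Relative training intensity

`RTI = mean session speed / reference speed`, reference = baseline timed
25-foot-walk speed (an explicit "highest attainable speed" override is
accepted). For the robot-assisted arm the ratio is corrected for
body-weight support by the **carried-load fraction** (×(1 − BWS)): at 50%
support both readings of the protocol's example give ×0.50, and load
fraction is the physiologically coherent direction (more support → lower
intensity). The alternative (`support_fraction`) is exposed behind a flag.
RTI is dichotomized at the **median of the subject's treatment arm**
(two-quantile rule; ties at the median classified high; even-cohort median
= midpoint of the central order statistics).

## Statistical battery

Choices pinned by reproducing printed worked examples:

* two-sample comparisons of summaries use the **pooled-variance Student
  t** (reproduces the published patient-vs-healthy p-values 0.015 / 0.004
  with df = 27; Welch does not);
* 2×2 contrasts use the **uncorrected** Pearson chi-square (reproduces
  the published 0.22; Yates gives ≈0.41);
* the group×time **mixed (split-plot) ANOVA** applies no sphericity
  correction (F(2,44) = 5.41 → p ≈ 0.008 under uncorrected df).

Raw-data comparisons follow the stated policy: Shapiro–Wilk at α = 0.05 on
each sample (paired: on the differences) gates a parametric branch (pooled
t / paired t) versus a rank branch (Mann–Whitney U / Wilcoxon signed-rank,
normal approximation with tie correction, no continuity correction — the
protocol is silent on continuity). Spearman's rho uses mid-ranks with the
t approximation (df = n − 2). Within-arm "trend" statistics are
within-subject linear-trend contrasts over T0/T1/T2 (per-subject slope,
one-sample t), the default reading of an underspecified analysis; paired
T0-vs-T2 tests are reported alongside. No multiple-testing correction is
applied (matching the source analysis); the report annotates the number of
tests run. `analyze_cohort()` emits the full battery as a flat data frame,
deterministically and invariantly to row order.

## The synthetic cohort: what it states and what it does not

The generator exists so that every stage is testable against known ground
truth; its defaults are declared conventions, not protocol facts.

**Forward model.** Per channel, HbO(t) = amplitude × (walk-block boxcar ⊛
canonical double-gamma HRF, peak 6 s, undershoot 16 s, ratio 1/6,
plateau-normalized); HbR = −⅓ × HbO. Concentrations map to OD by the
forward Beer–Lambert model and to intensity by I = I₀·10^(−OD), I₀ = 1.
Noise is added in the OD domain per channel and wavelength.

**Amplitudes** (response plateau, µM): patients 0.25 (more affected
hemisphere) / 0.19 (less affected); healthy controls 0.030 / 0.018.
Between-subject lognormal CV 0.45 (patients; matching the published
between-subject CV of the total) and 0.20 (healthy); between-channel CV
0.30. Through the filtered unit block response (≈35.8 µM·samples per µM of
amplitude) these produce hemispheric sums of the published order.
Longitudinal multipliers: robot-assisted arm 1 / 0.8 / 0.6 at T0/T1/T2,
overground arm 1 / 1.3 / 1.6, with lognormal per-subject jitter (SD 0.2)
and, in the robot arm, a coupling of the end-of-treatment multiplier to
training intensity (lower intensity → larger decrease), so the scenario
states the published direction of effects.

**Noise defaults**, with their HbO-equivalent readings: cardiac 1.1 Hz,
2e-3 OD (removed by the filter); respiratory 0.25 Hz, 1e-3; Mayer 0.1 Hz,
8e-4 (≈0.06 µM, passes the filter — the dominant in-band physiological
term); white 1.5e-3 OD per sample (≈0.12 µM before filtering); random-walk
drift with 5e-5 OD steps (≈0.1 µM total wander over the 4.5-min recording
— chosen so that drift power inside the analysis band is modest, as for a
stable optode cap; larger steps put unrealistic random-walk power directly
into the band); spikes 1/min at ~0.03 OD; baseline shifts 0.2/min at
~0.05 OD. Injected bad channels get gain 8 and/or white noise inflated to
0.3 OD (intensity CV ≈ 0.7, far beyond the 0.15 threshold), so they
violate QC by construction.

**Clinical covariates** are truncated normals centred on the published
baseline characteristics (age 56±10, EDSS 6.3±0.3 clipped to [6,7] in 0.5
steps, arm-specific gait speed/endurance/balance), with post-treatment
gains of ~9% gait speed, ~14% endurance, ~2 balance points in both arms
(half realized at mid-treatment). Training logs give robot sessions ~0.45
m/s at 40±8% support and overground sessions ~85% of reference speed.

**What a green test does not establish.** The generator has no
superficial/scalp compartment (so it cannot probe the short-channel
limitation), no real motion traces, sinusoidal (not drifting-frequency)
physiological oscillations, and independent noise across channels (no
spatial covariance). Recovery and calibration results certify the pipeline
against *this* stated world, not against vendor hardware.

**Two generator paths.** `simulate_cohort()` produces full raw optical
recordings. `simulate_cohort_table()` draws the *same* subject profiles
(shared code) but maps amplitudes through the deterministic noise-free
pipeline response (`unit_channel_auc()`, exact by linearity) straight to
biomarker values. The statistical-calibration acceptance runs (200 null +
100 effect replicates) use the table path — the full-optics equivalent
would take ~45 minutes — while the full path is exercised end-to-end by
the additivity, recovery and pipeline tests.

## Numerical conventions

* Half-open block windows realized as sample indices `onset ≤ k/fs <
  onset + walk_s` (tolerance 1e-9); a boundary sample belongs to the next
  phase. The default design yields 104 samples per walking block.
* Sample count `n = round(total duration × fs)` = 934 for the default
  270 s design.
* Median ties in RTI dichotomization go to "high"; even-cohort median is
  the midpoint rule.
* Degenerate statistics: zero pooled variance with equal means gives
  t = 0, p = 1 (with unequal means, p = 0 plus a warning); all-tied rank
  comparisons return U = n₁n₂/2, p = 1; constant inputs to Spearman are an
  error, not NA.
* All randomness descends from explicit integer seeds; recordings,
  cohorts and reports are pure functions of (inputs, seed).

## Known limitations

* The region (M1 vs PM) labels partition each hemisphere 12/12 by
  convention; no scalp geometry is modelled, so region-level analyses are
  an exposed convenience, not a validated localization.
* The intensity-CV QC proxy and the band edges stand in for unspecified
  vendor-software behaviour; both are configurable and their defaults are
  documented above.
* The discontinuity corrector's median-offset estimate absorbs any true
  signal trend across its ±10-sample window; for slow hemodynamic signals
  this bias is small but nonzero.
* With the default extinction pairing, healthy-scale HbO/HbR responses
  nearly cancel in the 760 nm OD; recovery at very low amplitudes is
  correspondingly less precise than for patient-scale responses.
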