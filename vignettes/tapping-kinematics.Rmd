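---
title: "Quantifying bradykinesia from video-derived finger-tapping signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bradykinesia from video-derived finger-tapping signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(taplab)
```

## The measurement problem

The finger-tapping task (MDS-UPDRS-III item 3.4) asks a patient to tap
index finger against thumb "as big and as fast as possible" while a
clinician rates slowness, amplitude decrement, and hesitations on a 0-4
scale. Markerless hand-pose estimation makes the same task measurable
from an ordinary video: a pose backend emits per-frame image-normalized
coordinates of the index fingertip and thumb tip, and everything that
follows — the aperture waveform, its conditioning, tap segmentation and
feature extraction — is deterministic signal processing that this package
implements. The package never touches video; its input boundary is a
long-format landmark CSV (`frame,time_s,landmark,x,y,confidence`), which
any backend can produce.

A note on units: pose backends report *image-normalized* coordinates in
[0, 1], but the field's convention is to label aperture quantities "px".
We keep normalized units throughout and label them `norm`; velocities
around 0.45-0.7 units/s are what such normalized apertures produce.

## From landmarks to features

1. **Aperture waveform.** `compute_distance_waveform()` takes the
   Euclidean distance between the two fingertips per retained frame, with
   timestamps `frame/fps`. Frames missing either landmark are flagged and
   enter quality control.
2. **Quality control.** `qc_segment()` passes a recording only if at most
   5% of frames are dropped or blurred (strictly greater than 5% fails,
   so exactly 5% passes), the longest clean run lasts at least 15 s, and
   no occlusion runs are present. Durations use the frame-count
   convention (`n` frames at `fps` cover `n/fps` seconds).
3. **Conditioning** (`condition_waveform()`), in a fixed order, each step
   appending one provenance entry:
   - *linear detrend* removes slow aperture drift (hand-camera distance
     changes);
   - *Savitzky-Golay smoothing*, polynomial order 2; the window is fixed
     a priori by frame rate and expected tap cycle as the largest odd
     sample count not exceeding one third of the expected cycle
     (`floor((fps/expected_freq)/3)`, floored at 5). One third of a cycle
     preserves tap peaks while suppressing landmark jitter; at 30 fps and
     the 2 Hz default expected rate the window is 5 samples.
   - *resampling to 50 Hz* by linear interpolation. The output length
     preserves the duration in frame periods (15 s at 30 fps gives
     exactly 750 samples at 50 Hz); at most one frame period at the tail
     is linearly extrapolated from the final segment. With the signal
     band-limited well below Nyquist at 6x oversampling, higher-order
     interpolation would change nothing material.
   - *5th-order Butterworth low-pass at 10 Hz*, applied
     forward-backward. Zero-phase filtering is essential: rhythm
     variability is computed from peak *times*, and a causal filter would
     shift them. The 10 Hz cutoff keeps the tapping fundamental
     (<= 5 Hz) and its first harmonics. The trace is mean-centred and
     reflected at the ends before filtering, so DC gain is exactly 1 and
     edge transients are suppressed.

   All four steps are linear operators, a property the test suite checks
   directly (`pipeline(ax + by) = a pipeline(x) + b pipeline(y)`).
4. **Tap segmentation.** `detect_taps()` finds local maxima (leftmost
   sample of an equal-height plateau), keeps those whose topographic
   prominence reaches 10% of the global range, and greedily suppresses —
   tallest peak first — any peak within the 0.2 s refractory interval of
   an accepted one. The refractory interval encodes the physiological
   ceiling of credible tapping (5 Hz) and prevents ripple near a true
   peak from double-counting; equivalence with a brute-force
   extrema-plus-suppression oracle is tested exhaustively on traces up to
   1000 samples. The valley between consecutive peaks is the minimum
   sample in between.

## The four features

With per-cycle amplitudes \(A_i\) (peak height minus the mean of its
adjacent valleys — a symmetric choice robust to residual baseline drift),
inter-peak intervals \(\Delta t_i\) and instantaneous frequencies
\(if_i = 1/\Delta t_i\):

| feature | definition | units | captures |
|---|---|---|---|
| `V` | mean \(|d_{k+1}-d_k|\cdot f_s\) over the conditioned trace | units/s | speed |
| `delta_a` | OLS slope of \(A_i\) on cycle index \(0,1,\dots\) | units/cycle | sequence effect |
| `aCoV` | \(\sigma_A/\mu_A\), sample SD | — | amplitude variability |
| `ifCoV` | \(\sigma_{if}/\mu_{if}\), sample SD | — | rhythm variability |

Interpretation choices that were genuinely open:

- `V` is the *mean absolute first derivative* of the aperture trace, the
  simplest estimator consistent with "units per second" and with typical
  normalized-aperture magnitudes. It is not peak velocity. For a
  sinusoidal aperture of half-range \(A\) at \(f\) Hz it converges to
  \(4Af\); equivalently \(2 A_{\mathrm{cycle}} f\) where
  \(A_{\mathrm{cycle}}\) is the per-cycle (peak-to-valley) amplitude —
  the form that also holds for the generator's raised-cosine pulses.
- `delta_a` is regressed on cycle *index*, not time ("units per cycle");
  the slope is invariant to the index origin.
- Both CoVs use the sample (n-1) standard deviation, the standard choice
  at 25-35 cycles per recording; the test suite pins this convention
  (population SD would shrink CoV by \(\sqrt{(n-1)/n}\)).
- Features require at least 5 detected cycles; fewer raises a typed
  `insufficient-cycles` error rather than returning unstable values.

`fit_taps()` wraps conditioning, segmentation and feature extraction into
a classed model object:

```{r example}
sim <- simulate_tap_waveform(
  tap_gen_params(mean_amplitude = 0.15, amplitude_cov = 0.3,
                 mean_frequency = 2, rhythm_cov = 0.4,
                 decrement_slope = -0.001, noise_sd = 0.005, seed = 7))
fit <- fit_taps(sim$waveform)
fit
coef(fit)
```

`summary()` adds the per-cycle table, `plot()` the annotated trace and
amplitude-decrement panel, `residuals()` the deviation from a
raised-cosine reconstruction through the detected anchors, and
`simulate()` draws new synthetic recordings at the fitted parameters.

## The synthetic generator

No patient videos ship with (or are reproducible from) this package, so
validation rests on a generative stand-in, `simulate_tap_waveform()`.
Its distributional choices are explicit stand-ins — the clinical
literature specifies no generative model for tapping waveforms:

- each tap is one **raised-cosine aperture pulse** (valley to peak to
  valley, two half-cosine arcs): smooth, band-limited, with negligible
  energy above ~3x the tapping rate;
- **peak times** are laid down from log-normal instantaneous-frequency
  draws matched to `mean_frequency` and `rhythm_cov`, so the realized
  peak-to-peak intervals carry exactly the target rhythm CoV;
- **amplitudes** are gamma draws matched to the (decrement-trended) mean
  and `amplitude_cov` — positive support without truncation artifacts;
- **decrement** enters as a deterministic linear trend on the expected
  amplitude *before* stochastic scatter, matching `delta_a`'s definition
  as a regression slope;
- Gaussian measurement noise is added last; identical seeds give
  bit-identical output.

Cohorts (`simulate_cohort()`) draw per-subject feature targets from
log-normal distributions bridged from published median [q1-q3] summaries
by `fit_lognormal_from_quartiles()`: `meanlog = log(median)`,
`sdlog = (log q3 - log q1)/(2 z_{0.75})`. A two-parameter log-normal
anchored at the printed median reproduces the median and the quartile
*ratio* exactly; when printed quartiles are asymmetric around the median
(as variability features typically are) the individual quartiles are
matched in ratio, not in place. This is the cost of a two-parameter
bridge and is inherent, not a bug.

What the generator deliberately does **not** emulate: hesitations and
halts, tremor superimposed on the aperture, slow fatigue beyond the
linear decrement, camera motion, or pose-estimation failure modes
(identity swaps, occlusion-induced jumps). Passing recovery tests
therefore demonstrates that the *pipeline* measures what it claims on
clean oscillatory signals with controlled variability — not that any
clinical classification result generalizes.

## Validation design and problem sizes

The test suite favours independent oracles over re-derived constants:
brute-force peak detection, pairwise-comparison AUC, exhaustive Youden
scans, closed-form OLS, hand-applied Benjamini-Hochberg. Monte-Carlo
checks use 200 replicates of 15 s recordings at 30 fps (the task's
standard acquisition format) for parameter recovery — estimator bias for
aCoV and ifCoV stays below 0.05 absolute for targets up to 0.6 — and 200
simulated 32-vs-10 cohorts for the discrimination bound; Welch-test
calibration uses 1000 null replicates. The cohort statistics
(Mann-Whitney with the AUC-U identity, DeLong ROC, Youden cutoffs,
logistic regression with Cox-Snell/Nagelkerke R2, Spearman with 1000
bootstrap iterations, BH adjustment) follow the conventions of the
clinical literature; where a convention is ambiguous we chose and
documented one:

- ROC orientation is fixed ("higher score = disease"), so AUCs below 0.5
  are reported as-is rather than silently flipped;
- DeLong SE/CI (the de facto standard) backs the ROC inference; the
  AUC-U identity is used for published-value consistency checks since it
  is free of any SE convention;
- Mann-Whitney p-values are exact (enumeration) when `n1*n2 <= 400`
  without ties — the scale of such cohorts — and tie- and
  continuity-corrected normal approximations otherwise;
- the Youden cutoff scans midpoints between adjacent sorted unique
  scores, breaking ties toward higher specificity, then lower cutoff;
- logistic predictors enter untransformed (odds ratios on CoV-scale
  predictors can legitimately be astronomically large; a standardized
  entry would hide that);
- BH families are formed per clinical anchor (all feature correlations
  against one anchor), a choice the literature leaves open.

## Degenerate inputs and numerical corners

Constant traces raise `insufficient-cycles` from the detector (zero
range admits no prominent peaks). Equal-height plateaus resolve to their
leftmost sample. Quartile triples with zero spread collapse the
log-normal scale to zero (point mass at the median). Peak times inherit
the 50 Hz grid, so a perfectly metronomic signal shows a residual ifCoV
up to ~0.04 from quantization alone — far below the ~0.1 separating
healthy from impaired tapping, but visible in tests, which bound rather
than zero it. On a finite sampled grid the least-squares trend of an
integer number of sine cycles is small but not exactly zero; the
detrend tests compare against the direct least-squares oracle instead of
assuming continuous-time orthogonality.

## Known limitations

- The pipeline analyzes a single hand's aperture trace; asymmetry
  indices, hesitation detection and non-linear sequence effects are out
  of scope.
- The synthetic clinical anchors attached by
  `attach_synthetic_clinical()` are labelled synthetic and encode only
  the *direction* of clinically reported associations; they exist so the
  correlation machinery can be exercised end-to-end, not to emulate any
  cohort.
- Classification results on simulated cohorts are upper bounds: the
  generator's groups are cleanly separated log-normals without the label
  noise, comorbidity and acquisition heterogeneity of clinical data.
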