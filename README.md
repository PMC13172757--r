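# taplab

Kinematic analysis of video-derived finger-tapping signals for
bradykinesia quantification.

Markerless hand-pose estimation turns an ordinary video of the
MDS-UPDRS-III finger-tapping task (item 3.4) into per-frame coordinates
of the index fingertip and thumb tip. `taplab` implements everything
downstream of the pose backend: it derives the index–thumb aperture
waveform d(t), conditions it (linear detrend → order-2 Savitzky–Golay →
resampling to 50 Hz → zero-phase 5th-order Butterworth low-pass at
10 Hz), segments tap cycles with a refractory-interval peak detector,
and extracts four clinically aligned features:

- **V** — tapping velocity, the mean absolute first derivative of d(t)
  (normalized units/s);
- **Δa** (`delta_a`) — amplitude decrement, the OLS slope of per-cycle
  amplitude A_i on cycle index (units/cycle; the "sequence effect");
- **aCoV** — amplitude variability, σ_A/μ_A;
- **ifCoV** — rhythm variability, σ_if/μ_if with if_i = 1/Δt_i the
  instantaneous frequency between consecutive tap peaks.

Cohort-level statistics mirror the conventions of the clinical
literature: Mann–Whitney U with the AUC–U identity
(AUC = U/(n₁·n₂)), ROC with DeLong SE/CI and Youden cutoffs, binary
logistic regression with Cox–Snell/Nagelkerke R², Spearman correlations
with bootstrap CIs, and Benjamini–Hochberg FDR adjustment. A seeded
synthetic tapping generator (raised-cosine pulses with controllable
amplitude/rhythm CoV, decrement and noise) stands in for patient videos
and makes every stage testable.

## Worked example

Simulate one impaired-like recording (high rhythm variability, mild
decrement), fit the tap-cycle model, and read off the features:

```r
library(taplab)
sim <- simulate_tap_waveform(
  tap_gen_params(mean_amplitude = 0.15, amplitude_cov = 0.3,
                 mean_frequency = 2, rhythm_cov = 0.4,
                 decrement_slope = -0.001, noise_sd = 0.005, seed = 7))
fit <- fit_taps(sim$waveform)
fit
#> Tap-cycle fit
#>   30 cycles over 15.0 s (mean rate 2.35 Hz)
#>       V delta_a    aCoV   ifCoV
#>  0.5491 -0.0001  0.2281  0.4319
```

Thirty tap cycles were detected; the extracted amplitude CoV (0.23) and
rhythm CoV (0.43) recover the generator's targets (0.3 and 0.4) up to
single-recording sampling noise, and the velocity of 0.55 units/s is
what a 0.14-unit mean aperture tapped at ~2 Hz produces (V ≈ 2·μ_A·f).
`summary(fit)`, `plot(fit)`, `residuals(fit)` and `simulate(fit)` give
the per-cycle table, annotated trace, reconstruction residuals and new
synthetic recordings at the fitted parameters.

A full synthetic case–control cohort, sized like a typical
imaging-anchored study (32 vs 10), and its discrimination statistics:

```r
pd <- group_spec("PD-like", 32, acov = c(0.33, 0.28, 0.56),
                 ifcov = c(0.405, 0.338, 0.620), v = c(0.45, 0.155, 0.61))
hc <- group_spec("HC-like", 10, acov = c(0.13, 0.075, 0.175),
                 ifcov = c(0.115, 0.093, 0.150), v = c(0.715, 0.505, 1.085))
co <- simulate_cohort(list(pd, hc), seed = 1)
roc_analysis(co$aCoV, co$group == "PD-like")
#> <tap_roc> AUC 0.978 (SE 0.019, 95% CI 0.941-1.000, p = 2.693e-141)
#>   Youden cutoff 0.2221: sens 84.4%, spec 100.0%, accuracy 88.1%
```

Amplitude variability separates the groups almost perfectly here — as
expected, since the group specs are cleanly separated log-normals; see
the vignette for why simulated AUCs are upper bounds. The AUC printed by
`roc_analysis()` always equals `auc_from_u(mann_whitney(...)$U, n1, n2)`
on the same data.

`run_pipeline()` orchestrates the whole flow (simulate → QC → condition
→ features → statistics) from a config list or YAML file and writes
`features.csv`, `group_tests.csv`, `roc.csv`, `logistic.csv`,
`correlations.csv` and a JSON run manifest; `inst/exec/taplab` exposes
the same steps as shell subcommands.

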