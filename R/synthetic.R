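#' Parameters for the synthetic tapping generator
#'
#' Bundles and validates the generative settings of one synthetic
#' finger-tapping recording. Amplitudes are drawn from a gamma
#' distribution matched to the target mean and CoV (strictly positive
#' support); instantaneous frequencies from a log-normal matched to
#' `mean_frequency` and `rhythm_cov`; the deterministic decrement trend is
#' injected on the expected cycle amplitude before stochastic scatter.
#'
#' @param mean_amplitude Mean aperture pulse height, image-normalized
#'   units (> 0).
#' @param amplitude_cov Target per-cycle amplitude CoV (>= 0).
#' @param mean_frequency Mean tapping rate, taps/s (> 0).
#' @param rhythm_cov Target CoV of instantaneous frequency (>= 0).
#' @param decrement_slope Deterministic amplitude trend, units/cycle
#'   (default 0; negative values emulate the sequence effect).
#' @param noise_sd Additive Gaussian measurement noise, aperture units
#'   (default 0).
#' @param fps Sampling rate of the rendered waveform (default 30).
#' @param duration_s Recording length in seconds (default 15); must admit
#'   at least 5 cycles.
#' @param seed Integer seed (optional; draws are reproducible given it).
#' @return A validated `tap_gen_params` list.
#' @export
tap_gen_params <- function(mean_amplitude, amplitude_cov = 0,
                           mean_frequency = 2, rhythm_cov = 0,
                           decrement_slope = 0, noise_sd = 0,
                           fps = 30, duration_s = 15, seed = NULL) {
  if (!is.finite(mean_amplitude) || mean_amplitude <= 0)
    stop_taplab("mean_amplitude must be > 0", "taplab_invalid_argument")
  if (mean_frequency <= 0)
    stop_taplab("mean_frequency must be > 0", "taplab_invalid_argument")
  if (amplitude_cov < 0 || rhythm_cov < 0 || noise_sd < 0)
    stop_taplab("amplitude_cov, rhythm_cov and noise_sd must be >= 0",
                "taplab_invalid_argument")
  if (fps <= 0 || duration_s <= 0)
    stop_taplab("fps and duration_s must be > 0", "taplab_invalid_argument")
  if (mean_frequency * duration_s < 5)
    stop_taplab("duration too short: at least 5 tap cycles required",
                "taplab_invalid_argument")
  structure(
    list(mean_amplitude = mean_amplitude, amplitude_cov = amplitude_cov,
         mean_frequency = mean_frequency, rhythm_cov = rhythm_cov,
         decrement_slope = decrement_slope, noise_sd = noise_sd,
         fps = fps, duration_s = duration_s, seed = seed),
    class = "tap_gen_params")
}

#' Log-normal bridge from printed median and quartiles
#'
#' Converts a published median \[q1-q3\] summary into the log-normal
#' distribution that reproduces it exactly: `meanlog = log(median)` and
#' `sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75))`. Used to sample
#' subject-level feature targets when only median/IQR summaries are
#' available; the log-normal respects the positivity and right skew of
#' CoV-type features.
#'
#' @param median,q1,q3 Printed median and quartiles, `0 < q1 < median < q3`
#'   (degenerate equality collapses the scale to 0).
#' @return List with `meanlog` and `sdlog`.
#' @examples
#' fit_lognormal_from_quartiles(0.33, 0.28, 0.56)
#' @export
fit_lognormal_from_quartiles <- function(median, q1, q3) {
  if (!all(is.finite(c(median, q1, q3))) || q1 <= 0)
    stop_taplab("quartiles must be positive and finite", "taplab_invalid_argument")
  if (!(q1 <= median && median <= q3) || q1 > q3)
    stop_taplab("need q1 <= median <= q3", "taplab_invalid_argument")
  if (q1 == q3 && !(q1 == median))
    stop_taplab("degenerate quartiles must equal the median", "taplab_invalid_argument")
  list(meanlog = log(median),
       sdlog = (log(q3) - log(q1)) / (2 * qnorm(0.75)))
}

#' Simulate one synthetic tapping waveform
#'
#' Renders `floor(mean_frequency * duration_s)` tap cycles as
#' raised-cosine aperture pulses: peak times are laid down from log-normal
#' instantaneous-frequency draws (so the realized peak-to-peak intervals
#' carry exactly the target rhythm CoV), cycle amplitudes from gamma draws
#' around the decrement-trended mean, and each cycle rises from the valley
#' midpoint to its peak and back along half-cosine arcs. Gaussian
#' measurement noise is added after rendering. The realized cycles
#' (ground truth) are returned alongside the waveform for recovery
#' testing.
#'
#' @param params A [tap_gen_params()].
#' @return List with `waveform` (a [distance_waveform()], provenance
#'   `"synthetic"`) and `cycles` (a `tap_cycles` with the realized peak
#'   times, amplitudes, intervals and instantaneous frequencies).
#' @examples
#' sim <- simulate_tap_waveform(tap_gen_params(0.15, 0.3, 2, 0.4, seed = 42))
#' sd(sim$cycles$amplitudes) / mean(sim$cycles$amplitudes)  # ~0.3
#' @export
simulate_tap_waveform <- function(params) {
  stopifnot(inherits(params, "tap_gen_params"))
  p <- params
  n_cycles <- floor(p$mean_frequency * p$duration_s + 1e-9)
  with_seed(p$seed, {
    # instantaneous frequencies for the n-1 inter-peak intervals
    if (p$rhythm_cov > 0) {
      sdlog <- sqrt(log(1 + p$rhythm_cov^2))
      meanlog <- log(p$mean_frequency) - sdlog^2 / 2
      inst_f <- rlnorm(n_cycles - 1L, meanlog, sdlog)
    } else inst_f <- rep(p$mean_frequency, n_cycles - 1L)
    dt <- 1 / inst_f
    peak_t <- cumsum(c(0.5 / p$mean_frequency, dt))
    mean_a <- pmax(p$mean_amplitude + p$decrement_slope * (seq_len(n_cycles) - 1),
                   1e-8)
    if (p$amplitude_cov > 0) {
      shape <- 1 / p$amplitude_cov^2
      amps <- rgamma(n_cycles, shape = shape, scale = mean_a / shape)
    } else amps <- mean_a
    n_samp <- round(p$fps * p$duration_s)
    t <- (seq_len(n_samp) - 1) / p$fps
    half <- 0.5 / p$mean_frequency
    valleys <- c(peak_t[1] - half,
                 (peak_t[-n_cycles] + peak_t[-1]) / 2,
                 peak_t[n_cycles] + half)
    d <- numeric(n_samp)
    for (i in seq_len(n_cycles)) {
      rise <- t >= valleys[i] & t < peak_t[i]
      fall <- t >= peak_t[i] & t < valleys[i + 1]
      if (any(rise))
        d[rise] <- amps[i] * 0.5 *
          (1 - cos(pi * (t[rise] - valleys[i]) / (peak_t[i] - valleys[i])))
      if (any(fall))
        d[fall] <- amps[i] * 0.5 *
          (1 + cos(pi * (t[fall] - peak_t[i]) / (valleys[i + 1] - peak_t[i])))
    }
    if (p$noise_sd > 0) d <- d + rnorm(n_samp, 0, p$noise_sd)
    keep <- peak_t <= t[n_samp]
    cycles <- structure(
      list(peak_idx = NULL, peak_times = peak_t[keep],
           valley_idx = NULL, valley_times = valleys[c(keep, FALSE)],
           amplitudes = amps[keep],
           intervals = diff(peak_t[keep]),
           inst_freq = 1 / diff(peak_t[keep])),
      class = "tap_cycles")
    list(
      waveform = distance_waveform(t, d, sample_rate_hz = p$fps,
                                   provenance = "synthetic"),
      cycles = cycles)
  })
}

#' Group-level specification for cohort simulation
#'
#' Describes one study group by its size and the printed median
#' \[q1-q3\] summaries of the three positive-valued features used to
#' parameterize subjects (amplitude CoV, rhythm CoV, velocity). Each is
#' bridged to a log-normal via [fit_lognormal_from_quartiles()].
#'
#' @param label Group label, e.g. `"PD-like"` or `"HC-like"`.
#' @param n_subjects Number of subjects (>= 2).
#' @param acov,ifcov,v Numeric `c(median, q1, q3)` on the aCoV, ifCoV and
#'   velocity scales.
#' @return A `group_spec` list.
#' @export
group_spec <- function(label, n_subjects, acov, ifcov, v) {
  if (n_subjects < 2)
    stop_taplab("n_subjects must be >= 2", "taplab_invalid_argument")
  chk <- function(x, nm) {
    if (length(x) != 3L || !(x[2] <= x[1] && x[1] <= x[3]))
      stop_taplab(sprintf("%s must be c(median, q1, q3) with q1 <= median <= q3", nm),
                  "taplab_invalid_argument")
    x
  }
  structure(
    list(label = label, n_subjects = as.integer(n_subjects),
         acov = chk(acov, "acov"), ifcov = chk(ifcov, "ifcov"),
         v = chk(v, "v")),
    class = "group_spec")
}

#' Simulate a labelled cohort of tapping recordings
#'
#' For each subject, feature targets (aCoV, ifCoV, V) are drawn from the
#' group's quartile-matched log-normals; a waveform is generated at those
#' targets (mean pulse height `V / (2 * mean_frequency)`, so the rendered
#' velocity matches the drawn target) and features are extracted — either
#' through the full conditioning + detection pipeline
#' (`extract = "waveform"`) or directly from the generator's realized
#' cycle list (`extract = "cycles"`, faster, no detection error).
#'
#' @param groups List of [group_spec()] objects (at least 2).
#' @param seed Integer seed for the whole cohort.
#' @param fps,duration_s,mean_frequency,noise_sd,decrement_slope Shared
#'   generator settings (defaults: 30 fps, 15 s, 2 Hz, 0.005, 0).
#' @param extract `"waveform"` (default) or `"cycles"`.
#' @return A `data.frame` (one row per subject): `subject_id`, `group`,
#'   `V`, `delta_a`, `aCoV`, `ifCoV`, `n_cycles`, `qc_pass`, plus the
#'   drawn ground-truth targets `target_aCoV`, `target_ifCoV`, `target_V`.
#' @examples
#' pd <- group_spec("PD-like", 4, acov = c(0.33, 0.28, 0.56),
#'                  ifcov = c(0.405, 0.338, 0.620), v = c(0.45, 0.155, 0.61))
#' hc <- group_spec("HC-like", 3, acov = c(0.13, 0.075, 0.175),
#'                  ifcov = c(0.115, 0.093, 0.150), v = c(0.715, 0.505, 1.085))
#' simulate_cohort(list(pd, hc), seed = 1, extract = "cycles")
#' @export
simulate_cohort <- function(groups, seed = NULL, fps = 30, duration_s = 15,
                            mean_frequency = 2, noise_sd = 0.005,
                            decrement_slope = 0,
                            extract = c("waveform", "cycles")) {
  extract <- match.arg(extract)
  if (length(groups) < 2L)
    stop_taplab("at least 2 groups required", "taplab_invalid_argument")
  stopifnot(all(vapply(groups, inherits, logical(1), "group_spec")))
  with_seed(seed, {
    rows <- list()
    sid <- 0L
    for (g in groups) {
      ln_a <- fit_lognormal_from_quartiles(g$acov[1], g$acov[2], g$acov[3])
      ln_f <- fit_lognormal_from_quartiles(g$ifcov[1], g$ifcov[2], g$ifcov[3])
      ln_v <- fit_lognormal_from_quartiles(g$v[1], g$v[2], g$v[3])
      for (i in seq_len(g$n_subjects)) {
        sid <- sid + 1L
        tg_a <- rlnorm(1, ln_a$meanlog, ln_a$sdlog)
        tg_f <- rlnorm(1, ln_f$meanlog, ln_f$sdlog)
        tg_v <- rlnorm(1, ln_v$meanlog, ln_v$sdlog)
        p <- tap_gen_params(
          mean_amplitude = tg_v / (2 * mean_frequency),
          amplitude_cov = tg_a, mean_frequency = mean_frequency,
          rhythm_cov = tg_f, decrement_slope = decrement_slope,
          noise_sd = noise_sd, fps = fps, duration_s = duration_s,
          seed = sample.int(.Machine$integer.max, 1))
        sim <- simulate_tap_waveform(p)
        ft <- tryCatch(
          if (extract == "waveform") {
            fit <- fit_taps(sim$waveform)
            fit$features
          } else {
            features_from_cycles(sim$cycles)
          },
          taplab_insufficient_cycles = function(e) NULL)
        rows[[sid]] <- data.frame(
          subject_id = sprintf("S%03d", sid), group = g$label,
          V = if (is.null(ft)) NA_real_ else ft$V,
          delta_a = if (is.null(ft)) NA_real_ else ft$delta_a,
          aCoV = if (is.null(ft)) NA_real_ else ft$aCoV,
          ifCoV = if (is.null(ft)) NA_real_ else ft$ifCoV,
          n_cycles = if (is.null(ft)) 0L else ft$n_cycles,
          qc_pass = !is.null(ft),
          target_aCoV = tg_a, target_ifCoV = tg_f, target_V = tg_v)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Attach synthetic clinical anchors to a simulated cohort
#'
#' Adds plausible clinical columns (MDS-UPDRS-III total, item 3.4 score,
#' disease duration, contralateral striatal/putaminal/caudate SBR) to a
#' simulated cohort so that correlation analyses can be exercised. Values
#' are synthetic stand-ins: severity scores increase monotonically (plus
#' noise) with the subject's amplitude-variability target in the disease
#' group, SBR decreases, and control subjects receive near-floor scores.
#' They emulate the direction of clinically observed associations, not any
#' patient data.
#'
#' @param cohort Output of [simulate_cohort()].
#' @param disease_label Label of the disease-like group (default the first
#'   group label).
#' @param seed Integer seed.
#' @return The cohort with columns `updrs3_total`, `item_3_4`,
#'   `duration_y`, `sbr_striatum`, `sbr_putamen`, `sbr_caudate` appended.
#' @export
attach_synthetic_clinical <- function(cohort, disease_label = cohort$group[1],
                                      seed = NULL) {
  with_seed(seed, {
    n <- nrow(cohort)
    dis <- cohort$group == disease_label
    sev <- scale(log(pmax(cohort$target_aCoV, 1e-6)))[, 1]
    updrs <- ifelse(dis, round(pmax(28 + 9 * sev + rnorm(n, 0, 6), 5)),
                    round(pmax(rnorm(n, 1.5, 1.2), 0)))
    item34 <- pmin(pmax(round(updrs / 12 + rnorm(n, 0, 0.5)), 0), 4)
    dur <- ifelse(dis, round(rlnorm(n, log(5), 0.5), 1), 0)
    sbr_str <- pmax(ifelse(dis, 1.1 - 0.25 * sev, 2.6) + rnorm(n, 0, 0.25), 0.2)
    cohort$updrs3_total <- updrs
    cohort$item_3_4 <- item34
    cohort$duration_y <- dur
    cohort$sbr_striatum <- round(sbr_str, 3)
    cohort$sbr_putamen <- round(pmax(sbr_str - 0.25 + rnorm(n, 0, 0.15), 0.1), 3)
    cohort$sbr_caudate <- round(pmax(sbr_str + 0.2 + rnorm(n, 0, 0.15), 0.1), 3)
    cohort
  })
}
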