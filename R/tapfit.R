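#' Fit the tap-cycle model to a distance waveform
#'
#' The central entry point of the package. Conditions the raw aperture
#' trace (detrend, Savitzky-Golay, resample, zero-phase Butterworth),
#' segments tap cycles with the refractory peak detector and computes the
#' four kinematic features. The returned `tapfit` behaves like a fitted
#' model object: `coef()` gives the feature quadruple, `fitted()` a
#' smooth per-cycle raised-cosine reconstruction through the detected
#' valleys and peaks, `residuals()` the conditioned trace minus that
#' reconstruction, `simulate()` new synthetic recordings at the fitted
#' parameters, and `plot()` the annotated trace.
#'
#' @param w A [distance_waveform()] (raw, or already conditioned if
#'   `condition = FALSE`), or a `landmark_series` (the aperture waveform is
#'   derived first).
#' @param condition Apply [condition_waveform()] first (default `TRUE`).
#' @param expected_freq,target_hz,cutoff_hz Conditioning parameters, see
#'   [condition_waveform()].
#' @param refractory_s,min_prominence_frac Detection parameters, see
#'   [detect_taps()].
#' @param qc QC report from [qc_segment()] (optional); a failing report is
#'   recorded in the features' `qc_pass` flag.
#' @return An object of class `tapfit` with components `features`,
#'   `cycles`, `waveform` (conditioned), `raw` (input waveform), `qc`,
#'   `params` and `call`.
#' @examples
#' p <- tap_gen_params(mean_amplitude = 0.15, amplitude_cov = 0.2,
#'                     mean_frequency = 2, rhythm_cov = 0.1, seed = 1)
#' sim <- simulate_tap_waveform(p)
#' fit <- fit_taps(sim$waveform)
#' coef(fit)
#' @export
fit_taps <- function(w, condition = TRUE, expected_freq = 2.0,
                     target_hz = 50, cutoff_hz = 10, refractory_s = 0.2,
                     min_prominence_frac = 0.1, qc = NULL) {
  cl <- match.call()
  if (inherits(w, "landmark_series")) {
    if (is.null(qc)) qc <- qc_segment(w)
    w <- compute_distance_waveform(w)
  }
  stopifnot(inherits(w, "distance_waveform"))
  raw <- w
  if (condition)
    w <- condition_waveform(w, expected_freq = expected_freq,
                            target_hz = target_hz, cutoff_hz = cutoff_hz)
  cycles <- detect_taps(w, refractory_s = refractory_s,
                        min_prominence_frac = min_prominence_frac)
  qc_pass <- if (is.null(qc)) TRUE else isTRUE(qc$pass)
  features <- features_from_cycles(cycles, V = compute_velocity(w),
                                   qc_pass = qc_pass)
  structure(
    list(features = features, cycles = cycles, waveform = w, raw = raw,
         qc = qc,
         params = list(expected_freq = expected_freq, target_hz = target_hz,
                       cutoff_hz = cutoff_hz, refractory_s = refractory_s,
                       min_prominence_frac = min_prominence_frac,
                       conditioned = condition),
         call = cl),
    class = "tapfit")
}

#' @export
coef.tapfit <- function(object, ...) {
  f <- object$features
  c(V = f$V, delta_a = f$delta_a, aCoV = f$aCoV, ifCoV = f$ifCoV)
}

#' @export
print.tapfit <- function(x, ...) {
  cat("Tap-cycle fit\n")
  cat(sprintf("  %d cycles over %.1f s (mean rate %.2f Hz)\n",
              x$features$n_cycles, diff(range(x$waveform$t)),
              mean(x$cycles$inst_freq)))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
summary.tapfit <- function(object, ...) {
  cy <- object$cycles
  out <- list(
    coefficients = coef(object),
    n_cycles = object$features$n_cycles,
    qc_pass = object$features$qc_pass,
    mean_amplitude = mean(cy$amplitudes),
    mean_frequency = mean(cy$inst_freq),
    duration_s = diff(range(object$waveform$t)),
    provenance = object$waveform$provenance,
    cycle_table = data.frame(
      cycle = seq_along(cy$amplitudes) - 1L,
      peak_time_s = cy$peak_times,
      amplitude = cy$amplitudes,
      interval_s = c(NA, cy$intervals))
  )
  class(out) <- "summary.tapfit"
  out
}

#' @export
print.summary.tapfit <- function(x, ...) {
  cat("Tap-cycle fit summary\n")
  cat(sprintf("  cycles: %d | mean amplitude: %.4g | mean rate: %.3g Hz | QC pass: %s\n",
              x$n_cycles, x$mean_amplitude, x$mean_frequency, x$qc_pass))
  cat("  conditioning:", paste(x$provenance, collapse = " -> "), "\n")
  cat("  features:\n")
  print(round(x$coefficients, 4))
  cat("  first cycles:\n")
  print(head(x$cycle_table, 5), row.names = FALSE)
  invisible(x)
}

#' @export
fitted.tapfit <- function(object, ...) {
  w <- object$waveform
  cy <- object$cycles
  render_cycle_arcs(w$t, w$d, cy)
}

# Raised-cosine arcs through the detected valley/peak anchors; outside the
# detected cycles the conditioned trace itself is used (zero residual).
render_cycle_arcs <- function(t, d, cy) {
  out <- d
  anchor_idx <- sort(c(cy$peak_idx, cy$valley_idx))
  for (k in seq_len(length(anchor_idx) - 1L)) {
    i0 <- anchor_idx[k]; i1 <- anchor_idx[k + 1L]
    seg <- i0:i1
    phase <- (t[seg] - t[i0]) / (t[i1] - t[i0])
    out[seg] <- d[i0] + (d[i1] - d[i0]) * 0.5 * (1 - cos(pi * phase))
  }
  out
}

#' @export
residuals.tapfit <- function(object, ...) {
  object$waveform$d - fitted(object)
}

#' Simulate new recordings from a fitted tap model
#'
#' Draws synthetic tapping waveforms whose generator parameters are
#' matched to the fitted cycles: mean amplitude and frequency from the
#' detected cycles, amplitude/rhythm CoV and decrement slope from the
#' extracted features, sampled at the conditioned rate over the fitted
#' duration.
#'
#' @param object A `tapfit`.
#' @param nsim Number of waveforms (default 1).
#' @param seed Integer seed (optional).
#' @param ... Unused.
#' @return A list of `nsim` [distance_waveform()] objects.
#' @export
simulate.tapfit <- function(object, nsim = 1, seed = NULL, ...) {
  f <- object$features
  cy <- object$cycles
  base <- list(
    mean_amplitude = mean(cy$amplitudes),
    amplitude_cov = f$aCoV,
    mean_frequency = mean(cy$inst_freq),
    rhythm_cov = f$ifCoV,
    decrement_slope = f$delta_a,
    noise_sd = stats::sd(residuals(object)),
    fps = object$waveform$sample_rate_hz,
    duration_s = diff(range(object$waveform$t)) +
      1 / object$waveform$sample_rate_hz)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max, nsim))
  lapply(seeds, function(s) {
    p <- do.call(tap_gen_params, c(base, list(seed = s)))
    simulate_tap_waveform(p)$waveform
  })
}

#' Plot a fitted tap model
#'
#' `which = 1` draws the conditioned aperture trace with detected peaks
#' and valleys; `which = 2` the per-cycle amplitudes against cycle index
#' with the decrement regression line.
#'
#' @param x A `tapfit`.
#' @param which Panels to draw (default `1:2`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.tapfit <- function(x, which = 1:2, ...) {
  w <- x$waveform
  cy <- x$cycles
  if (length(which) > 1L) {
    op <- par(mfrow = c(length(which), 1), mar = c(4, 4, 2, 1))
    on.exit(par(op))
  }
  if (1 %in% which) {
    plot(w$t, w$d, type = "l", xlab = "time (s)",
         ylab = sprintf("aperture (%s)", w$units),
         main = "Conditioned index-thumb aperture", ...)
    points(cy$peak_times, w$d[cy$peak_idx], pch = 19, col = "firebrick")
    points(cy$valley_times, w$d[cy$valley_idx], pch = 1, col = "steelblue")
  }
  if (2 %in% which) {
    i <- seq_along(cy$amplitudes) - 1L
    plot(i, cy$amplitudes, pch = 19, xlab = "cycle index",
         ylab = "cycle amplitude", main = "Amplitude decrement")
    abline(a = mean(cy$amplitudes) - x$features$delta_a * mean(i),
           b = x$features$delta_a, col = "firebrick")
  }
  invisible(x)
}
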