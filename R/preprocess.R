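#' Segment-level quality control
#'
#' Applies the recording-quality rules used before feature extraction: a
#' segment passes when at most 5% of frames are dropped/blurred (the rule
#' is strict ">5% fails", so exactly 5% passes), the longest contiguous
#' clean run lasts at least 15 s, and no hand-occlusion runs are present.
#'
#' @param series A `landmark_series`.
#' @param min_duration_s Minimum continuous clean duration in seconds
#'   (default 15).
#' @param max_dropped Maximum tolerated dropped/blurred frame fraction
#'   (default 0.05).
#' @return A `qc_report` list: `dropped_fraction`,
#'   `continuous_duration_s`, `occlusion_runs`, `pass`, `reasons`.
#' @export
qc_segment <- function(series, min_duration_s = 15, max_dropped = 0.05) {
  stopifnot(inherits(series, "landmark_series"))
  dropped <- attr(series, "dropped")
  occluded <- attr(series, "occluded")
  fps <- attr(series, "fps")
  frac <- mean(dropped | occluded)
  clean <- !(dropped | occluded)
  runs <- rle(clean)
  longest <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
  # frame-count convention: n clean frames cover n/fps seconds
  cont_s <- longest / fps
  occ_runs <- sum(rle(occluded)$values)
  reasons <- character()
  if (frac > max_dropped) reasons <- c(reasons, "dropped_frames")
  if (cont_s < min_duration_s) reasons <- c(reasons, "duration")
  if (occ_runs > 0) reasons <- c(reasons, "occlusion")
  structure(
    list(dropped_fraction = frac, continuous_duration_s = cont_s,
         occlusion_runs = occ_runs, pass = length(reasons) == 0L,
         reasons = reasons),
    class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "<qc_report> pass = %s | dropped %.1f%% | continuous %.2f s | %d occlusion run(s)\n",
    x$pass, 100 * x$dropped_fraction, x$continuous_duration_s,
    x$occlusion_runs))
  if (length(x$reasons)) cat("  reasons:", paste(x$reasons, collapse = ", "), "\n")
  invisible(x)
}

#' Remove the linear trend from a distance waveform
#'
#' Subtracts the least-squares line of `d` on `t`, removing slow aperture
#' drift (e.g. gradual hand-camera distance change) before cycle analysis.
#' The result has zero mean and zero slope; the step is idempotent.
#'
#' @param w A [distance_waveform()], at least 3 samples.
#' @return The detrended waveform with provenance entry `"detrend"`.
#' @export
detrend_linear <- function(w) {
  stopifnot(inherits(w, "distance_waveform"))
  if (length(w$d) < 3L)
    stop_taplab("detrend requires at least 3 samples", "taplab_invalid_argument")
  fit <- lm.fit(cbind(1, w$t), w$d)
  w$d <- unname(fit$residuals)
  wf_provenance_append(w, "detrend")
}

# Window rule: largest odd integer <= (fps / expected_freq) / 3, floored at
# 5 samples (about one third of the expected tap cycle).
savgol_window <- function(fps, expected_freq) {
  n <- floor((fps / expected_freq) / 3)
  if (n %% 2 == 0) n <- n - 1
  max(n, 5L)
}

#' Savitzky-Golay smoothing of the distance trace
#'
#' Order-2 Savitzky-Golay filter whose window is fixed a priori by the
#' frame rate and the expected tap cycle: the largest odd number of samples
#' not exceeding one third of the expected cycle, never below 5. Endpoints
#' are fitted with the filter's truncated-window polynomial rows, so
#' quadratic signals pass through unchanged everywhere.
#'
#' @param w A [distance_waveform()].
#' @param fps Sampling rate used for the window rule; defaults to the
#'   waveform's `sample_rate_hz`.
#' @param expected_freq Expected tapping frequency in Hz (default 2).
#' @return The smoothed waveform, provenance `"savgol(n)"`.
#' @export
smooth_savgol <- function(w, fps = NULL, expected_freq = 2.0) {
  stopifnot(inherits(w, "distance_waveform"))
  if (is.null(fps)) fps <- w$sample_rate_hz
  n <- savgol_window(fps, expected_freq)
  if (length(w$d) <= n)
    stop_taplab(sprintf("trace shorter than the %d-sample smoothing window", n),
                "taplab_invalid_argument")
  w$d <- as.numeric(signal::sgolayfilt(w$d, p = 2, n = n))
  wf_provenance_append(w, sprintf("savgol(window=%d,order=2)", n))
}

#' Resample a waveform onto a uniform grid
#'
#' Linear interpolation onto a uniform grid starting at the first
#' timestamp. The output length preserves the recording duration measured
#' in frame periods (`round(n_in * target_hz / rate_in)` for uniform
#' input), so 15 s at 30 fps yields 750 samples at 50 Hz; grid points
#' past the final timestamp (at most one frame period) are linearly
#' extrapolated from the last segment. Input already uniform at the target
#' rate is passed through unchanged (provenance is still appended).
#'
#' @param w A [distance_waveform()] with at least 2 samples.
#' @param target_hz Target sampling rate (default 50).
#' @return The resampled waveform, provenance `"resample(target)"`.
#' @export
resample_uniform <- function(w, target_hz = 50) {
  stopifnot(inherits(w, "distance_waveform"))
  n <- length(w$d)
  if (n < 2L)
    stop_taplab("resampling requires at least 2 samples", "taplab_invalid_argument")
  prov <- sprintf("resample(%g Hz)", target_hz)
  if (is_uniform_times(w$t) &&
      isTRUE(all.equal(1 / median(diff(w$t)), target_hz, tolerance = 1e-9))) {
    w$sample_rate_hz <- target_hz
    return(wf_provenance_append(w, prov))
  }
  rate_in <- if (is_uniform_times(w$t)) 1 / median(diff(w$t)) else
    (n - 1) / (w$t[n] - w$t[1])
  n_out <- round(n * target_hz / rate_in)
  tout <- w$t[1] + (seq_len(n_out) - 1) / target_hz
  dout <- approx(w$t, w$d, xout = tout, rule = 2)$y
  beyond <- tout > w$t[n]
  if (any(beyond)) {
    slope <- (w$d[n] - w$d[n - 1]) / (w$t[n] - w$t[n - 1])
    dout[beyond] <- w$d[n] + slope * (tout[beyond] - w$t[n])
  }
  out <- distance_waveform(tout, dout, sample_rate_hz = target_hz,
                           provenance = w$provenance, units = w$units)
  wf_provenance_append(out, prov)
}

#' Zero-phase Butterworth low-pass filter
#'
#' 5th-order Butterworth low-pass applied forward and backward
#' (zero phase, so peak timing — and hence rhythm variability — is
#' preserved). The trace mean is removed before filtering and restored
#' afterwards, and the signal is reflected at both ends to suppress edge
#' transients; DC gain is exactly 1.
#'
#' @param w A uniformly sampled [distance_waveform()].
#' @param order Filter order (default 5).
#' @param cutoff_hz Cutoff frequency in Hz (default 10); must be below the
#'   Nyquist frequency.
#' @return The filtered waveform, provenance `"butterworth(...)"`.
#' @export
lowpass_butterworth <- function(w, order = 5, cutoff_hz = 10) {
  stopifnot(inherits(w, "distance_waveform"))
  sr <- w$sample_rate_hz
  if (!is.finite(sr) || sr <= 2 * cutoff_hz)
    stop_taplab("cutoff must be below the Nyquist frequency",
                "taplab_invalid_argument")
  n <- length(w$d)
  bf <- signal::butter(order, cutoff_hz / (sr / 2), type = "low")
  mu <- mean(w$d)
  x <- w$d - mu
  # reflect ends (anti-symmetric about the endpoints) to tame transients
  k <- min(n - 1L, max(3L * order, 12L))
  left <- 2 * x[1] - x[(k + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - k)]
  y <- signal::filtfilt(bf, c(left, x, right))
  w$d <- y[(k + 1):(k + n)] + mu
  wf_provenance_append(w, sprintf("butterworth(order=%d,cutoff=%g Hz)", order, cutoff_hz))
}

#' Full signal-conditioning pipeline
#'
#' Applies, in order: linear detrend, Savitzky-Golay smoothing, resampling
#' to a uniform rate, and a zero-phase Butterworth low-pass. Each step
#' appends one provenance entry; downstream tap detection expects this
#' conditioned trace.
#'
#' @param w A raw [distance_waveform()].
#' @param expected_freq Expected tapping frequency in Hz (default 2).
#' @param target_hz Resampling rate (default 50).
#' @param cutoff_hz Low-pass cutoff (default 10).
#' @param order Butterworth order (default 5).
#' @return The conditioned waveform.
#' @export
condition_waveform <- function(w, expected_freq = 2.0, target_hz = 50,
                               cutoff_hz = 10, order = 5) {
  w <- detrend_linear(w)
  w <- smooth_savgol(w, expected_freq = expected_freq)
  w <- resample_uniform(w, target_hz = target_hz)
  lowpass_butterworth(w, order = order, cutoff_hz = cutoff_hz)
}
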