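#' Tap-cycle segmentation with a refractory interval
#'
#' Detects tap peaks on the conditioned aperture trace: candidate local
#' maxima (leftmost sample of equal-height plateaus) are kept when their
#' topographic prominence reaches `min_prominence_frac` of the global
#' signal range, then pruned greedily (highest peak first) so that no two
#' retained peaks lie within the refractory interval — guarding against
#' double counts from ripple near a true tap. The valley between two
#' consecutive peaks is the minimum sample in between; per-cycle amplitude
#' is the peak height minus the mean of its adjacent valleys.
#'
#' @param w A conditioned [distance_waveform()].
#' @param refractory_s Minimum peak spacing in seconds (default 0.2,
#'   i.e. a 5 Hz ceiling on credible tapping).
#' @param min_prominence_frac Prominence threshold as a fraction of the
#'   global range (default 0.1).
#' @return A `tap_cycles` object: `peak_idx`, `peak_times`, `valley_idx`,
#'   `valley_times`, `amplitudes`, `intervals` (between consecutive
#'   peaks), `inst_freq` (1/interval).
#' @examples
#' t <- seq(0, 15, by = 0.02)
#' w <- distance_waveform(t, sin(2 * pi * 2 * t))
#' detect_taps(w)$intervals[1:3]  # all 0.5 s at 2 Hz
#' @export
detect_taps <- function(w, refractory_s = 0.2, min_prominence_frac = 0.1) {
  stopifnot(inherits(w, "distance_waveform"))
  d <- w$d
  t <- w$t
  n <- length(d)
  rng <- max(d) - min(d)
  cand <- integer()
  if (n >= 3L && rng > 0) {
    i <- 2L
    while (i < n) {
      if (d[i] > d[i - 1L]) {
        # scan plateau of equal values; leftmost sample represents it
        j <- i
        while (j < n && d[j + 1L] == d[i]) j <- j + 1L
        if (j < n && d[j + 1L] < d[i]) cand <- c(cand, i)
        i <- j + 1L
      } else i <- i + 1L
    }
  }
  if (length(cand)) {
    prom <- vapply(cand, function(i) peak_prominence(d, i), numeric(1))
    cand <- cand[prom >= min_prominence_frac * rng]
  }
  # greedy refractory suppression, tallest first (ties -> leftmost)
  keep <- integer()
  for (i in cand[order(-d[cand], cand)]) {
    if (!length(keep) || all(abs(t[i] - t[keep]) > refractory_s))
      keep <- c(keep, i)
  }
  peaks <- sort(keep)
  if (length(peaks) < 5L)
    stop_taplab(sprintf("only %d tap peaks detected; at least 5 cycles required",
                        length(peaks)),
                "taplab_insufficient_cycles")
  valleys <- vapply(seq_len(length(peaks) - 1L), function(k) {
    seg <- (peaks[k] + 1L):(peaks[k + 1L] - 1L)
    seg[which.min(d[seg])]
  }, integer(1))
  vleft <- c(NA_integer_, valleys)   # valley left of peak k
  vright <- c(valleys, NA_integer_)  # valley right of peak k
  amps <- vapply(seq_along(peaks), function(k) {
    vv <- d[c(vleft[k], vright[k])]
    d[peaks[k]] - mean(vv[!is.na(vv)])
  }, numeric(1))
  intervals <- diff(t[peaks])
  structure(
    list(peak_idx = peaks, peak_times = t[peaks],
         valley_idx = valleys, valley_times = t[valleys],
         amplitudes = amps, intervals = intervals,
         inst_freq = 1 / intervals),
    class = "tap_cycles")
}

# Topographic prominence of the peak at index i: height above the higher
# of the two deepest points separating it from taller terrain (or edge).
peak_prominence <- function(d, i) {
  n <- length(d)
  lmin <- d[i]
  j <- i
  while (j > 1L) {
    j <- j - 1L
    if (d[j] > d[i]) break
    if (d[j] < lmin) lmin <- d[j]
  }
  rmin <- d[i]
  j <- i
  while (j < n) {
    j <- j + 1L
    if (d[j] > d[i]) break
    if (d[j] < rmin) rmin <- d[j]
  }
  d[i] - max(lmin, rmin)
}

#' @export
print.tap_cycles <- function(x, ...) {
  cat(sprintf(
    "<tap_cycles> %d peaks | mean amplitude %.4g | mean rate %.3g Hz\n",
    length(x$peak_times), mean(x$amplitudes), mean(x$inst_freq)))
  invisible(x)
}

#' Tapping velocity
#'
#' Mean absolute first derivative of the aperture trace, in aperture units
#' per second: `V = mean(|d[k+1] - d[k]|) * sample_rate`. For a sinusoidal
#' aperture of half-range A and frequency f this converges to 4Af.
#'
#' @param w A conditioned [distance_waveform()] with at least 2 samples.
#' @return Scalar velocity `V`.
#' @export
compute_velocity <- function(w) {
  stopifnot(inherits(w, "distance_waveform"))
  if (length(w$d) < 2L)
    stop_taplab("velocity requires at least 2 samples", "taplab_invalid_argument")
  mean(abs(diff(w$d))) * w$sample_rate_hz
}

#' Amplitude decrement (sequence effect)
#'
#' Ordinary least-squares slope of per-cycle amplitude on 0-based cycle
#' index, in aperture units per cycle. Negative values indicate the
#' progressive amplitude reduction typical of bradykinesia.
#'
#' @param cycles A `tap_cycles` object (or numeric amplitude vector) with
#'   at least 5 cycles.
#' @return Scalar slope `delta_a`.
#' @export
compute_amplitude_decrement <- function(cycles) {
  a <- if (inherits(cycles, "tap_cycles")) cycles$amplitudes else as.numeric(cycles)
  if (length(a) < 5L)
    stop_taplab("amplitude decrement requires at least 5 cycles",
                "taplab_insufficient_cycles")
  i <- seq_along(a) - 1
  sum((i - mean(i)) * (a - mean(a))) / sum((i - mean(i))^2)
}

#' Amplitude coefficient of variation
#'
#' Sample standard deviation (n-1 denominator) of per-cycle amplitudes
#' divided by their mean; dimensionless, invariant to amplitude scaling.
#'
#' @inheritParams compute_amplitude_decrement
#' @return Scalar `aCoV`.
#' @export
compute_acov <- function(cycles) {
  a <- if (inherits(cycles, "tap_cycles")) cycles$amplitudes else as.numeric(cycles)
  if (length(a) < 5L)
    stop_taplab("aCoV requires at least 5 cycles", "taplab_insufficient_cycles")
  if (mean(a) <= 0)
    stop_taplab("mean amplitude must be positive", "taplab_invalid_argument")
  sd(a) / mean(a)
}

#' Rhythm (instantaneous-frequency) coefficient of variation
#'
#' Sample sd over mean of the instantaneous frequencies `1/dt` between
#' consecutive tap peaks; dimensionless, invariant to uniform time
#' dilation.
#'
#' @param cycles A `tap_cycles` object (or numeric vector of inter-tap
#'   intervals in seconds) with at least 4 intervals.
#' @return Scalar `ifCoV`.
#' @export
compute_ifcov <- function(cycles) {
  dt <- if (inherits(cycles, "tap_cycles")) cycles$intervals else as.numeric(cycles)
  if (length(dt) < 4L)
    stop_taplab("ifCoV requires at least 4 inter-tap intervals",
                "taplab_insufficient_cycles")
  if (any(dt <= 0))
    stop_taplab("all inter-tap intervals must be positive",
                "taplab_invalid_argument")
  f <- 1 / dt
  sd(f) / mean(f)
}

#' Extract the four kinematic features from a conditioned waveform
#'
#' Runs [detect_taps()] and computes tapping velocity, amplitude
#' decrement, amplitude CoV and rhythm CoV.
#'
#' @param w A conditioned [distance_waveform()].
#' @param refractory_s,min_prominence_frac Passed to [detect_taps()].
#' @param qc_pass Logical QC flag carried through to the result
#'   (default `TRUE`).
#' @return A `kinematic_features` list with elements `V`, `delta_a`,
#'   `aCoV`, `ifCoV`, `n_cycles`, `qc_pass`.
#' @export
extract_features <- function(w, refractory_s = 0.2, min_prominence_frac = 0.1,
                             qc_pass = TRUE) {
  cycles <- detect_taps(w, refractory_s = refractory_s,
                        min_prominence_frac = min_prominence_frac)
  features_from_cycles(cycles, V = compute_velocity(w), qc_pass = qc_pass)
}

features_from_cycles <- function(cycles, V = NA_real_, qc_pass = TRUE) {
  structure(
    list(V = V,
         delta_a = compute_amplitude_decrement(cycles),
         aCoV = compute_acov(cycles),
         ifCoV = compute_ifcov(cycles),
         n_cycles = length(cycles$amplitudes),
         qc_pass = qc_pass),
    class = "kinematic_features")
}

#' @export
print.kinematic_features <- function(x, ...) {
  cat(sprintf(
    "<kinematic_features> V = %.4g | delta_a = %.4g | aCoV = %.4g | ifCoV = %.4g (%d cycles%s)\n",
    x$V, x$delta_a, x$aCoV, x$ifCoV, x$n_cycles,
    if (isTRUE(x$qc_pass)) "" else ", QC fail"))
  invisible(x)
}
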