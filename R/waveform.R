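#' Distance waveform container
#'
#' A `distance_waveform` holds the scalar index-thumb aperture trace of one
#' recording: timestamps `t` (seconds, strictly increasing), aperture `d`
#' (image-normalized units; the field's convention labels them "px"), the
#' nominal sampling rate, and an append-only provenance log of the
#' preprocessing steps already applied.
#'
#' @param t Numeric vector of timestamps in seconds, strictly increasing.
#' @param d Numeric vector of apertures, same length as `t`, all finite.
#' @param sample_rate_hz Sampling rate in Hz. If `NULL`, inferred from the
#'   median time step.
#' @param provenance Character vector naming transforms already applied.
#' @param units Unit label for `d` (default `"norm"`).
#' @return An object of class `distance_waveform`.
#' @examples
#' t <- seq(0, 5, by = 1 / 30)
#' w <- distance_waveform(t, 0.1 + 0.05 * sin(2 * pi * 2 * t))
#' w
#' @export
distance_waveform <- function(t, d, sample_rate_hz = NULL,
                              provenance = character(), units = "norm") {
  t <- as.numeric(t)
  d <- as.numeric(d)
  if (length(t) != length(d))
    stop_taplab("`t` and `d` must have the same length", "taplab_invalid_argument")
  if (length(t) == 0L)
    stop_taplab("empty waveform", "taplab_invalid_argument")
  if (any(!is.finite(d)))
    stop_taplab("`d` must be finite", "taplab_invalid_argument")
  if (length(t) > 1L && any(diff(t) <= 0))
    stop_taplab("`t` must be strictly increasing", "taplab_invalid_argument")
  if (is.null(sample_rate_hz)) {
    sample_rate_hz <- if (length(t) > 1L) 1 / median(diff(t)) else NA_real_
  }
  structure(
    list(t = t, d = d, sample_rate_hz = sample_rate_hz,
         provenance = as.character(provenance), units = units),
    class = "distance_waveform"
  )
}

# Append one provenance entry; steps never overwrite earlier history.
wf_provenance_append <- function(w, entry) {
  w$provenance <- c(w$provenance, entry)
  w
}

is_uniform_times <- function(t, tol = 1e-9) {
  if (length(t) < 3L) return(TRUE)
  dt <- diff(t)
  max(dt) - min(dt) < tol * max(dt)
}

#' @export
print.distance_waveform <- function(x, ...) {
  dur <- diff(range(x$t))
  cat(sprintf(
    "<distance_waveform> %d samples, %.2f s @ %.6g Hz [%s]\n",
    length(x$d), dur + 1 / x$sample_rate_hz, x$sample_rate_hz, x$units))
  cat(sprintf("  aperture range: [%.4g, %.4g]\n", min(x$d), max(x$d)))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' @export
length.distance_waveform <- function(x) length(x$d)

#' Read or write a distance waveform as CSV
#'
#' The waveform dialect is a two-column CSV `time_s,d`. Sampling-rate and
#' provenance metadata travel in an optional JSON sidecar `<path>.json`.
#'
#' @param path CSV file path.
#' @param w A [distance_waveform()].
#' @param sidecar Write/read the JSON metadata sidecar (default `TRUE`).
#' @return `read_waveform()` returns a `distance_waveform`;
#'   `write_waveform()` returns `path` invisibly.
#' @export
read_waveform <- function(path, sidecar = TRUE) {
  df <- read.csv(path)
  if (!all(c("time_s", "d") %in% names(df)))
    stop_taplab("waveform CSV must have columns time_s,d", "taplab_format_error")
  sr <- NULL
  prov <- character()
  units <- "norm"
  sc <- paste0(path, ".json")
  if (sidecar && file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(meta$sample_rate_hz)) sr <- meta$sample_rate_hz
    if (!is.null(meta$provenance)) prov <- meta$provenance
    if (!is.null(meta$units)) units <- meta$units
  }
  distance_waveform(df$time_s, df$d, sample_rate_hz = sr,
                    provenance = prov, units = units)
}

#' @rdname read_waveform
#' @export
write_waveform <- function(w, path, sidecar = TRUE) {
  stopifnot(inherits(w, "distance_waveform"))
  write.csv(data.frame(time_s = w$t, d = w$d), path, row.names = FALSE)
  if (sidecar) {
    jsonlite::write_json(
      list(sample_rate_hz = w$sample_rate_hz, provenance = w$provenance,
           units = w$units),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
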