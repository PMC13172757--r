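#' Read a hand-landmark table
#'
#' Reads the long-format landmark CSV dialect
#' `frame,time_s,landmark,x,y,confidence` (one row per landmark per frame)
#' produced by markerless hand-pose backends. Only the two fingertips used
#' by the tapping analysis are accepted (`INDEX_TIP`, `THUMB_TIP`).
#' Coordinates are image-normalized in \[0, 1\] with origin top-left, x
#' rightward, y downward. Frames in which either fingertip is missing are
#' retained in the frame accounting but flagged as dropped; frames whose
#' minimum landmark confidence falls below `occlusion_conf` are flagged as
#' occluded. A JSON sidecar `<path>.json` may carry `fps` and `hand_label`.
#'
#' @param path CSV file path.
#' @param fps Frames per second. Overrides the sidecar; if neither is
#'   given, inferred from the median `time_s` step.
#' @param hand_label One of `"left"`, `"right"`, `"dominant"`,
#'   `"most_affected"`; overrides the sidecar (default `"most_affected"`).
#' @param clamp If `TRUE`, coordinates outside \[0, 1\] are clamped with a
#'   warning instead of raising a format error.
#' @param occlusion_conf Frames with confidence strictly below this value
#'   are flagged occluded (default 0.1).
#' @return A `landmark_series`: a data frame with one row per retained
#'   frame and columns `frame`, `time_s`, `ix`, `iy`, `tx`, `ty`,
#'   `confidence`, plus attributes `fps`, `hand_label`, `frames` (all frame
#'   indices seen), `dropped` and `occluded` (logical, aligned to
#'   `frames`).
#' @seealso [compute_distance_waveform()], [qc_segment()]
#' @export
read_landmark_table <- function(path, fps = NULL, hand_label = NULL,
                                clamp = FALSE, occlusion_conf = 0.1) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "time_s", "landmark", "x", "y")
  if (!all(need %in% names(df)))
    stop_taplab(
      "landmark CSV must have columns frame,time_s,landmark,x,y[,confidence]",
      "taplab_format_error")
  if (!"confidence" %in% names(df)) df$confidence <- NA_real_
  sc <- paste0(path, ".json")
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (is.null(fps) && !is.null(meta$fps)) fps <- meta$fps
    if (is.null(hand_label) && !is.null(meta$hand_label))
      hand_label <- meta$hand_label
  }
  if (is.null(hand_label)) hand_label <- "most_affected"
  landmark_series(df, fps = fps, hand_label = hand_label, clamp = clamp,
                  occlusion_conf = occlusion_conf)
}

#' Construct a landmark series from a long-format data frame
#'
#' @param df Data frame with columns `frame`, `time_s`, `landmark`, `x`,
#'   `y` and optionally `confidence`.
#' @inheritParams read_landmark_table
#' @return A `landmark_series` (see [read_landmark_table()]).
#' @export
landmark_series <- function(df, fps = NULL, hand_label = "most_affected",
                            clamp = FALSE, occlusion_conf = 0.1) {
  valid_ids <- c("INDEX_TIP", "THUMB_TIP")
  if (nrow(df) == 0L)
    stop_taplab("empty landmark table", "taplab_invalid_argument")
  bad <- setdiff(unique(df$landmark), valid_ids)
  if (length(bad))
    stop_taplab(paste0("unknown landmark_id: ", paste(bad, collapse = ", ")),
                "taplab_format_error")
  hand_label <- match.arg(hand_label,
                          c("left", "right", "dominant", "most_affected"))
  for (id in valid_ids) {
    fr <- df$frame[df$landmark == id]
    if (length(fr) > 1L && any(diff(fr) <= 0))
      stop_taplab(paste0("frame_index not strictly increasing for ", id),
                  "taplab_format_error")
  }
  out_of_range <- !is.na(df$x) & !is.na(df$y) &
    (df$x < 0 | df$x > 1 | df$y < 0 | df$y > 1)
  if (any(out_of_range)) {
    if (!clamp)
      stop_taplab("coordinates outside [0,1]; use clamp = TRUE to clip",
                  "taplab_format_error")
    warning(sprintf("clamping %d coordinates to [0,1]", sum(out_of_range)))
    df$x <- pmin(pmax(df$x, 0), 1)
    df$y <- pmin(pmax(df$y, 0), 1)
  }
  if (is.null(fps)) {
    ts <- sort(unique(df$time_s))
    if (length(ts) < 2L)
      stop_taplab("cannot infer fps from a single frame; supply `fps`",
                  "taplab_invalid_argument")
    fps <- 1 / median(diff(ts))
  }
  if (!is.finite(fps) || fps <= 0)
    stop_taplab("fps must be > 0", "taplab_invalid_argument")

  frames <- sort(unique(df$frame))
  idx <- df[df$landmark == "INDEX_TIP", , drop = FALSE]
  thb <- df[df$landmark == "THUMB_TIP", , drop = FALSE]
  mi <- match(frames, idx$frame)
  mt <- match(frames, thb$frame)
  present <- !is.na(mi) & !is.na(mt) &
    complete.cases(idx[mi, c("x", "y")]) & complete.cases(thb[mt, c("x", "y")])
  conf <- pmin(ifelse(is.na(mi), NA, idx$confidence[mi]),
               ifelse(is.na(mt), NA, thb$confidence[mt]))
  occluded <- present & !is.na(conf) & conf < occlusion_conf
  dropped <- !present
  keep <- present & !occluded
  out <- data.frame(
    frame = frames[keep],
    time_s = idx$time_s[mi[keep]],
    ix = idx$x[mi[keep]], iy = idx$y[mi[keep]],
    tx = thb$x[mt[keep]], ty = thb$y[mt[keep]],
    confidence = conf[keep]
  )
  structure(out, class = c("landmark_series", "data.frame"),
            fps = fps, hand_label = hand_label, frames = frames,
            dropped = dropped, occluded = occluded)
}

#' Write a landmark series back to the long-format CSV dialect
#'
#' Dropped frames are not representable (their landmarks are unknown), so
#' the round trip `write -> read` is the identity on retained frames.
#'
#' @param series A `landmark_series`.
#' @param path Output CSV path; the metadata sidecar `<path>.json` records
#'   `fps` and `hand_label`.
#' @return `path`, invisibly.
#' @export
write_landmark_table <- function(series, path) {
  stopifnot(inherits(series, "landmark_series"))
  long <- rbind(
    data.frame(frame = series$frame, time_s = series$time_s,
               landmark = "INDEX_TIP", x = series$ix, y = series$iy,
               confidence = series$confidence),
    data.frame(frame = series$frame, time_s = series$time_s,
               landmark = "THUMB_TIP", x = series$tx, y = series$ty,
               confidence = series$confidence)
  )
  long <- long[order(long$frame, long$landmark), ]
  write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(
    list(fps = attr(series, "fps"), hand_label = attr(series, "hand_label")),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Fraction of frames flagged as dropped or occluded
#'
#' @param series A `landmark_series`.
#' @return Scalar in \[0, 1\].
#' @export
dropped_fraction <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  mean(attr(series, "dropped") | attr(series, "occluded"))
}

#' Derive the index-thumb aperture waveform
#'
#' Computes the Euclidean distance between the index fingertip and thumb
#' tip on every retained frame. Timestamps are taken as
#' `frame_index / fps`, so gaps left by dropped frames remain visible in
#' the time axis and are recorded for quality control.
#'
#' @param series A `landmark_series`.
#' @return A [distance_waveform()] with provenance `"distance"`; the
#'   attribute `n_gaps` counts missing-frame gaps inside the retained span.
#' @examples
#' df <- data.frame(frame = c(0, 0), time_s = c(0, 0),
#'                  landmark = c("INDEX_TIP", "THUMB_TIP"),
#'                  x = c(0.3, 0), y = c(0.4, 0), confidence = 1)
#' # a single frame cannot carry an fps; supply it
#' s <- landmark_series(df, fps = 30)
#' compute_distance_waveform(s)$d  # 3-4-5 triangle: 0.5
#' @export
compute_distance_waveform <- function(series) {
  stopifnot(inherits(series, "landmark_series"))
  if (nrow(series) == 0L)
    stop_taplab("no retained frames", "taplab_invalid_argument")
  fps <- attr(series, "fps")
  d <- sqrt((series$ix - series$tx)^2 + (series$iy - series$ty)^2)
  t <- series$frame / fps
  w <- distance_waveform(t, d, sample_rate_hz = fps, provenance = "distance")
  attr(w, "n_gaps") <- sum(diff(series$frame) > 1)
  attr(w, "dropped_fraction") <- dropped_fraction(series)
  w
}
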