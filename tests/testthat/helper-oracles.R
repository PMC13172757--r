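# Fixture builders and independent brute-force oracles used across tests.

# sinusoidal aperture waveform: d(t) = offset + A * sin(2*pi*f*t)
make_sine_wave <- function(f = 2, A = 0.1, offset = 0.15, fps = 50,
                           duration = 15) {
  t <- (seq_len(round(fps * duration)) - 1) / fps
  distance_waveform(t, offset + A * sin(2 * pi * f * t), sample_rate_hz = fps)
}

# long-format landmark table: thumb fixed, index moving vertically so the
# aperture is offset + A*sin(2*pi*f*t); selected frames lose the thumb row
make_landmark_df <- function(n_frames, fps = 30, f = 2, A = 0.1,
                             offset = 0.3, drop_frames = integer()) {
  fr <- seq_len(n_frames) - 1L
  ts <- fr / fps
  ap <- offset + A * sin(2 * pi * f * ts)
  idx <- data.frame(frame = fr, time_s = ts, landmark = "INDEX_TIP",
                    x = 0.5, y = 0.5 - ap, confidence = 0.99)
  thb <- data.frame(frame = fr, time_s = ts, landmark = "THUMB_TIP",
                    x = 0.5, y = 0.5, confidence = 0.99)
  thb <- thb[!thb$frame %in% drop_frames, ]
  df <- rbind(idx, thb)
  df[order(df$frame, df$landmark), ]
}

# naive O(n^2) peak oracle: plateau-leftmost local maxima, prominence by
# double scan, greedy refractory suppression tallest-first
oracle_peaks <- function(d, t, refractory_s, prom_frac) {
  n <- length(d)
  rng <- max(d) - min(d)
  cand <- c()
  for (i in 2:(n - 1)) {
    if (d[i] <= d[i - 1]) next
    j <- i
    while (j < n && d[j + 1] == d[i]) j <- j + 1
    if (j >= n || d[j + 1] >= d[i]) next
    # prominence: deepest point to the first taller sample on each side
    lmin <- d[i]
    for (k in (i - 1):1) {
      if (d[k] > d[i]) break
      lmin <- min(lmin, d[k])
    }
    rmin <- d[i]
    for (k in (j + 1):n) {
      if (d[k] > d[i]) break
      rmin <- min(rmin, d[k])
    }
    if (d[i] - max(lmin, rmin) >= prom_frac * rng) cand <- c(cand, i)
  }
  acc <- c()
  for (i in cand[order(-d[cand], cand)]) {
    if (!length(acc) || all(abs(t[i] - t[acc]) > refractory_s))
      acc <- c(acc, i)
  }
  sort(acc)
}

# pairwise-comparison AUC oracle: P(pos > neg) + 0.5 * P(pos == neg)
oracle_auc <- function(pos_scores, neg_scores) {
  s <- 0
  for (p in pos_scores) for (q in neg_scores)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos_scores) * length(neg_scores))
}

# exhaustive threshold-scan Youden oracle over every candidate cutoff
oracle_youden_j <- function(scores, pos) {
  u <- sort(unique(scores))
  cand <- (u[-1] + u[-length(u)]) / 2
  best <- -Inf
  for (c in cand) {
    j <- mean(scores[pos] >= c) + mean(scores[!pos] < c) - 1
    if (j > best) best <- j
  }
  best
}

# smooth random test trace: cumulative-sum noise passed twice through a
# short moving average (band-limited enough to have isolated extrema)
make_smooth_trace <- function(n, seed) {
  set.seed(seed)
  x <- cumsum(rnorm(n))
  k <- rep(1 / 7, 7)
  x <- stats::filter(x, k, circular = TRUE)
  as.numeric(stats::filter(x, k, circular = TRUE))
}
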