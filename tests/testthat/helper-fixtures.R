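# Shared fixtures and independent oracles used across test files.

# Independent exhaustive-scan extremum oracles (plain loops, no which.max).
oracle_argmax <- function(x, from, to) {
  best <- from
  for (i in from:to) if (x[i] > x[best]) best <- i
  best
}
oracle_argmin <- function(x, from, to) {
  best <- from
  for (i in from:to) if (x[i] < x[best]) best <- i
  best
}

# Independent shoelace area oracle (pairwise cross-product sum).
oracle_shoelace <- function(x, y) {
  n <- length(x)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + x[i] * y[j] - x[j] * y[i]
  }
  abs(s) / 2
}

# Independent BT.601 full-range YUV->RGB oracle, scalar per pixel.
oracle_yuv2rgb <- function(y, u, v) {
  r <- y + 1.402 * (v - 128)
  g <- y - 0.344136 * (u - 128) - 0.714136 * (v - 128)
  b <- y + 1.772 * (u - 128)
  pmin(255, pmax(0, c(r, g, b)))
}

# A clean (noise-free, drift-free) high-rate beat train.
clean_train <- function(duration_s = 12, fs = 60, seed = 101L, ...) {
  generate_beat_train(
    beat_model_params(noise_snr_db = Inf, drift_amp = 0, fs = fs,
                      seed = seed, ...),
    duration_s = duration_s)
}

# Segment a generated train with the standard preprocessing.
segment_train <- function(train) {
  sig <- suppressMessages(detrend_filter(train$signal))
  suppressMessages(detect_beats(sig))
}

# Construct a bare beat_segment from a value vector (for unit-level tests).
make_beat <- function(values, fs = 60) {
  structure(list(start_idx = 0L, end_idx = length(values),
                 values = as.numeric(values),
                 duration = length(values) / fs, fs = fs),
            class = "beat_segment")
}

# Psychological outcome columns of a generated cohort.
psych_outcomes <- c("swls", "svs", "panas_p", "panas_n", "phq9", "gad7",
                    "valence", "arousal")
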