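#' Construct a frame stack
#'
#' A frame stack is the rawest input of the pipeline: a sequence of fingertip
#' video frames captured under flashlight illumination, together with per-frame
#' timestamps. Frames are stored as a `T x H x W x 3` numeric array of
#' intensities in `[0, 255]`; the third colour axis is either YUV (as recorded
#' by most phone cameras) or RGB.
#'
#' @param frames numeric array `T x H x W x 3`, intensities in `[0, 255]`.
#' @param timestamps numeric vector of length `T`, seconds, strictly increasing.
#' @param color_space `"YUV"` or `"RGB"`.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, timestamps, color_space = c("RGB", "YUV")) {
  color_space <- match.arg(color_space)
  d <- dim(frames)
  if (length(d) != 4L || d[4] != 3L)
    stop("`frames` must be a T x H x W x 3 array")
  if (d[1] < 2L) stop("a frame stack needs at least 2 frames")
  if (length(timestamps) != d[1])
    stop("`timestamps` length must match the number of frames")
  if (any(diff(timestamps) <= 0))
    stop("`timestamps` must be strictly increasing")
  finite <- is.finite(frames)
  if (all(finite) && (min(frames) < 0 || max(frames) > 255))
    stop("frame intensities must lie in [0, 255]")
  structure(list(frames = frames, timestamps = as.numeric(timestamps),
                 color_space = color_space),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames, %dx%d px, %s, %.2f s\n",
              d[1], d[2], d[3], x$color_space,
              diff(range(x$timestamps))))
  invisible(x)
}

#' Construct a PPG signal
#'
#' A uniformly sampled single-channel pulse trace. Downstream beat detection
#' requires at least two seconds of signal.
#'
#' @param values numeric vector of amplitudes (arbitrary units).
#' @param fs sampling rate in Hz.
#' @param t0 start time in seconds.
#' @param source one of `"video"`, `"oximeter"`, `"synthetic"`.
#' @return An object of class `ppg_signal`.
#' @export
ppg_signal <- function(values, fs, t0 = 0,
                       source = c("video", "oximeter", "synthetic")) {
  source <- match.arg(source)
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) stop("`fs` must be > 0")
  if (!all(is.finite(values))) stop("`values` must be finite")
  if (length(values) < 2 * fs)
    stop("signal too short: need at least 2 s for beat detection")
  structure(list(values = as.numeric(values), fs = as.numeric(fs),
                 t0 = as.numeric(t0), source = source),
            class = "ppg_signal")
}

#' @export
print.ppg_signal <- function(x, ...) {
  cat(sprintf("<ppg_signal> %d samples @ %g Hz (%.1f s), source=%s\n",
              length(x$values), x$fs, length(x$values) / x$fs, x$source))
  invisible(x)
}

#' Time axis of a PPG signal
#' @param sig a `ppg_signal`.
#' @return numeric vector of sample times in seconds.
#' @export
ppg_time <- function(sig) {
  sig$t0 + (seq_along(sig$values) - 1L) / sig$fs
}

# BT.601 full-range YUV -> RGB. Chroma is centred at 128.
.yuv2rgb_pixel <- function(y, u, v) {
  r <- y + 1.402 * (v - 128)
  g <- y - 0.344136 * (u - 128) - 0.714136 * (v - 128)
  b <- y + 1.772 * (u - 128)
  c(r, g, b)
}

#' Convert a YUV frame stack to RGB
#'
#' Applies the BT.601 full-range conversion matrix element-wise and clips the
#' result to `[0, 255]`. Frames containing non-finite pixels are dropped; if
#' more than 10% of frames are dropped the stack is rejected.
#'
#' @param stack a `frame_stack` with `color_space = "YUV"`.
#' @return An RGB `frame_stack` with the same shape and timestamps
#'   (minus any rejected frames).
#' @export
convert_yuv_to_rgb <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$color_space == "RGB") {
    warning("stack is already RGB; returning input unchanged")
    return(stack)
  }
  bad <- apply(stack$frames, 1L, function(fr) any(!is.finite(fr)))
  if (mean(bad) > 0.10)
    stop(sprintf("%d of %d frames contain non-finite pixels (>10%%)",
                 sum(bad), length(bad)))
  frames <- stack$frames
  ts <- stack$timestamps
  if (any(bad)) {
    frames <- frames[!bad, , , , drop = FALSE]
    ts <- ts[!bad]
  }
  y <- frames[, , , 1L, drop = FALSE]
  u <- frames[, , , 2L, drop = FALSE]
  v <- frames[, , , 3L, drop = FALSE]
  out <- frames
  out[, , , 1L] <- y + 1.402 * (v - 128)
  out[, , , 2L] <- y - 0.344136 * (u - 128) - 0.714136 * (v - 128)
  out[, , , 3L] <- y + 1.772 * (u - 128)
  out[out < 0] <- 0
  out[out > 255] <- 255
  frame_stack(out, ts, color_space = "RGB")
}

#' Collapse an RGB frame stack into a single pulse trace
#'
#' Each frame is reduced to the spatial mean of each colour channel; the three
#' per-channel mean series are then combined with weights proportional to each
#' series' temporal standard deviation (normalized to sum to one), so channels
#' carrying more pulsatile variation contribute more. The blood-volume pulse
#' modulates all channels coherently while sensor noise does not, which is why
#' the SD-weighted average tracks the pulse better than any single channel.
#'
#' @param stack an RGB `frame_stack`.
#' @return A list of class `ppg_trace` with elements `values`, `timestamps`,
#'   and `weights` (the per-channel SD weights).
#' @export
frames_to_ppg <- function(stack) {
  stopifnot(inherits(stack, "frame_stack"))
  if (stack$color_space != "RGB")
    stop("frames_to_ppg expects an RGB stack; run convert_yuv_to_rgb() first")
  ch_means <- apply(stack$frames, c(1L, 4L), mean)  # T x 3
  sds <- apply(ch_means, 2L, stats::sd)
  if (all(sds == 0)) stop("no pulsatile content: all channel series constant")
  w <- sds / sum(sds)
  structure(list(values = as.numeric(ch_means %*% w),
                 timestamps = stack$timestamps,
                 weights = w),
            class = "ppg_trace")
}

#' Resample an irregular trace onto a uniform grid
#'
#' Smartphone camera frame rates are not fixed, so the raw trace carries
#' jittered timestamps. Linear interpolation onto a uniform grid spanning the
#' recorded interval makes the signal usable by the filtering and spectral
#' steps.
#'
#' @param values numeric amplitudes, or a `ppg_trace` (then `timestamps` is
#'   taken from it).
#' @param timestamps seconds, strictly increasing, same length as `values`.
#' @param fs_target target sampling rate in Hz (default 30, the nominal
#'   smartphone frame rate).
#' @param source provenance tag for the resulting signal.
#' @return A `ppg_signal` at `fs_target`.
#' @export
resample_uniform <- function(values, timestamps = NULL, fs_target = 30,
                             source = "video") {
  if (inherits(values, "ppg_trace")) {
    timestamps <- values$timestamps
    values <- values$values
  }
  if (length(values) < 2L) stop("need at least 2 samples")
  if (length(values) != length(timestamps))
    stop("`values` and `timestamps` lengths differ")
  if (anyDuplicated(timestamps)) stop("duplicate timestamps")
  if (any(diff(timestamps) <= 0)) stop("`timestamps` must be strictly increasing")
  if (!is.numeric(fs_target) || fs_target <= 0) stop("`fs_target` must be > 0")
  grid <- seq(timestamps[1L], timestamps[length(timestamps)], by = 1 / fs_target)
  out <- stats::approx(timestamps, values, xout = grid, method = "linear")$y
  ppg_signal(out, fs = fs_target, t0 = grid[1L], source = source)
}

#' Band-pass filter and orient a PPG signal
#'
#' Zero-phase Butterworth band-pass (default 0.5-8 Hz, covering the cardiac
#' fundamental and its first handful of harmonics while removing baseline
#' drift and high-frequency noise). After filtering, polarity is oriented so
#' that systolic upstrokes are maxima: transmissive smartphone PPG is often
#' inverted (more blood absorbs more light), and a pulse with sharp systolic
#' peaks has positive skewness, so the signal is flipped when its skewness is
#' negative.
#'
#' @param sig a `ppg_signal`.
#' @param band numeric length-2, pass band in Hz.
#' @param order Butterworth order (applied forwards and backwards).
#' @param auto_flip logical; apply the skewness polarity heuristic.
#' @return A filtered `ppg_signal`; attribute `"flipped"` records whether the
#'   polarity heuristic inverted the signal.
#' @export
detrend_filter <- function(sig, band = c(0.5, 8), order = 3, auto_flip = TRUE) {
  stopifnot(inherits(sig, "ppg_signal"))
  nyq <- sig$fs / 2
  if (band[2] >= nyq)
    band[2] <- 0.9 * nyq
  if (band[1] <= 0 || band[1] >= band[2]) stop("invalid pass band")
  n <- length(sig$values)
  if (n < 3 * (2 * order + 1) || n < 2 * sig$fs)
    stop("signal shorter than filter warm-up")
  bf <- signal::butter(order, band / nyq, type = "pass")
  # removing the mean first keeps the forward-backward pass free of the edge
  # transients a large DC offset excites
  filt <- signal::filtfilt(bf, sig$values - mean(sig$values))
  flipped <- FALSE
  if (auto_flip) {
    m <- mean(filt)
    s <- stats::sd(filt)
    if (s > 0) {
      skew <- mean(((filt - m) / s)^3)
      if (skew < 0) {
        filt <- -filt
        flipped <- TRUE
        message("detrend_filter: negative skewness, polarity flipped")
      }
    }
  }
  out <- ppg_signal(filt, fs = sig$fs, t0 = sig$t0, source = sig$source)
  attr(out, "flipped") <- flipped
  out
}

#' Read a two-column (time, value) delimited trace
#'
#' @param path file with header columns `time_s,value`.
#' @param sep field separator.
#' @return A `ppg_trace`.
#' @export
read_ppg_trace <- function(path, sep = ",") {
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (ncol(df) < 2L) stop("expected two columns (time_s, value)")
  structure(list(values = as.numeric(df[[2L]]),
                 timestamps = as.numeric(df[[1L]]),
                 weights = NULL),
            class = "ppg_trace")
}

#' Write a PPG signal as a two-column delimited trace
#' @param sig a `ppg_signal`.
#' @param path output path.
#' @export
write_ppg_signal <- function(sig, path) {
  stopifnot(inherits(sig, "ppg_signal"))
  df <- data.frame(time_s = ppg_time(sig), value = sig$values)
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
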