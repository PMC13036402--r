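#' Detect beats and segment a PPG signal into beat-to-beat intervals
#'
#' Systolic peaks are found with an adaptive-prominence detector: candidate
#' peaks must rise above a fraction of the signal's robust amplitude
#' (interquartile spread) and be separated by a refractory interval. Each
#' beat-to-beat interval (BBI) then spans consecutive inter-peak minima
#' (valleys), so every segment holds one full systolic-diastolic complex from
#' left valley (LV) to right valley (RV). Beats whose duration falls outside
#' the plausibility window are discarded.
#'
#' @param sig a detrended, uniformly sampled `ppg_signal` of at least 2 s.
#' @param min_prominence fraction of the robust amplitude a peak must exceed
#'   on the detection trace.
#' @param duration_range plausible beat duration window in seconds; beats
#'   outside it are dropped.
#' @return A list of `beat_segment` objects, each with `start_idx`, `end_idx`
#'   (0-based, half-open), `values`, `duration` (s), and `fs`.
#' @export
detect_beats <- function(sig, min_prominence = 0.3,
                         duration_range = c(0.3, 2.0)) {
  stopifnot(inherits(sig, "ppg_signal"))
  x <- sig$values
  fs <- sig$fs
  if (length(x) < 2 * fs) stop("signal too short for beat detection")
  if (stats::IQR(x) == 0) stop("no beats detected: signal has no oscillation")
  # beat-period estimate from the autocorrelation peak in the 27-200 bpm band;
  # the earliest lag within 10% of the maximum guards against locking onto a
  # period multiple
  ac <- as.numeric(stats::acf(x, lag.max = min(length(x) - 1L,
                                               round(2.5 * fs)),
                              plot = FALSE)$acf)
  lags <- seq(max(2L, round(0.3 * fs)), min(length(ac) - 1L, round(2.2 * fs)))
  if (length(lags) < 2L) stop("no beats detected: signal too short")
  acl <- ac[lags + 1L]
  cand <- lags[acl >= 0.9 * max(acl)]
  period_est <- cand[1L] / fs
  # systolic peaks on a low-passed detection trace so the reflected wave
  # cannot register as a separate beat, then refined on the raw signal
  nyq <- fs / 2
  cutoff <- min(1.8 / period_est, 0.9 * nyq)
  det <- signal::filtfilt(signal::butter(2, cutoff / nyq, type = "low"), x)
  amp <- stats::IQR(det)
  if (amp == 0) stop("no beats detected: signal has no oscillation")
  pk <- pracma::findpeaks(det,
                          minpeakheight = stats::median(det) +
                            min_prominence * amp,
                          minpeakdistance = max(1L,
                                                round(0.6 * period_est * fs)))
  if (is.null(pk) || nrow(pk) < 2L) stop("no beats detected: fewer than 2 peaks")
  w <- max(1L, round(0.25 * period_est * fs))
  peaks <- vapply(as.integer(sort(pk[, 2L])), function(p) {
    lo <- max(1L, p - w)
    hi <- min(length(x), p + w)
    as.integer(lo + which.max(x[lo:hi]) - 1L)
  }, integer(1L))
  peaks <- unique(peaks)
  # valleys: minimum between consecutive systolic peaks
  valleys <- vapply(seq_len(length(peaks) - 1L), function(i) {
    lo <- peaks[i]
    hi <- peaks[i + 1L]
    lo + which.min(x[lo:hi]) - 1L
  }, integer(1L))
  if (length(valleys) < 2L) stop("no beats detected: fewer than 2 valleys")
  beats <- lapply(seq_len(length(valleys) - 1L), function(i) {
    s <- valleys[i]
    e <- valleys[i + 1L]
    structure(list(start_idx = s - 1L, end_idx = e,  # 0-based half-open
                   values = x[s:e],
                   duration = (e - s) / fs,
                   fs = fs),
              class = "beat_segment")
  })
  keep <- vapply(beats, function(b)
    b$duration >= duration_range[1] && b$duration <= duration_range[2],
    logical(1L))
  if (any(!keep))
    message(sprintf("detect_beats: dropped %d beat(s) outside [%g, %g] s",
                    sum(!keep), duration_range[1], duration_range[2]))
  beats[keep]
}

#' @export
print.beat_segment <- function(x, ...) {
  cat(sprintf("<beat_segment> [%d, %d) %.3f s @ %g Hz\n",
              x$start_idx, x$end_idx, x$duration, x$fs))
  invisible(x)
}

#' Heart rate from segmented beats
#'
#' `60 / median(BBI duration)` in beats per minute; the median makes the
#' estimate insensitive to occasional missed or spurious beats and to beat
#' order.
#'
#' @param beats list of `beat_segment`s (at least 2).
#' @return Heart rate in bpm.
#' @export
compute_hr <- function(beats) {
  if (length(beats) < 2L) stop("need at least 2 beats to compute HR")
  60 / stats::median(vapply(beats, `[[`, numeric(1L), "duration"))
}

# Resample a beat to a fixed number of points by linear interpolation.
.normalize_beat_length <- function(values, n_out = 100L) {
  stats::approx(seq_along(values), values, n = n_out)$y
}

#' Template-correlation signal quality index
#'
#' Two ingredients, both standard in PPG quality assessment, multiplied and
#' clipped to `[0, 1]`:
#' \describe{
#'   \item{shape consistency}{each beat is length-normalized and correlated
#'     with the pointwise-median template beat; the mean Pearson correlation
#'     measures morphological agreement.}
#'   \item{rhythm consistency}{`max(0, 1 - 2 * cv)` where `cv` is the
#'     coefficient of variation of beat durations. Valley-to-peak
#'     segmentation forces even pseudo-beats cut from noise into a common
#'     arch shape, so shape correlation alone has an elevated floor; garbage
#'     recordings betray themselves through wildly inconsistent beat
#'     durations, which this factor captures.}
#' }
#' Morphologically and rhythmically consistent recordings score near 1;
#' noise- or artifact-dominated recordings fall below the conventional 0.5
#' gate and are discarded.
#'
#' @param beats list of `beat_segment`s (at least 2).
#' @param n_points number of points for length normalization.
#' @return SQI in `[0, 1]`.
#' @export
compute_sqi <- function(beats, n_points = 100L) {
  if (length(beats) < 2L) stop("need at least 2 beats to compute SQI")
  mat <- vapply(beats, function(b) .normalize_beat_length(b$values, n_points),
                numeric(n_points))
  ok <- apply(mat, 2L, stats::sd) > 0
  if (!any(ok)) stop("all beats have zero variance")
  mat <- mat[, ok, drop = FALSE]
  template <- apply(mat, 1L, stats::median)
  if (stats::sd(template) == 0) stop("template beat has zero variance")
  r <- mean(apply(mat, 2L, stats::cor, y = template))
  durs <- vapply(beats, `[[`, numeric(1L), "duration")
  cv <- stats::sd(durs) / mean(durs)
  rhythm <- max(0, 1 - 2 * cv)
  min(max(r * rhythm, 0), 1)
}

#' Ensemble-averaged beat
#'
#' Length-normalizes every beat and takes the pointwise median, returning a
#' single representative beat at the median beat duration. Ensemble averaging
#' suppresses additive noise by roughly the square root of the beat count, so
#' landmark geometry measured on the template is far more stable than any
#' single beat's; it is the estimator of choice when a recording-level
#' morphology summary is needed.
#'
#' Beats are aligned on their systolic peaks before averaging — valley
#' positions jitter under noise, and valley alignment would smear the
#' diastolic landmarks sitting at a fixed lag behind the peak.
#'
#' @param beats list of `beat_segment`s (at least 2).
#' @return A `beat_segment` holding the template waveform.
#' @export
ensemble_beat <- function(beats) {
  if (length(beats) < 2L) stop("need at least 2 beats")
  fs <- beats[[1L]]$fs
  lens <- vapply(beats, function(b) length(b$values), integer(1L))
  pks <- vapply(beats, function(b) which.max(b$values), integer(1L))
  left <- as.integer(round(stats::median(pks))) - 1L
  right <- as.integer(round(stats::median(lens - pks)))
  n_out <- left + right + 1L
  mat <- vapply(beats, function(b) {
    pk <- which.max(b$values)
    idx <- (pk - left):(pk + right)
    out <- rep(NA_real_, n_out)
    ok <- idx >= 1L & idx <= length(b$values)
    out[ok] <- b$values[idx[ok]]
    out
  }, numeric(n_out))
  tmpl <- apply(mat, 1L, stats::median, na.rm = TRUE)
  keep <- which(!is.na(tmpl))
  tmpl <- tmpl[keep[1L]:keep[length(keep)]]
  structure(list(start_idx = 0L, end_idx = length(tmpl),
                 values = tmpl, duration = length(tmpl) / fs, fs = fs),
            class = "beat_segment")
}

#' Filter sample records on completeness and signal quality
#'
#' Stage 1 drops records with any missing core feature ("partial feature
#' loss"); stage 2 drops records with SQI below the quality gate. An
#' accounting report records counts and retention percentages at each stage,
#' plus per-participant and per-beat bookkeeping means when the columns are
#' present.
#'
#' @param records data.frame of sample feature records; must carry a logical
#'   `complete` column and a numeric `sqi` column. Optional columns
#'   `participant_id` and `n_beats` feed the bookkeeping means.
#' @param sqi_threshold quality gate; records with `sqi <` this are dropped.
#' @return A list with `records` (the retained rows) and `report`, a
#'   data.frame with one row per filtering stage (`stage`, `n`,
#'   `pct_of_initial` to 1 decimal), carrying attributes
#'   `mean_samples_per_participant` and `mean_bbis_per_sample` when
#'   computable.
#' @export
filter_samples <- function(records, sqi_threshold = 0.5) {
  stopifnot(is.data.frame(records))
  if (!"complete" %in% names(records)) records$complete <- TRUE
  if (!"sqi" %in% names(records)) records$sqi <- 1
  n0 <- nrow(records)
  after_feat <- records[records$complete %in% TRUE, , drop = FALSE]
  n1 <- nrow(after_feat)
  after_sqi <- after_feat[!is.na(after_feat$sqi) &
                            after_feat$sqi >= sqi_threshold, , drop = FALSE]
  n2 <- nrow(after_sqi)
  pct <- function(n) if (n0 > 0) round(100 * n / n0, 1) else NA_real_
  report <- data.frame(
    stage = c("initial", "after_feature_loss", "after_sqi_gate"),
    n = c(n0, n1, n2),
    pct_of_initial = c(pct(n0), pct(n1), pct(n2)))
  if ("participant_id" %in% names(records) && n0 > 0)
    attr(report, "mean_samples_per_participant") <-
      round(n0 / length(unique(records$participant_id)), 2)
  if ("n_beats" %in% names(records) && n0 > 0)
    attr(report, "mean_bbis_per_sample") <-
      round(sum(records$n_beats) / n0)
  if (n2 == 0L) warning("no records survived filtering")
  list(records = after_sqi, report = report)
}
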