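# Linear LV-RV baseline under a beat; amplitudes are measured above it so
# slow drift across the beat does not leak into height features. The anchor
# level at each valley is the median of a few surrounding samples: the valley
# index itself is an argmin and therefore sits systematically low under
# noise, which would inflate every height measured from it.
.valley_level <- function(values, idx, halfwidth = 3L) {
  lo <- max(1L, idx - halfwidth)
  hi <- min(length(values), idx + halfwidth)
  stats::median(values[lo:hi])
}

.beat_baseline <- function(values, at) {
  n <- length(values)
  v1 <- .valley_level(values, 1L)
  vn <- .valley_level(values, n)
  v1 + (vn - v1) * (at - 1) / (n - 1)
}

# Shoelace area of a polygon given x/y vertex vectors (counter-clockwise or
# clockwise; absolute value returned).
.shoelace <- function(x, y) {
  n <- length(x)
  j <- c(2:n, 1L)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

#' Tangent-intersection estimate of the early systolic peak
#'
#' Smartphone auto-exposure smooths the systolic peak, so the measured peak
#' height under-reads the true one. The undistorted peak is estimated as the
#' intersection of the tangent at the maximal-upstroke point with the tangent
#' at the maximal-downslope point of the systolic decay: the two straight
#' flanks of the (unsmoothed) peak meet above the rounded measured apex.
#' Isolated here so an alternative estimator can be substituted.
#'
#' @param beat a `beat_segment`.
#' @param fid a `beat_fiducials`.
#' @return A list with `t_est` (seconds from beat start), `height_est`
#'   (amplitude above the LV-RV baseline), or `NULL` when the construction is
#'   degenerate (parallel tangents).
#' @export
estimate_esp <- function(beat, fid) {
  x <- beat$values
  d1 <- fid$d1
  fs <- beat$fs
  up_end <- fid$esp
  dn_end <- if (!is.na(fid$dn)) fid$dn else fid$rv
  if (up_end <= 1L || dn_end <= fid$esp) return(NULL)
  u <- .argmax_win(d1, 1L, up_end)
  w <- .argmin_win(d1, fid$esp, dn_end)
  su <- d1[u]
  sw <- d1[w]
  if (!is.finite(su) || !is.finite(sw) || su <= 0 || sw >= 0) return(NULL)
  tu <- (u - 1) / fs
  tw <- (w - 1) / fs
  t_est <- (x[w] - x[u] + su * tu - sw * tw) / (su - sw)
  y_est <- x[u] + su * (t_est - tu)
  base <- .beat_baseline(x, t_est * fs + 1)
  list(t_est = t_est, height_est = y_est - base)
}

#' Time-domain features of a single beat
#'
#' Intervals between the fiducial landmarks, amplitudes above the LV-RV
#' baseline, and the polygonal areas flanking the dicrotic notch:
#' \describe{
#'   \item{ppt / eppt}{peak-to-peak time ESP to DP, and its estimated variant
#'     using the tangent-intersection peak (s).}
#'   \item{si / esi}{stiffness index: body height / PPT (m/s), and the
#'     estimated variant.}
#'   \item{ri / eri}{reflection index: diastolic peak height over (measured /
#'     estimated) systolic peak height.}
#'   \item{ct, nt, dt, fn, sr, nv}{crest time LV-ESP, notch time LV-DN,
#'     diastolic time ESP-RV, first-peak-to-notch, second-peak-to-RV,
#'     notch-to-RV (s).}
#'   \item{is_slope}{first derivative at the inflection point (amplitude/s).}
#'   \item{rca, rda}{CT/NT and NT/(CT+DT).}
#'   \item{nh, sph}{notch and second-peak heights above baseline.}
#'   \item{a1, a2, ipa}{shoelace areas of the polygon (LV, ESP, DN, DN-base)
#'     and the triangle (IP, DN, RV), in amplitude x seconds, and their ratio
#'     A2/A1.}
#' }
#' Missing fiducials set the affected features to `NA`; a rejected beat
#' yields all-`NA`.
#'
#' @param beat a `beat_segment`.
#' @param fid a `beat_fiducials` (primary landmarks located).
#' @param height_m participant body height in metres.
#' @return A one-row data.frame of time-domain features plus the per-beat
#'   fallback flag `used_ip_as_dn`.
#' @export
compute_time_features <- function(beat, fid, height_m = 1.70) {
  fs <- beat$fs
  x <- beat$values
  na_row <- data.frame(
    si = NA_real_, ppt = NA_real_, eppt = NA_real_, ri = NA_real_,
    eri = NA_real_, esi = NA_real_, ct = NA_real_, nt = NA_real_,
    dt = NA_real_, is_slope = NA_real_, rca = NA_real_, rda = NA_real_,
    fn = NA_real_, sr = NA_real_, nv = NA_real_, nh = NA_real_,
    sph = NA_real_, a1 = NA_real_, a2 = NA_real_, ipa = NA_real_,
    used_ip_as_dn = NA)
  if (isTRUE(fid$rejected)) return(na_row)
  out <- na_row
  h_at <- function(i) x[i] - .beat_baseline(x, i)
  tt <- function(i) (i - 1) / fs
  esp <- fid$esp; dn <- fid$dn; dp <- fid$dp; ip <- fid$ip
  lv <- fid$lv; rv <- fid$rv
  out$ct <- tt(esp) - tt(lv)
  out$dt <- tt(rv) - tt(esp)
  esph <- h_at(esp)
  if (!is.na(dn)) {
    out$nt <- tt(dn) - tt(lv)
    out$fn <- tt(dn) - tt(esp)
    out$nv <- tt(rv) - tt(dn)
    out$nh <- h_at(dn)
    if (out$nt > 0) out$rca <- out$ct / out$nt
    denom <- out$ct + out$dt
    if (denom > 0) out$rda <- out$nt / denom
  }
  if (!is.na(dp)) {
    # peak-to-peak timing uses the sub-sample landmark positions
    esp_t <- if (!is.na(fid$esp_frac)) fid$esp_frac else as.numeric(esp)
    dp_t <- if (!is.na(fid$dp_frac)) fid$dp_frac else as.numeric(dp)
    out$ppt <- tt(dp_t) - tt(esp_t)
    out$sr <- tt(rv) - tt(dp_t)
    out$sph <- h_at(dp)
    if (out$ppt > 0) out$si <- height_m / out$ppt
    if (esph > 0) out$ri <- out$sph / esph
  }
  est <- estimate_esp(beat, fid)
  if (!is.null(est) && !is.na(dp) && est$height_est > 0) {
    dp_t <- if (!is.na(fid$dp_frac)) fid$dp_frac else as.numeric(dp)
    out$eri <- h_at(dp) / est$height_est
    out$eppt <- tt(dp_t) - est$t_est
    if (out$eppt > 0) out$esi <- height_m / out$eppt
  }
  if (!is.na(ip)) out$is_slope <- fid$d1[ip]
  if (!is.na(dn)) {
    out$a1 <- .shoelace(c(tt(lv), tt(esp), tt(dn), tt(dn)),
                        c(0, esph, h_at(dn), 0))
    if (!is.na(ip))
      out$a2 <- .shoelace(c(tt(ip), tt(dn), tt(rv)),
                          c(h_at(ip), h_at(dn), 0))
    if (!is.na(out$a1) && !is.na(out$a2) && out$a1 > 0)
      out$ipa <- out$a2 / out$a1
  }
  out$used_ip_as_dn <- isTRUE(fid$used_ip_as_dn)
  out
}

#' Curvature-domain (acceleration PPG) features of a single beat
#'
#' Ratios of the second derivative at the labelled extrema to its value at
#' point A. B/A, F/A and H/A are intrinsically negative (and E/A, G/A
#' positive), so all five are reported as absolute values for uniform
#' interpretation; the aging index keeps the signed ratios:
#' `ai = (B/A) - (E/A)`.
#'
#' @param fid a `beat_fiducials` with A-H located.
#' @return One-row data.frame with `b_a`, `e_a`, `f_a`, `g_a`, `h_a`
#'   (absolute ratios) and `ai`.
#' @export
compute_curvature_features <- function(fid) {
  out <- data.frame(b_a = NA_real_, e_a = NA_real_, f_a = NA_real_,
                    g_a = NA_real_, h_a = NA_real_, ai = NA_real_)
  if (isTRUE(fid$rejected) || is.na(fid$a)) return(out)
  d2 <- fid$d2
  da <- d2[fid$a]
  if (!is.finite(da) || da == 0) return(out)
  ratio <- function(i) if (is.na(i)) NA_real_ else d2[i] / da
  b <- ratio(fid$b); e <- ratio(fid$e); f <- ratio(fid$f)
  g <- ratio(fid$g); h <- ratio(fid$h)
  out$b_a <- abs(b); out$e_a <- abs(e); out$f_a <- abs(f)
  out$g_a <- abs(g); out$h_a <- abs(h)
  if (!is.na(b) && !is.na(e)) out$ai <- b - e
  out
}

#' Welch power spectral density estimate
#'
#' Hann-windowed, mean-detrended segments with 50% overlap, averaged
#' periodograms, one-sided density scaling (so the integral over frequency
#' recovers the signal variance, Parseval).
#'
#' @param x numeric signal.
#' @param fs sampling rate (Hz).
#' @param nperseg segment length in samples (clamped to `length(x)`).
#' @return A list with `freq` (Hz) and `psd` (power per Hz).
#' @export
welch_psd <- function(x, fs, nperseg = min(length(x), round(10 * fs))) {
  n <- length(x)
  nperseg <- min(as.integer(nperseg), n)
  if (nperseg < 8L) stop("segment too short for PSD estimation")
  step <- max(1L, nperseg %/% 2L)
  starts <- seq(1L, n - nperseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nperseg) / (nperseg + 1))
  u <- sum(w^2)
  nf <- nperseg %/% 2L + 1L
  acc <- numeric(nf)
  for (s in starts) {
    seg <- x[s:(s + nperseg - 1L)]
    seg <- (seg - mean(seg)) * w
    sp <- abs(stats::fft(seg)[seq_len(nf)])^2
    acc <- acc + sp
  }
  psd <- acc / (length(starts) * u * fs)
  # one-sided: double everything except DC (and Nyquist when present)
  if (nperseg %% 2L == 0L) {
    psd[2:(nf - 1L)] <- 2 * psd[2:(nf - 1L)]
  } else {
    psd[2:nf] <- 2 * psd[2:nf]
  }
  list(freq = (seq_len(nf) - 1L) * fs / nperseg, psd = psd)
}

# Locate the PSD peak nearest harmonic i*f0; nominal position when the
# search window is empty or the harmonic exceeds Nyquist.
.harmonic_peak <- function(freq, psd, f0, i, halfwidth = 0.4) {
  target <- i * f0
  sel <- which(freq >= target - halfwidth * f0 & freq <= target + halfwidth * f0)
  if (length(sel) == 0L) return(target)
  freq[sel[which.max(psd[sel])]]
}

#' Frequency-domain features of a whole recording
#'
#' The PSD of a pulsatile signal shows peaks at the cardiac fundamental and
#' its harmonics. The strength of the i-th harmonic, `S_i`, is the area under
#' the PSD between the midpoints separating it from its neighbours (the first
#' band starts at the midpoint between 0 and the first peak); integrating
#' bands rather than reading peak heights makes the estimate robust to noise.
#' The relative strengths `rpsd_i = S_i / sum(S_1..S_6)` form a simplex. The
#' Fourier weights `V_0..V_6` are the amplitudes of a truncated sinusoidal
#' series fitted by least squares to the length-normalized median template
#' beat. `nha` (normalized harmonic area) is the harmonic-energy fraction
#' above the fundamental, `sum(S_2..S_6)/sum(S_1..S_6)`, and
#' `ihar = (1 - nha) / ipa`.
#'
#' @param sig a detrended `ppg_signal`, at least `min_duration_s` long.
#' @param ipa_median sample-median inflection point area ratio (for `ihar`).
#' @param hr_bpm heart rate; when `NULL` the fundamental is detected as the
#'   largest PSD peak in 0.5-3 Hz.
#' @param n_harmonics number of harmonics carried (6).
#' @param min_duration_s minimum recording length for a stable PSD.
#' @return A one-row data.frame: `s1..s6`, `rpsd1..rpsd6`, `v0..v6`, `nha`,
#'   `ihar`, and the detected fundamental `f0_hz`.
#' @export
compute_spectral_features <- function(sig, ipa_median = NA_real_,
                                      hr_bpm = NULL, n_harmonics = 6L,
                                      min_duration_s = 30) {
  stopifnot(inherits(sig, "ppg_signal"))
  if (length(sig$values) / sig$fs < min_duration_s)
    stop(sprintf("need >= %g s of signal for spectral features", min_duration_s))
  ps <- welch_psd(sig$values, sig$fs)
  if (is.null(hr_bpm)) {
    band <- which(ps$freq >= 0.5 & ps$freq <= 3)
    if (length(band) == 0L || all(ps$psd[band] <= 0))
      stop("fundamental not detectable")
    f0 <- ps$freq[band[which.max(ps$psd[band])]]
  } else {
    f0 <- hr_bpm / 60
  }
  if (!is.finite(f0) || f0 <= 0) stop("fundamental not detectable")
  k <- n_harmonics
  peaks <- vapply(seq_len(k + 1L), function(i)
    .harmonic_peak(ps$freq, ps$psd, f0, i), numeric(1L))
  mids <- c(peaks[1L] / 2, (peaks[-(k + 1L)] + peaks[-1L]) / 2)
  s <- vapply(seq_len(k), function(i) {
    sel <- ps$freq >= mids[i] & ps$freq <= mids[i + 1L]
    if (sum(sel) < 2L) return(0)
    pracma::trapz(ps$freq[sel], ps$psd[sel])
  }, numeric(1L))
  if (sum(s) <= 0) stop("fundamental not detectable")
  rpsd <- s / sum(s)
  nha <- sum(s[-1L]) / sum(s)
  ihar <- if (is.finite(ipa_median) && ipa_median > 0) (1 - nha) / ipa_median
          else NA_real_
  v <- .fit_fourier_template(sig, k)
  out <- as.data.frame(c(as.list(stats::setNames(s, paste0("s", seq_len(k)))),
                         as.list(stats::setNames(rpsd, paste0("rpsd", seq_len(k)))),
                         as.list(stats::setNames(v, paste0("v", 0:k)))))
  out$nha <- nha
  out$ihar <- ihar
  out$f0_hz <- f0
  out
}

# Least-squares fit of V0 + sum_i Vi sin(2 pi i u + phi_i) to the
# length-normalized median template beat; returns c(V0, V1..Vk).
.fit_fourier_template <- function(sig, k) {
  tmpl <- tryCatch({
    beats <- detect_beats(sig)
    if (length(beats) < 2L) stop("too few beats")
    mat <- vapply(beats, function(b) .normalize_beat_length(b$values, 100L),
                  numeric(100L))
    apply(mat, 1L, stats::median)
  }, error = function(e) NULL)
  if (is.null(tmpl)) {
    warning("beat template unavailable; Fourier weights set to NA")
    return(rep(NA_real_, k + 1L))
  }
  u <- (seq_len(100L) - 1L) / 100
  X <- cbind(1, do.call(cbind, lapply(seq_len(k), function(i)
    cbind(sin(2 * pi * i * u), cos(2 * pi * i * u)))))
  beta <- stats::lm.fit(X, tmpl)$coefficients
  amp <- vapply(seq_len(k), function(i)
    sqrt(beta[2 * i]^2 + beta[2 * i + 1L]^2), numeric(1L))
  c(beta[1L], amp)
}

# Feature-name bookkeeping shared by normalization and selection.
.duration_features <- c("ppt", "eppt", "ct", "nt", "dt", "fn", "sr", "nv")
.stature_features <- c("ppt", "eppt")

#' Feature-to-domain dictionary
#'
#' @return Named character vector mapping every sample-level feature column to
#'   its domain: `time`, `curvature`, `frequency`, or `covariate`.
#' @export
feature_domains <- function() {
  c(stats::setNames(rep("time", 21L),
                    c("si", "ppt", "eppt", "ri", "eri", "esi", "ct", "nt",
                      "dt", "is_slope", "rca", "rda", "fn", "sr", "nv", "nh",
                      "sph", "a1", "a2", "ipa", "ipp")),
    stats::setNames(rep("curvature", 6L),
                    c("b_a", "e_a", "f_a", "g_a", "h_a", "ai")),
    stats::setNames(rep("frequency", 21L),
                    c(paste0("s", 1:6), paste0("rpsd", 1:6), paste0("v", 0:6),
                      "nha", "ihar")),
    stats::setNames(rep("covariate", 2L), c("sbp", "dbp")))
}

#' Normalize features to reference heart rate and stature
#'
#' Pulse waveform duration scales inversely with heart rate and reflected-wave
#' timing scales with vascular path length (body height). Duration-type
#' features (`ppt`, `eppt`, `ct`, `nt`, `dt`, `fn`, `sr`, `nv`) are mapped to
#' a reference HR of 75 bpm (a 0.8 s beat) by multiplying by `hr_bpm / 75`;
#' the path-length-sensitive intervals (`ppt`, `eppt`) are additionally
#' scaled by `170 / height_cm`. The stiffness indices are then recomputed
#' from the normalized intervals at the reference height
#' (`si = 1.70 / ppt`). Pure ratios, amplitudes, and spectral features are
#' untouched. Normalizing a record measured at 75 bpm and 170 cm is the
#' identity.
#'
#' @param feats data.frame of features (per beat or aggregated); columns not
#'   present are skipped.
#' @param hr_bpm measured heart rate (> 0).
#' @param height_cm body height in cm (> 0).
#' @param ref_hr,ref_height_cm reference conditions.
#' @return `feats` with normalized columns; attributes `hr_factor` and
#'   `height_factor` record the multipliers applied.
#' @export
normalize_features <- function(feats, hr_bpm, height_cm,
                               ref_hr = 75, ref_height_cm = 170) {
  if (!is.finite(hr_bpm) || hr_bpm <= 0) stop("`hr_bpm` must be > 0")
  if (!is.finite(height_cm) || height_cm <= 0) stop("`height_cm` must be > 0")
  hf <- hr_bpm / ref_hr
  sf <- ref_height_cm / height_cm
  for (col in intersect(.duration_features, names(feats)))
    feats[[col]] <- feats[[col]] * hf
  for (col in intersect(.stature_features, names(feats)))
    feats[[col]] <- feats[[col]] * sf
  ref_h_m <- ref_height_cm / 100
  if (all(c("si", "ppt") %in% names(feats)))
    feats$si <- ifelse(is.na(feats$ppt) | feats$ppt <= 0, NA_real_,
                       ref_h_m / feats$ppt)
  if (all(c("esi", "eppt") %in% names(feats)))
    feats$esi <- ifelse(is.na(feats$eppt) | feats$eppt <= 0, NA_real_,
                        ref_h_m / feats$eppt)
  attr(feats, "hr_factor") <- hf
  attr(feats, "height_factor") <- sf
  feats
}

#' Aggregate per-beat features into one sample record
#'
#' The median of each feature across beats (ignoring missing beats)
#' represents the sample; `ipp` is the percentage of beats that took the
#' no-second-peak fallback. A sample is flagged incomplete when it has fewer
#' than `min_beats` accepted beats or when any core feature is present in
#' less than half of them ("partial feature loss").
#'
#' @param per_beat data.frame, one row per accepted beat (time + curvature
#'   features, including the logical `used_ip_as_dn`).
#' @param participant_id,sample_id identifiers.
#' @param hr_bpm,sqi sample-level heart rate and signal quality.
#' @param height_cm,sbp,dbp covariates carried onto the record.
#' @param spectral optional one-row data.frame from
#'   [compute_spectral_features()].
#' @param min_beats minimum accepted beats for a complete record.
#' @param core_features features whose loss marks the record incomplete.
#' @return A one-row data.frame (a sample feature record) with identifiers,
#'   covariates, aggregated features, `ipp`, `n_beats`, `sqi`, `hr_bpm`, and
#'   the `complete` flag.
#' @export
aggregate_sample <- function(per_beat, participant_id, sample_id,
                             hr_bpm, sqi, height_cm = 170,
                             sbp = NA_real_, dbp = NA_real_,
                             spectral = NULL, min_beats = 5L,
                             core_features = c("ppt", "ri", "ct", "nt", "dt",
                                               "ipa", "b_a", "e_a", "f_a",
                                               "h_a")) {
  stopifnot(is.data.frame(per_beat))
  n_beats <- nrow(per_beat)
  flag_col <- per_beat$used_ip_as_dn
  feat_cols <- setdiff(names(per_beat), "used_ip_as_dn")
  med <- lapply(per_beat[feat_cols], function(v) {
    v <- v[!is.na(v)]
    if (length(v) == 0L) NA_real_ else stats::median(v)
  })
  coverage <- vapply(per_beat[feat_cols], function(v) mean(!is.na(v)),
                     numeric(1L))
  core_present <- intersect(core_features, feat_cols)
  complete <- n_beats >= min_beats &&
    all(coverage[core_present] >= 0.5) &&
    !anyNA(unlist(med[core_present]))
  out <- data.frame(participant_id = participant_id, sample_id = sample_id,
                    hr_bpm = hr_bpm, sqi = sqi, n_beats = n_beats,
                    height_cm = height_cm, sbp = sbp, dbp = dbp,
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(med))
  out$ipp <- if (n_beats > 0 && !is.null(flag_col))
    100 * mean(flag_col, na.rm = TRUE) else NA_real_
  if (!is.null(spectral)) out <- cbind(out, spectral)
  out$complete <- complete
  out
}

#' Full feature extraction for one recording
#'
#' Runs the per-sample pipeline: optional band-pass detrending, beat
#' detection, heart rate and SQI, per-beat fiducials and time/curvature
#' features, whole-recording spectral features, HR/stature normalization, and
#' median aggregation into a single sample feature record.
#'
#' @param sig a uniformly sampled `ppg_signal`.
#' @param participant_id,sample_id identifiers.
#' @param height_cm,sbp,dbp participant covariates.
#' @param preprocessed set `TRUE` when `sig` is already detrended/filtered.
#' @param normalize apply [normalize_features()] with the measured HR.
#' @param spectral compute frequency-domain features (needs a long enough
#'   recording; skipped with `NA`s when it fails).
#' @return A one-row sample feature record (see [aggregate_sample()]).
#' @export
extract_sample_features <- function(sig, participant_id = "P1",
                                    sample_id = "S1", height_cm = 170,
                                    sbp = NA_real_, dbp = NA_real_,
                                    preprocessed = FALSE, normalize = TRUE,
                                    spectral = TRUE) {
  stopifnot(inherits(sig, "ppg_signal"))
  if (!preprocessed) sig <- detrend_filter(sig)
  beats <- detect_beats(sig)
  hr <- compute_hr(beats)
  sqi <- compute_sqi(beats)
  height_m <- height_cm / 100
  rows <- lapply(beats, function(b) {
    fid <- locate_fiducials(b)
    cbind(compute_time_features(b, fid, height_m = height_m),
          compute_curvature_features(fid))
  })
  per_beat <- do.call(rbind, rows)
  spec_row <- NULL
  if (spectral) {
    ipa_med <- stats::median(per_beat$ipa, na.rm = TRUE)
    spec_row <- tryCatch(
      compute_spectral_features(sig, ipa_median = ipa_med, hr_bpm = hr),
      error = function(e) NULL)
    if (is.null(spec_row)) {
      nm <- c(paste0("s", 1:6), paste0("rpsd", 1:6), paste0("v", 0:6),
              "nha", "ihar", "f0_hz")
      spec_row <- as.data.frame(as.list(stats::setNames(
        rep(NA_real_, length(nm)), nm)))
    }
  }
  if (normalize)
    per_beat <- normalize_features(per_beat, hr_bpm = hr,
                                   height_cm = height_cm)
  rec <- aggregate_sample(per_beat, participant_id, sample_id,
                          hr_bpm = hr, sqi = sqi, height_cm = height_cm,
                          sbp = sbp, dbp = dbp, spectral = spec_row)
  rec
}
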