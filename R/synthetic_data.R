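#' Beat-model parameters for the synthetic pulse generator
#'
#' The generator models each beat as the superposition of a forward (systolic)
#' Gaussian wave and a reflected wave: a second Gaussian scaled by
#' `reflection_ratio` and delayed by `reflection_lag`. The two-mode morphology
#' is the minimal shape exposing every landmark the feature set needs
#' (systolic peak, dicrotic notch, diastolic peak); the lag programs the
#' peak-to-peak time and the ratio programs the reflection index. Defaults
#' describe a resting young adult recorded by a smartphone camera: 75 bpm,
#' 30 Hz sampling, a clear reflected wave, mild respiratory-scale baseline
#' drift, and 25 dB SNR.
#'
#' @param period beat period in s (0.8 s = 75 bpm).
#' @param systolic_amp systolic wave amplitude (arbitrary units).
#' @param systolic_center time of the systolic Gaussian centre after beat
#'   onset (s).
#' @param systolic_width systolic Gaussian SD (s).
#' @param reflection_ratio reflected/forward amplitude ratio in `[0, 1]`;
#'   0 removes the second peak entirely.
#' @param reflection_lag delay of the reflected wave behind the systolic
#'   centre (s); programs PPT. Must be < `period`.
#' @param reflection_width reflected Gaussian SD (s); wider than the systolic
#'   wave, as peripheral reflection disperses the pulse.
#' @param base_amp amplitude of a beat-locked cosine baseline wave (fraction
#'   of `systolic_amp`); the blood-volume pulse never decays to a flat line
#'   between beats, and this rounded foot makes the inter-beat valley a
#'   well-defined minimum. Set 0 for bare Gaussian superposition.
#' @param noise_snr_db additive white Gaussian noise level; `Inf` disables.
#' @param drift_amp,drift_freq sinusoidal baseline drift amplitude and
#'   frequency (respiratory-scale, default 0.1 Hz).
#' @param fs sampling rate in Hz, >= 20.
#' @param seed RNG seed.
#' @return A list of class `beat_model_params`.
#' @export
beat_model_params <- function(period = 0.8, systolic_amp = 1,
                              systolic_center = 0.22, systolic_width = 0.045,
                              reflection_ratio = 0.5, reflection_lag = 0.25,
                              reflection_width = 0.07, base_amp = 0.08,
                              noise_snr_db = 25,
                              drift_amp = 0.1, drift_freq = 0.1,
                              fs = 30, seed = 1L) {
  if (fs < 20) stop("`fs` must be >= 20 Hz")
  if (reflection_lag >= period) stop("`reflection_lag` must be < `period`")
  if (reflection_ratio < 0 || reflection_ratio > 1)
    stop("`reflection_ratio` must be in [0, 1]")
  # a Gaussian of SD w has negligible content above ~0.5/w Hz
  if (fs < 1 / min(systolic_width, reflection_width))
    stop("`fs` below Nyquist for the chosen Gaussian widths")
  structure(list(period = period, systolic_amp = systolic_amp,
                 systolic_center = systolic_center,
                 systolic_width = systolic_width,
                 reflection_ratio = reflection_ratio,
                 reflection_lag = reflection_lag,
                 reflection_width = reflection_width, base_amp = base_amp,
                 noise_snr_db = noise_snr_db, drift_amp = drift_amp,
                 drift_freq = drift_freq, fs = fs, seed = as.integer(seed)),
            class = "beat_model_params")
}

# Noise-free single-beat prototype evaluated at times t (s, beat-relative).
# The Gaussian pair carries the forward/reflected waves; the cosine is the
# periodic baseline component (added once per beat tile, so it sums to a
# beat-locked wave over the train).
.beat_prototype <- function(p, t) {
  g <- p$systolic_amp * exp(-(t - p$systolic_center)^2 /
                              (2 * p$systolic_width^2))
  r <- p$reflection_ratio * p$systolic_amp *
    exp(-(t - p$systolic_center - p$reflection_lag)^2 /
          (2 * p$reflection_width^2))
  g + r
}

# Periodic baseline wave of the train (not tiled, evaluated globally).
.baseline_wave <- function(p, t) {
  p$base_amp * p$systolic_amp *
    cos(2 * pi * (t - p$systolic_center) / p$period)
}

# True landmark times/amplitudes of the periodic train, measured on a dense
# noise-free grid (1 kHz): this is the generator's ground truth, independent
# of any extractor.
.prototype_truth <- function(p) {
  dt <- 1e-3
  t <- seq(0, p$period - dt, by = dt)
  # wrap neighbours so the inter-beat valley is defined
  q <- .beat_prototype(p, t) + .beat_prototype(p, t - p$period) +
    .beat_prototype(p, t + p$period) + .baseline_wave(p, t)
  i_esp <- which.max(q)
  t_esp <- t[i_esp]
  # diastolic region: from systolic centre + half lag onward
  t_dp <- NA_real_
  t_dn <- NA_real_
  ri <- NA_real_
  if (p$reflection_ratio > 0) {
    win <- which(t > t_esp + p$reflection_lag / 2 & t < p$period - dt)
    win <- win[win > 1L & win < length(q)]
    # highest interior local maximum of the dense prototype
    is_max <- q[win] > q[win - 1L] & q[win] >= q[win + 1L]
    if (any(is_max)) {
      locs <- win[is_max]
      i_dp <- locs[which.max(q[locs])]
      t_dp <- t[i_dp]
      mid <- i_esp:i_dp
      i_dn <- mid[which.min(q[mid])]
      t_dn <- t[i_dn]
    }
  }
  # valley: minimum of the wrapped train
  i_lv <- which.min(q)
  t_lv <- t[i_lv]
  v_lv <- q[i_lv]
  if (!is.na(t_dp)) ri <- (q[which(t == t_dp)] - v_lv) / (q[i_esp] - v_lv)
  list(t_lv = t_lv, t_esp = t_esp, t_dn = t_dn, t_dp = t_dp,
       ppt = if (is.na(t_dp)) NA_real_ else t_dp - t_esp,
       ri = ri,
       ct = (t_esp - t_lv) %% p$period,
       dt = if (t_lv > t_esp) t_lv - t_esp
            else t_lv + p$period - t_esp)
}

#' Generate a synthetic pulse train with ground-truth landmarks
#'
#' Tiles the two-Gaussian beat prototype at the programmed period, adds
#' sinusoidal baseline drift and white Gaussian noise at the stated SNR, and
#' returns both the signal and a per-beat manifest of true landmark times
#' (LV, ESP, DN, DP) and derived truths (PPT, RI, CT, DT) measured on the
#' dense noise-free prototype.
#'
#' @param params a [beat_model_params()].
#' @param duration_s recording length in seconds.
#' @return A list with `signal` (a `ppg_signal`), `truth` (data.frame, one
#'   row per complete beat, absolute times in seconds), and `params`.
#' @export
generate_beat_train <- function(params, duration_s = 30) {
  stopifnot(inherits(params, "beat_model_params"))
  p <- params
  set.seed(p$seed)
  n <- round(duration_s * p$fs)
  t <- (seq_len(n) - 1L) / p$fs
  n_beats <- ceiling(duration_s / p$period) + 1L
  clean <- .baseline_wave(p, t)
  for (k in 0:(n_beats - 1L))
    clean <- clean + .beat_prototype(p, t - k * p$period)
  drift <- p$drift_amp * sin(2 * pi * p$drift_freq * t)
  x <- clean + drift
  if (is.finite(p$noise_snr_db)) {
    s_pow <- stats::sd(clean)
    noise_sd <- s_pow / 10^(p$noise_snr_db / 20)
    x <- x + stats::rnorm(n, sd = noise_sd)
  }
  tru <- .prototype_truth(p)
  onsets <- (0:(n_beats - 1L)) * p$period
  truth <- data.frame(
    beat = seq_len(n_beats),
    t_lv = onsets + tru$t_lv, t_esp = onsets + tru$t_esp,
    t_dn = onsets + tru$t_dn, t_dp = onsets + tru$t_dp,
    ppt = tru$ppt, ri = tru$ri, ct = tru$ct, dt = tru$dt)
  truth <- truth[truth$t_esp <= duration_s, ]
  list(signal = ppg_signal(x, fs = p$fs, t0 = 0, source = "synthetic"),
       truth = truth, params = p)
}

#' Render a PPG signal as a synthetic fingertip frame stack
#'
#' Emulates the camera's view of the flashlight-illuminated fingertip: every
#' frame is a small image whose per-channel spatial mean equals a channel
#' baseline plus `gain * ppg` plus per-channel noise, with timestamps
#' jittered around the nominal frame interval. Channel gains mimic the red
#' channel's dominance in transmissive fingertip video.
#'
#' @param ppg a `ppg_signal` driving the frames.
#' @param h,w frame height and width in pixels.
#' @param channel_gains length-3 gains (R, G, B); must not all be zero.
#' @param baselines length-3 channel baselines (intensity units).
#' @param noise_sd per-channel additive noise SD on the channel mean.
#' @param jitter_pct timestamp jitter as a fraction of the frame interval.
#' @param seed RNG seed.
#' @return A `frame_stack` (RGB) plus attribute `"ppg_values"` with the
#'   driving series.
#' @export
generate_frame_stack <- function(ppg, h = 8L, w = 10L,
                                 channel_gains = c(6, 2.5, 1),
                                 baselines = c(185, 120, 60),
                                 noise_sd = 0.05, jitter_pct = 0.05,
                                 seed = 1L) {
  stopifnot(inherits(ppg, "ppg_signal"))
  if (h < 1L || w < 1L) stop("frame dimensions must be positive")
  if (all(channel_gains == 0)) stop("`channel_gains` must not all be zero")
  set.seed(seed)
  x <- ppg$values
  nT <- length(x)
  dt <- 1 / ppg$fs
  ts <- (seq_len(nT) - 1L) * dt
  if (jitter_pct > 0) {
    jit <- stats::runif(nT, -jitter_pct, jitter_pct) * dt
    jit[1L] <- 0
    ts <- ts + jit
    ts <- cummax(ts + seq_len(nT) * 1e-9)  # keep strictly increasing
  }
  frames <- array(0, dim = c(nT, h, w, 3L))
  for (ch in 1:3) {
    mean_series <- baselines[ch] + channel_gains[ch] * x +
      stats::rnorm(nT, sd = noise_sd)
    # spatial texture with zero mean so the channel mean is exact
    for (i in seq_len(nT)) {
      tex <- stats::rnorm(h * w, sd = 0.5)
      tex <- tex - mean(tex)
      frames[i, , , ch] <- mean_series[i] + tex
    }
  }
  frames[frames < 0] <- 0
  frames[frames > 255] <- 255
  out <- frame_stack(frames, ts, color_space = "RGB")
  attr(out, "ppg_values") <- x
  out
}

#' Cohort-simulation parameters
#'
#' @param n_participants number of participants (>= 2).
#' @param samples_per_participant repeated recordings per participant.
#' @param effect_map named numeric vector: slope of each psychological
#'   outcome's dependence on a participant-mean feature, as
#'   `c("outcome:feature" = slope)`; empty = null model.
#' @param noise_sd outcome noise SD (score units).
#' @param score_ranges named list of `c(min, max)` per outcome; defaults to
#'   the instruments' ranges (SWLS 5-35, SVS 7-49, PANAS subscales 10-50,
#'   PHQ-9 0-27, GAD-7 0-21, SAM 1-9).
#' @param seed RNG seed.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_participants = 20L, samples_per_participant = 3L,
                          effect_map = numeric(0L), noise_sd = 3,
                          score_ranges = NULL, seed = 1L) {
  if (n_participants < 2L) stop("need >= 2 participants")
  if (is.null(score_ranges))
    score_ranges <- list(swls = c(5, 35), svs = c(7, 49),
                         panas_p = c(10, 50), panas_n = c(10, 50),
                         phq9 = c(0, 27), gad7 = c(0, 21),
                         valence = c(1, 9), arousal = c(1, 9))
  for (rg in score_ranges)
    if (diff(rg) <= 0) stop("degenerate score range")
  if (length(effect_map) && !all(is.finite(effect_map)))
    stop("effect slopes must be finite")
  structure(list(n_participants = as.integer(n_participants),
                 samples_per_participant = as.integer(samples_per_participant),
                 effect_map = effect_map, noise_sd = noise_sd,
                 score_ranges = score_ranges, seed = as.integer(seed)),
            class = "cohort_params")
}

# Draw per-participant latent waveform parameters: resting HR, reflection
# morphology, stature, blood pressure.
.draw_participant_latents <- function(n) {
  data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    hr_bpm = stats::rnorm(n, 72, 8),
    reflection_ratio = pmin(0.85, pmax(0.15, stats::rnorm(n, 0.5, 0.15))),
    reflection_lag = pmin(0.34, pmax(0.18, stats::rnorm(n, 0.26, 0.035))),
    height_cm = round(stats::rnorm(n, 168, 8)),
    sbp = round(stats::rnorm(n, 115, 10)),
    dbp = round(stats::rnorm(n, 74, 7)),
    v0_level = stats::rnorm(n),   # spectral-baseline latent, independent
    stringsAsFactors = FALSE)
}

# Parametric sample-level features drawn directly from the latent model:
# participant mean + within-participant noise, no waveform synthesis. The
# statistical structure (nesting, feature domains) matches the signal path.
.parametric_sample_features <- function(lat, samples_per_participant) {
  rows <- list()
  for (i in seq_len(nrow(lat))) {
    k <- samples_per_participant
    ppt <- lat$reflection_lag[i] + stats::rnorm(k, 0, 0.01)
    ri <- lat$reflection_ratio[i] + stats::rnorm(k, 0, 0.04)
    ct <- 0.22 + 0.1 * lat$reflection_lag[i] + stats::rnorm(k, 0, 0.012)
    f_a <- 0.6 + 0.5 * lat$reflection_ratio[i] + stats::rnorm(k, 0, 0.06)
    h_a <- 0.25 + 0.3 * lat$reflection_ratio[i] + stats::rnorm(k, 0, 0.05)
    b_a <- 0.9 - 0.3 * lat$reflection_ratio[i] + stats::rnorm(k, 0, 0.05)
    e_a <- 0.45 + stats::rnorm(k, 0, 0.05)
    rpsd1 <- pmin(0.95, pmax(0.4, 0.85 - 0.3 * lat$reflection_ratio[i] +
                               stats::rnorm(k, 0, 0.04)))
    v0 <- 0.4 + 0.15 * lat$v0_level[i] + stats::rnorm(k, 0, 0.03)
    rows[[i]] <- data.frame(
      participant_id = lat$participant_id[i],
      sample_id = sprintf("%s_S%02d", lat$participant_id[i], seq_len(k)),
      hr_bpm = lat$hr_bpm[i] + stats::rnorm(k, 0, 2),
      sqi = pmin(1, pmax(0.55, stats::rnorm(k, 0.92, 0.05))),
      n_beats = round(stats::rnorm(k, 37, 3)),
      height_cm = lat$height_cm[i], sbp = lat$sbp[i], dbp = lat$dbp[i],
      ppt = ppt, ri = ri, ct = ct, eri = ri * 0.9,
      f_a = f_a, h_a = h_a, b_a = b_a, e_a = e_a,
      rpsd1 = rpsd1, v0 = v0, complete = TRUE,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Signal-path sample features: synthesize a beat train per sample and run the
# full extraction pipeline.
.signal_sample_features <- function(lat, samples_per_participant,
                                    sample_duration_s, fs, seed) {
  rows <- list()
  for (i in seq_len(nrow(lat))) {
    for (s in seq_len(samples_per_participant)) {
      bp <- beat_model_params(
        period = 60 / lat$hr_bpm[i],
        reflection_ratio = lat$reflection_ratio[i],
        reflection_lag = lat$reflection_lag[i],
        fs = fs,
        seed = seed + 1000L * i + s)
      train <- generate_beat_train(bp, duration_s = sample_duration_s)
      rec <- tryCatch(
        extract_sample_features(
          train$signal,
          participant_id = lat$participant_id[i],
          sample_id = sprintf("%s_S%02d", lat$participant_id[i], s),
          height_cm = lat$height_cm[i], sbp = lat$sbp[i], dbp = lat$dbp[i]),
        error = function(e) NULL)
      if (!is.null(rec)) rows[[length(rows) + 1L]] <- rec
    }
  }
  do.call(rbind, rows)
}

#' Generate a synthetic psychophysiological cohort
#'
#' Draws per-participant latent waveform parameters (resting HR, reflection
#' morphology, stature, blood pressure), produces repeated sample feature
#' records per participant, and assigns psychological scale scores as
#' `midpoint + sum(slope * standardized participant-mean feature) + noise`,
#' clipped to each instrument's range and integer-rounded. Scores act on
#' participant-mean features because the instruments are administered once
#' per participant.
#'
#' Two feature paths are available: `mode = "signal"` synthesizes a waveform
#' per sample and runs the full extraction pipeline (slow, end-to-end);
#' `mode = "parametric"` draws features directly from the same latent model
#' (fast, for Monte-Carlo studies of the statistics layer).
#'
#' @param cp a [cohort_params()].
#' @param mode `"parametric"` or `"signal"`.
#' @param sample_duration_s,fs signal-path recording length and rate.
#' @return A list with `cohort` (data.frame: one row per sample, features
#'   joined to participant-level scores) and `truth` (the latent table and
#'   the effect map).
#' @export
generate_cohort <- function(cp, mode = c("parametric", "signal"),
                            sample_duration_s = 30, fs = 60) {
  stopifnot(inherits(cp, "cohort_params"))
  mode <- match.arg(mode)
  set.seed(cp$seed)
  lat <- .draw_participant_latents(cp$n_participants)
  feats <- if (mode == "parametric")
    .parametric_sample_features(lat, cp$samples_per_participant)
  else
    .signal_sample_features(lat, cp$samples_per_participant,
                            sample_duration_s, fs, seed = cp$seed)
  # participant-mean features drive the scores
  num_cols <- setdiff(names(feats)[vapply(feats, is.numeric, logical(1L))],
                      c("n_beats"))
  pm <- stats::aggregate(feats[num_cols],
                         by = list(participant_id = feats$participant_id),
                         FUN = function(v) mean(v, na.rm = TRUE))
  scores <- data.frame(participant_id = pm$participant_id,
                       stringsAsFactors = FALSE)
  for (outc in names(cp$score_ranges)) {
    rg <- cp$score_ranges[[outc]]
    base <- mean(rg)
    eff <- numeric(nrow(pm))
    if (length(cp$effect_map)) {
      keys <- strsplit(names(cp$effect_map), ":", fixed = TRUE)
      for (j in seq_along(keys)) {
        if (keys[[j]][1L] != outc) next
        fcol <- keys[[j]][2L]
        if (!fcol %in% names(pm)) next
        v <- pm[[fcol]]
        sdv <- stats::sd(v, na.rm = TRUE)
        if (is.na(sdv) || sdv == 0) next
        eff <- eff + cp$effect_map[[j]] * (v - mean(v, na.rm = TRUE)) / sdv
      }
    }
    raw <- base + eff + stats::rnorm(nrow(pm), 0, cp$noise_sd)
    scores[[outc]] <- pmin(rg[2L], pmax(rg[1L], round(raw)))
  }
  cohort <- merge(feats, scores, by = "participant_id", sort = FALSE)
  list(cohort = cohort,
       truth = list(latents = lat, effect_map = cp$effect_map,
                    scores = scores))
}

#' Deterministic worked-example fixtures
#'
#' Regenerates the small fixtures used throughout the documentation and
#' tests: a clean 10-beat train, a no-second-peak train (reflection ratio 0),
#' a noisy low-quality trace, a 3-frame toy stack, and a 20-participant
#' cohort, each with its ground-truth manifest. All seeds are fixed, so
#' repeated calls are bit-identical.
#'
#' @param dir optional directory; when given, signals are written as
#'   two-column CSV and manifests as JSON.
#' @return Named list of fixtures.
#' @export
worked_example_fixtures <- function(dir = NULL) {
  clean <- generate_beat_train(
    beat_model_params(noise_snr_db = Inf, drift_amp = 0, fs = 60, seed = 11L),
    duration_s = 10 * 0.8 + 0.4)
  no_second_peak <- generate_beat_train(
    beat_model_params(reflection_ratio = 0, noise_snr_db = Inf,
                      drift_amp = 0, fs = 60, seed = 12L),
    duration_s = 10 * 0.8 + 0.4)
  noisy <- generate_beat_train(
    beat_model_params(noise_snr_db = -5, fs = 30, seed = 13L),
    duration_s = 20)
  toy_ppg <- ppg_signal(sin(2 * pi * 1.25 * (0:89) / 30), fs = 30,
                        source = "synthetic")
  toy_stack <- generate_frame_stack(toy_ppg, h = 2L, w = 2L, seed = 14L)
  toy3 <- frame_stack(toy_stack$frames[1:3, , , , drop = FALSE],
                      toy_stack$timestamps[1:3], color_space = "RGB")
  cohort <- generate_cohort(cohort_params(n_participants = 20L, seed = 15L))
  fixtures <- list(clean = clean, no_second_peak = no_second_peak,
                   noisy = noisy, toy_stack = toy3, cohort = cohort)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("clean", "no_second_peak", "noisy")) {
      write_ppg_signal(fixtures[[nm]]$signal,
                       file.path(dir, paste0(nm, ".csv")))
      jsonlite::write_json(fixtures[[nm]]$truth,
                           file.path(dir, paste0(nm, "_truth.json")),
                           digits = NA)
    }
    utils::write.csv(cohort$cohort, file.path(dir, "cohort.csv"),
                     row.names = FALSE)
  }
  fixtures
}
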