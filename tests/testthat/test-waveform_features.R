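# A hand-built beat with landmark positions known by construction: two
# half-sine lobes over a flat baseline, at 100 Hz.
build_known_beat <- function() {
  fs <- 100
  n <- 81L
  x <- numeric(n)
  x[6:30] <- sin(seq(0, pi, length.out = 25))            # systolic lobe
  x[31:61] <- 0.5 * sin(seq(0, pi, length.out = 31))     # diastolic lobe
  make_beat(x, fs = fs)
}

test_that("time-domain features follow the landmark arithmetic", {
  b <- build_known_beat()
  fid <- locate_fiducials(b)
  feats <- compute_time_features(b, fid, height_m = 1.70)
  fs <- 100
  # intervals are index differences over fs
  expect_equal(feats$ct, (fid$esp - fid$lv) / fs)
  expect_equal(feats$nt, (fid$dn - fid$lv) / fs)
  expect_equal(feats$dt, (fid$rv - fid$esp) / fs)
  # peak-to-peak intervals use the sub-sample landmark positions, which sit
  # within half a sample of the integer indices
  expect_equal(feats$ppt, (fid$dp_frac - fid$esp_frac) / fs)
  expect_lte(abs(fid$dp_frac - fid$dp), 0.5 + 1e-9)
  expect_lte(abs(fid$esp_frac - fid$esp), 0.5 + 1e-9)
  expect_equal(feats$fn, (fid$dn - fid$esp) / fs)
  expect_equal(feats$nv, (fid$rv - fid$dn) / fs)
  expect_equal(feats$sr, (fid$rv - fid$dp_frac) / fs)
  expect_equal(feats$si, 1.70 / feats$ppt)
  expect_equal(feats$rca, feats$ct / feats$nt)
  expect_equal(feats$rda, feats$nt / (feats$ct + feats$dt))
  # flat baseline: heights are raw values; RI = DPH / ESPH = 0.5 / 1
  expect_equal(feats$ri, 0.5, tolerance = 0.02)
})

test_that("stiffness and reflection ratios follow their closed forms", {
  # SI: height 1.70 m over PPT 0.25 s = 6.8 m/s, via a constructed lag
  tr <- clean_train(duration_s = 10, fs = 100, reflection_lag = 0.25)
  beats <- segment_train(tr)
  fid <- locate_fiducials(beats[[3]])
  feats <- compute_time_features(beats[[3]], fid, height_m = 1.70)
  expect_equal(feats$si, 1.70 / feats$ppt)
  expect_equal(feats$ppt, tr$truth$ppt[1], tolerance = 0.03)
  expect_equal(1.70 / 0.25, 6.8)
})

test_that("polygon areas equal the shoelace oracle on the same vertices", {
  b <- build_known_beat()
  fid <- locate_fiducials(b)
  feats <- compute_time_features(b, fid, height_m = 1.70)
  fs <- 100
  tt <- function(i) (i - 1) / fs
  x <- b$values  # baseline is zero at both valleys here
  base <- function(i) x[1] + (x[length(x)] - x[1]) * (i - 1) / (length(x) - 1)
  h <- function(i) x[i] - base(i)
  a1_oracle <- oracle_shoelace(c(tt(fid$lv), tt(fid$esp), tt(fid$dn), tt(fid$dn)),
                               c(0, h(fid$esp), h(fid$dn), 0))
  a2_oracle <- oracle_shoelace(c(tt(fid$ip), tt(fid$dn), tt(fid$rv)),
                               c(h(fid$ip), h(fid$dn), 0))
  expect_equal(feats$a1, a1_oracle)
  expect_equal(feats$a2, a2_oracle)
  expect_equal(feats$ipa, a2_oracle / a1_oracle)
})

test_that("curvature ratios are |d2/d2(A)| with a signed aging index", {
  fid <- structure(list(rejected = FALSE, a = 2L, b = 4L, e = 6L, f = 8L,
                        g = 10L, h = 12L,
                        d2 = c(0, 2, 0, -1, 0, 0.4, 0, -0.6, 0, 0.3, 0, -0.2)),
                   class = "beat_fiducials")
  cf <- compute_curvature_features(fid)
  expect_equal(cf$b_a, 0.5)        # |-1/2|
  expect_equal(cf$e_a, 0.2)
  expect_equal(cf$f_a, 0.3)
  expect_equal(cf$g_a, 0.15)
  expect_equal(cf$h_a, 0.1)
  expect_equal(cf$ai, -0.5 - 0.2)  # signed B/A - E/A
  # zero curvature at A -> undefined ratios
  fid$d2[2] <- 0
  expect_true(all(is.na(compute_curvature_features(fid))))
})

test_that("Welch PSD satisfies Parseval on known sinusoids", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 2 * sin(2 * pi * 1.25 * t)
  ps <- welch_psd(x, fs)
  # total power = variance = A^2/2
  expect_equal(pracma::trapz(ps$freq, ps$psd), 2, tolerance = 0.05)
})

test_that("harmonic strengths recover closed-form power splits", {
  fs <- 30
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  f0 <- 1.25
  pure <- ppg_signal(sin(2 * pi * f0 * t), fs = fs, source = "synthetic")
  sp <- compute_spectral_features(pure, ipa_median = 0.5, hr_bpm = f0 * 60)
  expect_equal(sp$rpsd1, 1, tolerance = 0.01)
  expect_lt(sp$nha, 0.01)
  expect_equal(sum(unlist(sp[paste0("rpsd", 1:6)])), 1, tolerance = 1e-9)

  two <- ppg_signal(sin(2 * pi * f0 * t) + 0.5 * sin(2 * pi * 2 * f0 * t),
                    fs = fs, source = "synthetic")
  sp2 <- compute_spectral_features(two, ipa_median = 0.5, hr_bpm = f0 * 60)
  expect_equal(sp2$rpsd1, 0.8, tolerance = 0.01)   # power ratio 1 : 0.25
  expect_equal(sp2$rpsd2, 0.2, tolerance = 0.01)
  expect_equal(sp2$ihar, (1 - sp2$nha) / 0.5)
})

test_that("Fourier template weights reconstruct band-limited beats", {
  fs <- 60
  f0 <- 1.25
  t <- seq(0, 60 - 1 / fs, by = 1 / fs)
  x <- 1.2 + sin(2 * pi * f0 * t + 0.4) + 0.4 * sin(2 * pi * 2 * f0 * t + 1.1) +
    0.15 * sin(2 * pi * 3 * f0 * t + 2.0)
  sig <- ppg_signal(x, fs = fs, source = "synthetic")
  sp <- compute_spectral_features(sig, hr_bpm = f0 * 60)
  # reconstruct the template from the fitted weights and compare: inside the
  # model class the least-squares fit must be near-exact
  beats <- suppressMessages(detect_beats(sig))
  mat <- vapply(beats, function(b)
    approx(seq_along(b$values), b$values, n = 100)$y, numeric(100))
  tmpl <- apply(mat, 1, median)
  u <- (0:99) / 100
  X <- cbind(1, do.call(cbind, lapply(1:6, function(i)
    cbind(sin(2 * pi * i * u), cos(2 * pi * i * u)))))
  recon <- X %*% qr.solve(X, tmpl)
  rmse <- sqrt(mean((recon - tmpl)^2))
  expect_lt(rmse, 0.01 * diff(range(tmpl)))
  # fitted amplitudes decrease like the generating ones
  expect_gt(sp$v1, sp$v2)
  expect_gt(sp$v2, sp$v3)
})

test_that("HR and stature normalization follows the declared conventions", {
  feats <- data.frame(ppt = 0.25, eppt = 0.27, ct = 0.20, nt = 0.3, dt = 0.5,
                      fn = 0.1, sr = 0.2, nv = 0.25, ri = 0.5, rca = 0.4,
                      ipa = 0.6, b_a = 0.7, si = 1.70 / 0.25,
                      esi = 1.70 / 0.27)
  # reference point is the identity
  ref <- normalize_features(feats, hr_bpm = 75, height_cm = 170)
  expect_equal(ref, feats, ignore_attr = TRUE)
  # hr 60: durations scale by 60/75
  slow <- normalize_features(feats, hr_bpm = 60, height_cm = 170)
  expect_equal(slow$ct, 0.20 * 60 / 75)
  expect_equal(slow$ct, 0.16)
  expect_equal(slow$ppt, 0.25 * 60 / 75)
  expect_equal(slow$si, 1.70 / slow$ppt)
  # ratios untouched under any hr/height
  tall <- normalize_features(feats, hr_bpm = 90, height_cm = 190)
  expect_equal(tall[c("ri", "rca", "ipa", "b_a")],
               feats[c("ri", "rca", "ipa", "b_a")])
  expect_equal(tall$ppt, 0.25 * (90 / 75) * (170 / 190))
  # idempotence at the reference point
  again <- normalize_features(tall, hr_bpm = 75, height_cm = 170)
  expect_equal(again, tall, ignore_attr = TRUE)
  expect_error(normalize_features(feats, hr_bpm = 0, height_cm = 170), "hr")
  expect_error(normalize_features(feats, hr_bpm = 75, height_cm = -1), "height")
})

test_that("median aggregation is robust and counts fallback beats", {
  pb <- data.frame(ppt = c(1, 2, 3), ri = c(0.4, 0.5, 0.6),
                   ct = c(0.2, 0.2, 0.2), nt = c(0.3, 0.3, 0.3),
                   dt = c(0.5, 0.5, 0.5), ipa = c(0.6, 0.6, 0.6),
                   b_a = 1, e_a = 1, f_a = 1, h_a = 1,
                   used_ip_as_dn = c(FALSE, FALSE, FALSE))
  rec <- aggregate_sample(pb, "P1", "S1", hr_bpm = 75, sqi = 0.9)
  expect_equal(rec$ppt, 2)
  expect_equal(rec$ipp, 0)
  expect_false(rec$complete)  # < 5 beats

  pb10 <- pb[rep(1:3, length.out = 10), ]
  pb10$used_ip_as_dn <- c(rep(TRUE, 3), rep(FALSE, 7))
  rec10 <- aggregate_sample(pb10, "P1", "S2", hr_bpm = 75, sqi = 0.9)
  expect_equal(rec10$ipp, 30)
  expect_true(rec10$complete)

  # beat order invariance and outlier robustness of the median
  shuf <- pb10[sample(nrow(pb10)), ]
  expect_equal(aggregate_sample(shuf, "P1", "S3", 75, 0.9)$ppt, rec10$ppt)
  out <- pb10
  out$ppt[1:2] <- 1e6
  expect_equal(aggregate_sample(out, "P1", "S4", 75, 0.9)$ppt,
               median(out$ppt))
  # a feature missing in most beats marks the sample incomplete
  lost <- pb10
  lost$ri[1:6] <- NA
  expect_false(aggregate_sample(lost, "P1", "S5", 75, 0.9)$complete)
})

test_that("programmed PPT and RI are recovered from noisy recordings", {
  for (lag in c(0.20, 0.30)) {
    for (ratio in c(0.35, 0.7)) {
      tr <- generate_beat_train(
        beat_model_params(reflection_lag = lag, reflection_ratio = ratio,
                          noise_snr_db = 20, fs = 100, seed = 42L),
        duration_s = 20)
      tb <- ensemble_beat(segment_train(tr))
      feats <- compute_time_features(tb, locate_fiducials(tb), 1.70)
      expect_equal(feats$ppt, tr$truth$ppt[1], tolerance = 0.10)
      expect_equal(feats$ri, tr$truth$ri[1], tolerance = 0.10)
    }
  }
})
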