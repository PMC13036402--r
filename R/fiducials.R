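#' Smoothed first and second derivatives of a beat
#'
#' Savitzky-Golay smoothing differentiation on the beat's own sample grid.
#' The second derivative of the pulse waveform is the acceleration PPG, whose
#' alternating extrema (labelled A-H) carry the curvature-domain features.
#' The window must be odd and is clamped to the beat length.
#'
#' @param beat a `beat_segment` of at least 7 samples, or a numeric vector
#'   (then `fs` must be given).
#' @param fs sampling rate in Hz; taken from the beat when omitted.
#' @param window Savitzky-Golay window length (odd).
#' @param poly_order polynomial order of the local fit.
#' @return A list with `d1` (units/s) and `d2` (units/s^2), each the same
#'   length as the beat.
#' @export
smooth_derivatives <- function(beat, fs = NULL, window = 7L, poly_order = 3L) {
  if (inherits(beat, "beat_segment")) {
    x <- beat$values
    fs <- beat$fs
  } else {
    x <- as.numeric(beat)
    if (is.null(fs)) stop("`fs` required when `beat` is a plain vector")
  }
  n <- length(x)
  if (n < 7L) stop("beat too short for derivative estimation (need >= 7 samples)")
  window <- as.integer(window)
  if (window %% 2L == 0L) window <- window + 1L
  if (window > n) window <- if (n %% 2L == 1L) n else n - 1L
  if (poly_order >= window) poly_order <- window - 1L
  dt <- 1 / fs
  d1 <- signal::sgolayfilt(x, p = poly_order, n = window, m = 1L, ts = dt)
  d2 <- signal::sgolayfilt(x, p = poly_order, n = window, m = 2L, ts = dt)
  list(d1 = as.numeric(d1), d2 = as.numeric(d2))
}

# Earliest-index argmax/argmin over an inclusive index window; NA if empty.
.argmax_win <- function(x, from, to) {
  if (is.na(from) || is.na(to) || from > to) return(NA_integer_)
  from + which.max(x[from:to]) - 1L
}
.argmin_win <- function(x, from, to) {
  if (is.na(from) || is.na(to) || from > to) return(NA_integer_)
  from + which.min(x[from:to]) - 1L
}

# Indices i where d1 crosses from positive to non-positive between i and i+1,
# restricted to the inclusive window (from, to) on i.
.down_crossings <- function(d1, from, to) {
  n <- length(d1)
  to <- min(to, n - 1L)
  if (from > to) return(integer(0L))
  i <- from:to
  i[d1[i] > 0 & d1[i + 1L] <= 0]
}

#' Locate the primary fiducial landmarks of a beat
#'
#' A valley-delimited beat runs LV -> systolic upstroke -> early systolic peak
#' (ESP) -> dicrotic notch (DN) -> diastolic peak (DP, the reflected wave) ->
#' RV. The DP is the first point after the ESP where the first derivative
#' crosses zero downwards with negative curvature; if no such second peak
#' exists the beat takes the fallback path: DP is the point of minimum second
#' derivative between ESP and RV, and the inflection point (IP) is designated
#' as the DN. The IP is otherwise the last positive-to-negative first
#' derivative transition before the DP.
#'
#' Beats whose global maximum sits on a boundary sample are rejected
#' (returned with `rejected = TRUE`) — a systolic peak at a valley boundary
#' means segmentation failed for that beat.
#'
#' @param beat a `beat_segment`.
#' @param deriv derivatives from [smooth_derivatives()]; computed when `NULL`.
#' @param rel_prominence floor on the rise a candidate diastolic peak must
#'   show above the intervening minimum, as a fraction of the systolic
#'   amplitude; the effective gate is the larger of this floor and 3x the
#'   estimated noise level. Candidates below it are treated as noise and the
#'   beat falls back to the no-second-peak path.
#' @return An object of class `beat_fiducials`: 1-based sample indices `lv`,
#'   `esp`, `dn`, `dp`, `ip`, `rv`, sub-sample refinements `esp_frac`
#'   (quadratic-vertex apex) and `dp_frac` (interpolated zero of the first
#'   derivative), flags `has_second_peak`, `used_ip_as_dn`, `rejected`, and
#'   the derivatives used.
#' @export
locate_primary_fiducials <- function(beat, deriv = NULL,
                                     rel_prominence = 0.01) {
  stopifnot(inherits(beat, "beat_segment"))
  x <- beat$values
  n <- length(x)
  if (is.null(deriv)) deriv <- smooth_derivatives(beat)
  d1 <- deriv$d1
  d2 <- deriv$d2
  lv <- 1L
  rv <- n
  esp <- which.max(x)
  fid <- structure(list(lv = lv, esp = esp, dn = NA_integer_, dp = NA_integer_,
                        ip = NA_integer_, rv = rv,
                        esp_frac = NA_real_, dp_frac = NA_real_,
                        a = NA_integer_, b = NA_integer_, c_pt = NA_integer_,
                        d_pt = NA_integer_, e = NA_integer_, f = NA_integer_,
                        g = NA_integer_, h = NA_integer_,
                        has_second_peak = NA, used_ip_as_dn = NA,
                        rejected = FALSE, d1 = d1, d2 = d2, fs = beat$fs),
                   class = "beat_fiducials")
  if (esp == 1L || esp == n) {
    fid$rejected <- TRUE
    return(fid)
  }
  # sub-sample peak position from the quadratic vertex through the apex
  den <- x[esp - 1L] - 2 * x[esp] + x[esp + 1L]
  off <- if (den < 0) 0.5 * (x[esp - 1L] - x[esp + 1L]) / den else 0
  fid$esp_frac <- esp + min(0.5, max(-0.5, off))
  # second peak: first downward zero-crossing of d1 with d2 < 0 after ESP.
  # A candidate must rise above the intervening minimum by more than the
  # noise could produce, otherwise wiggles on the diastolic tail masquerade
  # as reflected waves. Prominence is measured on a Savitzky-Golay-smoothed
  # copy (single-sample bumps flatten, the tens-of-milliseconds reflected
  # wave survives) and gated at 4x the smoother-residual SD -- an adaptive
  # noise estimate -- with `rel_prominence` of the systolic amplitude as a
  # floor for noise-free signals.
  amp <- x[esp] - min(x)
  cross <- .down_crossings(d1, esp + 1L, rv - 1L)
  cross <- cross[d2[cross] < 0]
  if (length(cross) > 0L && amp > 0) {
    win <- min(7L, if (n %% 2L == 1L) n else n - 1L)
    xs <- as.numeric(signal::sgolayfilt(x, p = min(3L, win - 1L), n = win))
    thr <- max(4 * stats::sd(x - xs), rel_prominence * amp)
    prom <- vapply(cross, function(i)
      xs[i] - min(xs[esp:i]), numeric(1L))
    cross <- cross[prom >= thr]
  }
  if (length(cross) > 0L) {
    fid$has_second_peak <- TRUE
    # sub-sample zero of d1 by linear interpolation across the sign change
    i <- cross[1L]
    frac <- if (d1[i] != d1[i + 1L]) d1[i] / (d1[i] - d1[i + 1L]) else 0
    fid$dp_frac <- i + frac
    fid$dp <- if (frac <= 0.5) i else i + 1L
    fid$dn <- .argmin_win(x, esp, fid$dp)
    # last +/- transition of d1 at or before the second peak; on a clean
    # two-peak beat this is the DP crossing itself, placing IP at the apex
    # of the reflected wave (the vertex the A2 triangle needs)
    ipc <- .down_crossings(d1, esp + 1L, fid$dp)
    fid$ip <- if (length(ipc) > 0L) ipc[length(ipc)] else fid$dn
    fid$used_ip_as_dn <- FALSE
  } else {
    fid$has_second_peak <- FALSE
    fid$dp <- .argmin_win(d2, esp + 1L, rv - 1L)
    fid$dn <- .argmin_win(x, esp, fid$dp)
    fid$ip <- fid$dn
    fid$used_ip_as_dn <- TRUE
  }
  fid
}

#' @export
print.beat_fiducials <- function(x, ...) {
  cat(sprintf(
    "<beat_fiducials> lv=%d esp=%d dn=%s dp=%s ip=%s rv=%d second_peak=%s%s\n",
    x$lv, x$esp, x$dn, x$dp, x$ip, x$rv, x$has_second_peak,
    if (isTRUE(x$rejected)) " [REJECTED]" else ""))
  invisible(x)
}

#' Locate the acceleration-PPG extrema A-H
#'
#' The second derivative of a pulse beat alternates between maxima and minima
#' labelled A-H. They are found by earliest-index argmax/argmin of the second
#' derivative over fixed windows, in dependency order: A is the largest and B
#' the smallest second derivative before the ESP; F is the smallest between
#' ESP and RV; E the largest between ESP and F; H the smallest between F and
#' RV; G the largest between F and H. C and D (between B and E) are often
#' unidentifiable in noisy signals and are left `NA` when their window is
#' empty; downstream features do not use them.
#'
#' @param beat a `beat_segment`.
#' @param fid a `beat_fiducials` from [locate_primary_fiducials()].
#' @return `fid` with slots `a`, `b`, `c_pt`, `d_pt`, `e`, `f`, `g`, `h`
#'   filled (some possibly `NA`).
#' @export
locate_second_derivative_points <- function(beat, fid) {
  stopifnot(inherits(beat, "beat_segment"), inherits(fid, "beat_fiducials"))
  if (isTRUE(fid$rejected)) return(fid)
  d2 <- fid$d2
  esp <- fid$esp
  rv <- fid$rv
  fid$a <- .argmax_win(d2, 1L, esp - 1L)
  fid$b <- .argmin_win(d2, 1L, esp - 1L)
  fid$f <- .argmin_win(d2, esp + 1L, rv - 1L)
  if (!is.na(fid$f)) {
    # "between X and Y" is read inclusively so a window never collapses to
    # nothing when adjacent extrema sit on neighbouring samples
    fid$e <- .argmax_win(d2, esp, fid$f)
    fid$h <- .argmin_win(d2, fid$f + 1L, rv - 1L)
    if (!is.na(fid$h)) fid$g <- .argmax_win(d2, fid$f, fid$h)
  }
  if (!is.na(fid$b) && !is.na(fid$e) && fid$e - fid$b >= 2L) {
    fid$c_pt <- .argmax_win(d2, fid$b + 1L, fid$e - 1L)
    fid$d_pt <- .argmin_win(d2, fid$b + 1L, fid$e - 1L)
  }
  fid
}

#' Locate all fiducials of a beat in one call
#' @inheritParams locate_primary_fiducials
#' @return A fully populated `beat_fiducials`.
#' @export
locate_fiducials <- function(beat, deriv = NULL) {
  fid <- locate_primary_fiducials(beat, deriv)
  locate_second_derivative_points(beat, fid)
}
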