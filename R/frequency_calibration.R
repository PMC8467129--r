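#' Reference spatial frequencies of the acquisition protocol
#'
#' The sixteen projected spatial frequencies used by the imaging
#' protocol, in mm^-1, from the planar channel (0) through 0.14.
#'
#' @return Numeric vector of length 16.
#' @export
sfdi_frequencies <- function() {
  c(0, 0.007, 0.0084, 0.0098, 0.0112, 0.0126, 0.014,
    0.028, 0.042, 0.056, 0.070, 0.084, 0.098, 0.112, 0.126, 0.14)
}

#' Estimate the fringe period of a 1-D reflectance profile
#'
#' Detects local minima on a lightly smoothed copy of the profile,
#' refines each minimum to sub-pixel precision by fitting a parabola
#' through its three surrounding samples, and returns the mean spacing
#' between consecutive minima in pixels. At least two minima (two full
#' periods in view) are required.
#'
#' The estimate is invariant to amplitude scaling and DC offset of the
#' profile.
#'
#' @param profile Numeric vector: fringe-normal reflectance curve,
#'   typically obtained by averaging an ROI along the fringe direction.
#' @param smooth Half-width of the moving-average smoother applied before
#'   minima detection, samples; 0 disables smoothing. Default 2.
#' @return Estimated period Tc in pixels.
#' @export
estimate_pixel_period <- function(profile, smooth = 2L) {
  profile <- as.numeric(profile)
  n <- length(profile)
  if (n < 5L) stop("profile too short", call. = FALSE)
  if (max(profile) - min(profile) <= 0) {
    stop("constant profile: no fringes to measure", call. = FALSE)
  }
  sm <- profile
  if (smooth > 0L) {
    k <- 2L * as.integer(smooth) + 1L
    sm <- stats::filter(profile, rep(1 / k, k), sides = 2L)
    sm <- as.numeric(sm)
  }
  idx <- which(!is.na(sm))
  mins <- integer(0)
  for (i in idx) {
    if (i <= 1L || i >= n) next
    if (!is.na(sm[i - 1L]) && !is.na(sm[i + 1L]) &&
        sm[i] < sm[i - 1L] && sm[i] <= sm[i + 1L]) {
      mins <- c(mins, i)
    }
  }
  if (length(mins) < 2L) {
    stop("fewer than two fringe minima: profile must span >= 2 periods",
         call. = FALSE)
  }
  # parabolic sub-pixel refinement on the raw profile
  pos <- vapply(mins, function(i) {
    if (i <= 1L || i >= n) return(as.numeric(i))
    y1 <- profile[i - 1L]; y2 <- profile[i]; y3 <- profile[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (!is.finite(den) || den <= 0) return(as.numeric(i))
    i + 0.5 * (y1 - y3) / den
  }, numeric(1L))
  mean(diff(pos))
}

#' Convert a camera pixel period to the actual period on the plane
#'
#' Scales the captured pixel period by the checkerboard magnification:
#' `Tr = Tc * Xr / Xc_mean`, where `Xr` is the physical checkerboard cell
#' length and `Xc_mean` the mean cell length in camera pixels.
#'
#' @param tc Pixel period of the captured fringes, pixels.
#' @param xr Actual checkerboard cell length, mm (default 5).
#' @param xc_mean Mean checkerboard cell length in the camera image,
#'   pixels.
#' @return Actual fringe period Tr on the sample plane, mm.
#' @export
#' @examples
#' camera_to_actual_period(158.2, 5, 78.3)  # ~10.1 mm
camera_to_actual_period <- function(tc, xr = 5, xc_mean) {
  stopifnot(tc > 0, xr > 0, xc_mean > 0)
  tc * xr / xc_mean
}

#' Ratio of generation period to actual period
#'
#' `rrp = Tp / Tr` in pixels per mm: how many projector pixels produce
#' one millimetre of fringe on the sample plane.
#'
#' @param tp Fringe generation period, projector pixels.
#' @param tr Actual fringe period on the plane, mm.
#' @return Period ratio, pixels per mm.
#' @export
#' @examples
#' period_ratio(40, 10.1) * 1000  # ~3960 pixel / m
period_ratio <- function(tp, tr) {
  stopifnot(tp > 0, tr > 0)
  tp / tr
}

#' Generation period needed to realise a target actual period
#'
#' Inverts the period ratio: `Tp = rrp * Tre`, quantised to the pattern
#' synthesis resolution. Periods below 2 pixels cannot be represented by
#' a sampled sinusoid and raise an error; a zero target frequency
#' (infinite period) must be handled as the planar channel instead.
#'
#' @param tre Required actual period on the plane, mm.
#' @param rrp Period ratio, pixels per mm.
#' @param resolution_px Quantisation step of the synthesised period,
#'   pixels. Default 0.1 (phase-accurate synthesis); integer projectors
#'   would use 1.
#' @return Generation period Tp, pixels.
#' @export
projection_period_for_target <- function(tre, rrp, resolution_px = 0.1) {
  stopifnot(rrp > 0, resolution_px > 0)
  if (!is.finite(tre) || tre <= 0) {
    stop("target period must be finite and > 0; the zero-frequency channel is planar and has no period",
         call. = FALSE)
  }
  tp <- round(rrp * tre / resolution_px) * resolution_px
  if (tp < 2) {
    stop(sprintf("generation period %.2f px < 2 px: target frequency not representable", tp),
         call. = FALSE)
  }
  tp
}

#' Percentage error between expected and verified periods
#'
#' `et = |Tre - Tv| / Tre * 100`.
#'
#' @param tre Expected actual period, mm (> 0).
#' @param tv Verified (measured) actual period, mm.
#' @return Percentage error.
#' @export
period_percentage_error <- function(tre, tv) {
  stopifnot(all(tre > 0))
  abs(tre - tv) / tre * 100
}

#' Two-step fringe frequency calibration
#'
#' Calibrates the generation periods that realise a list of target
#' actual periods. Step 1 uses a single initial period ratio `rrp0` for
#' every target, measures the realised period of each projected pattern,
#' and records the percentage error. Step 2 updates the period ratio per
#' frequency from the step-1 measurement (`rrp_k = Tp1 / Tv1`),
#' regenerates the patterns, and measures again. A frequency-independent
#' multiplicative bias in the optics is removed entirely by one update;
#' smooth frequency-dependent distortion is strongly reduced.
#'
#' Targets whose period is too long for the field of view cannot be
#' measured (period estimation needs at least two complete fringes plus
#' a margin for minima detection at arbitrary phase, the `min_periods`
#' rule); their updated ratio is extrapolated linearly in frequency
#' from the calibrated ones and they are flagged in the result. A
#' measurement failure at one frequency flags that row and leaves the
#' others untouched.
#'
#' @param rrp0 Initial period ratio, pixels per mm.
#' @param tre Target actual periods, mm (vector; use
#'   `1 / sfdi_frequencies()[-1]` for the protocol list).
#' @param measure Function `Tp -> Tv` returning the measured actual
#'   period (mm) realised by a pattern of generation period `Tp`
#'   (pixels); wraps real acquisition or a simulator.
#' @param fov_mm Field of view on the plane, mm. Default 150.
#' @param min_periods Minimum number of complete fringe periods that
#'   must fit in the field for a target to be measurable; targets below
#'   it are extrapolated. Default 2.2 (two periods plus margin).
#' @param resolution_px Period quantisation passed to
#'   [projection_period_for_target()].
#' @return Data frame with one row per target: `tre`, `fx`, `measured`
#'   flag, `tp1`, `tv1`, `et1`, `rrp_k`, `tp2`, `tv2`, `et2`.
#' @export
two_step_calibration <- function(rrp0, tre, measure, fov_mm = 150,
                                 min_periods = 2.2, resolution_px = 0.1) {
  stopifnot(rrp0 > 0, length(tre) >= 1L, is.function(measure))
  n <- length(tre)
  out <- data.frame(tre = tre, fx = 1 / tre,
                    measured = fov_mm / tre >= min_periods,
                    tp1 = NA_real_, tv1 = NA_real_, et1 = NA_real_,
                    rrp_k = NA_real_, tp2 = NA_real_, tv2 = NA_real_,
                    et2 = NA_real_)
  safe_measure <- function(tp) {
    tryCatch(measure(tp), error = function(e) NA_real_)
  }
  for (i in seq_len(n)) {
    if (!out$measured[i]) next
    out$tp1[i] <- projection_period_for_target(tre[i], rrp0, resolution_px)
    out$tv1[i] <- safe_measure(out$tp1[i])
    if (is.na(out$tv1[i])) {
      out$measured[i] <- FALSE
      next
    }
    out$et1[i] <- period_percentage_error(tre[i], out$tv1[i])
    out$rrp_k[i] <- out$tp1[i] / out$tv1[i]
  }
  # extrapolate the ratio linearly in frequency for unmeasured targets
  ok <- out$measured & !is.na(out$rrp_k)
  if (any(!ok) && sum(ok) >= 2L) {
    fit <- stats::lm(rrp_k ~ fx, data = out[ok, ])
    out$rrp_k[!ok] <- stats::predict(fit, newdata = out[!ok, , drop = FALSE])
  } else if (any(!ok) && sum(ok) == 1L) {
    out$rrp_k[!ok] <- out$rrp_k[ok]
  }
  for (i in seq_len(n)) {
    if (is.na(out$rrp_k[i]) || out$rrp_k[i] <= 0) next
    out$tp2[i] <- projection_period_for_target(tre[i], out$rrp_k[i],
                                               resolution_px)
    if (out$measured[i]) {
      out$tv2[i] <- safe_measure(out$tp2[i])
      if (!is.na(out$tv2[i])) {
        out$et2[i] <- period_percentage_error(tre[i], out$tv2[i])
      }
    }
  }
  out
}
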