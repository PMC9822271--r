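# Preprocessing: baseline/tilt correction, contact-point detection, optional
# smoothing. Detection of adhesion events is only well-posed on a
# baseline-corrected, contact-aligned retract trace.

# indices (into the z-ordered retract) of the baseline window: the
# farthest-from-surface `fraction` of the retract z-range, where tether
# events cannot reach (events end within ~2 contour lengths of contact).
baseline_window_idx <- function(z, fraction = 0.30) {
  zmin <- min(z)
  zmax <- max(z)
  which(z >= zmax - fraction * (zmax - zmin))
}

#' Estimate the retract baseline
#'
#' Fits a least-squares line `force = slope * z + intercept` over the
#' baseline window: the farthest-from-surface fraction of the retract
#' z-range (default 30%), which is free of adhesion events for tethers of
#' ~50 nm contour length on a 300 nm ramp.
#'
#' @param curve An `fd_curve`.
#' @param baseline_fraction Fraction of the retract z-range used as the
#'   baseline window (default 0.30).
#' @return Named numeric vector `c(slope = , intercept = )` in pN/nm and pN.
#' @export
estimate_baseline <- function(curve, baseline_fraction = 0.30) {
  r <- retract(curve)
  if (nrow(r) < 16L) stop("retract segment too short", call. = FALSE)
  idx <- baseline_window_idx(r$z, baseline_fraction)
  if (length(idx) < 8L) {
    stop("baseline window has fewer than 8 samples", call. = FALSE)
  }
  z <- r$z[idx]
  f <- r$force[idx]
  zc <- z - mean(z)
  slope <- sum(zc * f) / sum(zc^2)
  intercept <- mean(f) - slope * mean(z)
  c(slope = slope, intercept = intercept)
}

#' Subtract a fitted baseline from a curve
#'
#' Removes the linear baseline `slope * z + intercept` from the force trace
#' of every segment. Correcting an already-corrected curve is a no-op to
#' within the noise floor (the refitted slope and intercept are ~0).
#'
#' @param curve An `fd_curve`.
#' @param baseline Output of [estimate_baseline()]; fitted from `curve`
#'   itself when omitted.
#' @return The corrected `fd_curve` (attribute `corrected` set).
#' @export
correct_curve <- function(curve, baseline = NULL) {
  if (is.null(baseline)) baseline <- estimate_baseline(curve)
  if (!all(is.finite(baseline))) stop("baseline must be finite", call. = FALSE)
  out <- curve
  out$data$force <- curve$data$force -
    (baseline[["slope"]] * curve$data$z + baseline[["intercept"]])
  attr(out, "corrected") <- TRUE
  attr(out, "no_contact") <- attr(curve, "no_contact")
  out
}

#' Locate the tip-surface contact point
#'
#' On the baseline-corrected retract trace, the contact region is the
#' initial run (moving away from the surface) of repulsive force above
#' `+T`, with `T = contact_threshold_sigma` times the noise floor. The
#' contact point `z0` is the last sample of that run; re-origin the curve
#' with [align_contact()] so that `z0 -> 0`. A run must span at least 3
#' samples and start in the near quarter of the trace; otherwise the curve
#' is flagged `no-contact` and `z0` falls back to the first retract sample.
#'
#' @param curve Baseline-corrected `fd_curve`.
#' @param contact_threshold_sigma Contact threshold in units of the noise
#'   floor (default 3).
#' @return List with `z0` (nm) and logical `no_contact`.
#' @export
find_contact_point <- function(curve, contact_threshold_sigma = 3) {
  r <- retract(curve)
  nf <- estimate_noise(curve)
  thr <- max(contact_threshold_sigma * nf, 1e-3)
  above <- r$force > thr
  n <- nrow(r)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ok <- runs$values & runs$lengths >= 3L & starts <= ceiling(n / 4)
  if (!any(ok)) {
    return(list(z0 = r$z[1L], no_contact = TRUE))
  }
  k <- which(ok)[1L]
  list(z0 = r$z[ends[k]], no_contact = FALSE)
}

#' Re-origin a curve at its contact point
#'
#' Shifts `z` so that the contact point sits at `z = 0` and retract `z`
#' increases away from the surface, making tether extension directly
#' comparable to contour length.
#'
#' @param curve Baseline-corrected `fd_curve`.
#' @param contact Output of [find_contact_point()]; computed when omitted.
#' @inheritParams find_contact_point
#' @return The shifted `fd_curve`, with attributes `no_contact` and `z0`.
#' @export
align_contact <- function(curve, contact = NULL, contact_threshold_sigma = 3) {
  if (is.null(contact)) {
    contact <- find_contact_point(curve, contact_threshold_sigma)
  }
  out <- curve
  out$data$z <- curve$data$z - contact$z0
  attr(out, "corrected") <- attr(curve, "corrected")
  attr(out, "no_contact") <- isTRUE(contact$no_contact)
  attr(out, "z0") <- contact$z0
  out
}

#' Savitzky-Golay smoothing of the force trace
#'
#' Moving least-squares polynomial smoothing (degree 2) of the force trace
#' of every segment; the z grid is untouched. `window = 1` disables
#' smoothing and returns the input unchanged. Smoothing is off by default
#' throughout the pipeline because it biases rupture force magnitudes
#' downward; detection instead uses a noise-aware threshold on raw traces.
#'
#' @param curve An `fd_curve`.
#' @param window Odd window length in samples (1 = off, otherwise >= 5 and
#'   shorter than every segment).
#' @return The smoothed `fd_curve`.
#' @export
smooth_force <- function(curve, window) {
  if (length(window) != 1L || is.na(window) || window < 1 ||
      window %% 2 == 0) {
    stop("`window` must be a positive odd integer", call. = FALSE)
  }
  if (window == 1) return(curve)
  if (window < 5) stop("degree-2 smoothing needs `window` >= 5", call. = FALSE)
  out <- curve
  for (seg in unique(curve$data$segment)) {
    idx <- which(curve$data$segment == seg)
    if (window >= length(idx)) {
      stop("`window` must be shorter than segment '", seg, "'", call. = FALSE)
    }
    ord <- idx[order(curve$data$z[idx])]
    out$data$force[ord] <- signal::sgolayfilt(curve$data$force[ord],
                                              p = 2, n = window)
  }
  attr(out, "corrected") <- attr(curve, "corrected")
  attr(out, "no_contact") <- attr(curve, "no_contact")
  out
}
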