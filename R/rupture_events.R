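# Rupture-event detection on the corrected, contact-aligned retract trace,
# and extraction of the two classification features: the maximum adhesion
# force and the number of peaks.

#' Default detection parameters
#'
#' Event detection parameters with their pipeline defaults. `min_force` is
#' 75 pN = `sigma_multiplier` (5) times the default 15 pN instrument noise:
#' weak non-specific events (>= 80 pN) stay detectable while the false-peak
#' rate on pure noise remains below 1%. `min_separation` (8 nm) merges
#' minima closer than the spacing at which tether detachments are
#' physically independent (>= 15 nm); `release_width` (5 nm) is the z span
#' within which a genuine bond rupture must snap back toward baseline at
#' the 1000-2600 nm/s retract velocities used.
#'
#' @param min_force Minimum event magnitude in pN.
#' @param min_separation Events closer than this (nm) merge, keeping the
#'   deeper one.
#' @param sigma_multiplier Noise-floor multiplier entering the effective
#'   threshold `max(min_force, sigma_multiplier * noise_floor)`.
#' @param release_width Maximum z span (nm) for the post-minimum rise.
#' @param release_fraction Required rise toward baseline as a fraction of
#'   the event magnitude.
#' @param baseline_fraction Baseline window fraction (see
#'   [estimate_baseline()]).
#' @param contact_threshold_sigma Contact threshold in noise-floor units.
#' @param smooth_window Savitzky-Golay window (1 = smoothing off).
#' @return Named list of parameters.
#' @export
detection_params <- function(min_force = 75, min_separation = 8,
                             sigma_multiplier = 5, release_width = 5,
                             release_fraction = 0.5,
                             baseline_fraction = 0.30,
                             contact_threshold_sigma = 3,
                             smooth_window = 1) {
  list(min_force = min_force, min_separation = min_separation,
       sigma_multiplier = sigma_multiplier, release_width = release_width,
       release_fraction = release_fraction,
       baseline_fraction = baseline_fraction,
       contact_threshold_sigma = contact_threshold_sigma,
       smooth_window = smooth_window)
}

#' Estimate the noise floor of a corrected curve
#'
#' Robust spread (median absolute deviation scaled by 1.4826, i.e.
#' consistent for a Gaussian) of the force over the baseline window of the
#' retract trace. Robustness matters: a stray spike in the baseline must
#' not inflate the detection threshold.
#'
#' @param curve Baseline-corrected `fd_curve`.
#' @param baseline_fraction Baseline window fraction (default 0.30).
#' @return Noise floor in pN.
#' @export
estimate_noise <- function(curve, baseline_fraction = 0.30) {
  r <- retract(curve)
  idx <- baseline_window_idx(r$z, baseline_fraction)
  if (length(idx) < 8L) {
    stop("baseline window has fewer than 8 samples", call. = FALSE)
  }
  mad(r$force[idx])
}

#' Detect rupture (adhesion) events
#'
#' An event is a local force minimum on the post-contact retract trace of
#' magnitude at least `max(min_force, sigma_multiplier * noise_floor)`,
#' followed by a rise back toward baseline of at least `release_fraction`
#' of its magnitude within `release_width` nm — the abrupt snap-back that
#' distinguishes a molecular bond rupture from a gradual non-specific
#' adhesion ramp. Minima closer than `min_separation` merge, keeping the
#' deeper one. Events are returned in order of increasing z.
#'
#' @param curve Baseline-corrected, contact-aligned `fd_curve`.
#' @param min_force,min_separation,params Detection settings; `min_force`
#'   and `min_separation` override the corresponding entries of `params`.
#' @return Tibble of events with columns `z_rupture` (nm), `force`
#'   (positive magnitude, pN) and `release_width` (nm).
#' @export
detect_ruptures <- function(curve,
                            min_force = params$min_force,
                            min_separation = params$min_separation,
                            params = detection_params()) {
  r <- retract(curve)
  nf <- estimate_noise(curve, params$baseline_fraction)
  bl <- r$force[baseline_window_idx(r$z, params$baseline_fraction)]
  if (abs(mean(bl)) > 5 * max(nf, 1)) {
    stop("curve does not look baseline-corrected ",
         "(baseline mean far above noise floor); run correct_curve() first",
         call. = FALSE)
  }
  # post-contact region; on an aligned curve the contact ramp sits at z < 0
  keep <- r$z >= 0
  z <- r$z[keep]
  f <- r$force[keep]
  n <- length(z)
  empty <- tibble::tibble(z_rupture = numeric(0), force = numeric(0),
                          release_width = numeric(0))
  if (n < 3L) return(empty)
  thr <- max(min_force, params$sigma_multiplier * nf)
  cand <- which(f <= -thr)
  if (length(cand) == 0L) return(empty)
  dz <- median(diff(z))
  # a candidate is a local minimum within a half-separation window; two
  # genuine ruptures can sit on one unbroken sub-threshold stretch (the
  # next tether is already loaded when the first lets go), so minima are
  # found per window, not per threshold crossing
  w <- max(1L, ceiling(min_separation / dz / 2))
  is_min <- vapply(cand, function(i) {
    f[i] <= min(f[max(1L, i - w):min(n, i + w)])
  }, logical(1))
  mins <- cand[is_min]
  ev_z <- numeric(0); ev_f <- numeric(0); ev_w <- numeric(0)
  for (i in mins) {
    ahead <- which(z > z[i] & z <= z[i] + params$release_width)
    if (length(ahead) == 0L) next
    depth <- -f[i]
    rise <- cummax(f[ahead]) - f[i]
    hit <- which(rise >= params$release_fraction * depth)
    if (length(hit) == 0L) next
    ev_z <- c(ev_z, z[i])
    ev_f <- c(ev_f, depth)
    ev_w <- c(ev_w, z[ahead[hit[1L]]] - z[i])
  }
  if (length(ev_z) == 0L) return(empty)
  # merge surviving events closer than min_separation, keeping the deeper
  ord <- order(ev_z)
  ev_z <- ev_z[ord]; ev_f <- ev_f[ord]; ev_w <- ev_w[ord]
  keep_ev <- rep(TRUE, length(ev_z))
  for (i in seq_along(ev_z)[-1L]) {
    prev <- max(which(keep_ev[seq_len(i - 1L)]))
    if (ev_z[i] - ev_z[prev] < min_separation) {
      if (ev_f[i] > ev_f[prev]) keep_ev[prev] <- FALSE else keep_ev[i] <- FALSE
    }
  }
  tibble::tibble(z_rupture = ev_z[keep_ev], force = ev_f[keep_ev],
                 release_width = ev_w[keep_ev])
}

# quality flags: no-contact, saturated, baseline-jump, overrange.
# * saturated: a run of >= sat_run identical force values at a deeply
#   attractive level — the clipped rail of the detector.
# * baseline-jump: a discontinuous offset somewhere along the trace; seen
#   either as disagreeing half-means of the baseline-window residuals or as
#   a post-event "quiet" region (45-70% of the retract z span) sitting far
#   from zero after correction.
# * overrange: any sample beyond the instrument's plausible force range.
quality_flags <- function(curve, params = detection_params(),
                          sat_run = 5L, force_range = 2500) {
  r <- retract(curve)
  nf <- estimate_noise(curve, params$baseline_fraction)
  tol <- 5 * max(nf, 1)
  flags <- character(0)
  if (isTRUE(attr(curve, "no_contact"))) flags <- c(flags, "no-contact")
  runs <- rle(r$force)
  if (any(runs$lengths >= sat_run & runs$values <= -params$min_force)) {
    flags <- c(flags, "saturated")
  }
  idx <- baseline_window_idx(r$z, params$baseline_fraction)
  half <- length(idx) %/% 2L
  jump <- abs(mean(r$force[idx[seq_len(half)]]) -
              mean(r$force[idx[-seq_len(half)]])) > tol
  zmax <- max(r$z)
  quiet <- which(r$z >= 0.45 * zmax & r$z <= 0.70 * zmax & r$z > 0)
  if (length(quiet) >= 8L && abs(mean(r$force[quiet])) > tol) jump <- TRUE
  if (jump) flags <- c(flags, "baseline-jump")
  if (any(abs(r$force) > force_range)) flags <- c(flags, "overrange")
  flags
}

#' Extract classification features from a curve
#'
#' Collapses a detected event list into the two quantities the classifier
#' uses — the number of peaks and the maximum adhesion force — plus the
#' noise floor and quality flags. `f_max` is the positive magnitude of the
#' global force minimum of the post-contact retract region when at least
#' one event was detected, and 0 otherwise.
#'
#' @param curve Baseline-corrected, contact-aligned `fd_curve`.
#' @param events Event tibble from [detect_ruptures()] on the same curve;
#'   detected here when omitted.
#' @param params Detection parameters ([detection_params()]).
#' @return A list of class `curve_features` with elements `n_events`,
#'   `f_max` (pN), `noise_floor` (pN), `quality_flags` (character vector)
#'   and the `events` tibble.
#' @export
extract_features <- function(curve, events = NULL,
                             params = detection_params()) {
  if (is.null(events)) events <- detect_ruptures(curve, params = params)
  r <- retract(curve)
  post <- r$force[r$z >= 0]
  n_events <- nrow(events)
  f_max <- if (n_events > 0L) max(-min(post), max(events$force)) else 0
  structure(
    list(n_events = n_events,
         f_max = f_max,
         noise_floor = estimate_noise(curve, params$baseline_fraction),
         quality_flags = quality_flags(curve, params),
         events = events),
    class = "curve_features"
  )
}

#' @export
print.curve_features <- function(x, ...) {
  cat(sprintf("<curve_features> n_events = %d, f_max = %.1f pN, noise = %.1f pN\n",
              x$n_events, x$f_max, x$noise_floor))
  if (length(x$quality_flags)) {
    cat("  flags:", paste(x$quality_flags, collapse = ", "), "\n")
  }
  invisible(x)
}
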