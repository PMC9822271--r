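# Constructors for synthetic test traces that are already baseline-corrected
# and contact-aligned (z = 0 at contact, retract increasing away from the
# surface), so detection operations can be exercised in isolation.

flat_curve <- function(force = 0, n = 512, z_max = 300) {
  z <- seq(0, z_max, length.out = n)
  fd_curve(z, rep_len(force, n))
}

noise_curve <- function(sigma = 15, n = 1024, z_max = 300) {
  z <- seq(0, z_max, length.out = n)
  fd_curve(z, rnorm(n, 0, sigma))
}

# piecewise-linear sawtooth pulls: each event is a linear ramp from the end
# of the previous event down to -depth at z_peak, then instant release; the
# peak positions are inserted into the grid so the stated depths are attained
sawtooth_curve <- function(z_peaks, depths, n = 1024, z_max = 300) {
  z <- sort(unique(c(seq(0, z_max, length.out = n), z_peaks)))
  force <- numeric(length(z))
  start <- 0
  for (k in seq_along(z_peaks)) {
    seg <- z > start & z <= z_peaks[k]
    force[seg] <- -depths[k] * (z[seg] - start) / (z_peaks[k] - start)
    start <- z_peaks[k]
  }
  fd_curve(z, force)
}

# features object assembled by hand, for classifier unit tests
fake_features <- function(n_events, f_max, flags = character(0)) {
  structure(list(n_events = n_events, f_max = f_max, noise_floor = 15,
                 quality_flags = flags,
                 events = tibble::tibble(z_rupture = numeric(0),
                                         force = numeric(0),
                                         release_width = numeric(0))),
            class = "curve_features")
}
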