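# Physics-based generator of labeled force-distance curves: worm-like-chain
# (WLC) tether pulls with type-conditioned rupture-force distributions, a
# linear contact ramp, baseline tilt, Gaussian instrument noise and rare
# injected artifacts. Two condition presets emulate the pristine
# streptavidin surface and the biotin-albumin-blocked control.

#' Worm-like-chain tether model
#'
#' Entropic elasticity parameters of the PEG spacer tethering the ligand to
#' the tip: contour length L_c (~50 nm for a 10 kDa PEG), persistence
#' length p (0.38 nm, the accepted PEG value in water) and thermal energy
#' kT (4.114 pN nm at 298 K).
#'
#' @param contour_length L_c in nm (> 0).
#' @param persistence_length p in nm (> 0, < L_c).
#' @param kT Thermal energy in pN nm.
#' @return List of class `tether_model`.
#' @export
tether_model <- function(contour_length = 50, persistence_length = 0.38,
                         kT = 4.114) {
  if (contour_length <= 0 || persistence_length <= 0 || kT <= 0) {
    stop("all tether parameters must be positive", call. = FALSE)
  }
  if (persistence_length >= contour_length) {
    stop("persistence_length must be smaller than contour_length",
         call. = FALSE)
  }
  structure(list(contour_length = contour_length,
                 persistence_length = persistence_length, kT = kT),
            class = "tether_model")
}

#' WLC force at a given extension
#'
#' Marko-Siggia interpolation for the tension of a worm-like chain held at
#' end-to-end extension `x`:
#' `F = (kT/p) * (1 / (4 (1 - x/L_c)^2) - 1/4 + x/L_c)`.
#' Strictly increasing in `x` and divergent as `x -> L_c`.
#'
#' @param x Extension in nm, `0 <= x < contour_length` (vectorised).
#' @param model A [tether_model()].
#' @return Tension in pN (positive).
#' @export
wlc_force <- function(x, model = tether_model()) {
  if (any(x < 0) || any(x >= model$contour_length)) {
    stop("extension must satisfy 0 <= x < contour_length", call. = FALSE)
  }
  t <- x / model$contour_length
  (model$kT / model$persistence_length) * (1 / (4 * (1 - t)^2) - 0.25 + t)
}

#' WLC extension at a given force
#'
#' Inverse of [wlc_force()]: the unique extension in `[0, L_c)` at which
#' the chain tension equals `F`, found by bracketed root-finding to a force
#' residual below 1e-6 pN.
#'
#' @param F Tension in pN, `>= 0` (vectorised).
#' @param model A [tether_model()].
#' @return Extension in nm.
#' @export
wlc_extension_at_force <- function(F, model = tether_model()) {
  if (any(F < 0)) stop("force must be >= 0", call. = FALSE)
  Lc <- model$contour_length
  vapply(F, function(f) {
    if (f == 0) return(0)
    r <- uniroot(function(x) wlc_force(x, model) - f,
                 lower = 0, upper = Lc * (1 - 1e-9),
                 tol = 1e-12 * Lc, maxiter = 2000L)
    r$root
  }, numeric(1))
}

# inverse-CDF sampler for a normal truncated to [lo, hi]
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  p <- runif(n, pnorm(lo, mean, sd), pnorm(hi, mean, sd))
  qnorm(p, mean, sd)
}

#' Default per-type rupture specification
#'
#' Number-of-tether distributions and truncated-normal rupture-force
#' distributions for each curve type, matching the force scales of the
#' biotin-streptavidin system: non-specific adhesion N(150, 30) truncated
#' to \[80, 200\] pN; single-bond unbinding N(400, 80) truncated to
#' (200, 650\] pN (mean ~400 pN); simultaneous multi-bond detachment
#' N(1000, 250) truncated to (650, 2000\] pN. Contour lengths jitter
#' N(0, 5) nm around the 50 nm spacer; anchor offsets of independent
#' tethers are uniform in \[15, 60\] nm with pairwise spacing >= 15 nm.
#'
#' @return Nested list of class `rupture_spec`.
#' @export
default_rupture_spec <- function() {
  structure(list(
    nonspecific = list(mean = 150, sd = 30, lo = 80, hi = 200),
    single = list(mean = 400, sd = 80, lo = 200, hi = 650),
    simultaneous = list(mean = 1000, sd = 250, lo = 650, hi = 2000),
    n_independent = 2:4,        # tether count for independent-detachment curves
    n_extra_combined = 1:2,     # independent tethers added to a simultaneous pair
    contour_jitter_sd = 5,      # nm
    offset_range = c(15, 60),   # nm, anchor offsets of independent tethers
    min_offset_gap = 15,        # nm, pairwise anchor spacing
    saturation_level = 1500,    # pN, detector rail for clipped artifacts
    jump_height = c(300, 800),  # pN, baseline-step artifact magnitude
    jump_window = c(0.52, 0.66),# fraction of z range where the step occurs
    overrange_force = c(2100, 2400) # pN, beyond the 2000 pN ceiling
  ), class = "rupture_spec")
}

#' Simulation condition
#'
#' A named mixture over the seven curve types plus the instrument and
#' acquisition parameters of a batch: Gaussian force noise (15 pN),
#' baseline tilt (slope sd 0.02 pN/nm, offset sd 10 pN), a 300 nm retract
#' ramp sampled at 1024 points (~0.3 nm resolution, enough to resolve the
#' 5 nm release width of a rupture), a 500 pN contact trigger and the
#' cantilever spring constant (180 pN/nm).
#'
#' @param name Condition label.
#' @param mixture Named probability vector over `Type1`..`Type7`
#'   (non-negative, sums to 1).
#' @param noise_sigma Force noise sd in pN.
#' @param tilt_sd Baseline slope sd in pN/nm.
#' @param offset_sd Baseline offset sd in pN.
#' @param z_range Retract ramp length in nm.
#' @param samples Samples per curve.
#' @param trigger_force Contact trigger in pN (sets where the ramp starts).
#' @param spring_constant Cantilever stiffness in pN/nm.
#' @return List of class `sim_condition`.
#' @export
sim_condition <- function(name, mixture, noise_sigma = 15, tilt_sd = 0.02,
                          offset_sd = 10, z_range = 300, samples = 1024,
                          trigger_force = 500, spring_constant = 180) {
  if (is.null(names(mixture)) || !setequal(names(mixture), class_codes())) {
    stop("`mixture` must be named over Type1..Type7", call. = FALSE)
  }
  mixture <- mixture[class_codes()]
  if (any(mixture < 0) || abs(sum(mixture) - 1) > 1e-9) {
    stop("`mixture` entries must be >= 0 and sum to 1", call. = FALSE)
  }
  structure(list(name = name, mixture = mixture, noise_sigma = noise_sigma,
                 tilt_sd = tilt_sd, offset_sd = offset_sd, z_range = z_range,
                 samples = samples, trigger_force = trigger_force,
                 spring_constant = spring_constant),
            class = "sim_condition")
}

#' Pristine streptavidin condition preset
#'
#' Type mixture for a biotin-functionalized tip on a pristine
#' streptavidin-coated substrate: independent multiple detachment (Type4)
#' most frequent, then single interactions (Type3), then simultaneous
#' (Type5) and combined (Type6) multiple events; no-interaction plus
#' non-specific curves total 10% and artifacts ~1%, giving a success rate
#' of ~90% of all recorded curves.
#'
#' @return A [sim_condition()].
#' @export
preset_pristine <- function() {
  sim_condition("pristine",
                c(Type1 = 0.06, Type2 = 0.04, Type3 = 0.28, Type4 = 0.37,
                  Type5 = 0.14, Type6 = 0.10, Type7 = 0.01))
}

#' Blocked streptavidin condition preset
#'
#' Type mixture after saturating the surface streptavidin with
#' biotinylated albumin: 37% of curves show no interaction and Type1+Type2
#' exceed half of all curves; among the residual specific events (from
#' incompletely blocked, now isolated streptavidin) single interactions
#' outnumber independent multiple ones.
#'
#' @return A [sim_condition()].
#' @export
preset_blocked <- function() {
  sim_condition("blocked",
                c(Type1 = 0.37, Type2 = 0.16, Type3 = 0.22, Type4 = 0.13,
                  Type5 = 0.07, Type6 = 0.04, Type7 = 0.01))
}

# ---- internal rendering -------------------------------------------------

# draw anchor offsets: first tether at 0, others uniform in offset_range
# with pairwise gaps >= min_offset_gap
draw_offsets <- function(n_extra, spec) {
  for (try in 1:200) {
    off <- sort(runif(n_extra, spec$offset_range[1], spec$offset_range[2]))
    if (n_extra <= 1L || all(diff(off) >= spec$min_offset_gap)) {
      return(c(0, off))
    }
  }
  stop("could not place tether anchors with the required spacing",
       call. = FALSE)
}

# draw the tether set and artifact descriptor for one curve of a given type
draw_tethers <- function(class, spec, model) {
  jit <- function(k) pmax(model$contour_length / 2,
                          model$contour_length +
                            rnorm(k, 0, spec$contour_jitter_sd))
  tether <- function(offset, Lc, f) {
    data.frame(offset = offset, Lc = Lc, f_rupt = f)
  }
  artifact <- NULL
  tethers <- switch(class,
    Type1 = tether(numeric(0), numeric(0), numeric(0)),
    Type2 = {
      s <- spec$nonspecific
      tether(0, jit(1), rtrunc_norm(1, s$mean, s$sd, s$lo, s$hi))
    },
    Type3 = {
      s <- spec$single
      tether(0, jit(1), rtrunc_norm(1, s$mean, s$sd, s$lo, s$hi))
    },
    Type4 = {
      s <- spec$single
      k <- sample(spec$n_independent, 1L)
      tether(draw_offsets(k - 1L, spec), jit(k),
             rtrunc_norm(k, s$mean, s$sd, s$lo, s$hi))
    },
    Type5 = {
      s <- spec$simultaneous
      fc <- rtrunc_norm(1, s$mean, s$sd, s$lo, s$hi)
      Lc <- jit(1)
      tether(c(0, 0), c(Lc, Lc), c(fc / 2, fc / 2))
    },
    Type6 = {
      s <- spec$simultaneous
      si <- spec$single
      fc <- rtrunc_norm(1, s$mean, s$sd, s$lo, s$hi)
      Lc <- jit(1)
      k <- sample(spec$n_extra_combined, 1L)
      off <- draw_offsets(k, spec)[-1L]
      rbind(tether(c(0, 0), c(Lc, Lc), c(fc / 2, fc / 2)),
            tether(off, jit(k), rtrunc_norm(k, si$mean, si$sd, si$lo, si$hi)))
    },
    Type7 = {
      kind <- sample(c("saturate", "jump", "overrange"), 1L)
      if (kind == "saturate") {
        fc <- runif(1, 2500, 4000)
        Lc <- jit(1)
        artifact <- list(kind = "saturate", level = spec$saturation_level)
        tether(c(0, 0), c(Lc, Lc), c(fc / 2, fc / 2))
      } else if (kind == "jump") {
        artifact <- list(kind = "jump",
                         height = sample(c(-1, 1), 1L) *
                           runif(1, spec$jump_height[1], spec$jump_height[2]),
                         at = runif(1, spec$jump_window[1],
                                    spec$jump_window[2]))
        tether(numeric(0), numeric(0), numeric(0))
      } else {
        artifact <- list(kind = "overrange")
        tether(0, jit(1),
               runif(1, spec$overrange_force[1], spec$overrange_force[2]))
      }
    },
    stop("unknown curve class: ", class, call. = FALSE)
  )
  # ruptures a clean detection should resolve: a simultaneous pair is one
  # peak; artifacts are exempt
  expected_events <- switch(class,
    Type1 = 0L, Type2 = 1L, Type3 = 1L,
    Type4 = nrow(tethers), Type5 = 1L,
    Type6 = 1L + (nrow(tethers) - 2L), Type7 = NA_integer_)
  list(tethers = tethers, artifact = artifact,
       expected_events = expected_events)
}

# render the deterministic part of a retract trace: linear contact ramp,
# WLC tether pulls with the rupture force attained exactly at the last
# attached grid sample, baseline tilt/offset, and a baseline-step artifact
# if present. Noise and saturation clipping are applied by assemble_force().
render_retract <- function(tethers, condition, model, tilt, artifact = NULL) {
  z <- seq(0, condition$z_range, length.out = condition$samples)
  z_contact <- condition$trigger_force / condition$spring_constant
  ext <- z - z_contact
  force <- ifelse(ext < 0, -condition$spring_constant * ext, 0)
  if (nrow(tethers) > 0L) {
    for (i in seq_len(nrow(tethers))) {
      tm <- tether_model(tethers$Lc[i], model$persistence_length, model$kT)
      x_star <- wlc_extension_at_force(tethers$f_rupt[i], tm)
      x <- ext - tethers$offset[i]
      active <- which(x > 0 & x <= x_star)
      if (length(active) == 0L) next
      force[active] <- force[active] - wlc_force(x[active], tm)
      # the bond breaks between grid points; record its peak tension at the
      # last attached sample so the sampled trace attains the rupture force
      last <- active[length(active)]
      force[last] <- force[last] + wlc_force(x[last], tm) - tethers$f_rupt[i]
    }
  }
  if (!is.null(artifact) && artifact$kind == "jump") {
    force[z > artifact$at * condition$z_range] <-
      force[z > artifact$at * condition$z_range] + artifact$height
  }
  force <- force + tilt$slope * z + tilt$offset
  list(z = z, force = force, z_contact = z_contact)
}

assemble_force <- function(rendered, condition, artifact, noise_sigma) {
  force <- rendered$force
  if (noise_sigma > 0) {
    force <- force + rnorm(length(force), 0, noise_sigma)
  }
  if (!is.null(artifact) && artifact$kind == "saturate") {
    force[force < -artifact$level] <- -artifact$level
  }
  force
}

# ---- public generators --------------------------------------------------

#' Simulate one labeled force-distance curve
#'
#' Draws a tether set for the requested curve type, renders the retract
#' trace (linear contact ramp up to the 500 pN trigger, superposed WLC
#' tether pulls each released at its sampled rupture force, baseline tilt
#' and offset), and adds Gaussian noise. The noise-free rendering is
#' checked to classify back to the requested type under the default
#' analysis chain (rare draws that land on a class boundary — e.g.
#' overlapping independent tethers summing past 650 pN — are redrawn), so
#' generator truth and noise-free pipeline output agree by construction.
#'
#' @param class Target class code, `"Type1"`..`"Type7"`.
#' @param spec A [default_rupture_spec()].
#' @param condition A [sim_condition()].
#' @param model A [tether_model()].
#' @param noise Add Gaussian force noise (`condition$noise_sigma`)?
#' @param curve_index Temporal index stored in the metadata.
#' @return An `fd_curve` with `true_class` set in its metadata and a
#'   `truth` attribute (tether table, artifact descriptor, true contact
#'   point `z0`).
#' @export
simulate_curve <- function(class, spec = default_rupture_spec(),
                           condition = preset_pristine(),
                           model = tether_model(), noise = TRUE,
                           curve_index = 0L) {
  class <- match.arg(class, class_codes())
  for (try in 1:200) {
    drawn <- draw_tethers(class, spec, model)
    tilt <- list(slope = rnorm(1, 0, condition$tilt_sd),
                 offset = rnorm(1, 0, condition$offset_sd))
    rendered <- render_retract(drawn$tethers, condition, model, tilt,
                               drawn$artifact)
    quiet <- assemble_force(rendered, condition, drawn$artifact, 0)
    check <- fd_curve(rendered$z, quiet,
                      metadata = curve_metadata(
                        spring_constant = condition$spring_constant))
    checked <- analyze_curve(check)
    ok <- as.character(checked$class) == class &&
      (is.na(drawn$expected_events) ||
         checked$features$n_events == drawn$expected_events)
    if (ok) {
      force <- assemble_force(rendered, condition, drawn$artifact,
                              if (noise) condition$noise_sigma else 0)
      md <- curve_metadata(spring_constant = condition$spring_constant,
                           condition_label = condition$name,
                           curve_index = curve_index,
                           true_class = class)
      out <- fd_curve(rendered$z, force, metadata = md)
      attr(out, "truth") <- list(class = class, z0 = rendered$z_contact,
                                 tethers = drawn$tethers,
                                 artifact = drawn$artifact, tilt = tilt)
      return(out)
    }
  }
  stop("could not draw a ", class, " curve that classifies back to its label",
       call. = FALSE)
}

#' Simulate a noise-free single-rupture curve of given magnitude
#'
#' One WLC tether released at exactly `force` pN, no tilt and no noise by
#' default: the probe curve used for threshold sweeps and detector
#' calibration checks.
#'
#' @param force Rupture force magnitude in pN.
#' @param condition A [sim_condition()] providing grid and trigger; its
#'   noise and tilt are overridden by the arguments below.
#' @param model A [tether_model()].
#' @param noise_sigma Gaussian noise sd in pN (default 0).
#' @param tilt_slope,tilt_offset Baseline tilt (default none).
#' @return An `fd_curve`.
#' @export
simulate_single_rupture <- function(force, condition = preset_pristine(),
                                    model = tether_model(), noise_sigma = 0,
                                    tilt_slope = 0, tilt_offset = 0) {
  stopifnot(is.numeric(force), length(force) == 1L, force > 0)
  tethers <- data.frame(offset = 0, Lc = model$contour_length,
                        f_rupt = force)
  rendered <- render_retract(tethers, condition, model,
                             list(slope = tilt_slope, offset = tilt_offset))
  f <- assemble_force(rendered, condition, NULL, noise_sigma)
  out <- fd_curve(rendered$z, f,
                  metadata = curve_metadata(
                    spring_constant = condition$spring_constant))
  attr(out, "truth") <- list(z0 = rendered$z_contact, tethers = tethers)
  out
}

#' Simulate a batch of labeled curves in memory
#'
#' Draws `n` true classes i.i.d. from the condition mixture (or uses
#' `classes` as given) and simulates each curve. Fully reproducible for a
#' given `seed`.
#'
#' @param condition A [sim_condition()].
#' @param n Number of curves.
#' @param seed Optional integer seed (set once before all draws).
#' @param classes Optional explicit class vector of length `n`, bypassing
#'   the mixture.
#' @param spec,model Generator settings.
#' @param noise Add instrument noise?
#' @return List of `fd_curve` objects with `curve_index` 1..n.
#' @export
simulate_curves <- function(condition, n, seed = NULL, classes = NULL,
                            spec = default_rupture_spec(),
                            model = tether_model(), noise = TRUE) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(classes)) {
    classes <- sample(class_codes(), n, replace = TRUE,
                      prob = condition$mixture)
  }
  stopifnot(length(classes) == n)
  lapply(seq_len(n), function(i) {
    simulate_curve(classes[i], spec, condition, model, noise = noise,
                   curve_index = i)
  })
}

#' Simulate a batch and write it to disk
#'
#' Writes one curve file per curve (the columnar text dialect of
#' [write_fd_table()]) plus a `manifest.csv` recording filename, temporal
#' index, condition label and true class.
#'
#' @inheritParams simulate_curves
#' @param dir Output directory (created if needed).
#' @return The manifest tibble, invisibly.
#' @export
simulate_batch <- function(condition, n, dir, seed = NULL,
                           spec = default_rupture_spec(),
                           model = tether_model(), noise = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  curves <- simulate_curves(condition, n, seed = seed, spec = spec,
                            model = model, noise = noise)
  filenames <- sprintf("curve_%05d.tsv", seq_len(n))
  for (i in seq_len(n)) {
    write_fd_table(curves[[i]], file.path(dir, filenames[i]))
  }
  manifest <- tibble::tibble(
    filename = filenames,
    curve_index = seq_len(n),
    condition_label = condition$name,
    true_class = vapply(curves, function(cu) cu$metadata$true_class, "")
  )
  write_manifest(manifest, dir)
  invisible(manifest)
}
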