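#' Curve acquisition metadata
#'
#' Calibration and acquisition metadata attached to every force-distance
#' curve. Units: `spring_constant` pN/nm, `deflection_sensitivity` nm/V,
#' velocities nm/s, `contact_time` s.
#'
#' @param spring_constant Cantilever stiffness in pN/nm (must be > 0).
#' @param deflection_sensitivity Optical lever sensitivity in nm/V, or `NULL`
#'   when traces are already in force units.
#' @param forward_velocity,backward_velocity Approach / retract piezo
#'   velocities in nm/s.
#' @param contact_time Dwell time at the surface in seconds.
#' @param condition_label Free-text experimental condition
#'   (e.g. `"pristine"`, `"blocked"`).
#' @param curve_index Non-negative integer position of the curve in the
#'   temporal series.
#' @param true_class Optional ground-truth class code (`"Type1"`..`"Type7"`),
#'   set by the simulator and absent for real data.
#' @return A list of class `curve_metadata`.
#' @export
curve_metadata <- function(spring_constant = 180,
                           deflection_sensitivity = NULL,
                           forward_velocity = 1000,
                           backward_velocity = 2600,
                           contact_time = 1,
                           condition_label = NA_character_,
                           curve_index = 0L,
                           true_class = NA_character_) {
  if (!is.numeric(spring_constant) || length(spring_constant) != 1L ||
      !is.finite(spring_constant) || spring_constant <= 0) {
    stop("`spring_constant` must be a single positive number (pN/nm)",
         call. = FALSE)
  }
  if (!is.null(deflection_sensitivity)) {
    if (!is.numeric(deflection_sensitivity) || deflection_sensitivity <= 0) {
      stop("`deflection_sensitivity` must be positive (nm/V)", call. = FALSE)
    }
  }
  for (nm in c("forward_velocity", "backward_velocity")) {
    v <- get(nm)
    if (!is.null(v) && !is.na(v) && v <= 0) {
      stop("`", nm, "` must be positive (nm/s)", call. = FALSE)
    }
  }
  if (length(curve_index) != 1L || is.na(curve_index) || curve_index < 0) {
    stop("`curve_index` must be a single non-negative integer", call. = FALSE)
  }
  structure(
    list(
      spring_constant = as.numeric(spring_constant),
      deflection_sensitivity = if (is.null(deflection_sensitivity)) NULL
                               else as.numeric(deflection_sensitivity),
      forward_velocity = as.numeric(forward_velocity),
      backward_velocity = as.numeric(backward_velocity),
      contact_time = as.numeric(contact_time),
      condition_label = as.character(condition_label),
      curve_index = as.integer(curve_index),
      true_class = as.character(true_class)
    ),
    class = "curve_metadata"
  )
}

#' Construct a force-distance curve
#'
#' The central data object: one approach/retract record of piezo displacement
#' (nm) versus force (pN) with acquisition metadata. The retract segment must
#' always be present; `z` must be strictly monotone within each segment and
#' every segment must hold at least 16 samples. Attractive (adhesive) force is
#' negative.
#'
#' @param z Piezo displacement in nm.
#' @param force Force in pN (negative = attractive).
#' @param segment Segment label per sample, `"approach"` or `"retract"`
#'   (recycled if length 1).
#' @param metadata A [curve_metadata()] object.
#' @return An object of class `fd_curve`: a list with elements `data`
#'   (tibble with columns `segment`, `z`, `force`) and `metadata`.
#' @export
fd_curve <- function(z, force, segment = "retract", metadata = curve_metadata()) {
  if (length(segment) == 1L) segment <- rep(segment, length(z))
  dat <- tibble::tibble(
    segment = as.character(segment),
    z = as.numeric(z),
    force = as.numeric(force)
  )
  curve <- structure(list(data = dat, metadata = metadata),
                     class = "fd_curve")
  validate_fd_curve(curve)
}

#' Validate a force-distance curve
#'
#' Checks the structural invariants of an `fd_curve`: equal-length arrays,
#' at least 16 samples per segment, a retract segment present, finite values
#' and strictly monotone `z` within each segment.
#'
#' @param curve An `fd_curve`.
#' @return The curve, invisibly unchanged, or an error describing the
#'   violated invariant.
#' @export
validate_fd_curve <- function(curve) {
  if (!inherits(curve, "fd_curve")) stop("not an `fd_curve`", call. = FALSE)
  dat <- curve$data
  if (!all(c("segment", "z", "force") %in% names(dat))) {
    stop("curve data must have columns segment, z, force", call. = FALSE)
  }
  if (!all(dat$segment %in% c("approach", "retract"))) {
    stop("segment labels must be 'approach' or 'retract'", call. = FALSE)
  }
  if (!any(dat$segment == "retract")) {
    stop("retract segment is missing", call. = FALSE)
  }
  for (seg in unique(dat$segment)) {
    zs <- dat$z[dat$segment == seg]
    fs <- dat$force[dat$segment == seg]
    if (length(zs) < 16L) {
      stop("segment '", seg, "' has fewer than 16 samples", call. = FALSE)
    }
    if (anyNA(zs) || anyNA(fs) || !all(is.finite(zs)) || !all(is.finite(fs))) {
      stop("segment '", seg, "' contains non-finite values", call. = FALSE)
    }
    dz <- diff(zs)
    if (!(all(dz > 0) || all(dz < 0))) {
      stop("z is not strictly monotone within segment '", seg, "'",
           call. = FALSE)
    }
  }
  if (!inherits(curve$metadata, "curve_metadata")) {
    stop("metadata must be a `curve_metadata` object", call. = FALSE)
  }
  invisible(curve)
}

#' Extract the retract segment
#'
#' @param curve An `fd_curve`.
#' @return Tibble with columns `z`, `force`, ordered by increasing `z`.
#' @export
retract <- function(curve) {
  dat <- curve$data[curve$data$segment == "retract", c("z", "force")]
  dat[order(dat$z), ]
}

# replace the retract force trace (z grid untouched), preserving attributes
replace_retract_force <- function(curve, force) {
  idx <- which(curve$data$segment == "retract")
  idx <- idx[order(curve$data$z[idx])]
  out <- curve
  out$data$force[idx] <- force
  out
}

#' @export
print.fd_curve <- function(x, ...) {
  segs <- table(x$data$segment)
  cat("<fd_curve> ", paste(sprintf("%s: %d", names(segs), segs),
                           collapse = ", "), " samples\n", sep = "")
  r <- retract(x)
  cat(sprintf("  z range: %.1f .. %.1f nm, force range: %.1f .. %.1f pN\n",
              min(r$z), max(r$z), min(r$force), max(r$force)))
  md <- x$metadata
  cat(sprintf("  k = %.3g pN/nm, condition = %s, index = %d",
              md$spring_constant, md$condition_label, md$curve_index))
  if (!is.na(md$true_class)) cat(", true_class =", md$true_class)
  cat("\n")
  invisible(x)
}

#' Convert photodetector deflection to force
#'
#' Applies the optical-lever calibration `F = k * s * d`: cantilever spring
#' constant k (pN/nm) times deflection sensitivity s (nm/V) times the
#' photodetector signal d (V). With the stiffer cantilever of the model
#' system (k = 180 pN/nm, s = 11.11 nm/V) the 0.25 V force trigger
#' corresponds to ~500 pN.
#'
#' @param deflection Deflection signal in V (vectorised).
#' @param spring_constant Cantilever stiffness in pN/nm, > 0.
#' @param sensitivity Deflection sensitivity in nm/V, > 0.
#' @return Force in pN.
#' @export
deflection_to_force <- function(deflection, spring_constant, sensitivity) {
  if (!is.numeric(spring_constant) || spring_constant <= 0) {
    stop("`spring_constant` must be > 0", call. = FALSE)
  }
  if (!is.numeric(sensitivity) || sensitivity <= 0) {
    stop("`sensitivity` must be > 0", call. = FALSE)
  }
  spring_constant * sensitivity * deflection
}

# metadata keys serialised to / parsed from the file header
.meta_keys <- c("spring_constant", "deflection_sensitivity",
                "forward_velocity", "backward_velocity", "contact_time",
                "condition_label", "curve_index", "true_class")

#' Read a force-distance curve from a columnar text file
#'
#' The file dialect is instrument-agnostic and diffable: '#'-prefixed
#' `key=value` header lines carry the metadata, followed by a TSV body with
#' a column header `segment`, `z_nm`, and either `force_pN` or
#' `deflection_V`. A deflection column is converted to force on read when
#' both the spring constant and the deflection sensitivity are present in
#' the header.
#'
#' @param path Path to the file.
#' @return A validated [fd_curve()].
#' @export
read_fd_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    eq <- regexpr("=", kv, fixed = TRUE)
    if (eq < 0) next
    key <- trimws(substr(kv, 1L, eq - 1L))
    val <- trimws(substr(kv, eq + 1L, nchar(kv)))
    num <- suppressWarnings(as.numeric(val))
    meta[[key]] <- if (is.na(num) || key %in% c("condition_label", "true_class"))
      val else num
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)]
  if (length(body) < 2L) stop("no data rows in ", path, call. = FALSE)
  tab <- read.delim(text = paste(body, collapse = "\n"),
                    sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("segment", "z_nm") %in% names(tab))) {
    stop("missing mandatory column(s) in ", path,
         ": need segment, z_nm and force_pN or deflection_V", call. = FALSE)
  }
  args <- meta[intersect(names(meta), .meta_keys)]
  if (!is.null(args$curve_index)) args$curve_index <- as.integer(args$curve_index)
  md <- do.call(curve_metadata, args)
  if ("force_pN" %in% names(tab)) {
    force <- as.numeric(tab$force_pN)
  } else if ("deflection_V" %in% names(tab)) {
    if (is.null(md$deflection_sensitivity)) {
      stop("deflection_V column requires deflection_sensitivity metadata",
           call. = FALSE)
    }
    force <- deflection_to_force(as.numeric(tab$deflection_V),
                                 md$spring_constant,
                                 md$deflection_sensitivity)
  } else {
    stop("missing mandatory column in ", path,
         ": need force_pN or deflection_V", call. = FALSE)
  }
  fd_curve(z = as.numeric(tab$z_nm), force = force,
           segment = tab$segment, metadata = md)
}

#' Write a force-distance curve to a columnar text file
#'
#' Inverse of [read_fd_table()]: '#'-prefixed `key=value` metadata header
#' then a TSV body with columns `segment`, `z_nm`, `force_pN`. Numeric
#' round-trip is exact to 1e-6 in both nm and pN.
#'
#' @param curve A valid [fd_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fd_table <- function(curve, path) {
  validate_fd_curve(curve)
  md <- curve$metadata
  hdr <- character(0)
  for (key in .meta_keys) {
    val <- md[[key]]
    if (is.null(val) || (length(val) == 1L && is.na(val))) next
    if (is.numeric(val)) val <- sprintf("%.10g", val)
    hdr <- c(hdr, sprintf("# %s=%s", key, val))
  }
  body <- sprintf("%s\t%.6f\t%.6f",
                  curve$data$segment, curve$data$z, curve$data$force)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(hdr, "segment\tz_nm\tforce_pN", body), con)
  invisible(path)
}

#' Write a batch manifest
#'
#' A batch is a directory of one-curve-per-file tables plus a manifest CSV
#' with columns `filename`, `curve_index`, `condition_label`, `true_class`
#' (empty for real data).
#'
#' @param manifest Data frame with those four columns.
#' @param dir Batch directory.
#' @return Path of the written `manifest.csv`, invisibly.
#' @export
write_manifest <- function(manifest, dir) {
  path <- file.path(dir, "manifest.csv")
  write.csv(manifest[, c("filename", "curve_index", "condition_label",
                         "true_class")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read a batch manifest
#' @param dir Batch directory containing `manifest.csv`.
#' @return Tibble with the manifest columns.
#' @export
read_manifest <- function(dir) {
  path <- file.path(dir, "manifest.csv")
  if (!file.exists(path)) stop("no manifest.csv in ", dir, call. = FALSE)
  tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                             colClasses = c(filename = "character",
                                            condition_label = "character",
                                            true_class = "character")))
}
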