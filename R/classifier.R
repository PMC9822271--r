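# Seven-way curve classification from (number of peaks, maximum adhesion
# force) plus quality flags.

#' Curve class codes and labels
#'
#' The seven curve groups: six interaction classes defined by the maximum
#' adhesion force and the number of peaks, plus an artifact class for
#' discarded curves.
#'
#' @return Named character vector mapping code (`Type1`..`Type7`) to label.
#' @export
class_labels <- function() {
  c(Type1 = "no interaction",
    Type2 = "non-specific",
    Type3 = "single interaction",
    Type4 = "multiple-independent",
    Type5 = "multiple-simultaneous",
    Type6 = "multiple-combined",
    Type7 = "artifact")
}

#' Class codes as a factor level set
#' @return Character vector `Type1`..`Type7`.
#' @export
class_codes <- function() names(class_labels())

#' Classifier configuration
#'
#' The three force thresholds partitioning the adhesion-force axis:
#' `f_nonspecific` (200 pN) is the upper limit of non-specific adhesion,
#' `f_high` (650 pN) the upper limit of a single biotin-streptavidin
#' unbinding event, and `f_veryhigh` (2000 pN) the ceiling for simultaneous
#' multi-bond detachment; anything beyond it is discarded as an artifact.
#' All upper limits are inclusive, so ties at a boundary are deterministic.
#'
#' @param f_nonspecific,f_high,f_veryhigh Band limits in pN, strictly
#'   increasing and positive.
#' @return A list of class `classifier_config`.
#' @export
classifier_config <- function(f_nonspecific = 200, f_high = 650,
                              f_veryhigh = 2000) {
  if (!(0 < f_nonspecific && f_nonspecific < f_high && f_high < f_veryhigh)) {
    stop("need 0 < f_nonspecific < f_high < f_veryhigh", call. = FALSE)
  }
  structure(list(f_nonspecific = f_nonspecific, f_high = f_high,
                 f_veryhigh = f_veryhigh),
            class = "classifier_config")
}

#' Is a curve an experimental artifact?
#'
#' A curve is discarded (Type7) when its maximum adhesion force exceeds
#' `f_veryhigh`, or any of the quality flags `saturated`, `overrange`,
#' `baseline-jump` or `no-contact` is set.
#'
#' @param features A `curve_features` object ([extract_features()]).
#' @param config A [classifier_config()].
#' @return Logical.
#' @export
is_artifact <- function(features, config = classifier_config()) {
  stopifnot(inherits(features, "curve_features"))
  features$f_max > config$f_veryhigh ||
    any(c("saturated", "overrange", "baseline-jump", "no-contact") %in%
          features$quality_flags)
}

#' Classify one curve
#'
#' Total, deterministic decision rule over the feature pair
#' `(n_events, f_max)`:
#' \itemize{
#'   \item artifact (see [is_artifact()]) -> `Type7`
#'   \item `n_events == 0` -> `Type1` (no interaction)
#'   \item `f_max <= f_nonspecific` -> `Type2` (non-specific, regardless of
#'     peak count)
#'   \item one event, `f_max <= f_high` -> `Type3` (single interaction)
#'   \item two or more events, `f_max <= f_high` -> `Type4`
#'     (multiple, independent detachment)
#'   \item one event, `f_high < f_max <= f_veryhigh` -> `Type5`
#'     (multiple, simultaneous detachment)
#'   \item two or more events, `f_high < f_max <= f_veryhigh` -> `Type6`
#'     (combined independent and simultaneous detachment)
#' }
#'
#' @param features A `curve_features` object.
#' @param config A [classifier_config()].
#' @return Factor of length 1 with levels `Type1`..`Type7`.
#' @export
classify_curve <- function(features, config = classifier_config()) {
  stopifnot(inherits(features, "curve_features"))
  n <- features$n_events
  f <- features$f_max
  if (is.na(n) || is.na(f) || n < 0 || f < 0 ||
      (n == 0 && f != 0) || (n > 0 && f <= 0)) {
    stop("invalid features: n_events = ", n, ", f_max = ", f, call. = FALSE)
  }
  code <-
    if (is_artifact(features, config)) "Type7"
    else if (n == 0L) "Type1"
    else if (f <= config$f_nonspecific) "Type2"
    else if (f <= config$f_high) { if (n == 1L) "Type3" else "Type4" }
    else if (f <= config$f_veryhigh) { if (n == 1L) "Type5" else "Type6" }
    else "Type7"  # unreachable: covered by is_artifact; kept for totality
  factor(code, levels = class_codes())
}

#' Run the full analysis chain on one curve
#'
#' Baseline fit and subtraction, contact-point alignment, optional
#' smoothing, event detection, feature extraction and classification.
#'
#' @param curve A raw `fd_curve`.
#' @param config A [classifier_config()].
#' @param params Detection/preprocessing parameters ([detection_params()]).
#' @return List with the aligned `curve`, its `features` and the `class`
#'   factor.
#' @export
analyze_curve <- function(curve, config = classifier_config(),
                          params = detection_params()) {
  corrected <- correct_curve(curve,
                             estimate_baseline(curve, params$baseline_fraction))
  aligned <- align_contact(corrected,
                           contact_threshold_sigma = params$contact_threshold_sigma)
  if (params$smooth_window > 1) {
    aligned <- smooth_force(aligned, params$smooth_window)
  }
  features <- extract_features(aligned, params = params)
  list(curve = aligned, features = features,
       class = classify_curve(features, config))
}

results_row <- function(curve, analysis) {
  md <- curve$metadata
  tibble::tibble(
    curve_index = md$curve_index,
    condition_label = md$condition_label,
    n_events = analysis$features$n_events,
    f_max = analysis$features$f_max,
    noise_floor = analysis$features$noise_floor,
    flags = paste(analysis$features$quality_flags, collapse = ";"),
    class = as.character(analysis$class),
    true_class = md$true_class
  )
}

#' Classify a list of in-memory curves
#'
#' @param curves List of `fd_curve` objects in temporal order.
#' @param config A [classifier_config()].
#' @param params Detection parameters ([detection_params()]).
#' @return Results tibble, one row per curve, in input order, with columns
#'   `curve_index`, `condition_label`, `n_events`, `f_max`, `noise_floor`,
#'   `flags`, `class`, `true_class`.
#' @export
classify_curves <- function(curves, config = classifier_config(),
                            params = detection_params()) {
  rows <- lapply(curves, function(cu) {
    results_row(cu, analyze_curve(cu, config, params))
  })
  do.call(rbind, rows)
}

#' Classify a batch directory
#'
#' Reads every curve listed in the batch manifest (see [write_manifest()]),
#' runs [analyze_curve()] on each, and returns one results row per curve in
#' temporal order. A curve file that cannot be read or analysed does not
#' stop the batch: its row carries `class = NA` and `flags = "read-error"`,
#' and the number of failures is attached as attribute `n_failed` (and
#' raised as a warning).
#'
#' @param dir Batch directory containing curve files and `manifest.csv`.
#' @param config A [classifier_config()].
#' @param params Detection parameters.
#' @return Results tibble as in [classify_curves()]; attribute `n_failed`
#'   counts unreadable curves.
#' @export
classify_batch <- function(dir, config = classifier_config(),
                           params = detection_params()) {
  manifest <- read_manifest(dir)
  if (nrow(manifest) == 0L) {
    warning("empty batch: no curves listed in manifest")
    out <- tibble::tibble(curve_index = integer(0),
                          condition_label = character(0),
                          n_events = integer(0), f_max = numeric(0),
                          noise_floor = numeric(0), flags = character(0),
                          class = character(0), true_class = character(0))
    attr(out, "n_failed") <- 0L
    return(out)
  }
  manifest <- manifest[order(manifest$curve_index), ]
  rows <- vector("list", nrow(manifest))
  n_failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    rows[[i]] <- tryCatch({
      cu <- read_fd_table(file.path(dir, m$filename))
      results_row(cu, analyze_curve(cu, config, params))
    }, error = function(e) {
      n_failed <<- n_failed + 1L
      tibble::tibble(curve_index = m$curve_index,
                     condition_label = m$condition_label,
                     n_events = NA_integer_, f_max = NA_real_,
                     noise_floor = NA_real_, flags = "read-error",
                     class = NA_character_,
                     true_class = m$true_class)
    })
  }
  out <- do.call(rbind, rows)
  if (n_failed > 0L) {
    warning(n_failed, " curve(s) could not be analysed", call. = FALSE)
  }
  attr(out, "n_failed") <- n_failed
  out
}
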