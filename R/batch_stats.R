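# Batch-level statistics: type frequencies, success rate, adhesion-force
# histogram, windowed temporal-drift profile, and an RMS roughness utility
# for probe topography maps.

#' Type distribution of a classified batch
#'
#' Counts and percentages per curve class over all curves of a results
#' table, artifacts included — the success rate is defined with respect to
#' the total number of curves recorded.
#'
#' @param results Results tibble from [classify_curves()] /
#'   [classify_batch()] (needs a `class` column).
#' @return A list of class `type_distribution` with `counts` and
#'   `percentages` (named over `Type1`..`Type7`) and `n_total`.
#' @export
type_distribution <- function(results) {
  if (is.null(results) || nrow(results) == 0L) {
    stop("empty results table", call. = FALSE)
  }
  cls <- factor(results$class, levels = class_codes())
  if (anyNA(cls)) stop("results contain unclassified curves", call. = FALSE)
  n <- nrow(results)
  counts <- stats::setNames(as.integer(table(cls)), class_codes())
  structure(
    list(counts = counts,
         percentages = 100 * counts / n,
         n_total = n),
    class = "type_distribution"
  )
}

#' @export
print.type_distribution <- function(x, ...) {
  cat("<type_distribution> n =", x$n_total, "\n")
  print(round(x$percentages, 2))
  invisible(x)
}

#' Success rate of a batch
#'
#' Fraction of curves showing at least one specific biotin-streptavidin
#' interaction — classes Type3, Type4, Type5 and Type6 — out of all curves
#' recorded (Type1, Type2 and Type7 count in the denominator).
#'
#' @param dist A [type_distribution()].
#' @return Fraction in \[0, 1\].
#' @export
success_rate <- function(dist) {
  stopifnot(inherits(dist, "type_distribution"))
  sum(dist$counts[c("Type3", "Type4", "Type5", "Type6")]) / dist$n_total
}

#' Adhesion-force histogram
#'
#' Bins the per-curve maximum adhesion forces into half-open bins
#' `[lo, hi)` of width `bin_width` starting at 0. The default 50 pN width
#' places the 200 and 650 pN class limits on bin edges. The bin range
#' covers at least \[0, 2100) and extends upward so every curve is counted:
#' bin counts always sum to the number of curves.
#'
#' @param results Results tibble (needs `f_max`).
#' @param bin_width Bin width in pN (> 0).
#' @return List of class `adhesion_histogram` with `breaks` (bin edges,
#'   length one more than `counts`), `counts`, and `bin_width`.
#' @export
adhesion_histogram <- function(results, bin_width = 50) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    stop("`bin_width` must be > 0", call. = FALSE)
  }
  f <- results$f_max
  if (anyNA(f)) stop("results contain NA adhesion forces", call. = FALSE)
  top <- max(2100, if (length(f)) bin_width * (floor(max(f) / bin_width) + 1))
  breaks <- seq(0, bin_width * ceiling(top / bin_width), by = bin_width)
  # half-open [lo, hi): findInterval with left-closed intervals
  bin <- findInterval(f, breaks, rightmost.closed = FALSE, left.open = FALSE)
  counts <- tabulate(bin, nbins = length(breaks) - 1L)
  structure(list(breaks = breaks, counts = counts, bin_width = bin_width),
            class = "adhesion_histogram")
}

#' Temporal drift profile
#'
#' Splits the temporally ordered batch into consecutive, non-overlapping
#' windows of `window_size` curves and reports, per window and class, the
#' difference between the window percentage of that class and its overall
#' percentage across the batch. With windows that partition the batch
#' evenly, the unweighted mean of the differences over windows is exactly
#' zero for every class; a trailing partial window is reported but flagged.
#'
#' @param results Results tibble in temporal order.
#' @param window_size Curves per window (default 50).
#' @return Tibble of class `drift_profile` with columns `window` (1-based
#'   index), `class`, `delta_pct` (percentage points) and `partial`
#'   (logical flag for a trailing incomplete window); attribute
#'   `window_size`.
#' @export
drift_profile <- function(results, window_size = 50) {
  n <- nrow(results)
  if (!is.numeric(window_size) || window_size < 1 || window_size > n) {
    stop("`window_size` must be between 1 and the number of curves",
         call. = FALSE)
  }
  cls <- factor(results$class, levels = class_codes())
  overall <- 100 * as.vector(table(cls)) / n
  win <- ceiling(seq_len(n) / window_size)
  nwin <- max(win)
  rows <- lapply(seq_len(nwin), function(w) {
    in_w <- win == w
    pct <- 100 * as.vector(table(cls[in_w])) / sum(in_w)
    tibble::tibble(window = w, class = class_codes(),
                   delta_pct = pct - overall,
                   partial = sum(in_w) < window_size)
  })
  out <- do.call(rbind, rows)
  attr(out, "window_size") <- window_size
  class(out) <- c("drift_profile", class(out))
  out
}

#' RMS roughness of a height map
#'
#' Root-mean-square deviation of a 2-D topography grid about its mean
#' height, or about the best-fit plane when `plane_correct = TRUE`
#' (removes sample tilt before quantifying roughness).
#'
#' @param heightmap Numeric matrix of heights in nm, at least 2 x 2, all
#'   finite.
#' @param plane_correct Subtract the least-squares plane first.
#' @return RMS roughness in nm.
#' @export
rms_roughness <- function(heightmap, plane_correct = FALSE) {
  if (!is.matrix(heightmap) || nrow(heightmap) < 2L || ncol(heightmap) < 2L) {
    stop("`heightmap` must be a matrix of at least 2 x 2", call. = FALSE)
  }
  if (!all(is.finite(heightmap))) {
    stop("`heightmap` contains non-finite values", call. = FALSE)
  }
  h <- as.vector(heightmap)
  if (plane_correct) {
    x <- as.vector(row(heightmap))
    y <- as.vector(col(heightmap))
    resid <- h - stats::fitted(lm(h ~ x + y))
    sqrt(mean(resid^2))
  } else {
    sqrt(mean((h - mean(h))^2))
  }
}

#' Read a height map from disk
#'
#' Plain-text whitespace-separated matrices, or single-channel TIFF images
#' (via the tiff package) with an optional height scale factor.
#'
#' @param path File path (`.tif`/`.tiff` or text).
#' @param scale Multiplier applied to TIFF intensities to obtain nm.
#' @return Numeric matrix of heights in nm.
#' @export
read_heightmap <- function(path, scale = 1) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("reading TIFF height maps requires the 'tiff' package",
           call. = FALSE)
    }
    img <- tiff::readTIFF(path)
    if (length(dim(img)) == 3L) img <- img[, , 1L]
    img * scale
  } else {
    as.matrix(read.table(path))
  }
}

#' Batch report
#'
#' Bundles the batch statistics into one list, serialisable to JSON:
#' total count, per-class counts and percentages, success rate,
#' adhesion-force histogram and drift profile.
#'
#' @param results Results tibble.
#' @param window_size Drift window (curves).
#' @param bin_width Histogram bin width (pN).
#' @return Nested list ready for [jsonlite::write_json()].
#' @export
batch_report <- function(results, window_size = 50, bin_width = 50) {
  dist <- type_distribution(results)
  hist <- adhesion_histogram(results, bin_width)
  drift <- drift_profile(results, window_size)
  list(
    n_total = dist$n_total,
    counts = as.list(dist$counts),
    percentages = as.list(dist$percentages),
    success_rate = success_rate(dist),
    histogram = list(breaks = hist$breaks, counts = hist$counts),
    drift = lapply(split(drift, drift$window), function(d) {
      list(window = d$window[1L], partial = d$partial[1L],
           delta_pct = as.list(stats::setNames(d$delta_pct, d$class)))
    })
  )
}
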