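#' Default FTIR region map
#'
#' The conventional whole-cell fingerprint windows: fatty acids
#' W1 = \[3200, 2800), amides W2 = \[1800, 1500), mixed W3 = \[1500, 1200),
#' carbohydrates W4 = \[1200, 900) cm^-1, plus the 2100-1900 cm^-1 quality
#' window. Intervals are half-open on the low-wavenumber side: a wavenumber
#' `w` belongs to `c(high, low)` when `low < w <= high`.
#'
#' @return Named list of `c(high, low)` intervals.
#' @export
default_region_map <- function() {
  list(
    W1 = c(3200, 2800),
    W2 = c(1800, 1500),
    W3 = c(1500, 1200),
    W4 = c(1200, 900),
    quality = c(2100, 1900)
  )
}

resolve_region <- function(region, region_map = default_region_map()) {
  if (is.character(region)) {
    if (!region %in% names(region_map)) {
      abort(sprintf("Unknown region '%s' (have: %s).",
                    region, paste(names(region_map), collapse = ", ")))
    }
    region <- region_map[[region]]
  }
  region <- as.numeric(region)
  if (length(region) != 2) abort("A region is a c(high, low) interval.")
  sort(region, decreasing = TRUE)
}

region_columns <- function(wavenumber, interval) {
  which(wavenumber > interval[2] & wavenumber <= interval[1])
}

#' Signal-to-noise quality test
#'
#' Signal is the full-spectrum absorbance amplitude (max - min); noise is
#' the RMS of residuals after a linear detrend of the quality window
#' (2100-1900 cm^-1 by default, where whole-cell spectra are featureless).
#' This is a documented surrogate for the instrument software's proprietary
#' quality test; spectra pass when SNR exceeds `threshold` (4000 by
#' default). A zero-amplitude spectrum scores 0 (fail); a noise-free one
#' scores `Inf` (pass).
#'
#' @param set A `spectrum_set`.
#' @param quality_interval `c(high, low)` wavenumber window with >= 8 axis
#'   points.
#' @param threshold Pass threshold.
#' @return Tibble: sample_id, snr, pass.
#' @export
quality_snr <- function(set, quality_interval = c(2100, 1900), threshold = 4000) {
  stopifnot(inherits(set, "spectrum_set"))
  interval <- resolve_region(quality_interval)
  cols <- region_columns(set$wavenumber, interval)
  if (length(cols) < 8) {
    abort(sprintf("Quality interval [%g, %g] contains %d axis points (< 8).",
                  interval[1], interval[2], length(cols)))
  }
  x <- set$wavenumber[cols]
  snr <- apply(set$absorbance, 1, function(y) {
    signal <- max(y) - min(y)
    if (signal == 0) return(0)
    res <- residuals(lm(y[cols] ~ x))
    noise <- sqrt(mean(res^2))
    if (noise == 0) Inf else signal / noise
  })
  tibble::tibble(sample_id = set$meta$sample_id, snr = unname(snr),
                 pass = snr > threshold)
}

# lower convex hull (Andrew monotone chain) of points sorted by increasing x;
# returns indices of hull vertices
lower_hull_idx <- function(x, y) {
  n <- length(x)
  hull <- integer(0)
  for (i in seq_len(n)) {
    while (length(hull) >= 2) {
      k <- length(hull)
      o <- hull[k - 1]; a <- hull[k]
      cross <- (x[a] - x[o]) * (y[i] - y[o]) - (y[a] - y[o]) * (x[i] - x[o])
      if (cross <= 0) hull <- hull[-k] else break
    }
    hull <- c(hull, i)
  }
  hull
}

#' Rubberband baseline correction
#'
#' The classic "rubberband" of FTIR preprocessing: the baseline under each
#' spectrum is the piecewise-linear lower convex hull, anchored on
#' `n_points` equally spaced support abscissae (64 by default, the
#' instrument convention) and linearly interpolated back to the full axis;
#' the corrected spectrum is the original minus this baseline. Endpoints of
#' the corrected spectrum are 0 and hull points are non-negative up to
#' rounding.
#'
#' @param set A `spectrum_set`.
#' @param n_points Number of support abscissae (>= 2).
#' @return A `spectrum_set` of corrected spectra.
#' @export
rubberband_baseline <- function(set, n_points = 64) {
  stopifnot(inherits(set, "spectrum_set"))
  if (n_points < 2) abort("`n_points` must be >= 2.")
  # hull geometry on an increasing axis
  ord <- order(set$wavenumber)
  x <- set$wavenumber[ord]
  grid <- seq(x[1], x[length(x)], length.out = n_points)
  corrected <- t(apply(set$absorbance, 1, function(y_full) {
    y <- y_full[ord]
    h <- lower_hull_idx(x, y)
    anchors <- approx(x[h], y[h], xout = grid, rule = 2)$y
    baseline <- approx(grid, anchors, xout = x, rule = 2)$y
    out <- y - baseline
    out[order(ord)]
  }))
  spectrum_set(set$wavenumber, corrected, set$meta)
}

#' Vector normalization
#'
#' Subtracts each spectrum's mean, then scales to unit sum of squares (the
#' OPUS dialect), removing path-length and biomass effects. Scaling the
#' input by any positive factor leaves the output unchanged.
#'
#' @param set A `spectrum_set`; no spectrum may be constant.
#' @return A `spectrum_set` of normalized spectra.
#' @export
vector_normalize <- function(set) {
  stopifnot(inherits(set, "spectrum_set"))
  normalized <- t(apply(set$absorbance, 1, function(y) {
    y <- y - mean(y)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) abort("Cannot vector-normalize a constant spectrum.")
    y / nrm
  }))
  spectrum_set(set$wavenumber, normalized, set$meta)
}

#' Restrict spectra to a named region
#'
#' @param set A `spectrum_set`.
#' @param region Region name in `region_map` or a `c(high, low)` interval.
#' @param region_map Named list of intervals; see [default_region_map()].
#' @return A `spectrum_set` on the restricted axis; metadata preserved.
#' @export
extract_region <- function(set, region, region_map = default_region_map()) {
  stopifnot(inherits(set, "spectrum_set"))
  interval <- resolve_region(region, region_map)
  cols <- region_columns(set$wavenumber, interval)
  if (length(cols) == 0) {
    abort(sprintf("Region [%g, %g] does not intersect the axis.",
                  interval[1], interval[2]))
  }
  spectrum_set(set$wavenumber[cols], set$absorbance[, cols, drop = FALSE],
               set$meta)
}

#' Concatenate several regions into one spectrum set
#'
#' Used for whole-profile clustering on the informative fingerprint windows
#' (e.g. fatty acids plus the amide/mixed block), skipping the water and
#' silent regions.
#'
#' @inheritParams extract_region
#' @param regions Character vector of region names (or list of intervals).
#' @return A `spectrum_set` restricted to the union of the regions
#'   (columns kept in axis order).
#' @export
extract_regions <- function(set, regions, region_map = default_region_map()) {
  cols <- sort(unique(unlist(lapply(regions, function(r) {
    region_columns(set$wavenumber, resolve_region(r, region_map))
  }))))
  if (length(cols) == 0) abort("Regions do not intersect the axis.")
  spectrum_set(set$wavenumber[cols], set$absorbance[, cols, drop = FALSE],
               set$meta, uniform = FALSE)
}

#' Average replicate spectra
#'
#' One mean spectrum per metadata group; the new sample ids join the group
#' values and `n_averaged` records the group size.
#'
#' @param set A `spectrum_set`.
#' @param by Metadata columns to group by.
#' @return A `spectrum_set` of group means.
#' @export
average_replicates <- function(set, by = c("strain", "condition")) {
  stopifnot(inherits(set, "spectrum_set"))
  if (!all(by %in% names(set$meta))) abort("Unknown grouping column(s).")
  key <- do.call(paste, c(set$meta[by], sep = "_"))
  groups <- split(seq_len(nrow(set$absorbance)), factor(key, levels = unique(key)))
  means <- t(vapply(groups, function(idx) {
    colMeans(set$absorbance[idx, , drop = FALSE])
  }, numeric(length(set$wavenumber))))
  first <- vapply(groups, `[`, integer(1), 1)
  meta <- set$meta[first, c("sample_id", "strain", "condition", "replicate")]
  meta$sample_id <- names(groups)
  if (!"strain" %in% by) meta$strain <- NA_character_
  if (!"condition" %in% by) meta$condition <- NA_real_
  meta$replicate <- NA_integer_
  meta$n_averaged <- lengths(groups)
  spectrum_set(set$wavenumber, means, meta)
}

#' Zero out masked wavenumber intervals
#'
#' Optional stand-in for atmospheric compensation: gives zero weight to the
#' CO2 band and water-vapor line intervals.
#'
#' @param set A `spectrum_set`.
#' @param intervals List of `c(high, low)` intervals.
#' @return A `spectrum_set` with the masked columns set to 0.
#' @export
mask_intervals <- function(set, intervals = list(c(2400, 2300))) {
  stopifnot(inherits(set, "spectrum_set"))
  a <- set$absorbance
  for (iv in intervals) {
    cols <- region_columns(set$wavenumber, resolve_region(iv))
    a[, cols] <- 0
  }
  spectrum_set(set$wavenumber, a, set$meta)
}
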