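#' Per-strain profiles by replicate aggregation
#'
#' Collapses a spectrum set or feature table to one profile per strain,
#' optionally restricted to a subset of conditions first (pooling them).
#' Aggregation is the arithmetic mean by default; median is available.
#'
#' @param data A `spectrum_set` or `feature_table`.
#' @param conditions Conditions to keep (default: all, pooled together).
#' @param aggregate `"mean"` or `"median"`.
#' @return Numeric matrix, one row per strain.
#' @export
strain_profiles <- function(data, conditions = NULL,
                            aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  if (inherits(data, "spectrum_set")) {
    m <- data$absorbance; meta <- data$meta
  } else if (inherits(data, "feature_table")) {
    m <- intensity_matrix(data); meta <- data[ft_meta_cols]
  } else {
    abort("`data` must be a spectrum_set or feature_table.")
  }
  if (!is.null(conditions)) {
    keep <- meta$condition %in% conditions
    if (!any(keep)) abort("No samples in the requested condition(s).")
    m <- m[keep, , drop = FALSE]; meta <- meta[keep, ]
  }
  f <- if (aggregate == "mean") colMeans else function(x) apply(x, 2, median)
  groups <- split(seq_len(nrow(m)), meta$strain)
  out <- t(vapply(groups, function(idx) f(m[idx, , drop = FALSE]),
                  numeric(ncol(m))))
  out
}

# |x_i - x_j| for all strain pairs (sorted labels) x all descriptors
pair_abs_diff <- function(profiles) {
  labs <- sort(rownames(profiles))
  profiles <- profiles[labs, , drop = FALSE]
  pairs <- combn(length(labs), 2)
  P <- abs(profiles[pairs[1, ], , drop = FALSE] -
             profiles[pairs[2, ], , drop = FALSE])
  rownames(P) <- paste(labs[pairs[1, ]], labs[pairs[2, ]], sep = "|")
  P
}

# vectorized per-descriptor correlation of |dx| pair vectors with a genetic
# lower triangle; constant descriptors are recorded as r = 0 (kept in the
# PSW denominator so denominators stay comparable across conditions)
scan_r <- function(profiles, genetic_d) {
  labs <- sort(rownames(profiles))
  if (!setequal(labs, rownames(genetic_d))) {
    abort(sprintf(
      "Strain labels differ from genetic matrix (profiles: %s; genetic: %s).",
      paste(labs, collapse = ","), paste(sort(rownames(genetic_d)), collapse = ",")
    ))
  }
  if (length(labs) < 3) abort("Descriptor scan needs >= 3 strains.")
  g <- lower_triangle(genetic_d, labs)
  P <- pair_abs_diff(profiles)
  r <- suppressWarnings(as.vector(cor(P, g)))
  constant <- !is.finite(r)
  r[constant] <- 0
  list(r = r, g = g, P = P, constant = constant, labs = labs)
}

#' Per-descriptor correlation scan
#'
#' The core single-descriptor procedure: for every descriptor (one
#' wavenumber or one metabolite), strain distances are the absolute
#' differences of the replicate-averaged per-strain values (1-D Euclidean),
#' and these are Pearson-correlated with the genetic distance matrix. The
#' scan runs separately within each condition. Constant descriptors get
#' r = 0 and stay in the denominator of any downstream percentage.
#'
#' Permutation p-values (exhaustive over label permutations for small strain
#' counts) accompany each r; the parametric alternative is reported via
#' [matrix_correlation()] semantics.
#'
#' @param data A `spectrum_set` or `feature_table`.
#' @param genetic_d Labeled genetic distance matrix over the strains.
#' @param aggregate Replicate aggregation, `"mean"` (default) or `"median"`.
#' @param p_method `"permutation"` (default), `"parametric_t"`, or `"none"`
#'   to skip p-values.
#' @param n_perm,seed Passed to the permutation test when sampling is
#'   needed.
#' @return Tibble: condition, descriptor (numeric wavenumber or metabolite
#'   name), r, p_value, constant.
#' @export
descriptor_scan <- function(data, genetic_d,
                            aggregate = c("mean", "median"),
                            p_method = c("permutation", "parametric_t", "none"),
                            n_perm = 9999, seed = 1L) {
  aggregate <- match.arg(aggregate)
  p_method <- match.arg(p_method)
  genetic_d <- as_distance_matrix(genetic_d)
  meta <- if (inherits(data, "spectrum_set")) data$meta else data[ft_meta_cols]
  descriptors <- if (inherits(data, "spectrum_set")) {
    data$wavenumber
  } else {
    metabolite_names(data)
  }
  conds <- sort(unique(meta$condition))
  purrr::map_dfr(conds, function(cc) {
    profiles <- strain_profiles(data, conditions = cc, aggregate = aggregate)
    sr <- scan_r(profiles, genetic_d)
    p <- rep(NA_real_, length(sr$r))
    if (p_method != "none") {
      n <- length(sr$labs)
      if (p_method == "parametric_t") {
        m <- length(sr$g)
        r2 <- pmin(sr$r^2, 1 - 1e-15)
        t_stat <- sr$r * sqrt(m - 2) / sqrt(1 - r2)
        p <- 2 * pt(-abs(t_stat), df = m - 2)
      } else if (factorial(n) <= n_perm) {
        Pm <- all_permutations(n)
        gd <- genetic_d[sr$labs, sr$labs]
        g_perm <- apply(Pm, 1, function(idx) lower_triangle(gd[idx, idx]))
        r_perm <- suppressWarnings(cor(sr$P, g_perm)) # n_desc x n!
        r_perm[!is.finite(r_perm)] <- 0
        p <- rowMeans(abs(r_perm) >= abs(sr$r) - 1e-12)
      } else {
        gd <- genetic_d[sr$labs, sr$labs]
        g_perm <- with_seed(seed, {
          vapply(seq_len(n_perm), function(i) {
            idx <- sample.int(n)
            lower_triangle(gd[idx, idx])
          }, numeric(length(sr$g)))
        })
        r_perm <- suppressWarnings(cor(sr$P, g_perm))
        r_perm[!is.finite(r_perm)] <- 0
        p <- (1 + rowSums(abs(r_perm) >= abs(sr$r) - 1e-12)) / (1 + n_perm)
      }
      p[sr$constant] <- 1
    }
    tibble::tibble(
      condition = cc, descriptor = descriptors,
      r = unname(sr$r), p_value = unname(p), constant = unname(sr$constant)
    )
  })
}

#' Percentage of significative wavelengths (PSW)
#'
#' The fraction (x100) of descriptors whose scan correlation exceeds the
#' threshold (strictly), 0.75 by default. All scanned descriptors — including
#' constant ones, recorded as r = 0 — count in the denominator.
#'
#' @param scan Numeric r vector, or a [descriptor_scan()] tibble (grouped by
#'   condition, and by marker if present).
#' @param threshold Correlation threshold.
#' @return A percentage in \[0, 100\], or a tibble of them.
#' @export
#' @examples
#' psw(c(0.8, 0.5, 0.9, 0.2)) # 50
psw <- function(scan, threshold = 0.75) {
  if (is.numeric(scan)) {
    if (length(scan) == 0) abort("Empty scan.")
    return(100 * mean(scan > threshold))
  }
  if (!is.data.frame(scan) || !"r" %in% names(scan)) {
    abort("`scan` must be an r vector or a descriptor_scan tibble.")
  }
  if (nrow(scan) == 0) abort("Empty scan.")
  keys <- intersect(c("marker", "condition"), names(scan))
  scan |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(psw = 100 * mean(.data$r > threshold), .groups = "drop")
}

#' Classify a PSW trend over increasing ethanol conditions
#'
#' Trend typology of the stress response: `non_monotonous` when the maximum
#' PSW sits at an interior condition (rise then fall); otherwise `high` when
#' the maximum reaches at least `split` percent, else `low`. The default
#' split of 5 sits between the observed low-response maxima (2-4%) and
#' high-response maxima (6-32%).
#'
#' @param psw_by_condition PSW values ordered by increasing condition
#'   (>= 3).
#' @param split Low/high boundary in PSW percent.
#' @return `"low"`, `"high"` or `"non_monotonous"`.
#' @export
#' @examples
#' classify_trend(c(0, 0, 1.67, 2.44)) # low
classify_trend <- function(psw_by_condition, split = 5.0) {
  x <- as.numeric(psw_by_condition)
  if (length(x) < 3) abort("Trend classification needs >= 3 conditions.")
  if (any(x < 0 | x > 100)) abort("PSW values must lie in [0, 100].")
  i <- which.max(x)
  if (i != 1 && i != length(x)) return("non_monotonous")
  if (max(x) >= split) "high" else "low"
}

#' PSW trends for a panel of markers
#'
#' Runs the per-descriptor scan for each marker distance matrix, computes
#' PSW per condition and classifies each marker's trend.
#'
#' @param data A `spectrum_set` or `feature_table`.
#' @param genetic_ds Named list of genetic distance matrices, one per
#'   marker.
#' @param threshold PSW correlation threshold.
#' @param split Trend split; see [classify_trend()].
#' @inheritParams descriptor_scan
#' @return List with `scan` (tibble marker, condition, descriptor, r,
#'   p_value) and `trends` (tibble marker, condition, psw, trend_class).
#' @export
psw_trends <- function(data, genetic_ds, threshold = 0.75, split = 5.0,
                       aggregate = "mean", p_method = "none") {
  if (is.null(names(genetic_ds))) abort("`genetic_ds` must be a named list.")
  scan <- purrr::imap_dfr(genetic_ds, function(d, marker) {
    dplyr::mutate(
      descriptor_scan(data, d, aggregate = aggregate, p_method = p_method),
      marker = marker, .before = 1
    )
  })
  trends <- psw(scan, threshold) |>
    dplyr::arrange(.data$marker, .data$condition) |>
    dplyr::group_by(.data$marker) |>
    dplyr::mutate(trend_class = classify_trend(.data$psw, split)) |>
    dplyr::ungroup()
  list(scan = scan, trends = trends)
}

#' Plot PSW trends by marker
#'
#' @param trends The `trends` tibble from [psw_trends()].
#' @return A ggplot.
#' @export
plot_psw_trends <- function(trends) {
  ggplot2::ggplot(trends, ggplot2::aes(
    x = .data$condition, y = .data$psw,
    colour = .data$marker, group = .data$marker
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~trend_class) +
    ggplot2::labs(x = "ethanol (% v/v)", y = "PSW (%)")
}

#' Region-wise maximum scan correlation, control vs. stressed
#'
#' For each marker and each spectral region, the maximum per-wavelength scan
#' correlation, computed separately for the control group (lowest condition)
#' and the stressed group (all other conditions pooled; replicates and
#' conditions averaged per strain before scanning).
#'
#' @param spectra A preprocessed `spectrum_set`.
#' @param genetic_ds Named list of marker distance matrices.
#' @param region_map Named region intervals (the `quality` entry is
#'   ignored).
#' @param threshold Significance flag threshold.
#' @param aggregate Replicate aggregation.
#' @return Tibble: marker, region, group, max_r, significant.
#' @export
region_max_correlation <- function(spectra, genetic_ds,
                                   region_map = default_region_map(),
                                   threshold = 0.75, aggregate = "mean") {
  stopifnot(inherits(spectra, "spectrum_set"))
  if (is.null(names(genetic_ds))) abort("`genetic_ds` must be a named list.")
  regions <- region_map[setdiff(names(region_map), "quality")]
  conds <- sort(unique(spectra$meta$condition))
  if (length(conds) < 2) abort("Need a control and at least one stressed condition.")
  groups <- list(
    control = strain_profiles(spectra, conditions = conds[1], aggregate = aggregate),
    stressed = strain_profiles(spectra, conditions = conds[-1], aggregate = aggregate)
  )
  purrr::imap_dfr(genetic_ds, function(d, marker) {
    purrr::imap_dfr(groups, function(profiles, group) {
      sr <- scan_r(profiles, as_distance_matrix(d))
      purrr::imap_dfr(regions, function(interval, region) {
        cols <- region_columns(spectra$wavenumber, resolve_region(interval))
        if (length(cols) == 0) {
          abort(sprintf("Region %s is empty on this axis.", region))
        }
        tibble::tibble(marker = marker, region = region, group = group,
                       max_r = max(sr$r[cols]))
      })
    })
  }) |>
    dplyr::mutate(significant = .data$max_r > threshold)
}
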