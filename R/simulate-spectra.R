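#' Simulate an FTIR spectrum set for a scenario
#'
#' Emulates a whole-cell transmission FTIR batch on the standard
#' 4000-400 cm^-1 axis at 4 cm^-1 resolution (901 points). Each sample is
#' the sum of
#' * a smooth random baseline (degree <= 3 polynomial, coefficients
#'   `N(0, baseline_sd)`), emulating scatter baselines removable by the
#'   rubberband method,
#' * the planted signals: for each [planted_signal()], at condition `c`,
#'   the chosen wavelengths inside the target region gain
#'   `amplitude_per_condition[c] * score(strain)` where the scores are the
#'   1-D embedding of the source locus' tree distances ([strain_scores()]),
#' * i.i.d. Gaussian noise with `sd = noise_sd`.
#'
#' Planted wavelength positions are drawn once per signal (seeded), so they
#' are identical across samples. The whole set is deterministic in the
#' scenario seed.
#'
#' @inheritParams locus_trees
#' @param region_map Region map used to resolve planted-region names.
#' @return A `spectrum_set` with
#'   `strains x conditions x n_replicates` spectra; the planted wavenumbers
#'   are recorded in `attr(, "planted_wavenumbers")`.
#' @export
simulate_spectra <- function(scenario, region_map = default_region_map()) {
  stopifnot(inherits(scenario, "scenario_config"))
  wn <- seq(4000, 400, by = -4)
  strains <- scenario$tree$tip.label
  meta <- tidyr::expand_grid(
    strain = strains,
    condition = scenario$conditions,
    replicate = seq_len(scenario$n_replicates)
  ) |>
    dplyr::mutate(sample_id = paste(.data$strain, .data$condition,
                                    .data$replicate, sep = "_"),
                  .before = 1)

  # planted wavelength positions and strain scores, fixed across samples
  planted <- purrr::imap(scenario$planted_signals, function(ps, k) {
    interval <- resolve_region(ps$region, region_map)
    cols <- region_columns(wn, interval)
    if (length(cols) == 0) {
      abort(sprintf("Planted region [%g, %g] lies outside the axis.",
                    interval[1], interval[2]))
    }
    if (ps$n_wavelengths > length(cols)) {
      abort(sprintf("Planted signal wants %d wavelengths but region has %d.",
                    ps$n_wavelengths, length(cols)))
    }
    idx <- with_seed(
      child_seed(scenario$seed, paste0("plant::", k)),
      sort(sample(cols, ps$n_wavelengths))
    )
    scores <- strain_scores(locus_true_distances(scenario, ps$source_locus))
    list(idx = idx, scores = scores, amps = ps$amplitude_per_condition)
  })

  absorbance <- with_seed(child_seed(scenario$seed, "spectra"), {
    t(vapply(seq_len(nrow(meta)), function(i) {
      y <- numeric(length(wn))
      if (scenario$baseline_sd > 0) {
        cf <- rnorm(4, 0, scenario$baseline_sd)
        tt <- seq(0, 1, length.out = length(wn))
        y <- y + cf[1] + cf[2] * tt + cf[3] * tt^2 + cf[4] * tt^3
      }
      ci <- match(meta$condition[i], scenario$conditions)
      for (pl in planted) {
        y[pl$idx] <- y[pl$idx] + pl$amps[ci] * pl$scores[[meta$strain[i]]]
      }
      if (scenario$noise_sd > 0) y <- y + rnorm(length(wn), 0, scenario$noise_sd)
      y
    }, numeric(length(wn))))
  })

  out <- spectrum_set(wn, absorbance, meta)
  attr(out, "planted_wavenumbers") <- lapply(planted, function(pl) wn[pl$idx])
  out
}
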