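#' Default mortality profile for the four-strain scenario
#'
#' Strain x condition mortality percentages shaped like the published
#' ethanol dose response of the *sensu stricto* type strains: one sensitive
#' strain saturating by 12% ethanol, one tolerant strain and two
#' intermediates.
#'
#' @inheritParams locus_trees
#' @return Tibble: strain, condition, mortality (%).
#' @export
default_mortality_profile <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  strains <- scenario$tree$tip.label
  conds <- scenario$conditions
  base <- rbind(
    c(0, 40.6, 97.2, 100.0),
    c(0, 12.3, 12.5, 13.3),
    c(0, 0.0, 10.8, 20.3),
    c(0, 0.0, 3.7, 9.7)
  )
  profile <- matrix(0, length(strains), length(conds))
  for (i in seq_along(strains)) {
    row <- base[(i - 1) %% nrow(base) + 1, ]
    profile[i, ] <- approx(seq_along(row), row,
                           xout = seq(1, nrow(base), length.out = length(conds)))$y
  }
  tibble::tibble(
    strain = rep(strains, each = length(conds)),
    condition = rep(conds, length(strains)),
    mortality = as.vector(t(profile))
  )
}

#' Simulate plate-count viability records
#'
#' For each strain x condition, the control count `Ct` is fixed and the
#' treated viable count is `Cv ~ Poisson(Ct * (1 - M/100))` (plate-count
#' noise). The control (lowest) condition always has `M = 0`. Deterministic
#' in the scenario seed.
#'
#' @inheritParams locus_trees
#' @param mortality_profile Data frame `strain`, `condition`, `mortality`
#'   (% in \[0, 100\]); defaults to [default_mortality_profile()].
#' @param Ct Control viable count (> 0).
#' @return Tibble: strain, condition, Cv, Ct.
#' @export
simulate_viability <- function(scenario,
                               mortality_profile = default_mortality_profile(scenario),
                               Ct = 1e6) {
  stopifnot(inherits(scenario, "scenario_config"))
  mp <- tibble::as_tibble(mortality_profile)
  need <- c("strain", "condition", "mortality")
  if (!all(need %in% names(mp))) {
    abort("`mortality_profile` needs columns strain, condition, mortality.")
  }
  if (any(mp$mortality < 0 | mp$mortality > 100)) {
    abort("Mortality values must lie in [0, 100].")
  }
  if (Ct <= 0) abort("`Ct` must be > 0.")
  mp$mortality[mp$condition == min(scenario$conditions)] <- 0
  with_seed(child_seed(scenario$seed, "viability"), {
    mp |>
      dplyr::mutate(
        Cv = rpois(dplyr::n(), Ct * (1 - .data$mortality / 100)),
        Ct = Ct
      ) |>
      dplyr::select("strain", "condition", "Cv", "Ct")
  })
}
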