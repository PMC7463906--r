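#' Simulate an annotated LC-MS feature table
#'
#' Emulates the entry point of the metabolomics branch: a samples x
#' metabolites table of positive intensities with per-sample strain,
#' condition and replicate metadata. Intensities are log-normal around
#' metabolite-specific baselines; a seeded subset of `n_affected`
#' metabolites carries strain effects proportional to the source locus'
#' genetic distances, amplified with the ethanol dose:
#'
#' `log I = mu_m + effect_size * (beta_m . e(strain)) * (1 + dose_scale * cond/max(cond)) + N(0, rep_sd)`
#'
#' where `e(strain)` is the full principal-coordinate embedding of the
#' locus distance matrix (scaled to unit mean pairwise distance) and each
#' affected metabolite gets a direction `beta_m` in that space. Directions
#' are drawn as blocks of random orthonormal frames (equal magnitudes,
#' jointly whitened), so the planted between-strain log-profile distances
#' reproduce the embedded locus distances exactly rather than only on
#' average. With `effect_size = 0` the table is exchangeable across strains
#' (a null table). Deterministic in the scenario seed.
#'
#' By default (`basis = "realized"`) the driving distances are estimated
#' from the locus' simulated alignment — the metabolome responds to the
#' strains' actual genotypes, divergence sampling noise included.
#' `basis = "expected"` uses the gene-tree path distances instead, useful
#' for analytic constructions.
#'
#' @inheritParams locus_trees
#' @param n_metabolites Number of metabolite columns (>= 2); the study scale
#'   is 89 annotated metabolites.
#' @param source_locus Locus driving the strain effect; defaults to the
#'   first planted signal's locus, else the first locus.
#' @param n_affected Number of strain-responsive metabolites.
#' @param effect_size Strain effect multiplier on the log scale.
#' @param dose_scale Relative amplification of the strain effect at the
#'   highest ethanol condition.
#' @param rep_sd Replicate log-scale noise.
#' @param basis `"realized"` (distances estimated from the simulated
#'   alignment; default) or `"expected"` (gene-tree path distances).
#' @param baseline_meanlog_sd Spread of metabolite baseline abundances on
#'   the log scale.
#' @param n_replicates Replicates per strain x condition; defaults to 5 (the
#'   usual LC-MS design, against 3 independent readings for FTIR), not the
#'   scenario-wide replicate count.
#' @return A `feature_table` tibble (state `"raw"`): metadata columns
#'   `sample_id`, `strain`, `condition`, `replicate` then one column per
#'   metabolite (`met001`, ...).
#' @export
simulate_feature_table <- function(scenario, n_metabolites = 89,
                                   source_locus = NULL,
                                   n_affected = max(2L, round(0.4 * n_metabolites)),
                                   effect_size = 1.5,
                                   dose_scale = 1,
                                   rep_sd = 0.05,
                                   basis = c("realized", "expected"),
                                   baseline_meanlog_sd = 0.5,
                                   n_replicates = 5) {
  basis <- match.arg(basis)
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  stopifnot(inherits(scenario, "scenario_config"))
  if (n_metabolites < 2) abort("`n_metabolites` must be >= 2.")
  if (is.null(source_locus)) {
    source_locus <- if (length(scenario$planted_signals)) {
      scenario$planted_signals[[1]]$source_locus
    } else {
      scenario$locus_specs$locus[1]
    }
  }
  d_src <- if (basis == "expected") {
    locus_true_distances(scenario, source_locus)
  } else {
    evolutionary_distance(simulate_locus_alignment(scenario, source_locus))
  }
  emb <- strain_embedding(d_src)
  strains <- scenario$tree$tip.label
  meta <- tidyr::expand_grid(
    strain = strains,
    condition = scenario$conditions,
    replicate = seq_len(n_replicates)
  ) |>
    dplyr::mutate(sample_id = paste(.data$strain, .data$condition,
                                    .data$replicate, sep = "_"),
                  .before = 1)
  met_names <- sprintf("met%03d", seq_len(n_metabolites))
  max_cond <- max(scenario$conditions)
  dose_w <- if (max_cond > 0) 1 + dose_scale * meta$condition / max_cond else rep(1, nrow(meta))

  intens <- with_seed(child_seed(scenario$seed, "features"), {
    mu <- rnorm(n_metabolites, log(1e5), baseline_meanlog_sd)
    k <- ncol(emb)
    n_aff <- min(n_affected, n_metabolites)
    n_aff <- max(k, k * (n_aff %/% k)) # whole orthonormal blocks
    affected <- sample.int(n_metabolites, n_aff)
    frames <- do.call(rbind, lapply(seq_len(n_aff %/% k), function(b) {
      qr.Q(qr(matrix(rnorm(k * k), k, k)))
    }))
    beta <- matrix(0, n_metabolites, k)
    beta[affected, ] <- frames / sqrt(n_aff / k)
    shift <- emb[meta$strain, , drop = FALSE] %*% t(beta) # samples x metabolites
    logI <- matrix(rnorm(nrow(meta) * n_metabolites, 0, rep_sd),
                   nrow(meta), n_metabolites)
    logI <- sweep(logI, 2, mu, `+`)
    logI <- logI + effect_size * dose_w * shift
    exp(logI)
  })
  colnames(intens) <- met_names
  feature_table(dplyr::bind_cols(meta, tibble::as_tibble(intens)),
                state = "raw")
}
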