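#' Describe a synthetic study scenario
#'
#' A scenario bundles everything the synthetic-data generators need to emulate
#' a multi-locus genotype/metabolome study on a small set of yeast strains:
#' a strain tree, per-locus alignment lengths and rate multipliers, the
#' ordered ethanol conditions, replicate counts, noise levels and any
#' "planted" spectral signals that tie a wavenumber region to one locus'
#' genetic distances.
#'
#' Each locus is simulated on its own copy of the strain tree whose branch
#' lengths are jittered by independent log-normal multipliers
#' (`sd = jitter_sd` on the log scale, seeded per locus) and then rescaled
#' so the gene tree keeps the base tree's total length. This emulates
#' gene-tree heterogeneity among real marker panels — mitochondrial, rDNA
#' and single-copy nuclear loci disagree substantially about relative
#' strain distances — while the locus `rate` alone controls overall
#' divergence. With `jitter_sd = 0` all loci share exactly proportional
#' distance matrices, which makes them indistinguishable to scale-invariant
#' matrix correlation.
#'
#' @param tree_newick Rooted strain tree in Newick format with branch lengths
#'   in substitutions/site. Must have at least 3 uniquely labeled leaves.
#' @param locus_specs Data frame with columns `locus`, `length`
#'   (alignment columns, >= 1), `rate` (rate multiplier, > 0) and optionally
#'   `jitter_sd` (log-scale branch-length jitter, >= 0; default taken from
#'   `jitter_sd`).
#' @param conditions Strictly increasing ethanol percentages (v/v).
#' @param n_replicates Replicates per strain x condition (>= 1).
#' @param noise_sd Standard deviation of i.i.d. Gaussian noise added to each
#'   simulated absorbance value.
#' @param baseline_sd Scale of the random smooth (degree <= 3 polynomial)
#'   baseline added to each simulated spectrum; 0 disables baselines.
#' @param planted_signals List of [planted_signal()] objects.
#' @param jitter_sd Default per-locus branch-length jitter (log scale).
#' @param seed Integer master seed; all generators derive their streams from
#'   it, so equal configs give identical outputs.
#'
#' @return An object of class `scenario_config`.
#' @seealso [planted_signal()], [simulate_spectra()],
#'   [simulate_feature_table()], [simulate_viability()]
#' @export
#' @examples
#' sc <- scenario_config(seed = 1)
#' sc$conditions
scenario_config <- function(tree_newick = default_strain_tree(),
                            locus_specs = default_locus_specs(),
                            conditions = c(0, 8, 12, 16),
                            n_replicates = 3,
                            noise_sd = 0.005,
                            baseline_sd = 0.02,
                            planted_signals = list(),
                            jitter_sd = 1.6,
                            seed = 1L) {
  tree <- parse_tree(tree_newick)
  if (length(tree$tip.label) < 3) abort("Scenario tree must have >= 3 leaves.")
  if (anyDuplicated(tree$tip.label)) abort("Scenario tree leaf labels must be unique.")
  locus_specs <- tibble::as_tibble(locus_specs)
  required <- c("locus", "length", "rate")
  if (!all(required %in% names(locus_specs))) {
    abort("`locus_specs` needs columns locus, length, rate.")
  }
  if (!"jitter_sd" %in% names(locus_specs)) locus_specs$jitter_sd <- jitter_sd
  if (anyDuplicated(locus_specs$locus)) abort("Locus names must be unique.")
  if (any(locus_specs$length < 1)) abort("Alignment lengths must be >= 1.")
  if (any(locus_specs$rate <= 0)) abort("Rate multipliers must be > 0.")
  if (any(locus_specs$jitter_sd < 0)) abort("jitter_sd must be >= 0.")
  if (length(conditions) < 1 || is.unsorted(conditions, strictly = TRUE)) {
    abort("`conditions` must be strictly increasing.")
  }
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  if (noise_sd < 0 || baseline_sd < 0) abort("Noise scales must be >= 0.")
  for (ps in planted_signals) {
    if (!inherits(ps, "planted_signal")) {
      abort("`planted_signals` must be a list of planted_signal() objects.")
    }
    if (length(ps$amplitude_per_condition) != length(conditions)) {
      abort(sprintf(
        "Planted signal on locus '%s': %d amplitudes for %d conditions.",
        ps$source_locus, length(ps$amplitude_per_condition), length(conditions)
      ))
    }
    if (!ps$source_locus %in% locus_specs$locus) {
      abort(sprintf("Planted signal references unknown locus '%s'.", ps$source_locus))
    }
  }
  structure(
    list(
      tree = tree, locus_specs = locus_specs, conditions = as.numeric(conditions),
      n_replicates = as.integer(n_replicates), noise_sd = noise_sd,
      baseline_sd = baseline_sd, planted_signals = planted_signals,
      seed = as.integer(seed)
    ),
    class = "scenario_config"
  )
}

#' @export
print.scenario_config <- function(x, ...) {
  cat(sprintf(
    "<scenario_config> %d strains, %d loci, conditions %s%%, %d replicate(s), seed %d\n",
    length(x$tree$tip.label), nrow(x$locus_specs),
    paste(x$conditions, collapse = "/"), x$n_replicates, x$seed
  ))
  if (length(x$planted_signals)) {
    for (ps in x$planted_signals) {
      cat(sprintf(
        "  planted: %s <- %s, amplitudes %s, %d wavelengths\n",
        paste(ps$region, collapse = "-"), ps$source_locus,
        paste(ps$amplitude_per_condition, collapse = "/"), ps$n_wavelengths
      ))
    }
  }
  invisible(x)
}

#' Plant a condition-dependent, locus-driven spectral signal
#'
#' Describes a signal the spectra generator superimposes on a wavenumber
#' region: at condition `c`, `n_wavelengths` positions inside `region` gain
#' `amplitude_per_condition[c] * score(strain)`, where the strain scores are
#' the 1-D classical-scaling embedding of the source locus' tree-derived
#' distance matrix. Pairwise absolute score differences therefore track the
#' locus' genetic distances, so a per-wavelength correlation scan can
#' recover the planted locus.
#'
#' @param region Region name (`"W1"`..`"W4"`, looked up in
#'   [default_region_map()]) or a numeric `c(high, low)` wavenumber interval.
#' @param source_locus Locus whose distances drive the strain separation.
#' @param amplitude_per_condition One amplitude per scenario condition.
#' @param n_wavelengths Number of affected wavelengths within the region.
#' @return An object of class `planted_signal`.
#' @export
planted_signal <- function(region, source_locus, amplitude_per_condition,
                           n_wavelengths = 50) {
  if (n_wavelengths < 1) abort("`n_wavelengths` must be >= 1.")
  if (any(!is.finite(amplitude_per_condition))) abort("Amplitudes must be finite.")
  structure(
    list(
      region = region, source_locus = source_locus,
      amplitude_per_condition = as.numeric(amplitude_per_condition),
      n_wavelengths = as.integer(n_wavelengths)
    ),
    class = "planted_signal"
  )
}

#' Default four-strain tree for synthetic scenarios
#'
#' Mirrors the topology of the *Saccharomyces sensu stricto* type strains
#' (bayanus/pastorianus vs. paradoxus/cerevisiae) with barcode-scale branch
#' lengths in substitutions/site.
#' @return Newick string.
#' @export
default_strain_tree <- function() {
  paste0(
    "((S_bayanus:0.040,S_pastorianus:0.030):0.020,",
    "(S_paradoxus:0.022,S_cerevisiae:0.018):0.015);"
  )
}

#' Default locus panel for synthetic scenarios
#'
#' Twelve loci named after the classical yeast marker panel (ITS, LSU, SSU,
#' TEF1a, ACT1, RPB1, RPB2, mtCOXII, mtSSU, FAS1, ICL1, DAL2) with
#' field-realistic alignment lengths and relative rate multipliers
#' (mitochondrial and spacer loci faster than ribosomal subunits). The
#' ITS_LSU concatenation is built downstream with [concatenate_alignments()],
#' not simulated as its own locus.
#' @return Tibble with columns locus, length, rate.
#' @export
default_locus_specs <- function() {
  tibble::tibble(
    locus = c("ITS", "LSU", "SSU", "TEF1a", "ACT1", "RPB1",
              "RPB2", "mtCOXII", "mtSSU", "FAS1", "ICL1", "DAL2"),
    length = c(600L, 570L, 1700L, 1000L, 1100L, 1200L,
               1200L, 700L, 900L, 1500L, 1000L, 900L),
    rate = c(1.6, 0.8, 0.4, 0.9, 0.8, 1.0,
             1.0, 2.2, 1.8, 1.1, 1.2, 1.4)
  )
}

parse_tree <- function(tree) {
  if (inherits(tree, "phylo")) return(tree)
  if (!is.character(tree) || length(tree) != 1) {
    abort("Tree must be a Newick string or an ape 'phylo' object.")
  }
  phy <- tryCatch(suppressWarnings(ape::read.tree(text = tree)),
                  error = function(e) NULL)
  if (is.null(phy) || is.null(phy$tip.label)) {
    abort(sprintf("Could not parse Newick tree: %s", tree))
  }
  if (is.null(phy$edge.length)) abort("Tree must carry branch lengths.")
  if (any(!is.finite(phy$edge.length)) || any(phy$edge.length < 0)) {
    abort("Tree branch lengths must be finite and >= 0.")
  }
  phy
}

#' Per-locus gene trees of a scenario
#'
#' Applies the per-locus branch-length jitter (log-normal multipliers, seeded
#' from the scenario seed and the locus name) and the locus rate multiplier
#' to the scenario strain tree.
#'
#' @param scenario A [scenario_config()].
#' @return Named list of `phylo` trees, one per locus, branch lengths in
#'   expected substitutions/site for that locus.
#' @export
locus_trees <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  specs <- scenario$locus_specs
  out <- purrr::pmap(specs, function(locus, length, rate, jitter_sd, ...) {
    phy <- scenario$tree
    if (jitter_sd > 0) {
      mult <- with_seed(
        child_seed(scenario$seed, paste0("tree::", locus)),
        rlnorm(length(phy$edge.length), meanlog = -jitter_sd^2 / 2, sdlog = jitter_sd)
      )
      jittered <- phy$edge.length * mult
      # redistribute length among branches without changing the total:
      # loci then differ in distance-matrix shape, not in overall divergence,
      # and fast loci cannot be pushed into distance-correction saturation
      phy$edge.length <- jittered * (sum(phy$edge.length) / sum(jittered))
    }
    phy$edge.length <- phy$edge.length * rate
    phy
  })
  setNames(out, specs$locus)
}

#' True (tree-derived) distance matrix of one scenario locus
#'
#' Path-length distances on the locus gene tree, i.e. the expected number of
#' substitutions per site separating each strain pair at that locus. These
#' are the distances the planted spectral/metabolite signals are built from;
#' analysis-side estimates from the simulated alignments recover them up to
#' sampling noise.
#'
#' @inheritParams locus_trees
#' @param locus Locus name.
#' @return Labeled symmetric matrix.
#' @export
locus_true_distances <- function(scenario, locus) {
  trees <- locus_trees(scenario)
  if (!locus %in% names(trees)) {
    abort(sprintf("Unknown locus '%s'.", locus))
  }
  d <- cophenetic(trees[[locus]])
  labs <- sort(rownames(d))
  as_distance_matrix(d[labs, labs])
}

#' 1-D strain embedding of a locus distance matrix
#'
#' Classical scaling (principal coordinates) in one dimension, rescaled to
#' unit standard deviation with the sign fixed so the first strain scores
#' >= 0. For distances that are exactly a line metric the embedding is exact
#' and pairwise absolute score differences reproduce the distances up to a
#' single scale factor.
#'
#' @param d Labeled symmetric distance matrix.
#' @return Named numeric vector of strain scores.
#' @export
strain_scores <- function(d) {
  d <- as_distance_matrix(d)
  sc <- cmdscale(as.dist(d), k = 1)[, 1]
  s <- sd(sc)
  if (s == 0) abort("Degenerate distance matrix: all strains coincide.")
  sc <- sc / s
  if (sc[1] < 0) sc <- -sc
  sc
}

#' Full principal-coordinate strain embedding
#'
#' Classical scaling of a strain distance matrix keeping every positive
#' eigenvalue dimension, rescaled so the mean pairwise embedded distance is
#' 1. Between-strain Euclidean distances in this space reproduce the input
#' distances as closely as classical scaling allows (exactly, for
#' Euclidean-embeddable inputs).
#'
#' @param d Labeled symmetric distance matrix.
#' @return Numeric matrix, one row per strain.
#' @export
strain_embedding <- function(d) {
  d <- as_distance_matrix(d)
  # tree metrics need not be Euclidean; negative-eigenvalue axes are dropped
  mds <- suppressWarnings(cmdscale(as.dist(d), k = nrow(d) - 1, eig = TRUE))
  keep <- which(mds$eig > max(mds$eig) * 1e-9)
  keep <- intersect(keep, seq_len(ncol(mds$points)))
  e <- mds$points[, keep, drop = FALSE]
  scale_by <- mean(dist(e))
  if (scale_by == 0) abort("Degenerate distance matrix: all strains coincide.")
  e / scale_by
}
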