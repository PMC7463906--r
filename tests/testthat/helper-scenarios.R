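# shared fixtures, all built in code

# path-graph strain tree whose cophenetic matrix is exactly a line metric
# (positions 0, 0.01, 0.03, 0.07 substitutions/site), so the 1-D embedding
# of its distances is exact and planted per-wavelength correlations hit 1
line_tree <- "(((A:0.01,B:0.0):0.02,C:0.0):0.04,D:0.0);"

line_scenario <- function(seed = 1, amplitudes = c(0, 0, 0, 0.2),
                          n_wavelengths = 50, noise_sd = 0, baseline_sd = 0,
                          region = "W2") {
  scenario_config(
    tree_newick = line_tree,
    locus_specs = data.frame(
      locus = c("L1", "L2"), length = c(800L, 800L),
      rate = c(1, 1), jitter_sd = 0
    ),
    planted_signals = list(
      planted_signal(region, "L1", amplitudes, n_wavelengths = n_wavelengths)
    ),
    noise_sd = noise_sd, baseline_sd = baseline_sd, seed = seed
  )
}

# small fast scenario for pipeline-level tests
small_scenario <- function(seed = 1, ...) {
  scenario_config(
    locus_specs = default_locus_specs()[c(1, 2, 7, 11), ],
    seed = seed, ...
  )
}

# tiny labeled symmetric matrix from its lower triangle
sym_from_lower <- function(v, labels) {
  n <- length(labels)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  m[lower.tri(m)] <- v
  m + t(m)
}

# minimal feature_table builder
tiny_feature_table <- function(values, state = "raw") {
  n <- nrow(values)
  feature_table(
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = paste0("s", seq_len(n)),
        strain = rep(c("x", "y"), length.out = n),
        condition = 0, replicate = seq_len(n)
      ),
      tibble::as_tibble(values)
    ),
    state = state
  )
}

# minimal spectrum_set builder on an arbitrary decreasing axis
tiny_spectrum_set <- function(absorbance, wavenumber = NULL, strains = NULL,
                              conditions = NULL) {
  n <- nrow(absorbance)
  if (is.null(wavenumber)) wavenumber <- seq(4000, by = -4,
                                             length.out = ncol(absorbance))
  strains <- strains %||% paste0("st", seq_len(n))
  conditions <- conditions %||% rep(0, n)
  meta <- tibble::tibble(
    sample_id = paste(strains, conditions, seq_len(n), sep = "_"),
    strain = strains, condition = conditions, replicate = seq_len(n)
  )
  spectrum_set(wavenumber, absorbance, meta)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# independent brute-force Mantel oracle: enumerate label permutations
# recursively and correlate lower triangles directly
brute_force_perm_p <- function(d1, d2) {
  labs <- sort(rownames(d1))
  v1 <- d1[labs, labs][lower.tri(d1)]
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    unlist(lapply(seq_along(v), function(i) {
      lapply(permute(v[-i]), function(rest) c(v[i], rest))
    }), recursive = FALSE)
  }
  r_obs <- cor(v1, d2[labs, labs][lower.tri(d2)])
  r_all <- vapply(permute(labs), function(p) {
    m <- d2[p, p]
    dimnames(m) <- list(labs, labs)
    cor(v1, m[lower.tri(m)])
  }, numeric(1))
  list(r = r_obs, p = mean(abs(r_all) >= abs(r_obs) - 1e-12))
}
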