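#' Write every synthetic input of a scenario to disk
#'
#' Materializes the scenario as the file formats the analysis stages read:
#' one aligned FASTA per locus, a wide spectra CSV, a feature-table CSV, a
#' viability CSV and a key=value echo of the configuration.
#'
#' @inheritParams locus_trees
#' @param out_dir Output directory (created if needed).
#' @return Named list of written paths, invisibly.
#' @export
simulate_scenario <- function(scenario, out_dir) {
  stopifnot(inherits(scenario, "scenario_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  loci_dir <- file.path(out_dir, "loci")
  dir.create(loci_dir, showWarnings = FALSE)
  alns <- simulate_locus_alignments(scenario)
  fasta <- purrr::imap_chr(alns, function(a, locus) {
    write_alignment_fasta(a, file.path(loci_dir, paste0(locus, ".fasta")))
  })
  paths <- list(
    loci = fasta,
    spectra = file.path(out_dir, "spectra.csv"),
    features = file.path(out_dir, "features.csv"),
    viability = file.path(out_dir, "viability.csv"),
    config = file.path(out_dir, "scenario.cfg")
  )
  write_spectra_csv(simulate_spectra(scenario), paths$spectra)
  write_feature_csv(simulate_feature_table(scenario), paths$features)
  readr::write_csv(simulate_viability(scenario), paths$viability)
  writeLines(scenario_to_text(scenario), paths$config)
  invisible(paths)
}

scenario_to_text <- function(scenario) {
  c(
    paste0("tree=", ape::write.tree(scenario$tree)),
    paste0("conditions=", paste(scenario$conditions, collapse = ",")),
    paste0("n_replicates=", scenario$n_replicates),
    paste0("noise_sd=", scenario$noise_sd),
    paste0("baseline_sd=", scenario$baseline_sd),
    paste0("seed=", scenario$seed),
    paste0("locus=", scenario$locus_specs$locus, ":",
           scenario$locus_specs$length, ":", scenario$locus_specs$rate, ":",
           scenario$locus_specs$jitter_sd),
    unlist(lapply(scenario$planted_signals, function(ps) {
      paste0("planted=", paste(ps$region, collapse = "-"), ":", ps$source_locus,
             ":", paste(ps$amplitude_per_condition, collapse = ","), ":",
             ps$n_wavelengths)
    }))
  )
}

#' Per-marker genetic distance matrices (with ITS_LSU concatenation)
#'
#' Computes one distance matrix per alignment and, when both ITS and LSU are
#' present, adds their concatenation as marker `ITS_LSU`.
#'
#' @param alignments Named list of `marker_alignment` objects.
#' @param model,deletion Passed to [evolutionary_distance()].
#' @return Named list of labeled distance matrices.
#' @export
marker_distances <- function(alignments, model = "K80", deletion = "complete") {
  ds <- purrr::map(alignments, evolutionary_distance,
                   model = model, deletion = deletion)
  if (all(c("ITS", "LSU") %in% names(alignments))) {
    ds$ITS_LSU <- evolutionary_distance(
      concatenate_alignments(alignments[c("ITS", "LSU")], locus = "ITS_LSU"),
      model = model, deletion = deletion
    )
  }
  ds
}

#' Standard FTIR preprocessing chain
#'
#' Quality assessment (reported, not enforced), rubberband baseline
#' correction, then vector normalization of the whole spectra — in that
#' order, matching instrument practice.
#'
#' @param set A raw `spectrum_set`.
#' @param n_points Rubberband support points.
#' @param snr_threshold Quality threshold; failing spectra are dropped only
#'   when `enforce_quality = TRUE`.
#' @param enforce_quality Drop failing spectra.
#' @return List: `set` (processed `spectrum_set`), `qc` (tibble from
#'   [quality_snr()]).
#' @export
preprocess_spectra <- function(set, n_points = 64, snr_threshold = 4000,
                               enforce_quality = FALSE) {
  qc <- quality_snr(set, threshold = snr_threshold)
  if (enforce_quality) {
    keep <- qc$pass
    if (!any(keep)) abort("Every spectrum failed the quality test.")
    set <- spectrum_set(set$wavenumber, set$absorbance[keep, , drop = FALSE],
                        set$meta[keep, ])
  }
  out <- set |> rubberband_baseline(n_points = n_points) |> vector_normalize()
  list(set = out, qc = qc)
}

resolve_inputs <- function(inputs) {
  if (inherits(inputs, "scenario_config")) {
    return(list(
      alignments = simulate_locus_alignments(inputs),
      spectra = simulate_spectra(inputs),
      features = simulate_feature_table(inputs),
      viability = simulate_viability(inputs)
    ))
  }
  if (is.list(inputs) && !is.null(inputs$loci_dir)) {
    files <- list.files(inputs$loci_dir, pattern = "\\.fa(sta)?$",
                        full.names = TRUE)
    if (length(files) == 0) abort("No FASTA files in `loci_dir`.")
    alignments <- setNames(
      lapply(files, read_alignment_fasta),
      sub("\\.[^.]*$", "", basename(files))
    )
    list(
      alignments = alignments,
      spectra = if (!is.null(inputs$spectra_csv)) read_spectra_csv(inputs$spectra_csv),
      features = if (!is.null(inputs$feature_csv)) read_feature_csv(inputs$feature_csv),
      viability = if (!is.null(inputs$viability_csv)) {
        readr::read_csv(inputs$viability_csv, show_col_types = FALSE)
      }
    )
  } else {
    abort("`inputs` must be a scenario_config or a list with $loci_dir etc.")
  }
}

write_log <- function(out_dir, lines) {
  if (!is.null(out_dir)) {
    writeLines(lines, file.path(out_dir, "run_log.txt"))
  }
}

#' Resting-state predictability analysis
#'
#' The first published analysis structure: per-locus genetic distances, an
#' NJ tree with bootstrap for the ITS_LSU benchmark, whole-profile FTIR and
#' LC-MS clustering of the control samples, and a ranked table of
#' Mantel-style correlations of every marker against the FTIR and LC-MS
#' distance matrices.
#'
#' FTIR whole-profile distances use the informative fingerprint windows
#' (fatty acids 3200-2800 plus amides/mixed 1800-1200 cm^-1) after
#' preprocessing; LC-MS distances use the feature table after IQR
#' filtering, median normalization, log2 transformation and Pareto scaling
#' (the log2 scale on which the differential-metabolite analyses are
#' drawn). Both are restricted to the control (lowest) condition and
#' averaged per strain.
#'
#' @param inputs A [scenario_config()] (inputs generated in memory) or a
#'   list of paths: `loci_dir`, `spectra_csv`, `feature_csv`.
#' @param model Distance model for the markers.
#' @param threshold Correlation significance threshold.
#' @param n_boot Bootstrap replicates for the ITS_LSU tree.
#' @param seed Seed for bootstrap and any sampled permutation test.
#' @param out_dir Optional directory: writes distance CSVs, Newick trees,
#'   the correlation table and a run log.
#' @return List of class `genophen_resting`: `marker_distances`,
#'   `its_lsu_tree`, `ftir_hca`, `lcms_hca`, `ftir_distance`,
#'   `lcms_distance`, `correlations` (ranked tibble), `qc`.
#' @export
run_resting <- function(inputs, model = "K80", threshold = 0.75,
                        n_boot = 1000, seed = 1L, out_dir = NULL) {
  t0 <- Sys.time()
  x <- resolve_inputs(inputs)
  ds <- marker_distances(x$alignments, model = model)
  tree <- if (all(c("ITS", "LSU") %in% names(x$alignments))) {
    bootstrap_support(
      concatenate_alignments(x$alignments[c("ITS", "LSU")], locus = "ITS_LSU"),
      model = model, n_reps = n_boot, seed = seed
    )
  }
  pre <- preprocess_spectra(x$spectra)
  fingerprint <- extract_regions(pre$set, list(c(3200, 2800), c(1800, 1200)))
  control <- min(fingerprint$meta$condition)
  ftir_profiles <- strain_profiles(fingerprint, conditions = control)
  ftir_d <- profile_distance(ftir_profiles)
  ftir_hca <- hca(ftir_profiles, distance = "euclidean")

  ft <- x$features |> iqr_filter() |> median_normalize() |>
    log_transform() |> pareto_scale()
  lcms_profiles <- strain_profiles(ft, conditions = min(ft$condition))
  lcms_d <- profile_distance(lcms_profiles)
  lcms_hca <- hca(lcms_profiles, distance = "spearman")

  correlations <- purrr::imap_dfr(ds, function(d, marker) {
    dplyr::bind_rows(
      dplyr::mutate(matrix_correlation(d, ftir_d, seed = seed),
                    marker = marker, phenotype = "FTIR", .before = 1),
      dplyr::mutate(matrix_correlation(d, lcms_d, seed = seed),
                    marker = marker, phenotype = "LC-MS", .before = 1)
    )
  }) |>
    dplyr::mutate(significant = .data$r > threshold) |>
    dplyr::arrange(.data$phenotype, dplyr::desc(.data$r))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    readr::write_csv(correlations, file.path(out_dir, "resting_correlations.csv"))
    for (mk in names(ds)) {
      readr::write_csv(
        tibble::as_tibble(ds[[mk]], rownames = "strain"),
        file.path(out_dir, paste0("distance_", mk, ".csv"))
      )
    }
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "its_lsu_nj.nwk"))
    write_dendrogram_newick(ftir_hca, file.path(out_dir, "ftir_hca.nwk"))
    write_dendrogram_newick(lcms_hca, file.path(out_dir, "lcms_hca.nwk"))
    write_log(out_dir, c(
      sprintf("analysis=resting seed=%d model=%s threshold=%g", seed, model, threshold),
      sprintf("markers=%d", length(ds)),
      sprintf("elapsed_s=%.2f", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    ))
  }
  structure(
    list(marker_distances = ds, its_lsu_tree = tree,
         ftir_hca = ftir_hca, lcms_hca = lcms_hca,
         ftir_distance = ftir_d, lcms_distance = lcms_d,
         correlations = correlations, qc = pre$qc),
    class = "genophen_resting"
  )
}

#' Stress-predictivity analysis
#'
#' The second published analysis structure: the mortality table, per-marker
#' PSW trends with their typology over the ethanol series, and the
#' region-wise maximum correlations for control versus pooled stressed
#' spectra.
#'
#' @inheritParams run_resting
#' @param split PSW trend split; see [classify_trend()].
#' @return List of class `genophen_stress`: `mortality`, `scan`, `psw`
#'   (trend tibble), `region_table`, `qc`.
#' @export
run_stress <- function(inputs, model = "K80", threshold = 0.75, split = 5.0,
                       seed = 1L, out_dir = NULL) {
  t0 <- Sys.time()
  x <- resolve_inputs(inputs)
  if (length(unique(x$spectra$meta$condition)) < 3) {
    abort("Stress analysis needs >= 3 conditions.")
  }
  mort <- if (!is.null(x$viability)) mortality_table(x$viability)
  ds <- marker_distances(x$alignments, model = model)
  pre <- preprocess_spectra(x$spectra)
  tr <- psw_trends(pre$set, ds, threshold = threshold, split = split)
  region_tbl <- region_max_correlation(pre$set, ds, threshold = threshold)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(mort)) readr::write_csv(mort, file.path(out_dir, "mortality.csv"))
    readr::write_csv(tr$scan, file.path(out_dir, "descriptor_scan.csv"))
    readr::write_csv(tr$trends, file.path(out_dir, "psw_trends.csv"))
    readr::write_csv(region_tbl, file.path(out_dir, "region_max_correlation.csv"))
    write_log(out_dir, c(
      sprintf("analysis=stress seed=%d model=%s threshold=%g split=%g",
              seed, model, threshold, split),
      sprintf("markers=%d conditions=%s", length(ds),
              paste(sort(unique(x$spectra$meta$condition)), collapse = ",")),
      sprintf("elapsed_s=%.2f", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    ))
  }
  structure(
    list(mortality = mort, scan = tr$scan, psw = tr$trends,
         region_table = region_tbl, qc = pre$qc),
    class = "genophen_stress"
  )
}

#' @export
print.genophen_resting <- function(x, ...) {
  cat("<genophen_resting>\n")
  top <- dplyr::slice_max(x$correlations, .data$r, n = 1, by = "phenotype")
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  top %s marker: %s (r = %.3f, p = %.3f)\n",
                top$phenotype[i], top$marker[i], top$r[i], top$p_value[i]))
  }
  invisible(x)
}

#' @export
print.genophen_stress <- function(x, ...) {
  cat("<genophen_stress>\n")
  counts <- table(dplyr::distinct(x$psw, .data$marker, .data$trend_class)$trend_class)
  cat("  trend classes:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}
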