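#' Construct a feature table
#'
#' A tibble of per-sample metabolite intensities carrying the metadata
#' columns `sample_id`, `strain`, `condition`, `replicate` followed by one
#' numeric column per metabolite, plus a processing-state flag. States move
#' monotonically `raw -> filtered -> normalized -> scaled` through
#' [iqr_filter()], [median_normalize()] and [pareto_scale()].
#'
#' @param df Data frame with the metadata columns and metabolite columns.
#' @param state One of `"raw"`, `"filtered"`, `"normalized"`, `"scaled"`.
#' @return A `feature_table` (tibble subclass).
#' @export
feature_table <- function(df, state = "raw") {
  df <- tibble::as_tibble(df)
  state <- match.arg(state, c("raw", "filtered", "normalized", "scaled"))
  need <- c("sample_id", "strain", "condition", "replicate")
  if (!all(need %in% names(df))) {
    abort(sprintf("Feature table needs metadata columns: %s.",
                  paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) abort("Sample ids must be unique.")
  mets <- setdiff(names(df), need)
  if (length(mets) == 0) abort("Feature table has no metabolite columns.")
  if (anyDuplicated(mets)) abort("Metabolite names must be unique.")
  vals <- as.matrix(df[mets])
  if (!is.numeric(vals) || any(!is.finite(vals))) {
    abort("Metabolite intensities must be finite numbers.")
  }
  if (state == "raw" && any(vals < 0)) {
    abort("Raw intensities must be >= 0.")
  }
  df <- df[c(need, mets)]
  structure(df, class = c("feature_table", class(tibble::tibble()))) |>
    set_ft_state(state)
}

ft_state <- function(table) attr(table, "ft_state") %||% "raw"
set_ft_state <- function(table, state) {
  attr(table, "ft_state") <- state
  table
}
ft_meta_cols <- c("sample_id", "strain", "condition", "replicate")

#' Metabolite column names of a feature table
#' @param table A `feature_table`.
#' @return Character vector.
#' @export
metabolite_names <- function(table) setdiff(names(table), ft_meta_cols)

#' Intensity matrix of a feature table
#' @param table A `feature_table`.
#' @return Numeric matrix, rownames = sample ids.
#' @export
intensity_matrix <- function(table) {
  m <- as.matrix(table[metabolite_names(table)])
  rownames(m) <- table$sample_id
  m
}

require_state <- function(table, allowed, op) {
  if (!inherits(table, "feature_table")) {
    abort(sprintf("`%s` expects a feature_table.", op))
  }
  if (!ft_state(table) %in% allowed) {
    abort(sprintf("`%s` expects state %s, got '%s'.",
                  op, paste(sQuote(allowed), collapse = "/"), ft_state(table)))
  }
  invisible(table)
}

#' Read / write a feature table CSV
#'
#' @param path CSV path with the metadata columns plus metabolite columns.
#' @param state Processing state to stamp on the table.
#' @return A `feature_table`.
#' @export
read_feature_csv <- function(path, state = "raw") {
  feature_table(readr::read_csv(path, show_col_types = FALSE), state = state)
}

#' @rdname read_feature_csv
#' @param table A `feature_table`.
#' @return `path`, invisibly.
#' @export
write_feature_csv <- function(table, path) {
  readr::write_csv(tibble::as_tibble(table), path)
  invisible(path)
}

#' Interquartile-range filter
#'
#' Near-constant metabolites carry no discriminant signal; metabolites are
#' ranked by IQR across samples and the lowest `drop_fraction` (floor of the
#' count) are removed. Zero-IQR metabolites are always removed, regardless
#' of the fraction.
#'
#' @param table A raw `feature_table`.
#' @param drop_fraction Fraction in \[0, 1) of metabolites to drop.
#' @return A `feature_table` with state `"filtered"`.
#' @export
iqr_filter <- function(table, drop_fraction = 0.1) {
  require_state(table, "raw", "iqr_filter")
  if (drop_fraction < 0 || drop_fraction >= 1) {
    abort("`drop_fraction` must be in [0, 1).")
  }
  m <- intensity_matrix(table)
  iqr <- apply(m, 2, function(x) diff(quantile(x, c(0.25, 0.75), names = FALSE)))
  n_drop <- floor(drop_fraction * ncol(m))
  by_rank <- colnames(m)[order(iqr)][seq_len(n_drop)]
  drop <- union(colnames(m)[iqr == 0], by_rank)
  keep <- setdiff(colnames(m), drop)
  if (length(keep) == 0) abort("IQR filter would remove every metabolite.")
  set_ft_state(table[c(ft_meta_cols, keep)], "filtered")
}

#' Median normalization
#'
#' Divides each sample's intensities by that sample's median, so every
#' sample's median becomes 1.
#'
#' @param table A `feature_table` (raw or filtered) whose per-sample medians
#'   are all > 0.
#' @return A `feature_table` with state `"normalized"`.
#' @export
median_normalize <- function(table) {
  require_state(table, c("raw", "filtered"), "median_normalize")
  m <- intensity_matrix(table)
  med <- apply(m, 1, median)
  if (any(med <= 0)) {
    abort(sprintf("Sample median <= 0 for: %s.",
                  paste(rownames(m)[med <= 0], collapse = ", ")))
  }
  out <- table
  out[metabolite_names(table)] <- tibble::as_tibble(sweep(m, 1, med, `/`))
  set_ft_state(out, "normalized")
}

#' Log2 transformation
#'
#' Optional variance-stabilizing step between normalization and scaling,
#' matching the log2 scale on which differential-metabolite heatmaps are
#' drawn. Requires strictly positive intensities.
#'
#' @param table A normalized `feature_table`.
#' @return A `feature_table`, still in state `"normalized"`.
#' @export
log_transform <- function(table) {
  require_state(table, "normalized", "log_transform")
  m <- intensity_matrix(table)
  if (any(m <= 0)) abort("log_transform needs strictly positive intensities.")
  out <- table
  out[metabolite_names(table)] <- tibble::as_tibble(log2(m))
  set_ft_state(out, "normalized")
}

#' Pareto scaling
#'
#' Per metabolite: subtract the mean and divide by the square root of the
#' standard deviation — a compromise between unit variance and no scaling
#' that damps the dominance of high-abundance metabolites. Zero-variance
#' metabolites are set to 0 with a warning.
#'
#' @param table A normalized `feature_table`.
#' @return A `feature_table` with state `"scaled"`.
#' @export
pareto_scale <- function(table) {
  require_state(table, "normalized", "pareto_scale")
  m <- intensity_matrix(table)
  mu <- colMeans(m)
  s <- apply(m, 2, sd)
  if (any(s == 0)) {
    warn(sprintf("Zero-variance metabolite(s) set to 0: %s.",
                 paste(colnames(m)[s == 0], collapse = ", ")))
  }
  scaled <- sweep(m, 2, mu, `-`)
  nz <- s > 0
  scaled[, nz] <- sweep(scaled[, nz, drop = FALSE], 2, sqrt(s[nz]), `/`)
  scaled[, !nz] <- 0
  out <- table
  out[metabolite_names(table)] <- tibble::as_tibble(scaled)
  set_ft_state(out, "scaled")
}
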