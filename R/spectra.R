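#' Construct a spectrum set
#'
#' Container for a batch of FTIR spectra sharing one wavenumber axis:
#' a strictly decreasing, uniformly spaced axis in cm^-1, a samples x
#' wavelengths absorbance matrix and per-sample metadata.
#'
#' @param wavenumber Numeric axis, strictly decreasing, uniform step
#'   (within 1e-9).
#' @param absorbance Numeric matrix, one row per sample, `length(wavenumber)`
#'   columns, finite values.
#' @param meta Data frame with columns `sample_id` (unique), `strain`,
#'   `condition`, `replicate`, aligned with the rows of `absorbance`.
#' @param uniform Require a uniform axis step (within 1e-9). Region
#'   concatenation (see [extract_regions()]) produces legitimate gaps and
#'   sets this to `FALSE`.
#' @return Object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumber, absorbance, meta, uniform = TRUE) {
  wavenumber <- as.numeric(wavenumber)
  if (length(wavenumber) < 2) abort("Axis needs >= 2 wavenumbers.")
  steps <- diff(wavenumber)
  if (any(steps >= 0)) abort("Wavenumber axis must be strictly decreasing.")
  if (uniform && max(abs(steps - steps[1])) > 1e-9) {
    abort("Wavenumber axis step is not uniform.")
  }
  absorbance <- as.matrix(absorbance)
  if (ncol(absorbance) != length(wavenumber)) {
    abort("Absorbance columns must match the axis length.")
  }
  if (any(!is.finite(absorbance))) abort("Absorbance values must be finite.")
  meta <- tibble::as_tibble(meta)
  need <- c("sample_id", "strain", "condition", "replicate")
  if (!all(need %in% names(meta))) {
    abort(sprintf("Metadata needs columns: %s.", paste(need, collapse = ", ")))
  }
  if (nrow(meta) != nrow(absorbance)) {
    abort("Metadata rows must match absorbance rows.")
  }
  if (anyDuplicated(meta$sample_id)) {
    abort(sprintf("Duplicate sample id(s): %s",
                  paste(unique(meta$sample_id[duplicated(meta$sample_id)]),
                        collapse = ", ")))
  }
  rownames(absorbance) <- meta$sample_id
  colnames(absorbance) <- wavenumber
  structure(list(wavenumber = wavenumber, absorbance = absorbance, meta = meta),
            class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf(
    "<spectrum_set> %d spectra x %d wavenumbers (%.0f..%.0f cm-1, step %.0f)\n",
    nrow(x$absorbance), length(x$wavenumber),
    x$wavenumber[1], x$wavenumber[length(x$wavenumber)],
    abs(x$wavenumber[2] - x$wavenumber[1])
  ))
  invisible(x)
}

#' @export
tidy.spectrum_set <- function(x, ...) {
  wide <- tibble::as_tibble(x$absorbance)
  names(wide) <- as.character(x$wavenumber)
  dplyr::bind_cols(x$meta, wide) |>
    tidyr::pivot_longer(-names(x$meta), names_to = "wavenumber",
                        values_to = "absorbance") |>
    dplyr::mutate(wavenumber = as.numeric(.data$wavenumber))
}

#' @export
autoplot.spectrum_set <- function(object, colour = "strain", ...) {
  tidy(object) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$wavenumber, y = .data$absorbance,
      group = .data$sample_id, colour = .data[[colour]]
    )) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::scale_x_reverse() +
    ggplot2::facet_wrap(~condition, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance")
}

#' Read a wide spectra CSV
#'
#' Expects the layout written by [write_spectra_csv()]: first column
#' `wavenumber_cm1`, then one column per sample named
#' `<strain>_<condition>_<replicate>` (strain names may themselves contain
#' underscores; condition and replicate are taken from the right).
#'
#' @param path CSV path.
#' @param strict Error on a shuffled axis instead of sorting it.
#' @return A `spectrum_set`.
#' @export
read_spectra_csv <- function(path, strict = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (names(df)[1] != "wavenumber_cm1") {
    abort("First column must be 'wavenumber_cm1'.")
  }
  wn <- df$wavenumber_cm1
  if (is.unsorted(rev(wn), strictly = TRUE)) {
    if (strict) abort("Wavenumber axis is not strictly decreasing.")
    ord <- order(wn, decreasing = TRUE)
    df <- df[ord, ]
    wn <- df$wavenumber_cm1
  }
  ids <- names(df)[-1]
  meta <- parse_sample_ids(ids)
  spectrum_set(wn, t(as.matrix(df[, -1])), meta)
}

parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_")
  bad <- ids[vapply(parts, length, integer(1)) < 3]
  if (length(bad)) {
    abort(sprintf("Cannot parse strain/condition/replicate from sample id(s): %s",
                  paste(bad, collapse = ", ")))
  }
  tibble::tibble(
    sample_id = ids,
    strain = vapply(parts, function(p) paste(head(p, -2), collapse = "_"), character(1)),
    condition = as.numeric(vapply(parts, function(p) p[length(p) - 1], character(1))),
    replicate = as.integer(vapply(parts, function(p) p[length(p)], character(1)))
  )
}

#' Write a spectrum set as wide CSV
#'
#' @param set A `spectrum_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(set, path) {
  stopifnot(inherits(set, "spectrum_set"))
  df <- tibble::tibble(wavenumber_cm1 = set$wavenumber)
  df <- dplyr::bind_cols(df, tibble::as_tibble(t(set$absorbance)))
  names(df)[-1] <- set$meta$sample_id
  readr::write_csv(df, path)
  invisible(path)
}
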