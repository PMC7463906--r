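#' Hierarchical clustering with Ward linkage
#'
#' Agglomerative clustering of profile rows with Ward's criterion
#' (`stats::hclust(method = "ward.D2")`, i.e. Ward on unsquared distances).
#' Distances are either Euclidean or Spearman (`1 -` Spearman correlation
#' between rows). Ward linkage formally assumes Euclidean geometry; applying
#' it to Spearman distances follows common chemometrics practice and is
#' flagged as such in the documentation rather than prevented.
#'
#' @param x Numeric matrix (items in rows, rownames as labels) or a
#'   `feature_table` / `spectrum_set`, whose intensity/absorbance matrix is
#'   used.
#' @param distance `"euclidean"` or `"spearman"`.
#' @param linkage Only `"ward"` is offered.
#' @return An `hclust` dendrogram.
#' @export
#' @examples
#' m <- rbind(a = c(0, 0), b = c(1, 0), c = c(10, 0))
#' hca(m)$height
hca <- function(x, distance = c("euclidean", "spearman"), linkage = "ward") {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage, "ward")
  if (inherits(x, "feature_table")) x <- intensity_matrix(x)
  if (inherits(x, "spectrum_set")) x <- x$absorbance
  x <- as.matrix(x)
  if (nrow(x) < 2) abort("Clustering needs >= 2 items.")
  d <- switch(distance,
    euclidean = dist(x),
    spearman = as.dist(1 - cor(t(x), method = "spearman"))
  )
  if (any(is.na(d))) abort("Distance matrix contains NaN.")
  hclust(d, method = "ward.D2")
}

#' Dendrogram as a tree file
#'
#' Converts an `hclust` result to a phylogram and writes Newick, so
#' metabolome/spectra dendrograms can sit next to the marker trees.
#'
#' @param h An `hclust` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(h, path) {
  stopifnot(inherits(h, "hclust"))
  write_newick(ape::as.phylo(h), path)
}

#' Cell mortality from viable counts
#'
#' `M = (1 - Cv/Ct) * 100`. Negative values (growth relative to the
#' control) are kept, not clipped; use the `flag_negative` column to spot
#' them.
#'
#' @param Cv Viable count(s) in the tested sample (>= 0).
#' @param Ct Viable count(s) in the control (> 0).
#' @return Tibble: Cv, Ct, mortality, flag_negative.
#' @export
#' @examples
#' mortality(875, 1000)$mortality # 12.5
mortality <- function(Cv, Ct) {
  if (any(Ct <= 0)) abort("`Ct` must be > 0.")
  if (any(Cv < 0)) abort("`Cv` must be >= 0.")
  m <- (1 - Cv / Ct) * 100
  tibble::tibble(Cv = Cv, Ct = Ct, mortality = m, flag_negative = m < 0)
}

#' Mortality table from viability records
#'
#' @param viability Tibble with columns strain, condition, Cv, Ct (e.g. from
#'   [simulate_viability()] or a plate-count CSV).
#' @return Tibble: strain, condition, mortality, flag_negative.
#' @export
mortality_table <- function(viability) {
  v <- tibble::as_tibble(viability)
  need <- c("strain", "condition", "Cv", "Ct")
  if (!all(need %in% names(v))) {
    abort("Viability records need columns strain, condition, Cv, Ct.")
  }
  dplyr::bind_cols(
    v[c("strain", "condition")],
    mortality(v$Cv, v$Ct)[c("mortality", "flag_negative")]
  )
}
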