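#' Pairwise evolutionary distances from an alignment
#'
#' Closed-form pairwise distance estimators, expressed as substitutions per
#' site:
#' * `p` — raw proportion of mismatching sites;
#' * `JC69` — `-3/4 * log(1 - 4p/3)`;
#' * `K80` — `-1/2 * log(1 - 2P - Q) - 1/4 * log(1 - 2Q)` with `P`, `Q` the
#'   transition and transversion proportions;
#' * `TN93` — the Tamura-Nei closed form separating purine and pyrimidine
#'   transitions, with base frequencies estimated from each sequence pair.
#'
#' Sites containing `-` or `N` are removed for the whole alignment
#' (`deletion = "complete"`, the default, matching `ape::dist.dna`) or per
#' pair (`"pairwise"`). A saturated pair (logarithm argument <= 0) is an
#' error naming the pair rather than a silent `NaN`.
#'
#' @param aln A `marker_alignment`.
#' @param model One of `"K80"` (default), `"p"`, `"JC69"`, `"TN93"`.
#' @param deletion `"complete"` or `"pairwise"`.
#' @return Labeled symmetric matrix of distances with zero diagonal;
#'   attribute `model` records the estimator.
#' @export
#' @examples
#' aln <- marker_alignment(c(a = "ACGTACGTAC", b = "ACGTACGTAT"))
#' evolutionary_distance(aln, model = "JC69")
evolutionary_distance <- function(aln,
                                  model = c("K80", "p", "JC69", "TN93"),
                                  deletion = c("complete", "pairwise")) {
  stopifnot(inherits(aln, "marker_alignment"))
  model <- match.arg(model)
  deletion <- match.arg(deletion)
  m <- seq_matrix(aln)
  if (nrow(m) < 2) abort("Need >= 2 taxa to compute distances.")
  ok <- m %in% c("A", "C", "G", "T")
  dim(ok) <- dim(m)
  if (deletion == "complete") {
    keep <- apply(ok, 2, all)
    m <- m[, keep, drop = FALSE]
    ok <- ok[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      use <- ok[i, ] & ok[j, ]
      if (!any(use)) {
        abort(sprintf("No comparable sites between '%s' and '%s'.",
                      aln$taxa[i], aln$taxa[j]))
      }
      x <- m[i, use]; y <- m[j, use]
      d[i, j] <- d[j, i] <-
        pair_distance(x, y, model, aln$taxa[i], aln$taxa[j])
    }
  }
  attr(d, "model") <- model
  d
}

pair_distance <- function(x, y, model, name_i, name_j) {
  n <- length(x)
  diff <- x != y
  p <- mean(diff)
  if (p == 0) return(0)
  saturated <- function(what) {
    abort(sprintf("Saturated distance (%s) between '%s' and '%s'.",
                  what, name_i, name_j))
  }
  purine <- function(b) b %in% c("A", "G")
  is_transition <- diff & (purine(x) == purine(y))
  P <- mean(is_transition)        # transitions
  Q <- p - P                      # transversions
  switch(model,
    p = p,
    JC69 = {
      arg <- 1 - 4 * p / 3
      if (arg <= 0) saturated("JC69")
      -0.75 * log(arg)
    },
    K80 = {
      a1 <- 1 - 2 * P - Q
      a2 <- 1 - 2 * Q
      if (a1 <= 0 || a2 <= 0) saturated("K80")
      -0.5 * log(a1) - 0.25 * log(a2)
    },
    TN93 = {
      b <- factor(c(x, y), levels = c("A", "C", "G", "T"))
      f <- as.numeric(table(b)) / (2 * n)
      gA <- f[1]; gC <- f[2]; gG <- f[3]; gT <- f[4]
      gR <- gA + gG; gY <- gC + gT
      P1 <- mean(diff & x %in% c("A", "G") & y %in% c("A", "G"))
      P2 <- mean(diff & x %in% c("C", "T") & y %in% c("C", "T"))
      if (gA * gG == 0 || gC * gT == 0 || gR * gY == 0) {
        abort(sprintf(
          "Degenerate base composition between '%s' and '%s' for TN93.",
          name_i, name_j
        ))
      }
      k1 <- 2 * gA * gG / gR
      k2 <- 2 * gT * gC / gY
      k3 <- 2 * (gR * gY - gA * gG * gY / gR - gT * gC * gR / gY)
      a1 <- 1 - P1 / k1 - Q / (2 * gR)
      a2 <- 1 - P2 / k2 - Q / (2 * gY)
      a3 <- 1 - Q / (2 * gR * gY)
      if (a1 <= 0 || a2 <= 0 || a3 <= 0) saturated("TN93")
      -k1 * log(a1) - k2 * log(a2) - k3 * log(a3)
    }
  )
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration (via `ape::nj`). For an additive input matrix the
#' tree's path-length matrix reproduces the input exactly (up to numerical
#' error); negative branch lengths are kept by default so that exactness is
#' preserved, with `clamp_negative = TRUE` available for display.
#'
#' @param d Labeled symmetric distance matrix (>= 3 taxa).
#' @param clamp_negative Set negative branch lengths to zero.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d, clamp_negative = FALSE) {
  d <- as_distance_matrix(d)
  if (nrow(d) < 3) abort("Neighbor-joining needs >= 3 taxa.")
  phy <- ape::nj(as.dist(d))
  if (clamp_negative) phy$edge.length <- pmax(phy$edge.length, 0)
  phy
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree for
#' each replicate and scores every internal bipartition of the full-data
#' tree by the percentage of replicate trees containing it. Replicates whose
#' distance matrix fails (e.g. saturation) are skipped and counted; support
#' percentages are over the successful replicates. Deterministic in `seed`.
#'
#' @inheritParams evolutionary_distance
#' @param n_reps Number of bootstrap replicates (>= 1); the study design
#'   uses 1000.
#' @param seed Integer seed.
#' @return The full-data NJ `phylo` tree with integer percentage supports in
#'   `node.label` and attributes `n_reps`, `n_failed`.
#' @export
bootstrap_support <- function(aln, model = "K80", n_reps = 1000, seed = 1L,
                              deletion = "complete") {
  stopifnot(inherits(aln, "marker_alignment"))
  if (n_reps < 1) abort("`n_reps` must be >= 1.")
  full <- neighbor_joining(evolutionary_distance(aln, model, deletion))
  m <- seq_matrix(aln)
  n_sites <- ncol(m)
  boots <- list()
  n_failed <- 0L
  with_seed(seed, {
    for (r in seq_len(n_reps)) {
      cols <- sample.int(n_sites, n_sites, replace = TRUE)
      rep_aln <- marker_alignment(
        setNames(apply(m[, cols, drop = FALSE], 1, paste, collapse = ""),
                 aln$taxa),
        locus = aln$locus
      )
      tr <- tryCatch(
        neighbor_joining(evolutionary_distance(rep_aln, model, deletion)),
        error = function(e) NULL
      )
      if (is.null(tr)) n_failed <- n_failed + 1L else boots[[length(boots) + 1]] <- tr
    }
  })
  if (length(boots) == 0) abort("All bootstrap replicates failed.")
  counts <- ape::prop.clades(full, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  full$node.label <- as.integer(round(100 * counts / length(boots)))
  attr(full, "n_reps") <- as.integer(n_reps)
  attr(full, "n_failed") <- n_failed
  if (n_failed > 0) {
    inform(sprintf("bootstrap_support: %d of %d replicates failed and were skipped.",
                   n_failed, n_reps))
  }
  full
}

#' Write a tree as Newick
#'
#' Branch lengths are always written; bootstrap supports (if present) become
#' internal node labels. Leaf labels containing spaces or Newick
#' metacharacters are single-quoted ([read_newick()] strips the quotes
#' again).
#'
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  needs_quote <- which(grepl("[][ ():,;]", tree$tip.label))
  originals <- tree$tip.label[needs_quote]
  # write.tree mangles awkward labels; write placeholders, then splice the
  # quoted originals into the serialized string
  tree$tip.label[needs_quote] <- sprintf("xQUOTEMEx%dx", seq_along(needs_quote))
  txt <- ape::write.tree(tree)
  for (i in seq_along(needs_quote)) {
    txt <- sub(sprintf("xQUOTEMEx%dx", i), paste0("'", originals[i], "'"),
               txt, fixed = TRUE)
  }
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick tree
#'
#' Thin wrapper over `ape::read.tree` that strips the single quotes
#' [write_newick()] places around awkward leaf labels.
#'
#' @param path Newick file path.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) abort(sprintf("Could not parse Newick file: %s", path))
  tr$tip.label <- sub("^'(.*)'$", "\\1", tr$tip.label)
  tr
}
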