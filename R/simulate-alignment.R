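#' Simulate an aligned marker locus on a tree
#'
#' Evolves ungapped DNA sequences along a rooted tree under the Jukes-Cantor
#' (JC69) model: the root sequence is uniform over A/C/G/T and every site
#' evolves independently on each branch, substituting with probability
#' `3/4 * (1 - exp(-4 * b * rate / 3))` for branch length `b`
#' (substitutions/site) and landing uniformly on one of the three other
#' bases. Output is deterministic in `seed`.
#'
#' @param tree Newick string or `phylo` object; branch lengths finite, >= 0.
#' @param length Number of alignment columns (>= 1).
#' @param rate_multiplier Locus rate multiplier (>= 0); 0 yields identical
#'   sequences.
#' @param seed Integer seed.
#' @param locus Locus name stored on the alignment.
#' @return A `marker_alignment`: locus name, taxa and equal-length aligned
#'   sequences.
#' @export
#' @examples
#' aln <- simulate_marker_alignment("((A:0.1,B:0.1):0.05,(C:0.1,D:0.1):0.05);",
#'                                  length = 200, seed = 7)
#' aln
simulate_marker_alignment <- function(tree, length, rate_multiplier = 1,
                                      seed = 1L, locus = "locus") {
  phy <- parse_tree(tree)
  if (!is.numeric(length) || length < 1) abort("`length` must be a positive integer.")
  if (rate_multiplier < 0) abort("`rate_multiplier` must be >= 0.")
  length <- as.integer(length)
  bases <- c("A", "C", "G", "T")
  n_node <- max(phy$edge)
  with_seed(seed, {
    seqs <- vector("list", n_node)
    root <- phy$edge[1, 1]
    seqs[[root]] <- sample(bases, length, replace = TRUE)
    done <- rep(FALSE, n_node); done[root] <- TRUE
    pending <- seq_len(nrow(phy$edge))
    while (length(pending)) {
      progressed <- FALSE
      keep <- integer()
      for (e in pending) {
        from <- phy$edge[e, 1]; to <- phy$edge[e, 2]
        if (!done[from]) { keep <- c(keep, e); next }
        p_sub <- 0.75 * (1 - exp(-4 * phy$edge.length[e] * rate_multiplier / 3))
        s <- seqs[[from]]
        hit <- which(runif(length) < p_sub)
        if (length(hit)) {
          # uniform over the three other bases
          shift <- sample.int(3, length(hit), replace = TRUE)
          idx <- (match(s[hit], bases) - 1L + shift) %% 4L + 1L
          s[hit] <- bases[idx]
        }
        seqs[[to]] <- s
        done[to] <- TRUE
        progressed <- TRUE
      }
      if (!progressed) abort("Malformed tree: edge table is not connected.")
      pending <- keep
    }
    tips <- seq_along(phy$tip.label)
    out <- vapply(tips, function(i) paste(seqs[[i]], collapse = ""), character(1))
    marker_alignment(setNames(out, phy$tip.label), locus = locus)
  })
}

#' Simulate every locus of a scenario
#'
#' One [simulate_marker_alignment()] call per row of the scenario's locus
#' table, each on its jittered gene tree (see [locus_trees()]) with a
#' locus-specific seed derived from the scenario seed.
#'
#' @inheritParams locus_trees
#' @return Named list of `marker_alignment` objects.
#' @export
simulate_locus_alignments <- function(scenario) {
  stopifnot(inherits(scenario, "scenario_config"))
  setNames(
    lapply(scenario$locus_specs$locus, simulate_locus_alignment,
           scenario = scenario),
    scenario$locus_specs$locus
  )
}

#' @rdname simulate_locus_alignments
#' @param locus Locus name. The alignment for one locus is identical whether
#'   simulated alone or as part of [simulate_locus_alignments()].
#' @export
simulate_locus_alignment <- function(scenario, locus) {
  stopifnot(inherits(scenario, "scenario_config"))
  spec_row <- scenario$locus_specs[scenario$locus_specs$locus == locus, ]
  if (nrow(spec_row) == 0) abort(sprintf("Unknown locus '%s'.", locus))
  phy <- locus_trees(scenario)[[locus]]
  simulate_marker_alignment(
    phy, spec_row$length,
    rate_multiplier = 1, # rate already folded into the gene tree
    seed = child_seed(scenario$seed, paste0("aln::", locus)),
    locus = locus
  )
}
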