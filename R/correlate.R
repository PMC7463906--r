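#' Euclidean distance matrix between profiles
#'
#' @param profiles Numeric matrix (items in rows, labels as rownames), or a
#'   `feature_table` / `spectrum_set` whose intensity/absorbance matrix is
#'   used.
#' @return Labeled symmetric distance matrix.
#' @export
profile_distance <- function(profiles) {
  if (inherits(profiles, "feature_table")) profiles <- intensity_matrix(profiles)
  if (inherits(profiles, "spectrum_set")) profiles <- profiles$absorbance
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2) abort("Need >= 2 profiles.")
  if (is.null(rownames(profiles))) abort("Profiles need rownames as labels.")
  as_distance_matrix(as.matrix(dist(profiles)))
}

# all permutations of 1..n as an n! x n matrix
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

#' Mantel-style correlation between two distance matrices
#'
#' Pearson correlation between the lower-triangle vectors of two labeled
#' distance matrices, aligned by label (order-insensitive). Significance is
#' by Mantel row/column permutation of the second matrix — exhaustive over
#' all `n!` label permutations when `n! <= n_perm` (always, for 4-6 items),
#' sampled with `p = (1 + #{|r*| >= |r|}) / (1 + n_perm)` otherwise. The
#' parametric t p-value (`t = r * sqrt(m - 2) / sqrt(1 - r^2)` on the
#' `m = n(n-1)/2` pairs) is what naive `cor.test` on distance vectors
#' reports; it ignores pair dependence and is anti-conservative, so
#' permutation is the default.
#'
#' @param d1,d2 Labeled symmetric matrices over identical label sets.
#' @param method `"permutation"` or `"parametric_t"`.
#' @param n_perm Permutation budget for the sampled test.
#' @param seed Seed for the sampled test.
#' @return One-row tibble: r, p_value, n_items, n_pairs, method, exhaustive,
#'   seed.
#' @export
#' @examples
#' d <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
#'             dimnames = list(letters[1:3], letters[1:3]))
#' matrix_correlation(d, d)$r # 1
matrix_correlation <- function(d1, d2, method = c("permutation", "parametric_t"),
                               n_perm = 9999, seed = 1L) {
  method <- match.arg(method)
  d1 <- as_distance_matrix_loose(d1)
  d2 <- as_distance_matrix_loose(d2)
  if (!setequal(rownames(d1), rownames(d2))) {
    abort(sprintf(
      "Label sets differ (only in first: %s; only in second: %s).",
      paste(setdiff(rownames(d1), rownames(d2)), collapse = ",") ,
      paste(setdiff(rownames(d2), rownames(d1)), collapse = ",")
    ))
  }
  labs <- sort(rownames(d1))
  n <- length(labs)
  if (n < 3) abort("Matrix correlation needs >= 3 items.")
  v1 <- lower_triangle(d1, labs)
  v2 <- lower_triangle(d2, labs)
  if (sd(v1) == 0 || sd(v2) == 0) {
    abort("Zero-variance lower triangle; correlation is undefined.")
  }
  r <- cor(v1, v2)
  m <- length(v1)
  if (method == "parametric_t") {
    t_stat <- r * sqrt(m - 2) / sqrt(1 - r^2)
    p <- 2 * pt(-abs(t_stat), df = m - 2)
    exhaustive <- NA
  } else if (factorial(n) <= n_perm) {
    P <- all_permutations(n)
    r_perm <- apply(P, 1, function(idx) {
      cor(v1, lower_triangle(d2[labs, labs][idx, idx]))
    })
    p <- mean(abs(r_perm) >= abs(r) - 1e-12)
    exhaustive <- TRUE
  } else {
    r_perm <- with_seed(seed, {
      vapply(seq_len(n_perm), function(i) {
        idx <- sample.int(n)
        cor(v1, lower_triangle(d2[labs, labs][idx, idx]))
      }, numeric(1))
    })
    p <- (1 + sum(abs(r_perm) >= abs(r) - 1e-12)) / (1 + n_perm)
    exhaustive <- FALSE
  }
  tibble::tibble(
    r = r, p_value = p, n_items = n, n_pairs = m,
    method = method, exhaustive = exhaustive,
    seed = if (isFALSE(exhaustive)) as.integer(seed) else NA_integer_
  )
}

# distances from profiles may legally be asymmetric only by fp noise; the
# correlation-derived matrices elsewhere are NOT distances, so only shape,
# labels and finiteness are enforced here plus symmetry.
as_distance_matrix_loose <- function(m) {
  stop_if_not_square(m, "matrix")
  if (any(!is.finite(m))) abort("Matrix contains non-finite values.")
  if (max(abs(m - t(m))) > 1e-8) abort("Matrix is not symmetric.")
  m
}
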