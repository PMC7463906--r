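# internal helpers shared across modules

# run expr with a local RNG state seeded by `seed`; restores global state
with_seed <- function(seed, expr) {
  if (!is.null(old <- get0(".Random.seed", envir = globalenv()))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# derive a stream-specific child seed below 2^31 from a master seed
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(paste0(stream)) * seq_along(utf8ToInt(paste0(stream))))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483629L)
}

# lower-triangle vector of a labeled square matrix, fixed label order
lower_triangle <- function(m, labels = NULL) {
  if (!is.null(labels)) m <- m[labels, labels, drop = FALSE]
  m[lower.tri(m)]
}

stop_if_not_square <- function(m, arg = "matrix") {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort(sprintf("`%s` must be a square matrix.", arg))
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    abort(sprintf("`%s` must have row and column labels.", arg))
  }
  if (!identical(rownames(m), colnames(m))) {
    abort(sprintf("`%s` row and column labels differ.", arg))
  }
  invisible(m)
}

# validated labeled symmetric distance matrix
as_distance_matrix <- function(m, tol = 1e-8) {
  stop_if_not_square(m, "distance matrix")
  if (any(!is.finite(m))) abort("Distance matrix contains non-finite values.")
  if (max(abs(m - t(m))) > tol) abort("Distance matrix is not symmetric.")
  if (max(abs(diag(m))) > tol) abort("Distance matrix diagonal is not zero.")
  m
}
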