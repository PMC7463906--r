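#' PLS-DA with VIP scores
#'
#' Partial least squares discriminant analysis: PLS2 via NIPALS on the
#' one-hot (column-centered) class indicator matrix, then variable
#' importance in projection per metabolite:
#'
#' `VIP_j = sqrt( p * sum_a( SSY_a * (w_aj / ||w_a||)^2 ) / sum_a(SSY_a) )`
#'
#' with `p` the number of metabolites and `SSY_a` the Y-variance explained
#' by component `a` (`q_a^2 * t_a' t_a`). Because each weight vector has
#' unit norm, the mean of squared VIPs equals 1 exactly — the basis of the
#' "greater than one" selection rule.
#'
#' Deflation that produces a zero-norm weight vector stops extraction early
#' with a message; the result records the achieved number of components.
#'
#' @param table A Pareto-scaled `feature_table`.
#' @param class_labels Factor-like class labels, one per sample (>= 2
#'   classes); defaults to the strain column.
#' @param n_components Number of PLS components (the default 2 suits small
#'   class designs); must be `<= min(samples - 1, metabolites)`.
#' @param tol,max_iter NIPALS convergence controls.
#' @return An object of class `plsda_vip`: tibble of VIP scores plus fit
#'   internals; see [tidy.plsda_vip()] and [glance.plsda_vip()].
#' @export
#' @examples
#' sc <- scenario_config(seed = 3)
#' ft <- simulate_feature_table(sc, n_metabolites = 20) |>
#'   iqr_filter() |> median_normalize() |> pareto_scale()
#' fit <- plsda_vip(ft)
#' mean(tidy(fit)$vip^2) # 1 by construction
plsda_vip <- function(table, class_labels = NULL, n_components = 2,
                      tol = 1e-10, max_iter = 500) {
  require_state(table, "scaled", "plsda_vip")
  X <- intensity_matrix(table)
  if (is.null(class_labels)) class_labels <- table$strain
  class_labels <- as.factor(class_labels)
  if (length(class_labels) != nrow(X)) {
    abort("`class_labels` must have one label per sample.")
  }
  if (nlevels(droplevels(class_labels)) < 2) {
    abort("PLS-DA needs >= 2 classes.")
  }
  n <- nrow(X); p <- ncol(X)
  if (n_components < 1 || n_components > min(n - 1, p)) {
    abort("`n_components` must be in [1, min(samples - 1, metabolites)].")
  }
  Y <- stats::model.matrix(~ class_labels - 1)
  colnames(Y) <- levels(class_labels)
  Y <- scale(Y, center = TRUE, scale = FALSE)

  W <- matrix(0, p, 0); ssy <- numeric(0)
  Xa <- X; Ya <- Y
  achieved <- 0L
  for (a in seq_len(n_components)) {
    u <- Ya[, which.max(apply(Ya, 2, var))]
    w <- numeric(p); t_old <- NULL
    for (it in seq_len(max_iter)) {
      w <- drop(crossprod(Xa, u))
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      t_scr <- drop(Xa %*% w)
      q <- drop(crossprod(Ya, t_scr)) / sum(t_scr^2)
      u <- drop(Ya %*% q) / sum(q^2)
      if (!is.null(t_old) && sqrt(sum((t_scr - t_old)^2)) < tol * sqrt(sum(t_scr^2))) break
      t_old <- t_scr
    }
    if (sqrt(sum(w^2)) < tol || sum(w^2) == 0) {
      inform(sprintf("plsda_vip: deflation degenerate at component %d; stopping early.", a))
      break
    }
    t_scr <- drop(Xa %*% w)
    tt <- sum(t_scr^2)
    if (tt < tol) {
      inform(sprintf("plsda_vip: zero-variance score at component %d; stopping early.", a))
      break
    }
    p_load <- drop(crossprod(Xa, t_scr)) / tt
    q <- drop(crossprod(Ya, t_scr)) / tt
    Xa <- Xa - tcrossprod(t_scr, p_load)
    Ya <- Ya - tcrossprod(t_scr, q)
    W <- cbind(W, w)
    ssy <- c(ssy, sum(q^2) * tt)
    achieved <- a
  }
  if (achieved == 0) abort("PLS-DA extracted no components.")
  # weights already unit-norm; VIP formula
  vip <- sqrt(p * drop(W^2 %*% ssy) / sum(ssy))
  structure(
    list(
      vip = tibble::tibble(metabolite = colnames(X), vip = unname(vip)),
      n_components = achieved,
      class_labels = class_labels,
      weights = W,
      ssy = ssy,
      n_samples = n,
      n_metabolites = p
    ),
    class = "plsda_vip"
  )
}

#' @export
print.plsda_vip <- function(x, ...) {
  cat(sprintf("<plsda_vip> %d metabolites, %d samples, %d component(s), %d classes\n",
              x$n_metabolites, x$n_samples, x$n_components,
              nlevels(x$class_labels)))
  cat(sprintf("  mean(VIP^2) = %.9f; %d metabolite(s) with VIP > 1\n",
              mean(x$vip$vip^2), sum(x$vip$vip > 1)))
  invisible(x)
}

#' Tidy a PLS-DA VIP fit
#' @param x A `plsda_vip` object.
#' @param ... Unused.
#' @return Tibble: metabolite, vip, selected (VIP > 1).
#' @export
tidy.plsda_vip <- function(x, ...) {
  dplyr::mutate(x$vip, selected = .data$vip > 1)
}

#' One-row fit summary
#' @param x A `plsda_vip` object.
#' @param ... Unused.
#' @return Tibble: n_samples, n_metabolites, n_components, n_classes,
#'   mean_vip_sq, n_selected.
#' @export
glance.plsda_vip <- function(x, ...) {
  tibble::tibble(
    n_samples = x$n_samples,
    n_metabolites = x$n_metabolites,
    n_components = x$n_components,
    n_classes = nlevels(x$class_labels),
    mean_vip_sq = mean(x$vip$vip^2),
    n_selected = sum(x$vip$vip > 1)
  )
}

#' @export
autoplot.plsda_vip <- function(object, top = 25, ...) {
  tidy(object) |>
    dplyr::slice_max(.data$vip, n = top) |>
    ggplot2::ggplot(ggplot2::aes(
      x = .data$vip, y = stats::reorder(.data$metabolite, .data$vip),
      fill = .data$selected
    )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::labs(x = "VIP score", y = NULL, fill = "VIP > 1")
}

#' Select discriminant metabolites by the VIP > 1 rule
#'
#' Since the mean squared VIP is exactly 1, metabolites scoring strictly
#' above 1 contribute more than average to class separation.
#'
#' @param fit A `plsda_vip` object.
#' @param threshold Strict selection threshold (default 1).
#' @return Character vector of metabolite names, input order preserved.
#' @export
select_discriminant <- function(fit, threshold = 1) {
  stopifnot(inherits(fit, "plsda_vip"))
  fit$vip$metabolite[fit$vip$vip > threshold]
}
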