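#' Variable influence on projection (VIP) scores
#'
#' VIP_j = sqrt( p * sum_a[ SSY_a * (w_aj / ||w_a||)^2 ] / sum_a SSY_a ),
#' where p is the number of variables, w_a the a-th weight vector and SSY_a
#' the response sum of squares explained by component a. By construction the
#' mean squared VIP over variables equals 1, so VIP = 1 marks average
#' influence and cutoffs around 1 select above-average variables.
#'
#' @param model A fitted `pls_model`.
#' @param cutoff Threshold recorded in the result (used by
#'   [select_by_vip()]); default 1.
#' @return A `vip_result` with fields `vip` (named per-variable scores),
#'   `cutoff`, `retained_mask` and `retained_count` (strict `vip > cutoff`).
#' @export
vip_scores <- function(model, cutoff = 1) {
  stopifnot(inherits(model, "pls_model"))
  ssy <- model$ssy_per_component
  if (all(ssy == 0)) stop("all components explain zero Y variance", call. = FALSE)
  W <- model$W
  p <- nrow(W)
  wn2 <- colSums(W^2)                     # ||w_a||^2 (1 by construction)
  contrib <- sweep(W^2, 2, wn2, "/")      # (w_aj/||w_a||)^2
  vip <- sqrt(p * as.numeric(contrib %*% ssy) / sum(ssy))
  names(vip) <- model$variable_ids
  mask <- vip > cutoff
  structure(list(vip = vip, cutoff = cutoff, retained_mask = mask,
                 retained_count = sum(mask)),
            class = "vip_result")
}

#' Select variables by VIP cutoff
#'
#' Retains variables with VIP strictly greater than the cutoff.
#'
#' @param vip A `vip_result` from [vip_scores()].
#' @param cutoff Non-negative threshold.
#' @return Character vector (or integer indices when variables are unnamed)
#'   of retained variable ids, with attribute `"mask"`. Zero retained
#'   variables raise an empty-selection error (condition class
#'   `"ftirpls_empty_selection"`), which grid code treats as an infeasible
#'   cell rather than a failure.
#' @export
select_by_vip <- function(vip, cutoff) {
  stopifnot(inherits(vip, "vip_result"))
  if (cutoff < 0) stop("cutoff must be >= 0", call. = FALSE)
  mask <- vip$vip > cutoff
  if (!any(mask)) {
    stop(structure(class = c("ftirpls_empty_selection", "error", "condition"),
                   list(message = sprintf(
                          "no variable has VIP > %.3g (max VIP %.3g)",
                          cutoff, max(vip$vip)),
                        call = sys.call(-1))))
  }
  ids <- if (is.null(names(vip$vip))) which(mask) else names(vip$vip)[mask]
  attr(ids, "mask") <- mask
  ids
}

#' Principal component analysis of a spectral matrix
#'
#' Thin wrapper around the singular-value decomposition of the
#' column-centered (optionally scaled) matrix, returning the pieces used for
#' score plots.
#'
#' @param X Numeric matrix, samples in rows.
#' @param n_components Number of components, at most `min(n - 1, p)`.
#' @param scaling Optional column scaling applied first
#'   (`"center_only"` default; `"uv"` or `"pareto"` as in [scale_columns()]).
#' @return List with `scores`, `loadings` and `explained` (variance
#'   fractions).
#' @export
pca_spectra <- function(X, n_components = 2L,
                        scaling = c("center_only", "uv", "pareto")) {
  scaling <- match.arg(scaling)
  Xs <- scale_columns(X, scaling)$X
  r <- min(nrow(Xs) - 1, ncol(Xs))
  if (n_components > r) {
    stop("n_components must be <= min(n - 1, p) = ", r, call. = FALSE)
  }
  sv <- svd(Xs, nu = n_components, nv = n_components)
  ev <- sv$d^2 / sum(sv$d^2)
  list(scores = sv$u %*% diag(sv$d[seq_len(n_components)],
                              n_components, n_components),
       loadings = sv$v,
       explained = ev[seq_len(n_components)])
}
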