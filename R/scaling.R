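#' Column scaling for multivariate modelling
#'
#' Mean-centers every column and divides by a method-dependent factor:
#' the column standard deviation for unit-variance (`"uv"`) scaling, its
#' square root for Pareto scaling, or 1 for centering only. Columns that are
#' constant (zero variance) cannot be uv/pareto scaled and are dropped with
#' a warning.
#'
#' @param X Numeric matrix, samples in rows.
#' @param method `"uv"`, `"pareto"` or `"center_only"`.
#' @return List with `X` (the scaled matrix, possibly with constant columns
#'   dropped) and `spec`, a `scaling_spec` storing means, divisors and the
#'   retained-column indices for application to new data.
#' @export
scale_columns <- function(X, method = c("uv", "pareto", "center_only")) {
  method <- match.arg(method)
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("scaling needs >= 2 samples", call. = FALSE)
  mu <- colMeans(X)
  sdv <- sqrt(colSums(sweep(X, 2, mu)^2) / (nrow(X) - 1))
  keep <- seq_len(ncol(X))
  if (method != "center_only" && any(sdv == 0)) {
    warning(sum(sdv == 0), " constant column(s) dropped before ", method,
            " scaling", call. = FALSE)
    keep <- which(sdv > 0)
    if (!length(keep)) stop("all columns constant", call. = FALSE)
  }
  scales <- switch(method,
                   uv = sdv[keep],
                   pareto = sqrt(sdv[keep]),
                   center_only = rep(1, length(keep)))
  spec <- structure(list(method = method, column_means = mu[keep],
                         column_scales = scales, keep = keep,
                         colnames = colnames(X)[keep]),
                    class = "scaling_spec")
  list(X = apply_scaling(X, spec), spec = spec)
}

#' Apply a stored scaling specification to new data
#'
#' @param X Numeric matrix whose columns match the matrix the spec was
#'   fitted on.
#' @param spec A `scaling_spec` from [scale_columns()].
#' @return The centered and scaled matrix restricted to the retained columns.
#' @export
apply_scaling <- function(X, spec) {
  stopifnot(inherits(spec, "scaling_spec"))
  X <- as.matrix(X)[, spec$keep, drop = FALSE]
  sweep(sweep(X, 2, spec$column_means), 2, spec$column_scales, "/")
}

#' Dummy-code class labels for PLS-DA
#'
#' Two classes yield a single 0/1 column (first level 0, second level 1), so
#' prediction errors are in class units and a 12-month class gap converts
#' directly to months. Three or more classes yield one indicator column per
#' class.
#'
#' @param labels Factor or character vector of class labels.
#' @return Numeric response matrix with `length(labels)` rows; the class
#'   levels are stored in attribute `"class_levels"`.
#' @export
dummy_code <- function(labels) {
  f <- if (is.factor(labels)) droplevels(labels) else factor(labels)
  k <- nlevels(f)
  if (k < 2) stop("need >= 2 classes, got ", k, call. = FALSE)
  Y <- if (k == 2) {
    matrix(as.numeric(f) - 1, ncol = 1,
           dimnames = list(NULL, levels(f)[2]))
  } else {
    m <- stats::model.matrix(~ f - 1)
    dimnames(m) <- list(NULL, levels(f))
    attributes(m)[c("assign", "contrasts")] <- NULL
    m
  }
  attr(Y, "class_levels") <- levels(f)
  Y
}
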