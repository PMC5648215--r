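#' Permutation test with R2Y / Q2Y intercepts
#'
#' Refits the model under `n_permutations` random permutations of the
#' response rows, records for each permuted fit the statistic triple
#' (correlation with the original response, R2Y, Q2Y), appends the original
#' model at correlation 1, and fits ordinary least-squares lines to the R2Y
#' and Q2Y points as functions of the correlation. The intercepts of these
#' lines at correlation 0 estimate the fit and predictability a chance model
#' would attain: a model is considered valid when the R2Y intercept is below
#' 0.4 and the Q2Y intercept below 0.05.
#'
#' The correlation statistic is the mean over response columns of the
#' absolute Pearson correlation between permuted and original column. Q2Y
#' inside the loop uses the same fold scheme as the original model so
#' differences reflect label permutation only.
#'
#' @param X Unscaled predictor matrix.
#' @param Y Response matrix or vector (uncentered; dummy-coded for PLS-DA).
#' @param ncomp Number of PLS components.
#' @param n_permutations Number of permutations (>= 20; default 400).
#' @param scaling X scaling method.
#' @param seed Integer seed driving the permutations.
#' @param n_folds,fold_scheme Cross-validation settings for Q2Y.
#' @param anchored Fit the intercept lines through the cloud by ordinary
#'   least squares (`FALSE`, default) or force them through the original
#'   model's point at correlation 1 (`TRUE`).
#' @return A `permutation_result` with the point cloud, both intercepts,
#'   the validity verdict and the seed.
#' @export
permutation_test <- function(X, Y, ncomp, n_permutations = 400L,
                             scaling = c("uv", "pareto", "center_only"),
                             seed = 1L, n_folds = 7L,
                             fold_scheme = c("venetian", "random"),
                             anchored = FALSE) {
  scaling <- match.arg(scaling)
  fold_scheme <- match.arg(fold_scheme)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n_permutations < 20) stop("n_permutations must be >= 20", call. = FALSE)
  if (all(apply(Y, 2, stats::sd) == 0)) {
    stop("constant response: permutation test undefined", call. = FALSE)
  }
  # X never changes across permutations: scale it (and each CV fold) once
  Xs <- scale_columns(X, scaling)$X
  folds <- assign_folds(n, min(n_folds, n), fold_scheme, seed)
  fold_data <- lapply(unique(folds), function(k) {
    test <- folds == k
    sc <- scale_columns(X[!test, , drop = FALSE], scaling)
    list(test = test,
         Xtr = sc$X,
         Xte = apply_scaling(X[test, , drop = FALSE], sc$spec))
  })
  eval_labels <- function(Yp) {
    Ypc <- sweep(Yp, 2, colMeans(Yp))
    r2 <- nipals_pls(Xs, Ypc, ncomp)$r2y_cum[ncomp]
    press <- 0
    for (fd in fold_data) {
      ytr <- Yp[!fd$test, , drop = FALSE]
      mu <- colMeans(ytr)
      a_eff <- min(ncomp, nrow(fd$Xtr) - 1)
      f <- nipals_pls(fd$Xtr, sweep(ytr, 2, mu), a_eff)
      pred <- sweep(fd$Xte %*% f$B, 2, mu, "+")
      press <- press + sum((Yp[fd$test, , drop = FALSE] - pred)^2)
    }
    q2 <- 1 - press / sum(sweep(Yp, 2, colMeans(Yp))^2)
    c(r2, q2)
  }
  orig <- eval_labels(Y)
  r2_orig <- orig[1]; q2_orig <- orig[2]
  perms <- with_seed(seed, replicate(n_permutations, sample.int(n),
                                     simplify = FALSE))
  pts <- vapply(perms, function(ord) {
    Yp <- Y[ord, , drop = FALSE]
    corr <- mean(abs(diag(stats::cor(Yp, Y))))
    st <- eval_labels(Yp)
    c(correlation = corr, r2y = st[1], q2y = st[2])
  }, numeric(3))
  points <- rbind(data.frame(t(pts)),
                  data.frame(correlation = 1, r2y = r2_orig, q2y = q2_orig))
  r2y_intercept <- line_intercept(points$correlation, points$r2y, anchored)
  q2y_intercept <- line_intercept(points$correlation, points$q2y, anchored)
  structure(list(n_permutations = n_permutations, points = points,
                 r2y_intercept = r2y_intercept,
                 q2y_intercept = q2y_intercept,
                 valid = is_valid_model(r2y_intercept, q2y_intercept),
                 r2y = r2_orig, q2y = q2_orig, seed = seed,
                 anchored = anchored),
            class = "permutation_result")
}

# intercept at x = 0 of a least-squares line through (x, y); `anchored`
# forces the line through the last point (the original model at x = 1)
line_intercept <- function(x, y, anchored = FALSE) {
  if (stats::sd(x) == 0) return(mean(y))
  if (anchored) {
    n <- length(x)
    x0 <- x[n]; y0 <- y[n]
    dx <- x - x0; dy <- y - y0
    slope <- sum(dx * dy) / sum(dx^2)
    y0 - slope * x0
  } else {
    unname(stats::coef(stats::lm(y ~ x))[1])
  }
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("<permutation_result> %d permutations, seed %d\n",
              x$n_permutations, x$seed))
  cat(sprintf("  R2Y=%.3f Q2Y=%.3f | intercepts: R2Y %.3f, Q2Y %.3f -> %s\n",
              x$r2y, x$q2y, x$r2y_intercept, x$q2y_intercept,
              if (x$valid) "valid" else "NOT valid"))
  invisible(x)
}

#' Validity gate on permutation intercepts
#'
#' A model is valid when the permutation R2Y intercept is strictly below
#' 0.4 and the Q2Y intercept strictly below 0.05.
#'
#' @param r2y_intercept,q2y_intercept Finite intercept values.
#' @param r2y_limit,q2y_limit Gate thresholds (defaults 0.4 and 0.05).
#' @return Logical.
#' @export
is_valid_model <- function(r2y_intercept, q2y_intercept,
                           r2y_limit = 0.4, q2y_limit = 0.05) {
  if (!is.finite(r2y_intercept) || !is.finite(q2y_intercept)) {
    stop("intercepts must be finite", call. = FALSE)
  }
  r2y_intercept < r2y_limit && q2y_intercept < q2y_limit
}

#' Export permutation points as a plain table
#'
#' @param x A `permutation_result`.
#' @param path Optional csv path; when given the table is also written.
#' @return Data frame with columns correlation, r2y, q2y (the last row is
#'   the unpermuted model).
#' @export
permutation_points <- function(x, path = NULL) {
  stopifnot(inherits(x, "permutation_result"))
  if (!is.null(path)) utils::write.csv(x$points, path, row.names = FALSE)
  x$points
}
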