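#' Fit a PLS model by NIPALS
#'
#' Component-wise NIPALS PLS2 with deflation of both blocks, the classic
#' algorithm behind commercial chemometrics software. `X` is scaled
#' internally according to `scaling`; `Y` (a dummy-coded class matrix for
#' PLS-DA or a numeric response for PLSR) is mean-centered internally.
#'
#' For each component the inner loop iterates
#' `w = X'u / ||X'u||`, `t = Xw`, `c = Y't / t't`, `u = Yc / c'c`
#' to convergence (tolerance 1e-10 on the relative change of `t`, at most
#' 500 iterations; single-response models converge in one pass), then
#' deflates `X` by the loading `p = X't / t't` and `Y` by `t c'`. The sign
#' of each weight vector is fixed so its largest-magnitude element is
#' positive, making output reproducible.
#'
#' @param X Numeric predictor matrix (samples x variables), unscaled.
#' @param Y Numeric response matrix or vector, uncentered.
#' @param ncomp Number of components A, `1 <= A <= min(n - 1, p)`.
#' @param scaling X scaling method passed to [scale_columns()].
#' @param class_labels Optional factor of class labels (stored for PLS-DA
#'   predictions).
#' @return A `pls_model` with weights `W`, X loadings `P`, Y loadings `C`,
#'   scores `T`, regression coefficients `B` (for scaled X and centered Y),
#'   per-component explained Y sum of squares `ssy_per_component`,
#'   cumulative `r2y_cum`, the X `scaling` spec and Y centers.
#' @export
fit_pls <- function(X, Y, ncomp, scaling = c("uv", "pareto", "center_only"),
                    class_labels = NULL) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row counts differ", call. = FALSE)
  sc <- scale_columns(X, scaling)
  y_means <- colMeans(Y)
  Yc <- sweep(Y, 2, y_means)
  fit <- nipals_pls(sc$X, Yc, ncomp)
  structure(c(fit,
              list(scaling = sc$spec, y_means = y_means,
                   variable_ids = sc$spec$colnames,
                   class_labels = class_labels,
                   class_levels = attr(Y, "class_levels"))),
            class = "pls_model")
}

# core NIPALS on already centered/scaled blocks
nipals_pls <- function(X, Y, ncomp, tol = 1e-10, max_iter = 500L) {
  n <- nrow(X); p <- ncol(X); m <- ncol(Y)
  ncomp <- as.integer(ncomp)
  if (ncomp < 1 || ncomp > min(n - 1, p)) {
    stop("ncomp must be in 1..min(n-1, p) = ", min(n - 1, p), call. = FALSE)
  }
  W <- matrix(0, p, ncomp); P <- matrix(0, p, ncomp)
  C <- matrix(0, m, ncomp); Tm <- matrix(0, n, ncomp)
  ssy <- numeric(ncomp); r2y <- numeric(ncomp)
  ss_tot <- sum(Y^2)
  if (ss_tot == 0) stop("response has zero variance", call. = FALSE)
  Xd <- X; Yd <- Y
  for (a in seq_len(ncomp)) {
    u <- Yd[, which.max(colSums(Yd^2)), drop = TRUE]
    t_old <- rep(Inf, n)
    for (it in seq_len(max_iter)) {
      w <- crossprod(Xd, u)[, 1]
      wn <- sqrt(sum(w^2))
      if (wn == 0) stop("NIPALS breakdown at component ", a, call. = FALSE)
      w <- w / wn
      t_vec <- Xd %*% w
      cc <- crossprod(Yd, t_vec)[, 1] / sum(t_vec^2)
      u <- (Yd %*% cc) / sum(cc^2)
      if (sqrt(sum((t_vec - t_old)^2)) <= tol * sqrt(sum(t_vec^2))) break
      t_old <- t_vec
      if (it == max_iter) {
        stop("NIPALS did not converge at component ", a, call. = FALSE)
      }
    }
    # reproducible sign: largest-|.| element of w positive
    s <- sign(w[which.max(abs(w))])
    w <- s * w; t_vec <- s * t_vec; cc <- s * cc
    tt <- sum(t_vec^2)
    p_vec <- crossprod(Xd, t_vec)[, 1] / tt
    Yhat_a <- tcrossprod(t_vec, cc)
    ssy[a] <- sum(Yhat_a^2)
    Xd <- Xd - tcrossprod(t_vec, p_vec)
    Yd <- Yd - Yhat_a
    W[, a] <- w; P[, a] <- p_vec; C[, a] <- cc; Tm[, a] <- t_vec
    r2y[a] <- 1 - sum(Yd^2) / ss_tot
  }
  # B for scaled X / centered Y: B = W (P'W)^-1 C'
  B <- W %*% solve(crossprod(P, W), t(C))
  list(ncomp = ncomp, W = W, P = P, C = C, T = Tm, B = B,
       ssy_per_component = ssy, r2y_cum = r2y, ss_tot_y = ss_tot)
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> A=%d, %d variables, %d samples, scaling=%s\n",
              x$ncomp, nrow(x$W), nrow(x$T), x$scaling$method))
  cat(sprintf("  R2Y(cum) = %s\n",
              paste(sprintf("%.3f", x$r2y_cum), collapse = " ")))
  invisible(x)
}

#' Predict responses (and classes) from a fitted PLS model
#'
#' Applies the stored column scaling, the regression coefficients, and the
#' response centering. For PLS-DA models (fitted with class labels) hard
#' class calls are added: threshold 0.5 on the single 0/1 column for two
#' classes, argmax over indicator columns otherwise.
#'
#' @param object A `pls_model`.
#' @param newdata Numeric matrix whose columns match the training variables
#'   (by name when both are named).
#' @param ... Unused.
#' @return List with `y` (numeric predictions) and, for PLS-DA, `class`.
#' @export
predict.pls_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  ids <- object$variable_ids
  if (!is.null(ids) && !is.null(colnames(X))) {
    missing <- setdiff(ids, colnames(X))
    if (length(missing)) {
      stop("newdata lacks variables: ",
           paste(utils::head(missing, 5), collapse = ", "),
           if (length(missing) > 5) ", ..." else "", call. = FALSE)
    }
    X <- X[, ids, drop = FALSE]
    Xs <- sweep(sweep(X, 2, object$scaling$column_means), 2,
                object$scaling$column_scales, "/")
  } else {
    if (ncol(X) != length(object$scaling$keep) &&
        ncol(X) >= max(object$scaling$keep)) {
      X <- X[, object$scaling$keep, drop = FALSE]
    }
    if (ncol(X) != length(object$scaling$column_means)) {
      stop("newdata has ", ncol(X), " columns; model expects ",
           length(object$scaling$column_means), call. = FALSE)
    }
    Xs <- sweep(sweep(X, 2, object$scaling$column_means), 2,
                object$scaling$column_scales, "/")
  }
  Yhat <- sweep(Xs %*% object$B, 2, object$y_means, "+")
  out <- list(y = Yhat)
  lv <- object$class_levels
  if (!is.null(lv)) {
    out$class <- if (length(lv) == 2) {
      factor(ifelse(Yhat[, 1] >= 0.5, lv[2], lv[1]), levels = lv)
    } else {
      factor(lv[max.col(Yhat, ties.method = "first")], levels = lv)
    }
  }
  out
}

#' Cross-validated predictive ability Q2Y
#'
#' Computes Q2Y = 1 - PRESS / SS, where PRESS accumulates squared
#' prediction errors over cross-validation folds and SS is the total sum of
#' squares of the mean-centered response. Folds are contiguous-interleaved
#' ("venetian blinds") over the sample order by default, or randomized under
#' `seed`. Scaling and centering are refit inside each training fold.
#'
#' @param X Unscaled predictor matrix.
#' @param Y Response matrix or vector (uncentered).
#' @param ncomp Number of PLS components.
#' @param n_folds Number of folds (default 7, at most `nrow(X)`).
#' @param scaling X scaling method.
#' @param fold_scheme `"venetian"` (interleaved by order) or `"random"`.
#' @param seed Integer seed for `fold_scheme = "random"`.
#' @return Q2Y (scalar).
#' @export
q2y <- function(X, Y, ncomp, n_folds = 7L,
                scaling = c("uv", "pareto", "center_only"),
                fold_scheme = c("venetian", "random"), seed = 1L) {
  scaling <- match.arg(scaling)
  fold_scheme <- match.arg(fold_scheme)
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X)
  if (n_folds < 2 || n_folds > n) {
    stop("n_folds must be in 2..n_samples", call. = FALSE)
  }
  folds <- assign_folds(n, n_folds, fold_scheme, seed)
  Yc <- sweep(Y, 2, colMeans(Y))
  ss_tot <- sum(Yc^2)
  press <- 0
  for (k in unique(folds)) {
    test <- folds == k
    fit <- fit_pls(X[!test, , drop = FALSE], Y[!test, , drop = FALSE],
                   ncomp = min(ncomp, sum(!test) - 1), scaling = scaling)
    pred <- predict(fit, X[test, , drop = FALSE])$y
    press <- press + sum((Y[test, , drop = FALSE] - pred)^2)
  }
  1 - press / ss_tot
}

assign_folds <- function(n, n_folds, fold_scheme, seed) {
  if (fold_scheme == "venetian") {
    ((seq_len(n) - 1L) %% n_folds) + 1L
  } else {
    with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  }
}

# evaluate code with a private RNG state, restoring the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' Root-mean-square errors of estimation and prediction
#'
#' `rmsee()` is the training-set error with the degrees-of-freedom
#' correction used by chemometrics software, `sqrt(SS_res / (n - 1 - A))`;
#' set `df_correct = FALSE` for the plain `sqrt(SS_res / n)`. `rmsep()` is
#' the root-mean-square prediction error on held-out data.
#'
#' @param model A fitted `pls_model`.
#' @param X Training predictor matrix (unscaled).
#' @param Y Training response.
#' @param df_correct Use the `n - 1 - A` divisor (default `TRUE`).
#' @return Scalar error in response units.
#' @export
rmsee <- function(model, X, Y, df_correct = TRUE) {
  Y <- as.matrix(Y)
  n <- nrow(Y)
  if (df_correct && n <= model$ncomp + 1) {
    stop("rmsee needs n_train > A + 1", call. = FALSE)
  }
  res <- Y - predict(model, X)$y
  div <- if (df_correct) n - 1 - model$ncomp else n
  sqrt(sum(res^2) / (div * ncol(Y)))
}

#' @rdname rmsee
#' @param X_test,Y_test Held-out predictors and responses.
#' @export
rmsep <- function(model, X_test, Y_test) {
  Y_test <- as.matrix(Y_test)
  res <- Y_test - predict(model, X_test)$y
  sqrt(mean(res^2))
}

#' Convert a class-unit RMSE to months
#'
#' With the two age classes dummy-coded 0/1 and 12 months apart, an RMSE of
#' 0.044 in class units corresponds to 0.528 months.
#'
#' @param rmse Non-negative RMSE in class units.
#' @param class_gap_months Months between adjacent classes (default 12).
#' @return RMSE expressed in months.
#' @export
rmse_to_months <- function(rmse, class_gap_months = 12) {
  if (any(rmse < 0)) stop("rmse must be >= 0", call. = FALSE)
  rmse * class_gap_months
}
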