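test_that("scale_columns meets the uv and pareto contracts", {
  X <- with_seed(1, matrix(stats::rnorm(60, sd = rep(c(1, 4, 0.5), each = 20)),
                           20, 3))
  uv <- scale_columns(X, "uv")
  expect_equal(unname(apply(uv$X, 2, stats::sd)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(colMeans(uv$X)), rep(0, 3), tolerance = 1e-12)

  par <- scale_columns(X, "pareto")
  sds <- apply(X, 2, stats::sd)
  expect_equal(unname(par$X), unname(sweep(X, 2, colMeans(X)) %*%
                                       diag(1 / sqrt(sds))), tolerance = 1e-12)

  # applying the stored spec to the training matrix reproduces fit output
  expect_equal(apply_scaling(X, uv$spec), uv$X, tolerance = 1e-12)

  # constant columns dropped with a warning under uv
  Xc <- cbind(X, 5)
  expect_warning(sc <- scale_columns(Xc, "uv"), "constant")
  expect_equal(ncol(sc$X), 3)
  expect_error(scale_columns(X[1, , drop = FALSE], "uv"), ">= 2")
})

test_that("dummy coding is 0/1 for two classes and one-hot for more", {
  expect_equal(unname(dummy_code(c("5yr", "6yr", "6yr"))[, 1]), c(0, 1, 1))
  Y3 <- dummy_code(factor(c("TR", "RH", "LR")))
  expect_equal(dim(Y3), c(3, 3))
  expect_equal(unname(rowSums(Y3)), rep(1, 3))
  expect_equal(diag(Y3[match(colnames(Y3), c("TR", "RH", "LR")), ]),
               rep(1, 3))
  expect_error(dummy_code(rep("a", 4)), "2 classes")
})

test_that("NIPALS recovers exact linear relationships", {
  # single predictor: one component suffices
  x <- with_seed(2, matrix(stats::rnorm(8), 8, 1))
  fit1 <- fit_pls(x, 3 * x[, 1], 1, scaling = "center_only")
  expect_equal(fit1$r2y_cum[1], 1, tolerance = 1e-9)
  # correlated predictors: full-rank component count reproduces the
  # least-squares fit, so any in-span response is fit exactly
  X <- with_seed(2, matrix(stats::rnorm(40), 8, 5))
  y <- 3 * X[, 2]
  fit <- fit_pls(X, y, 5, scaling = "center_only")
  expect_equal(fit$r2y_cum[5], 1, tolerance = 1e-9)
  expect_equal(unname(predict(fit, X)$y[, 1]), y, tolerance = 1e-6)
})

test_that("NIPALS first component matches the SVD of X'Y (oracle)", {
  dims <- with_seed(123, data.frame(n = sample(4:10, 50, TRUE),
                                    p = sample(2:10, 50, TRUE),
                                    m = sample(1:3, 50, TRUE)))
  for (seed in 1:50) {
    prob <- random_pls_problem(dims$n[seed], dims$p[seed], dims$m[seed],
                               seed = seed)
    Xc <- scale(prob$X, scale = FALSE)
    Yc <- scale(prob$Y, scale = FALSE)
    fit <- ftirpls:::nipals_pls(Xc, Yc, 1)
    u1 <- svd(crossprod(Xc, Yc))$u[, 1]
    u1 <- u1 * sign(u1[which.max(abs(u1))])
    expect_equal(fit$W[, 1], u1, tolerance = 1e-6)
  }
})

test_that("pls model invariants hold on random fits", {
  prob <- random_pls_problem(12, 8, 2, seed = 9)
  fit <- fit_pls(prob$X, prob$Y, 4, scaling = "uv")
  # scores mutually orthogonal
  G <- crossprod(fit$T)
  off <- G - diag(diag(G))
  expect_lt(max(abs(off)) / max(diag(G)), 1e-8)
  # r2y_cum non-decreasing and within [0, 1]
  expect_true(all(diff(fit$r2y_cum) >= -1e-12))
  expect_true(all(fit$r2y_cum >= 0 & fit$r2y_cum <= 1 + 1e-12))
  # B-route predictions equal the component-recursion route
  Xs <- apply_scaling(prob$X, fit$scaling)
  recursion <- Xs %*% fit$W %*% solve(crossprod(fit$P, fit$W)) %*% t(fit$C)
  expect_equal(Xs %*% fit$B, recursion, tolerance = 1e-9)
  # more components never reduce training R2Y
  fit1 <- fit_pls(prob$X, prob$Y, 1, scaling = "uv")
  expect_gte(fit$r2y_cum[4] + 1e-12, fit1$r2y_cum[1])
  expect_error(fit_pls(prob$X, prob$Y, 12, scaling = "uv"), "ncomp")
})

test_that("predict applies scaling, thresholds 2-class calls, argmaxes k-class", {
  prob <- random_pls_problem(10, 6, 1, seed = 4)
  labels <- factor(rep(c("5yr", "6yr"), 5))
  fit <- fit_pls(prob$X, dummy_code(labels), 2, scaling = "center_only",
                 class_labels = labels)
  # linearity under center_only: shifting a row by delta shifts the
  # prediction by the B-weighted delta
  delta <- rep(0.5, 6)
  p0 <- predict(fit, prob$X[1, , drop = FALSE])$y
  p1 <- predict(fit, matrix(prob$X[1, ] + delta, 1))$y
  expect_equal(p1 - p0, matrix(delta %*% fit$B, 1), tolerance = 1e-9)
  # residuals consistent with r2y_cum
  res <- dummy_code(labels) - predict(fit, prob$X)$y
  Yc <- scale(dummy_code(labels), scale = FALSE)
  expect_equal(1 - sum(res^2) / sum(Yc^2), fit$r2y_cum[2], tolerance = 1e-9)
  # hard calls at the 0.5 threshold
  calls <- predict(fit, prob$X)$class
  expect_s3_class(calls, "factor")
  expect_setequal(levels(calls), c("5yr", "6yr"))

  # column mismatch errors mention the missing variables
  colnames(prob$X) <- paste0("v", 1:6)
  fitn <- fit_pls(prob$X, dummy_code(labels), 1)
  Xbad <- prob$X[, 1:4]
  expect_error(predict(fitn, Xbad), "v5")
})

test_that("q2y is 1 for a perfect linear response and <= r2y generally", {
  X <- with_seed(6, matrix(stats::rnorm(120), 30, 4))
  y <- 2 * X[, 1] - X[, 3]
  expect_equal(q2y(X, y, 4, scaling = "center_only"), 1, tolerance = 1e-6)
  # q2y below training r2y on noisy data
  yn <- y + with_seed(7, stats::rnorm(30, sd = 2))
  fit <- fit_pls(X, yn, 2, scaling = "uv")
  expect_lt(q2y(X, yn, 2, scaling = "uv"), fit$r2y_cum[2])
})

test_that("q2y of pure noise is negative in expectation", {
  # simulation oracle: mean Q2Y over repeated noise draws must be < 0
  q <- vapply(1:200, function(i) {
    d <- with_seed(1000 + i, list(X = matrix(stats::rnorm(30 * 5), 30, 5),
                                  y = stats::rnorm(30)))
    q2y(d$X, d$y, 1, scaling = "uv")
  }, numeric(1))
  expect_lt(mean(q), 0)
})

test_that("rmsee uses the df-corrected divisor and rmsep is order-invariant", {
  # residuals (0.1, -0.1, 0.1, -0.1) with A = 1 -> sqrt(0.04 / 2)
  X <- matrix(c(1, 2, 3, 4), 4, 1)
  fit <- fit_pls(X, c(1, 2, 3, 4), 1, scaling = "center_only")
  fit$B[] <- 0  # force predictions to the mean
  y <- c(2.5 + 0.1, 2.5 - 0.1, 2.5 + 0.1, 2.5 - 0.1)
  fit$y_means <- 2.5
  expect_equal(rmsee(fit, X, y), sqrt(0.04 / 2), tolerance = 1e-12)
  expect_equal(rmsee(fit, X, y, df_correct = FALSE), sqrt(0.04 / 4),
               tolerance = 1e-12)

  prob <- random_pls_problem(10, 5, 1, seed = 12)
  f <- fit_pls(prob$X[1:6, ], prob$Y[1:6, ], 2, scaling = "center_only")
  Xt <- prob$X[7:10, ]; Yt <- prob$Y[7:10, , drop = FALSE]
  ord <- c(3, 1, 4, 2)
  expect_equal(rmsep(f, Xt, Yt), rmsep(f, Xt[ord, ], Yt[ord, , drop = FALSE]),
               tolerance = 1e-12)
  # perfect predictions give zero
  expect_equal(rmsep(f, Xt, predict(f, Xt)$y), 0, tolerance = 1e-12)
})

test_that("rmse_to_months multiplies by the 12-month class gap", {
  expect_equal(rmse_to_months(0.044), 0.528)
  expect_equal(rmse_to_months(0.096), 1.152)
  expect_equal(rmse_to_months(0), 0)
  expect_error(rmse_to_months(-0.1), ">= 0")
})

test_that("VIP matches the direct formula and satisfies its identity", {
  prob <- random_pls_problem(10, 6, 1, seed = 21)
  fit <- fit_pls(prob$X, prob$Y, 2, scaling = "uv")
  v <- vip_scores(fit)
  # direct-formula oracle from W and ssy
  p <- nrow(fit$W)
  ssy <- fit$ssy_per_component
  direct <- sqrt(p * rowSums(sweep(
    sweep(fit$W^2, 2, colSums(fit$W^2), "/"), 2, ssy, "*")) / sum(ssy))
  expect_equal(unname(v$vip), unname(direct), tolerance = 1e-9)
  # mean squared VIP = 1
  expect_equal(mean(v$vip^2), 1, tolerance = 1e-6)
  # uniform weights with A = 1 give VIP = 1 everywhere
  u <- fit
  u$W <- matrix(1 / sqrt(4), 4, 1)
  u$ssy_per_component <- 1
  u$variable_ids <- paste0("v", 1:4)
  uv <- vip_scores(u)
  expect_equal(unname(uv$vip), rep(1, 4), tolerance = 1e-12)
  # strict cutoff: all-equal VIP of 1 retains nothing at cutoff 1
  expect_error(select_by_vip(uv, 1), class = "ftirpls_empty_selection")
  # cutoff 0 retains everything
  expect_length(select_by_vip(v, 0), 6)
  expect_error(select_by_vip(v, max(v$vip) + 1),
               class = "ftirpls_empty_selection")
})

test_that("pca matches the covariance eigen-decomposition", {
  X <- with_seed(30, matrix(stats::rnorm(24), 6, 4))
  pc <- pca_spectra(X, 3)
  ev <- eigen(stats::cov(X))
  expect_equal(pc$explained[1:3],
               (ev$values / sum(ev$values))[1:3], tolerance = 1e-9)
  expect_equal(abs(pc$loadings[, 1]), abs(ev$vectors[, 1]), tolerance = 1e-9)
  # scores orthogonal
  G <- crossprod(pc$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  # rank-1 matrix: first component explains everything
  r1 <- tcrossprod(1:5, c(2, -1, 3)) + 1
  expect_equal(pca_spectra(r1, 1)$explained[1], 1, tolerance = 1e-9)
  expect_error(pca_spectra(X, 6), "n_components")
})

test_that("pls model text serialization round trips predictions", {
  prob <- random_pls_problem(10, 6, 1, seed = 33)
  colnames(prob$X) <- sprintf("%d", seq(1000, 980, by = -4))
  labels <- factor(rep(c("5yr", "6yr"), 5))
  fit <- fit_pls(prob$X, dummy_code(labels), 2, scaling = "uv",
                 class_labels = labels)
  path <- file.path(withr::local_tempdir(), "model.yaml")
  write_pls_model(fit, path)
  back <- read_pls_model(path)
  expect_equal(predict(back, prob$X)$y, predict(fit, prob$X)$y,
               tolerance = 1e-9)
  expect_equal(as.character(predict(back, prob$X)$class),
               as.character(predict(fit, prob$X)$class))
})
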