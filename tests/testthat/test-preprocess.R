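test_that("preprocess_config validates its fields", {
  cfg <- preprocess_config("vector", derivative_order = 2)
  expect_equal(cfg$sg_window, 9L)
  expect_equal(cfg$sg_poly_order, 2L)
  expect_error(preprocess_config("minmax", derivative_order = 1), "vector")
  expect_error(preprocess_config("vector", sg_window = 8), "odd")
  expect_error(preprocess_config("vector", derivative_order = 2,
                                 sg_poly_order = 1), ">=")
  expect_error(preprocess_config("area", excluded_regions =
                                   list(c(1000, 1200), c(1100, 1300))),
               "disjoint")
})

test_that("remove_regions drops closed intervals and is idempotent", {
  wn <- seq(4000, 652, by = -4)
  s <- spectrum_set(wn, matrix(1, 1, length(wn)), "absorbance",
                    data.frame(sample_id = "s1"))
  # brute-force enumeration oracle for the default regions
  inside <- function(v) (v >= 3500 & v <= 4000) |
    (v >= 2208 & v <= 2442) | (v >= 600 & v <= 914)
  expected <- wn[!inside(wn)]
  r <- remove_regions(s)
  expect_equal(r$wavenumbers, expected)
  expect_equal(n_wavenumbers(r), 587)
  # closed interval: a point exactly on the 3500 boundary is removed
  expect_false(3500 %in% r$wavenumbers)
  # idempotent
  r2 <- remove_regions(r)
  expect_equal(r2$wavenumbers, r$wavenumbers)
  # empty region list / disjoint region are identities
  expect_equal(remove_regions(s, list())$wavenumbers, wn)
  expect_equal(remove_regions(s, list(c(4500, 5000)))$wavenumbers, wn)
  expect_error(remove_regions(s, list(c(0, 1e5))), "all wavenumbers")
})

test_that("sg_derivative is exact on polynomials and matches the fit oracle", {
  wn <- seq(2000, 1804, by = -4)
  meta <- data.frame(sample_id = c("const", "ramp", "rand"))
  rand <- with_seed(7, stats::runif(length(wn)))
  x <- rbind(rep(0.7, length(wn)), 0.002 * wn + 0.1, rand)
  s <- spectrum_set(wn, x, "absorbance", meta)

  d1 <- sg_derivative(s, 1, 9, 2)
  expect_identical(d1$mode, "derivative")
  # derivative of a constant is zero everywhere (edges included)
  expect_equal(max(abs(d1$intensities["const", ])), 0, tolerance = 1e-9)
  # linear ramp: first derivative is the slope, exactly, everywhere
  expect_equal(unname(d1$intensities["ramp", ]),
               rep(0.002, length(wn)), tolerance = 1e-9)

  # brute-force oracle: least-squares quadratic over the 9-point window,
  # differentiated analytically at the window center
  oracle <- function(y, wn, i, d) {
    idx <- (i - 4):(i + 4)
    fit <- stats::lm(y[idx] ~ poly(wn[idx], 2, raw = TRUE))
    b <- stats::coef(fit)
    if (d == 1) b[2] + 2 * b[3] * wn[i] else 2 * b[3]
  }
  d2 <- sg_derivative(s, 2, 9, 2)
  for (i in c(5, 20, 44)) {
    expect_equal(d1$intensities["rand", i], unname(oracle(rand, wn, i, 1)),
                 tolerance = 1e-9)
    expect_equal(d2$intensities["rand", i], unname(oracle(rand, wn, i, 2)),
                 tolerance = 1e-9)
  }
  # edge points come from the terminal window's polynomial, differentiated
  # at the edge abscissa
  edge_oracle <- function(y, wn, i, d) {
    idx <- if (i <= 4) 1:9 else (length(wn) - 8):length(wn)
    b <- stats::coef(stats::lm(y[idx] ~ poly(wn[idx], 2, raw = TRUE)))
    if (d == 1) b[2] + 2 * b[3] * wn[i] else 2 * b[3]
  }
  for (i in c(1, 3, length(wn) - 1)) {
    expect_equal(d1$intensities["rand", i],
                 unname(edge_oracle(rand, wn, i, 1)), tolerance = 1e-9)
    expect_equal(d2$intensities["rand", i],
                 unname(edge_oracle(rand, wn, i, 2)), tolerance = 1e-9)
  }
})

test_that("sg_derivative is linear and rejects bad grids", {
  wn <- seq(1500, 1404, by = -4)
  a <- with_seed(1, stats::runif(length(wn)))
  b <- with_seed(2, stats::runif(length(wn)))
  mk <- function(v) spectrum_set(wn, matrix(v, 1), "absorbance",
                                 data.frame(sample_id = "s"))
  lhs <- sg_derivative(mk(2 * a - 3 * b), 1)$intensities
  rhs <- 2 * sg_derivative(mk(a), 1)$intensities -
    3 * sg_derivative(mk(b), 1)$intensities
  expect_equal(lhs, rhs, tolerance = 1e-9)

  irregular <- spectrum_set(c(wn[-2]), matrix(a[-2], 1), "absorbance",
                            data.frame(sample_id = "s"))
  expect_error(sg_derivative(irregular, 1), "uniform")
  small <- spectrum_set(wn[1:5], matrix(a[1:5], 1), "absorbance",
                        data.frame(sample_id = "s"))
  expect_error(sg_derivative(small, 1, sg_window = 9), "larger than grid")
})

test_that("area normalization yields unit trapezoidal integral", {
  wn <- seq(1900, 1500, by = -4)
  W <- 1900 - 1500
  s <- spectrum_set(wn, rbind(rep(0.4, length(wn)),
                              with_seed(3, stats::runif(length(wn), 0.2, 1))),
                    "absorbance", data.frame(sample_id = c("flat", "rand")))
  a <- normalize_area(s)
  # flat spectrum of value c on width W -> every value 1/W
  expect_equal(unname(a$intensities["flat", ]), rep(1 / W, length(wn)),
               tolerance = 1e-12)
  # any sample integrates to 1
  w <- ftirpls:::trapezoid_weights(wn)
  expect_equal(unname(a$intensities %*% w)[, 1], c(1, 1), tolerance = 1e-9)
})

test_that("min-max normalization divides by the range only", {
  s <- spectrum_set(c(1000, 996, 992), rbind(c(0, 1, 2)), "absorbance",
                    data.frame(sample_id = "s1"))
  m <- normalize_minmax(s)
  expect_equal(unname(m$intensities[1, ]), c(0, 0.5, 1))
  s2 <- spectrum_set(c(1000, 996), rbind(c(2, 4)), "absorbance",
                     data.frame(sample_id = "s1"))
  expect_equal(unname(normalize_minmax(s2)$intensities[1, ]), c(1, 2))
  # unit range afterwards
  r <- apply(m$intensities, 1, function(v) max(v) - min(v))
  expect_equal(unname(r), 1)
  const <- spectrum_set(c(1000, 996), rbind(c(1, 1)), "absorbance",
                        data.frame(sample_id = "c"))
  expect_error(normalize_minmax(const), "degenerate")
})

test_that("vector normalization gives unit norm and is idempotent", {
  s <- spectrum_set(c(1000, 996), rbind(c(3, 4)), "absorbance",
                    data.frame(sample_id = "s1"))
  v <- normalize_vector(s)
  expect_equal(unname(v$intensities[1, ]), c(0.6, 0.8))
  expect_equal(normalize_vector(v)$intensities, v$intensities,
               tolerance = 1e-12)

  r <- tiny_set(n = 5, seed = 11)
  nr <- normalize_vector(r)
  expect_equal(unname(sqrt(rowSums(nr$intensities^2))), rep(1, 5),
               tolerance = 1e-12)
})

test_that("all normalizations are invariant to positive scaling of a sample", {
  s <- tiny_set(n = 1, wn = seq(2000, 1804, by = -4), seed = 5)
  set2 <- s
  set2$intensities <- 3.7 * s$intensities
  for (f in list(normalize_area, normalize_minmax, normalize_vector)) {
    expect_equal(f(set2)$intensities, f(s)$intensities, tolerance = 1e-12)
  }
})

test_that("run_preprocess composes the stages in the documented order", {
  d <- small_design(n_plants = 2L)
  s <- generate_spectra(d, seed = 3)
  out <- run_preprocess(s, preprocess_config("vector", derivative_order = 2))
  # 587 of 838 grid points survive, unit-norm second-derivative rows
  expect_equal(n_wavenumbers(out), 587)
  expect_identical(out$mode, "derivative")
  expect_equal(unname(sqrt(rowSums(out$intensities^2))),
               rep(1, n_samples(out)), tolerance = 1e-12)
  # stage-by-stage oracle
  manual <- normalize_vector(remove_regions(sg_derivative(s, 2, 9, 2)))
  expect_equal(out$intensities, manual$intensities, tolerance = 1e-12)
  # excluded wavenumbers never appear in the output
  expect_false(any(out$wavenumbers >= 3500 |
                     (out$wavenumbers >= 2208 & out$wavenumbers <= 2442) |
                     out$wavenumbers <= 914))

  # transmittance input is converted first
  dt <- small_design(n_plants = 1L)
  dt$output_mode <- "percent_transmittance"
  st <- generate_spectra(do.call(synthetic_design, unclass(dt)), seed = 3)
  outt <- run_preprocess(st, preprocess_config("area"))
  w <- ftirpls:::trapezoid_weights(outt$wavenumbers)
  expect_equal(unname(outt$intensities %*% w)[, 1],
               rep(1, n_samples(outt)), tolerance = 1e-9)
})
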