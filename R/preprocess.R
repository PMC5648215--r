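#' Preprocessing configuration
#'
#' Captures one preprocessing recipe: the normalization scheme, the
#' Savitzky-Golay derivative settings, and the wavenumber regions excluded
#' before normalization. The defaults remove the water-vapor region
#' (4000-3500 cm^-1) and the two CO2 regions (2442-2208 and 914-600 cm^-1).
#'
#' Derivatives are only taken on the vector-normalization path: area and
#' min-max normalization operate on plain absorbance spectra, while first or
#' second Savitzky-Golay derivatives feed vector normalization.
#'
#' @param method Normalization method: `"area"`, `"minmax"` or `"vector"`.
#' @param derivative_order 0 (none), 1 or 2. Must be 0 unless
#'   `method = "vector"`.
#' @param sg_window Odd number of Savitzky-Golay smoothing points (default 9).
#' @param sg_poly_order Polynomial order of the Savitzky-Golay fit, at least
#'   `derivative_order` and less than `sg_window` (default 2).
#' @param excluded_regions List of length-2 numeric vectors, closed
#'   wavenumber intervals in cm^-1 to drop.
#' @return A `preprocess_config` object.
#' @export
preprocess_config <- function(method = c("area", "minmax", "vector"),
                              derivative_order = 0L,
                              sg_window = 9L,
                              sg_poly_order = 2L,
                              excluded_regions = default_excluded_regions()) {
  method <- match.arg(method)
  derivative_order <- as.integer(derivative_order)
  sg_window <- as.integer(sg_window)
  sg_poly_order <- as.integer(sg_poly_order)
  if (!derivative_order %in% 0:2) {
    stop("derivative_order must be 0, 1 or 2", call. = FALSE)
  }
  if (derivative_order > 0 && method != "vector") {
    stop("derivatives are applied on the vector-normalization path only; ",
         "method '", method, "' requires derivative_order = 0", call. = FALSE)
  }
  if (sg_window %% 2 == 0 || sg_window <= sg_poly_order) {
    stop("sg_window must be odd and > sg_poly_order", call. = FALSE)
  }
  if (sg_poly_order < derivative_order) {
    stop("sg_poly_order must be >= derivative_order", call. = FALSE)
  }
  excluded_regions <- lapply(excluded_regions, function(r) {
    r <- sort(as.numeric(r))
    if (length(r) != 2 || anyNA(r)) {
      stop("each excluded region must be a numeric interval", call. = FALSE)
    }
    r
  })
  if (length(excluded_regions) > 1) {
    m <- do.call(rbind, excluded_regions)
    m <- m[order(m[, 1]), , drop = FALSE]
    if (any(m[-1, 1] <= m[-nrow(m), 2])) {
      stop("excluded_regions must be pairwise disjoint", call. = FALSE)
    }
  }
  structure(list(method = method, derivative_order = derivative_order,
                 sg_window = sg_window, sg_poly_order = sg_poly_order,
                 excluded_regions = excluded_regions),
            class = "preprocess_config")
}

#' Default excluded wavenumber regions
#'
#' Water vapor (4000-3500 cm^-1) and the two atmospheric CO2 regions
#' (2442-2208 and 914-600 cm^-1), all treated as closed intervals.
#' @return List of length-2 numeric vectors.
#' @export
default_excluded_regions <- function() {
  list(c(3500, 4000), c(2208, 2442), c(600, 914))
}

#' @export
print.preprocess_config <- function(x, ...) {
  cat(sprintf("<preprocess_config> method=%s derivative=%d sg=(%d pts, order %d)\n",
              x$method, x$derivative_order, x$sg_window, x$sg_poly_order))
  for (r in x$excluded_regions) {
    cat(sprintf("  exclude [%.6g, %.6g] cm^-1\n", r[1], r[2]))
  }
  invisible(x)
}

#' Drop wavenumber regions from a spectrum set
#'
#' Removes every grid point lying inside any of the given closed intervals.
#' The order of the surviving points and the metadata are unchanged.
#'
#' @param s A [spectrum_set].
#' @param regions List of length-2 numeric intervals (cm^-1).
#' @return A [spectrum_set] on the retained grid.
#' @export
remove_regions <- function(s, regions = default_excluded_regions()) {
  stopifnot(inherits(s, "spectrum_set"))
  if (!length(regions)) return(s)
  drop <- rep(FALSE, n_wavenumbers(s))
  for (r in regions) {
    r <- sort(as.numeric(r))
    drop <- drop | (s$wavenumbers >= r[1] & s$wavenumbers <= r[2])
  }
  if (all(drop)) stop("all wavenumbers fall in excluded regions", call. = FALSE)
  set_intensities(s, s$intensities[, !drop, drop = FALSE],
                  wavenumbers = s$wavenumbers[!drop])
}

#' Savitzky-Golay derivative of each spectrum
#'
#' Fits a sliding least-squares polynomial per sample and returns its
#' analytic derivative with respect to wavenumber, in absorbance x cm^d
#' units. The grid must be uniform and contiguous, so the derivative is
#' taken before any region removal. Edge points come from the polynomial
#' fitted to the terminal window.
#'
#' @param s A [spectrum_set] with `mode = "absorbance"`.
#' @param derivative_order Derivative order d >= 1.
#' @param sg_window Odd window length in points (default 9).
#' @param sg_poly_order Polynomial order (default 2).
#' @return A [spectrum_set] with `mode = "derivative"`.
#' @export
sg_derivative <- function(s, derivative_order = 2L, sg_window = 9L,
                          sg_poly_order = 2L) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$mode != "absorbance") {
    stop("sg_derivative() requires absorbance spectra", call. = FALSE)
  }
  d <- as.integer(derivative_order)
  if (d < 1) stop("derivative_order must be >= 1", call. = FALSE)
  if (sg_window %% 2 == 0 || sg_poly_order >= sg_window ||
      sg_poly_order < d) {
    stop("need odd sg_window > sg_poly_order >= derivative_order",
         call. = FALSE)
  }
  wn <- s$wavenumbers
  if (length(wn) < sg_window) {
    stop("window (", sg_window, ") larger than grid (", length(wn), ")",
         call. = FALSE)
  }
  steps <- diff(wn)
  if (max(abs(steps - steps[1])) > 1e-6 * abs(steps[1])) {
    stop("non-uniform wavenumber grid; derivative requires uniform spacing",
         call. = FALSE)
  }
  h <- abs(steps[1])
  # sgolayfilt differentiates w.r.t. the stored (descending) axis; flip the
  # sign for odd orders to get the derivative w.r.t. increasing wavenumber
  sgn <- if (steps[1] < 0 && d %% 2 == 1) -1 else 1
  out <- t(apply(s$intensities, 1, function(row) {
    sgn * signal::sgolayfilt(row, p = sg_poly_order, n = sg_window,
                             m = d, ts = h)
  }))
  set_intensities(s, out, mode = "derivative")
}

#' Area normalization
#'
#' Divides each spectrum by its total integrated absorbance, computed with
#' the trapezoidal rule over the retained grid (piecewise per contiguous
#' segment when regions have been excised), so each normalized spectrum
#' integrates to 1.
#'
#' @param s A [spectrum_set] with `mode = "absorbance"`.
#' @return A normalized [spectrum_set].
#' @export
normalize_area <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$mode != "absorbance") {
    stop("normalize_area() requires absorbance spectra", call. = FALSE)
  }
  w <- trapezoid_weights(s$wavenumbers)
  areas <- as.numeric(s$intensities %*% w)
  if (any(areas <= 0)) {
    bad <- which(areas <= 0)[1]
    stop("degenerate spectrum (integral <= 0) for sample '",
         s$metadata$sample_id[bad], "'", call. = FALSE)
  }
  set_intensities(s, s$intensities / areas)
}

# trapezoidal quadrature weights on a (possibly gapped) descending grid;
# gaps wider than 1.5x the modal step break the integration into segments
trapezoid_weights <- function(wn) {
  n <- length(wn)
  if (n < 2) stop("need >= 2 points to integrate", call. = FALSE)
  gaps <- abs(diff(wn))
  step <- stats::median(gaps)
  w <- numeric(n)
  for (i in seq_len(n - 1)) {
    if (gaps[i] <= 1.5 * step) {        # contiguous pair
      w[i] <- w[i] + gaps[i] / 2
      w[i + 1] <- w[i + 1] + gaps[i] / 2
    }
  }
  w
}

#' Min-max normalization
#'
#' Divides each spectrum by the difference between its highest and lowest
#' absorbance values (division only; the minimum is not subtracted), so the
#' range of each normalized spectrum equals 1.
#'
#' @param s A [spectrum_set] with `mode = "absorbance"`.
#' @return A normalized [spectrum_set].
#' @export
normalize_minmax <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$mode != "absorbance") {
    stop("normalize_minmax() requires absorbance spectra", call. = FALSE)
  }
  rng <- apply(s$intensities, 1, function(r) max(r) - min(r))
  if (any(rng <= 0)) {
    stop("degenerate constant spectrum for sample '",
         s$metadata$sample_id[which(rng <= 0)[1]], "'", call. = FALSE)
  }
  set_intensities(s, s$intensities / rng)
}

#' Vector (Euclidean norm) normalization
#'
#' Divides each spectrum by its Euclidean norm over the retained points,
#' yielding unit-norm rows. Applicable to absorbance or derivative spectra.
#'
#' @param s A [spectrum_set] with `mode` `"absorbance"` or `"derivative"`.
#' @return A normalized [spectrum_set].
#' @export
normalize_vector <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (!s$mode %in% c("absorbance", "derivative")) {
    stop("normalize_vector() requires absorbance or derivative spectra",
         call. = FALSE)
  }
  nrm <- sqrt(rowSums(s$intensities^2))
  if (any(nrm <= 0)) {
    stop("zero-norm spectrum for sample '",
         s$metadata$sample_id[which(nrm <= 0)[1]], "'", call. = FALSE)
  }
  set_intensities(s, s$intensities / nrm)
}

#' Run a full preprocessing recipe
#'
#' Executes, in order: transmittance-to-absorbance conversion (when needed);
#' Savitzky-Golay differentiation on the contiguous grid (vector path only);
#' excluded-region removal; then the configured normalization, whose
#' constants therefore use only the retained points.
#'
#' @param s A [spectrum_set] in percent transmittance or absorbance.
#' @param cfg A [preprocess_config].
#' @return The analysis-ready [spectrum_set].
#' @export
run_preprocess <- function(s, cfg) {
  stopifnot(inherits(s, "spectrum_set"), inherits(cfg, "preprocess_config"))
  if (!s$mode %in% c("percent_transmittance", "absorbance")) {
    stop("run_preprocess() expects raw transmittance or absorbance input",
         call. = FALSE)
  }
  if (s$mode == "percent_transmittance") s <- to_absorbance(s)
  if (cfg$derivative_order > 0) {
    s <- sg_derivative(s, cfg$derivative_order, cfg$sg_window,
                       cfg$sg_poly_order)
  }
  s <- remove_regions(s, cfg$excluded_regions)
  switch(cfg$method,
         area = normalize_area(s),
         minmax = normalize_minmax(s),
         vector = normalize_vector(s))
}
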