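#' Absorption band specification
#'
#' One Gaussian absorption band of the synthetic FT-IR generator, with
#' class-dependent amplitude multipliers.
#'
#' @param center Band center in cm^-1.
#' @param fwhm Full width at half maximum in cm^-1 (> 0).
#' @param base_amplitude Peak absorbance of the band for the reference
#'   class (>= 0).
#' @param age_multipliers Named numeric factors per age class
#'   (names `"5yr"`, `"6yr"`), all > 0.
#' @param part_multipliers Named numeric factors per part
#'   (names `"tap_root"`, `"rhizome"`, `"lateral_root"`), all > 0.
#' @param assignment Free-text biochemical assignment of the band.
#' @return A `band_spec`.
#' @export
band_spec <- function(center, fwhm, base_amplitude,
                      age_multipliers = c("5yr" = 1, "6yr" = 1),
                      part_multipliers = c(tap_root = 1, rhizome = 1,
                                           lateral_root = 1),
                      assignment = "") {
  stopifnot(fwhm > 0, base_amplitude >= 0,
            all(age_multipliers > 0), all(part_multipliers > 0))
  structure(list(center = center, fwhm = fwhm,
                 base_amplitude = base_amplitude,
                 age_multipliers = age_multipliers,
                 part_multipliers = part_multipliers,
                 assignment = assignment),
            class = "band_spec")
}

#' Synthetic study design
#'
#' Describes a simulated FT-IR study: the wavenumber grid, the band library
#' with class effects, atmospheric artifact bands, the sampling layout
#' (plants x ages x parts x analytical replicates), and the noise model
#' (between-plant lognormal amplitude variation, per-replicate
#' multiplicative scatter, linear baseline drift and additive noise).
#'
#' @param grid Numeric `c(start, stop, step)` in cm^-1 (default 4000, 650,
#'   4; the grid runs 4000 down to 652 giving 838 points).
#' @param bands List of [band_spec]s.
#' @param artifact_bands List of [band_spec]s placed inside the excluded
#'   regions (water vapor, CO2), re-drawn independently per replicate.
#' @param n_plants_per_group Plants per age class (default 12).
#' @param ages Age classes simulated.
#' @param parts Plant parts simulated.
#' @param n_replicates Analytical replicates per plant part (default 6).
#' @param plant_amplitude_cv Between-plant lognormal coefficient of
#'   variation of band amplitudes.
#' @param replicate_noise_sd Additive absorbance noise per point.
#' @param scatter_sd Log-sd of the per-replicate multiplicative scatter.
#' @param baseline `c(offset_sd, slope_sd)` of the per-replicate linear
#'   baseline (absorbance; absorbance per cm^-1).
#' @param output_mode `"absorbance"` or `"percent_transmittance"`.
#' @return A `synthetic_design`.
#' @export
synthetic_design <- function(grid = c(4000, 650, 4),
                             bands,
                             artifact_bands = list(),
                             n_plants_per_group = 12L,
                             ages = c("5yr", "6yr"),
                             parts = c("tap_root", "rhizome", "lateral_root"),
                             n_replicates = 6L,
                             plant_amplitude_cv = 0.06,
                             replicate_noise_sd = 0.002,
                             scatter_sd = 0.05,
                             baseline = c(offset_sd = 0.01, slope_sd = 1e-5),
                             output_mode = c("absorbance",
                                             "percent_transmittance")) {
  output_mode <- match.arg(output_mode)
  stopifnot(length(grid) == 3, grid[3] > 0, grid[1] > grid[2],
            n_plants_per_group >= 1, n_replicates >= 1,
            plant_amplitude_cv >= 0, replicate_noise_sd >= 0,
            scatter_sd >= 0, all(baseline >= 0))
  structure(list(grid = as.numeric(grid), bands = bands,
                 artifact_bands = artifact_bands,
                 n_plants_per_group = as.integer(n_plants_per_group),
                 ages = ages, parts = parts,
                 n_replicates = as.integer(n_replicates),
                 plant_amplitude_cv = plant_amplitude_cv,
                 replicate_noise_sd = replicate_noise_sd,
                 scatter_sd = scatter_sd,
                 baseline = as.numeric(baseline),
                 output_mode = output_mode),
            class = "synthetic_design")
}

#' Default synthetic design
#'
#' Eight bands at the characteristic mid-IR wavenumbers of ginseng root
#' powder (3335, 2923, 1733, 1621, 1417, 1373, 1253 and 1018 cm^-1), with
#' age effects on the polysaccharide band (1018) and the ginsenoside bands
#' (3335, 2923), and part effects on the calcium oxalate band (1621) and
#' 1018. Atmospheric artifact bands sit inside each of the three excluded
#' regions (water vapor near 3700, CO2 near 2350 and 670 cm^-1). The layout
#' is 12 plants per age class, 3 parts and 6 analytical replicates, i.e.
#' 432 spectra.
#'
#' @return A [synthetic_design].
#' @export
default_design <- function() {
  bands <- list(
    band_spec(3335, 90, 0.20, age_multipliers = c("5yr" = 1, "6yr" = 1.30),
              assignment = "O-H / N-H stretching; ginsenoside hydroxyls"),
    band_spec(2923, 55, 0.20, age_multipliers = c("5yr" = 1, "6yr" = 1.30),
              assignment = "C-H stretching; ginsenosides, lipids"),
    band_spec(1733, 35, 0.30, assignment = "C=O stretching; lipids"),
    band_spec(1621, 40, 0.50,
              part_multipliers = c(tap_root = 1, rhizome = 1.4,
                                   lateral_root = 0.7),
              assignment = "asym. OC=O stretching; calcium oxalate"),
    band_spec(1417, 40, 0.25, assignment = "asym. CH3 stretching; lipids"),
    band_spec(1373, 30, 0.25, assignment = "COO-/CH3; lipids, proteins"),
    band_spec(1253, 35, 0.20, assignment = "amide III; proteins"),
    band_spec(1018, 60, 0.35, age_multipliers = c("5yr" = 1, "6yr" = 1.30),
              part_multipliers = c(tap_root = 1.2, rhizome = 1,
                                   lateral_root = 0.8),
              assignment = "C-O-C stretching; polysaccharides"))
  artifacts <- list(
    band_spec(3700, 100, 0.05, assignment = "water vapor"),
    band_spec(2350, 40, 0.08, assignment = "CO2 stretching"),
    band_spec(670, 30, 0.06, assignment = "CO2 bending"))
  synthetic_design(bands = bands, artifact_bands = artifacts)
}

design_grid <- function(design) {
  g <- design$grid
  wn <- seq(g[1], g[2], by = -g[3])
  if (length(wn) < 2) stop("grid step incompatible with range", call. = FALSE)
  wn
}

gaussian_band <- function(wn, center, fwhm, amplitude) {
  amplitude * exp(-4 * log(2) * (wn - center)^2 / fwhm^2)
}

#' Generate a synthetic FT-IR spectrum set
#'
#' Per plant, each band amplitude is drawn lognormally (mean-preserving)
#' around `base_amplitude x age_multiplier x part_multiplier` with the
#' design's between-plant CV. Per analytical replicate, the spectrum is
#' `scatter x sum(bands) + baseline + noise`, with artifact bands re-drawn
#' independently per replicate. Output is deterministic under `seed`; the
#' caller's RNG stream is left untouched.
#'
#' @param design A [synthetic_design].
#' @param seed Integer seed.
#' @return A [spectrum_set] with fully populated metadata (one biological
#'   sample = one plant part; `plant_id` unique across age classes).
#' @export
generate_spectra <- function(design = default_design(), seed = 1L) {
  stopifnot(inherits(design, "synthetic_design"))
  with_seed(seed, generate_spectra_impl(design))
}

generate_spectra_impl <- function(design) {
  wn <- design_grid(design)
  sdlog <- sqrt(log(1 + design$plant_amplitude_cv^2))
  rows <- list(); meta <- list(); r <- 0L
  for (age in design$ages) {
    for (plant in seq_len(design$n_plants_per_group)) {
      plant_id <- sprintf("%s_P%02d", sub("yr", "y", age), plant)
      for (part in design$parts) {
        # plant x part level band amplitudes (biological variation)
        amps <- vapply(design$bands, function(b) {
          mu <- b$base_amplitude * b$age_multipliers[[age]] *
            b$part_multipliers[[part]]
          mu * stats::rlnorm(1, meanlog = -sdlog^2 / 2, sdlog = sdlog)
        }, numeric(1))
        pure <- rowSums(vapply(seq_along(design$bands), function(k) {
          gaussian_band(wn, design$bands[[k]]$center,
                        design$bands[[k]]$fwhm, amps[k])
        }, numeric(length(wn))))
        for (rep_i in seq_len(design$n_replicates)) {
          scatter <- exp(stats::rnorm(1, 0, design$scatter_sd))
          base <- stats::rnorm(1, 0, design$baseline[1]) +
            stats::rnorm(1, 0, design$baseline[2]) * (wn - mean(wn))
          artifact <- 0
          for (b in design$artifact_bands) {
            artifact <- artifact + gaussian_band(
              wn, b$center, b$fwhm,
              b$base_amplitude * exp(stats::rnorm(1, 0, 0.3)))
          }
          noise <- stats::rnorm(length(wn), 0, design$replicate_noise_sd)
          r <- r + 1L
          rows[[r]] <- scatter * pure + artifact + base + noise
          meta[[r]] <- data.frame(
            sample_id = sprintf("%s_%s_r%d", plant_id, part, rep_i),
            plant_id = plant_id, age_class = age, part = part,
            replicate_index = rep_i, stringsAsFactors = FALSE)
        }
      }
    }
  }
  A <- do.call(rbind, rows)
  metadata <- do.call(rbind, meta)
  if (design$output_mode == "percent_transmittance") {
    spectrum_set(wn, 100 * 10^(-A), "percent_transmittance", metadata)
  } else {
    spectrum_set(wn, A, "absorbance", metadata)
  }
}

#' Ground-truth discriminating bands of a design
#'
#' Lists, per task, the bands whose class multipliers actually differ
#' between the task's classes, with a window of one FWHM either side of the
#' center; this is the reference for VIP-recovery checks.
#'
#' @param design A [synthetic_design].
#' @return List with data frames `age` and `part`, each with columns
#'   `center`, `window_lo`, `window_hi`, `assignment`.
#' @export
truth_table <- function(design = default_design()) {
  stopifnot(inherits(design, "synthetic_design"))
  differ <- function(mults, classes) {
    v <- unlist(mults[classes])
    length(v) > 1 && diff(range(v)) > 0
  }
  per_task <- function(which_mult, classes) {
    hit <- vapply(design$bands, function(b)
      differ(as.list(b[[which_mult]]), classes), logical(1))
    do.call(rbind, lapply(design$bands[hit], function(b) {
      data.frame(center = b$center, window_lo = b$center - b$fwhm,
                 window_hi = b$center + b$fwhm,
                 assignment = b$assignment, stringsAsFactors = FALSE)
    })) %||% data.frame(center = numeric(0), window_lo = numeric(0),
                        window_hi = numeric(0),
                        assignment = character(0))
  }
  list(age = per_task("age_multipliers", design$ages),
       part = per_task("part_multipliers", design$parts))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
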