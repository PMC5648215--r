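# Small in-code fixtures shared across test files.

# tiny spectrum set: n samples on a uniform descending grid
tiny_set <- function(n = 3, wn = seq(2000, 1600, by = -4), seed = 42,
                     mode = "absorbance") {
  x <- with_seed(seed, matrix(stats::runif(n * length(wn), 0.1, 1),
                              nrow = n))
  spectrum_set(wn, x, mode,
               data.frame(sample_id = sprintf("s%d", seq_len(n)),
                          plant_id = sprintf("p%d", seq_len(n)),
                          age_class = NA_character_, part = NA_character_,
                          replicate_index = NA_integer_))
}

# borrow the package-internal seeded-RNG helper
with_seed <- ftirpls:::with_seed

# a small, fast synthetic design for pipeline tests: 4 plants per age,
# tap root only, otherwise the default band library and noise model
small_design <- function(parts = "tap_root", n_plants = 4L) {
  d <- default_design()
  synthetic_design(bands = d$bands, artifact_bands = d$artifact_bands,
                   n_plants_per_group = n_plants, parts = parts,
                   plant_amplitude_cv = d$plant_amplitude_cv,
                   replicate_noise_sd = d$replicate_noise_sd,
                   scatter_sd = d$scatter_sd, baseline = d$baseline)
}

# random PLS problem for oracle checks
random_pls_problem <- function(n = 8, p = 5, m = 1, seed = 1) {
  with_seed(seed, list(X = matrix(stats::rnorm(n * p), n, p),
                       Y = matrix(stats::rnorm(n * m), n, m)))
}

# design with every class multiplier equal to 1 (null structure)
null_design <- function(parts = "tap_root", n_plants = 4L) {
  d <- default_design()
  bands <- lapply(d$bands, function(b) {
    b$age_multipliers[] <- 1
    b$part_multipliers[] <- 1
    b
  })
  synthetic_design(bands = bands, artifact_bands = d$artifact_bands,
                   n_plants_per_group = n_plants, parts = parts)
}
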