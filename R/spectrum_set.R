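#' Construct a spectrum set
#'
#' A `spectrum_set` bundles an FT-IR wavenumber grid, an intensity matrix
#' (samples in rows), the intensity mode, and per-sample metadata. It is the
#' object every pipeline stage consumes and produces.
#'
#' @param wavenumbers Numeric vector of wavenumbers in cm^-1. Stored in
#'   strictly decreasing order (instrument export order, 4000 down to 650);
#'   an ascending input is reversed together with the intensity columns.
#' @param intensities Numeric matrix, `n_samples x n_wavenumbers`.
#' @param mode One of `"percent_transmittance"`, `"absorbance"`,
#'   `"derivative"`.
#' @param metadata Data frame with one row per sample. Must contain
#'   `sample_id` (unique); the columns `plant_id`, `age_class`
#'   (`"5yr"`/`"6yr"`), `part` (`"tap_root"`/`"rhizome"`/`"lateral_root"`)
#'   and `replicate_index` (1..6) are used by the discrimination tasks and
#'   may be `NA` when not applicable.
#'
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(wavenumbers, intensities, mode, metadata) {
  if (is.vector(intensities)) intensities <- matrix(intensities, nrow = 1)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  wavenumbers <- as.numeric(wavenumbers)
  if (length(wavenumbers) != ncol(intensities)) {
    stop("length(wavenumbers) must equal ncol(intensities)", call. = FALSE)
  }
  if (anyDuplicated(wavenumbers)) {
    stop("duplicated wavenumbers are not allowed", call. = FALSE)
  }
  if (length(wavenumbers) > 1) {
    d <- diff(wavenumbers)
    if (all(d > 0)) {           # ascending input: flip to storage order
      wavenumbers <- rev(wavenumbers)
      intensities <- intensities[, rev(seq_along(wavenumbers)), drop = FALSE]
    } else if (!all(d < 0)) {
      stop("wavenumbers must be strictly monotone", call. = FALSE)
    }
  }
  mode <- match.arg(mode, c("percent_transmittance", "absorbance", "derivative"))
  metadata <- as.data.frame(metadata, stringsAsFactors = FALSE)
  if (is.null(metadata$sample_id)) {
    stop("metadata must contain a sample_id column", call. = FALSE)
  }
  metadata$sample_id <- as.character(metadata$sample_id)
  if (nrow(metadata) != nrow(intensities)) {
    stop("metadata rows (", nrow(metadata), ") do not match samples (",
         nrow(intensities), ")", call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("sample_id values must be unique", call. = FALSE)
  }
  if (mode == "percent_transmittance" && any(intensities <= 0)) {
    bad <- which(intensities <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "percent transmittance must be > 0 (sample '%s' at %.6g cm^-1)",
      metadata$sample_id[bad[1]], wavenumbers[bad[2]]), call. = FALSE)
  }
  rownames(intensities) <- metadata$sample_id
  colnames(intensities) <- format(wavenumbers, trim = TRUE, scientific = FALSE)
  structure(
    list(wavenumbers = wavenumbers, intensities = intensities,
         mode = mode, metadata = metadata),
    class = "spectrum_set")
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("<spectrum_set> %d samples x %d wavenumbers [%s]\n",
              nrow(x$intensities), length(x$wavenumbers), x$mode))
  cat(sprintf("  grid: %.6g .. %.6g cm^-1\n",
              x$wavenumbers[1], x$wavenumbers[length(x$wavenumbers)]))
  meta <- x$metadata
  for (col in c("age_class", "part", "replicate_index")) {
    if (!is.null(meta[[col]]) && !all(is.na(meta[[col]]))) {
      cat(sprintf("  %s: %s\n", col,
                  paste(names(table(meta[[col]])), collapse = ", ")))
    }
  }
  invisible(x)
}

#' Number of samples / wavenumbers in a spectrum set
#' @param s A `spectrum_set`.
#' @return Integer count.
#' @export
n_samples <- function(s) nrow(s$intensities)

#' @rdname n_samples
#' @export
n_wavenumbers <- function(s) length(s$wavenumbers)

#' Subset a spectrum set by sample
#'
#' @param s A `spectrum_set`.
#' @param i Logical or integer index over samples.
#' @return A `spectrum_set` with the selected samples.
#' @export
subset_samples <- function(s, i) {
  spectrum_set(s$wavenumbers, s$intensities[i, , drop = FALSE], s$mode,
               s$metadata[i, , drop = FALSE])
}

# internal: replace the intensity matrix (and optionally the grid),
# preserving mode/metadata unless overridden
set_intensities <- function(s, intensities, wavenumbers = s$wavenumbers,
                            mode = s$mode) {
  spectrum_set(wavenumbers, intensities, mode, s$metadata)
}

#' Convert percent transmittance to absorbance
#'
#' Applies the Beer-Lambert conversion A = -log10(T / 100) elementwise.
#' Transmittance is taken in percent, the instrument-software convention,
#' so T = 100 maps to A = 0 and T = 1 to A = 2.
#'
#' @param s A `spectrum_set` with `mode = "percent_transmittance"`.
#' @return A `spectrum_set` with `mode = "absorbance"`; grid and metadata
#'   unchanged.
#' @export
to_absorbance <- function(s) {
  stopifnot(inherits(s, "spectrum_set"))
  if (s$mode != "percent_transmittance") {
    stop("to_absorbance() requires mode 'percent_transmittance', got '",
         s$mode, "'", call. = FALSE)
  }
  if (any(s$intensities <= 0)) {
    bad <- which(s$intensities <= 0, arr.ind = TRUE)[1, ]
    stop(sprintf(
      "nonpositive transmittance for sample '%s' at %.6g cm^-1",
      s$metadata$sample_id[bad[1]], s$wavenumbers[bad[2]]), call. = FALSE)
  }
  set_intensities(s, -log10(s$intensities / 100), mode = "absorbance")
}
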