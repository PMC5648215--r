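#' Read FT-IR spectra from disk
#'
#' Two formats are supported. `csv_wide` is a delimited table whose first
#' column holds wavenumbers and each further column one sample; a metadata
#' sidecar (same path with `_metadata.csv` appended to the stem) is read when
#' present. `jcamp_dx` reads one single-spectrum JCAMP-DX file per path and
#' merges the spectra onto their (required common) grid.
#'
#' @param path File path (`csv_wide`) or character vector of file paths
#'   (`jcamp_dx`, one file per spectrum).
#' @param format `"csv_wide"` or `"jcamp_dx"`.
#' @param mode Intensity mode of the stored values. For JCAMP files the mode
#'   is taken from the `##YUNITS` header when `mode` is `NULL`.
#' @return A [spectrum_set].
#' @export
read_spectra <- function(path, format = c("csv_wide", "jcamp_dx"),
                         mode = NULL) {
  format <- match.arg(format)
  if (format == "csv_wide") {
    read_spectra_csv(path, mode = if (is.null(mode)) "absorbance" else mode)
  } else {
    read_spectra_jcamp(path, mode = mode)
  }
}

read_spectra_csv <- function(path, mode) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.csv(path, check.names = FALSE)
  if (ncol(tab) < 2) {
    stop("csv_wide file needs a wavenumber column plus >= 1 sample column: ",
         path, call. = FALSE)
  }
  wn <- suppressWarnings(as.numeric(tab[[1]]))
  if (anyNA(wn)) {
    stop(sprintf("unparseable wavenumber at line %d of %s",
                 which(is.na(wn))[1] + 1L, path), call. = FALSE)
  }
  if (anyDuplicated(wn)) {
    stop(sprintf("duplicated wavenumber %.6g at line %d of %s",
                 wn[anyDuplicated(wn)], anyDuplicated(wn) + 1L, path),
         call. = FALSE)
  }
  ids <- colnames(tab)[-1]
  x <- t(as.matrix(tab[, -1, drop = FALSE]))
  if (anyNA(x) || !is.numeric(x)) {
    stop("non-numeric intensity values in ", path, call. = FALSE)
  }
  meta <- read_metadata_sidecar(metadata_sidecar_path(path), ids)
  ord <- order(wn, decreasing = TRUE)
  spectrum_set(wn[ord], x[, ord, drop = FALSE], mode, meta)
}

metadata_sidecar_path <- function(path) {
  sub("\\.[A-Za-z0-9]+$", "", path) |> paste0("_metadata.csv")
}

read_metadata_sidecar <- function(meta_path, ids) {
  if (file.exists(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    if (is.null(meta$sample_id)) {
      stop("metadata sidecar lacks sample_id column: ", meta_path,
           call. = FALSE)
    }
    missing <- setdiff(ids, meta$sample_id)
    if (length(missing)) {
      stop("metadata sidecar missing samples: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    meta[match(ids, meta$sample_id), , drop = FALSE]
  } else {
    data.frame(sample_id = ids, plant_id = NA_character_,
               age_class = NA_character_, part = NA_character_,
               replicate_index = NA_integer_, stringsAsFactors = FALSE)
  }
}

read_spectra_jcamp <- function(paths, mode = NULL) {
  specs <- lapply(paths, read_jcamp_file)
  grid <- specs[[1]]$x
  for (k in seq_along(specs)[-1]) {
    if (length(specs[[k]]$x) != length(grid) ||
        max(abs(specs[[k]]$x - grid)) > 1e-6 * max(abs(grid))) {
      stop(sprintf("grid mismatch between '%s' and '%s' (no interpolation)",
                   paths[1], paths[k]), call. = FALSE)
    }
  }
  x <- do.call(rbind, lapply(specs, `[[`, "y"))
  modes <- vapply(specs, `[[`, "", "mode")
  if (is.null(mode)) {
    if (length(unique(modes)) != 1L || is.na(modes[1])) {
      stop("mode not deducible from ##YUNITS; pass mode= explicitly",
           call. = FALSE)
    }
    mode <- modes[1]
  }
  ids <- vapply(specs, `[[`, "", "title")
  ids[is.na(ids) | ids == ""] <- basename(paths)[is.na(ids) | ids == ""]
  ids <- make.unique(ids)
  meta <- data.frame(sample_id = ids, plant_id = NA_character_,
                     age_class = NA_character_, part = NA_character_,
                     replicate_index = NA_integer_,
                     stringsAsFactors = FALSE)
  ord <- order(grid, decreasing = TRUE)
  spectrum_set(grid[ord], x[, ord, drop = FALSE], mode, meta)
}

#' Write a spectrum set to a wide delimited table
#'
#' Writes the wavenumber-first wide table at full floating precision and the
#' per-sample metadata to a sibling file (`<stem>_metadata.csv`).
#'
#' @param s A [spectrum_set] with at least one sample.
#' @param path Output path for the wide csv.
#' @param format Only `"csv_wide"` is supported.
#' @return Invisibly, the paths written.
#' @export
write_spectra <- function(s, path, format = "csv_wide") {
  stopifnot(inherits(s, "spectrum_set"))
  format <- match.arg(format, "csv_wide")
  if (n_samples(s) == 0L) stop("cannot write an empty sample set", call. = FALSE)
  tab <- data.frame(wavenumber = s$wavenumbers,
                    t(s$intensities), check.names = FALSE)
  colnames(tab) <- c("wavenumber", s$metadata$sample_id)
  # full precision so a write -> read round trip is lossless
  old <- options(digits = 17); on.exit(options(old))
  utils::write.csv(format(tab, digits = 17, trim = TRUE, scientific = FALSE),
                   path, row.names = FALSE, quote = FALSE)
  meta_path <- metadata_sidecar_path(path)
  utils::write.csv(s$metadata, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, meta_path))
}
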