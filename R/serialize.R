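# Plain-text persistence of fitted PLS models, so a model trained in one
# session can be reloaded for prediction (CLI `predict`). Everything lives
# in a single YAML document; matrices are stored row-wise at 15 significant
# digits, ample for class calls and error metrics.

#' Write / read a fitted PLS model as structured text
#'
#' @param model A `pls_model`.
#' @param path Output (input) file path.
#' @return `write_pls_model()` returns the path invisibly;
#'   `read_pls_model()` returns a `pls_model`.
#' @export
write_pls_model <- function(model, path) {
  stopifnot(inherits(model, "pls_model"))
  mat2list <- function(m) apply(unname(as.matrix(m)), 1, as.numeric,
                                simplify = FALSE)
  doc <- list(
    object = "ftirpls_pls_model",
    ncomp = model$ncomp,
    variable_ids = as.list(model$variable_ids),
    class_levels = as.list(model$class_levels),
    y_means = as.numeric(model$y_means),
    r2y_cum = as.numeric(model$r2y_cum),
    ssy_per_component = as.numeric(model$ssy_per_component),
    scaling = list(method = model$scaling$method,
                   column_means = as.numeric(model$scaling$column_means),
                   column_scales = as.numeric(model$scaling$column_scales),
                   keep = as.integer(model$scaling$keep)),
    W = mat2list(model$W), P = mat2list(model$P), C = mat2list(model$C),
    B = mat2list(model$B))
  writeLines(yaml::as.yaml(doc, precision = 15L), path)
  invisible(path)
}

#' @rdname write_pls_model
#' @export
read_pls_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (!identical(doc$object, "ftirpls_pls_model")) {
    stop("not an ftirpls model file: ", path, call. = FALSE)
  }
  list2mat <- function(l) do.call(rbind, lapply(l, as.numeric))
  ids <- unlist(doc$variable_ids)
  scaling <- structure(list(method = doc$scaling$method,
                            column_means = as.numeric(doc$scaling$column_means),
                            column_scales = as.numeric(doc$scaling$column_scales),
                            keep = as.integer(doc$scaling$keep),
                            colnames = ids),
                       class = "scaling_spec")
  structure(list(ncomp = as.integer(doc$ncomp),
                 W = list2mat(doc$W), P = list2mat(doc$P),
                 C = list2mat(doc$C), B = list2mat(doc$B),
                 r2y_cum = as.numeric(doc$r2y_cum),
                 ssy_per_component = as.numeric(doc$ssy_per_component),
                 y_means = as.numeric(doc$y_means),
                 scaling = scaling, variable_ids = ids,
                 class_levels = if (length(doc$class_levels))
                   unlist(doc$class_levels) else NULL),
            class = "pls_model")
}
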