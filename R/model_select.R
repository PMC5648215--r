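#' Grid specification for two-stage model selection
#'
#' Stage 1 screens every (normalization, scaling, components) cell of a
#' PLS-DA model by permutation validity and picks, per normalization, the
#' valid cell with the highest Q2Y. Stage 2 sweeps VIP cutoffs for each
#' screened configuration on a training/test split by analytical replicate
#' and ranks the valid candidates by RMSEP.
#'
#' @param normalizations Subset of `"area"`, `"minmax"`, `"vector_d1"`,
#'   `"vector_d2"` (vector normalization after first / second derivative).
#' @param scalings Subset of `"uv"`, `"pareto"`.
#' @param component_counts Candidate numbers of PLS components (default 1:3).
#' @param vip_cutoffs Non-negative cutoffs, sorted ascending
#'   (default 0.5, 0.7, 1.0, 1.3, 1.5).
#' @param test_replicate_index Analytical replicate held out as the test
#'   set (default 6).
#' @param n_permutations Permutations per validity test (default 400).
#' @param n_folds Cross-validation folds for Q2Y (default 7).
#' @param seed Integer seed for permutation draws.
#' @return A `grid_spec`.
#' @export
grid_spec <- function(normalizations = c("area", "minmax", "vector_d1",
                                         "vector_d2"),
                      scalings = c("uv", "pareto"),
                      component_counts = 1:3,
                      vip_cutoffs = c(0.5, 0.7, 1.0, 1.3, 1.5),
                      test_replicate_index = 6L,
                      n_permutations = 400L,
                      n_folds = 7L,
                      seed = 1L) {
  normalizations <- match.arg(normalizations,
                              c("area", "minmax", "vector_d1", "vector_d2"),
                              several.ok = TRUE)
  scalings <- match.arg(scalings, c("uv", "pareto"), several.ok = TRUE)
  if (!length(component_counts) || any(component_counts < 1)) {
    stop("component_counts must be positive", call. = FALSE)
  }
  if (any(vip_cutoffs < 0) || is.unsorted(vip_cutoffs)) {
    stop("vip_cutoffs must be non-negative and sorted", call. = FALSE)
  }
  structure(list(normalizations = normalizations, scalings = scalings,
                 component_counts = as.integer(component_counts),
                 vip_cutoffs = vip_cutoffs,
                 test_replicate_index = as.integer(test_replicate_index),
                 n_permutations = as.integer(n_permutations),
                 n_folds = as.integer(n_folds), seed = as.integer(seed)),
            class = "grid_spec")
}

# map a normalization axis label to its preprocessing recipe
normalization_config <- function(normalization) {
  switch(normalization,
         area = preprocess_config("area"),
         minmax = preprocess_config("minmax"),
         vector_d1 = preprocess_config("vector", derivative_order = 1L),
         vector_d2 = preprocess_config("vector", derivative_order = 2L),
         stop("unknown normalization '", normalization, "'", call. = FALSE))
}

#' Split a spectrum set by analytical replicate
#'
#' The test set holds exactly one replicate per biological sample (the one
#' with `replicate_index == test_replicate_index`); the training set holds
#' the rest. The partition is disjoint and exhaustive.
#'
#' @param s A [spectrum_set] whose metadata carries `replicate_index`.
#' @param test_replicate_index Replicate number to hold out.
#' @return List with elements `train` and `test` ([spectrum_set]s).
#' @export
split_replicates <- function(s, test_replicate_index = 6L) {
  stopifnot(inherits(s, "spectrum_set"))
  idx <- s$metadata$replicate_index
  if (is.null(idx) || anyNA(idx)) {
    bad <- if (is.null(idx)) s$metadata$sample_id else
      s$metadata$sample_id[is.na(idx)]
    stop("replicate_index missing for samples: ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  test <- idx == test_replicate_index
  if (!any(test)) {
    stop("no sample has replicate_index == ", test_replicate_index,
         call. = FALSE)
  }
  list(train = subset_samples(s, !test), test = subset_samples(s, test))
}

#' Screen preprocessing / scaling / component configurations (stage 1)
#'
#' For every grid cell: preprocess the full spectrum set, fit a PLS-DA
#' model, compute R2Y, cross-validated Q2Y and the permutation intercepts,
#' and apply the validity gate. Per normalization method, the valid cell
#' with the highest Q2Y (ties: higher R2Y, then fewer components) is marked
#' `selected` for stage 2. Cells whose preprocessing or fit fails are
#' marked infeasible with the reason; the run continues.
#'
#' @param s A [spectrum_set] (raw transmittance or absorbance).
#' @param labels Class labels, one per sample.
#' @param grid A [grid_spec].
#' @return Data frame of candidates (stage `"screen"`), one row per cell.
#' @export
screen_configurations <- function(s, labels, grid = grid_spec()) {
  stopifnot(inherits(s, "spectrum_set"), inherits(grid, "grid_spec"))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) {
    stop("need >= 2 classes to screen", call. = FALSE)
  }
  Y <- dummy_code(labels)
  cells <- expand.grid(normalization = grid$normalizations,
                       scaling = grid$scalings,
                       ncomp = grid$component_counts,
                       stringsAsFactors = FALSE)
  pre_cache <- lapply(stats::setNames(nm = grid$normalizations), function(nm) {
    tryCatch(run_preprocess(s, normalization_config(nm))$intensities,
             error = function(e) e)
  })
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    cell <- cells[i, ]
    out <- data.frame(stage = "screen", cell,
                      vip_cutoff = NA_real_, retained = NA_integer_,
                      r2y = NA_real_, q2y = NA_real_,
                      r2y_intercept = NA_real_, q2y_intercept = NA_real_,
                      rmsee = NA_real_, rmsep = NA_real_,
                      valid = FALSE, selected = FALSE,
                      infeasible = NA_character_,
                      stringsAsFactors = FALSE)
    X <- pre_cache[[cell$normalization]]
    if (inherits(X, "error")) {
      out$infeasible <- conditionMessage(X)
      return(out)
    }
    res <- tryCatch({
      fit <- fit_pls(X, Y, cell$ncomp, scaling = cell$scaling)
      perm <- permutation_test(X, Y, cell$ncomp,
                               n_permutations = grid$n_permutations,
                               scaling = cell$scaling, seed = grid$seed,
                               n_folds = grid$n_folds)
      out$r2y <- fit$r2y_cum[cell$ncomp]
      out$q2y <- perm$q2y
      out$r2y_intercept <- perm$r2y_intercept
      out$q2y_intercept <- perm$q2y_intercept
      out$valid <- perm$valid
      out
    }, error = function(e) {
      out$infeasible <- conditionMessage(e)
      out
    })
    res
  })
  tab <- do.call(rbind, rows)
  # per-normalization stage-2 pick: valid cell with max Q2Y
  for (nm in unique(tab$normalization)) {
    cand <- which(tab$normalization == nm & tab$valid)
    if (length(cand)) {
      o <- cand[order(-tab$q2y[cand], -tab$r2y[cand], tab$ncomp[cand])]
      tab$selected[o[1]] <- TRUE
    }
  }
  tab
}

#' Sweep VIP cutoffs over the screened configurations (stage 2)
#'
#' For each stage-1 selected configuration and each VIP cutoff: fit a PLSR
#' model on the training replicates only, score VIP, retain variables above
#' the cutoff, refit on the retained variables, and record RMSEE (training),
#' RMSEP (held-out replicate), R2Y, Q2Y and the permutation intercepts, all
#' computed on the training side except RMSEP. A cutoff retaining zero
#' variables marks the cell infeasible.
#'
#' @param s A [spectrum_set] including all replicates.
#' @param labels Class labels, one per sample of `s`.
#' @param screened Output of [screen_configurations()] (its `selected` rows
#'   define the configurations swept).
#' @param grid A [grid_spec].
#' @return Data frame of candidates (stage `"vip_sweep"`).
#' @export
vip_sweep <- function(s, labels, screened, grid = grid_spec()) {
  stopifnot(inherits(s, "spectrum_set"), inherits(grid, "grid_spec"))
  labels <- factor(labels)
  sel <- screened[screened$selected, , drop = FALSE]
  if (!nrow(sel)) stop("no stage-1 configuration was selected", call. = FALSE)
  split <- split_replicates(s, grid$test_replicate_index)
  is_test <- s$metadata$replicate_index == grid$test_replicate_index
  y_train <- dummy_code(labels[!is_test])
  y_test_lab <- factor(labels[is_test], levels = levels(droplevels(labels[!is_test])))

  rows <- list()
  for (j in seq_len(nrow(sel))) {
    cfg <- sel[j, ]
    Xtr_full <- run_preprocess(split$train,
                               normalization_config(cfg$normalization))$intensities
    Xte_full <- run_preprocess(split$test,
                               normalization_config(cfg$normalization))$intensities
    base_fit <- fit_pls(Xtr_full, y_train, cfg$ncomp, scaling = cfg$scaling,
                        class_labels = labels[!is_test])
    vips <- vip_scores(base_fit)
    for (cutoff in grid$vip_cutoffs) {
      out <- data.frame(stage = "vip_sweep",
                        normalization = cfg$normalization,
                        scaling = cfg$scaling, ncomp = cfg$ncomp,
                        vip_cutoff = cutoff, retained = NA_integer_,
                        r2y = NA_real_, q2y = NA_real_,
                        r2y_intercept = NA_real_, q2y_intercept = NA_real_,
                        rmsee = NA_real_, rmsep = NA_real_,
                        valid = FALSE, selected = FALSE,
                        infeasible = NA_character_,
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        ids <- select_by_vip(vips, cutoff)
        Xtr <- Xtr_full[, ids, drop = FALSE]
        Xte <- Xte_full[, ids, drop = FALSE]
        ncomp_eff <- min(cfg$ncomp, ncol(Xtr), nrow(Xtr) - 1)
        fit <- fit_pls(Xtr, y_train, ncomp_eff, scaling = cfg$scaling,
                       class_labels = labels[!is_test])
        perm <- permutation_test(Xtr, y_train, ncomp_eff,
                                 n_permutations = grid$n_permutations,
                                 scaling = cfg$scaling, seed = grid$seed,
                                 n_folds = grid$n_folds)
        out$retained <- length(ids)
        out$r2y <- fit$r2y_cum[ncomp_eff]
        out$q2y <- perm$q2y
        out$r2y_intercept <- perm$r2y_intercept
        out$q2y_intercept <- perm$q2y_intercept
        out$valid <- perm$valid
        out$rmsee <- rmsee(fit, Xtr, y_train)
        out$rmsep <- rmsep(fit, Xte, dummy_code_as(y_test_lab, y_train))
        out
      }, error = function(e) {
        out$infeasible <- conditionMessage(e)
        out
      })
      rows[[length(rows) + 1L]] <- res
    }
  }
  do.call(rbind, rows)
}

# dummy-code test labels on the training coding (levels fixed by training)
dummy_code_as <- function(labels, Y_train) {
  lv <- attr(Y_train, "class_levels")
  f <- factor(labels, levels = lv)
  if (anyNA(f)) stop("test labels outside training classes", call. = FALSE)
  if (length(lv) == 2) {
    matrix(as.numeric(f) - 1, ncol = 1)
  } else {
    m <- matrix(0, length(f), length(lv), dimnames = list(NULL, lv))
    m[cbind(seq_along(f), as.integer(f))] <- 1
    m
  }
}

#' Pick the best candidate from a sweep table
#'
#' Among valid candidates, returns the row with the lowest RMSEP; ties are
#' broken by higher Q2Y, then fewer retained variables, then fewer
#' components. With no valid candidate a "no-winner" result carrying the
#' full table is returned.
#'
#' @param candidates Data frame from [vip_sweep()] (or a combined table;
#'   only rows with an RMSEP value compete).
#' @return List with `winner` (one-row data frame or `NULL`) and
#'   `candidates`.
#' @export
select_best <- function(candidates) {
  if (is.null(candidates) || !nrow(candidates)) {
    stop("no candidates to select from", call. = FALSE)
  }
  pool <- candidates[candidates$valid & !is.na(candidates$rmsep), ,
                     drop = FALSE]
  if (!nrow(pool)) {
    return(list(winner = NULL, candidates = candidates))
  }
  o <- order(pool$rmsep, -pool$q2y, pool$retained, pool$ncomp)
  list(winner = pool[o[1], , drop = FALSE], candidates = candidates)
}

#' Run a full discrimination task
#'
#' Filters the samples for the task, then runs the two-stage selection:
#' configuration screening on all replicates, VIP-cutoff sweep on the
#' replicate split, and winner selection by RMSEP among valid candidates.
#' For two-class age tasks the winner's errors are also converted to months
#' (12 months between adjacent age classes), and test-replicate class calls
#' are reported.
#'
#' @param s A [spectrum_set] with populated metadata.
#' @param task `"age_within_part"` (labels = age class, samples restricted
#'   to one `part`) or `"part_within_age"` (labels = part, samples
#'   restricted to one `age_class`).
#' @param subset For `age_within_part`, the part to analyse
#'   (`"tap_root"`, `"rhizome"` or `"lateral_root"`); for
#'   `part_within_age`, the age class (`"5yr"` or `"6yr"`).
#' @param grid A [grid_spec].
#' @return A `discrimination_report`: list with `task`, `subset`,
#'   `screen` and `sweep` candidate tables, `winner`, `months` (RMSEP in
#'   months, two-class tasks only), `test_accuracy` and `test_calls`.
#' @export
run_discrimination <- function(s, task = c("age_within_part",
                                           "part_within_age"),
                               subset, grid = grid_spec()) {
  task <- match.arg(task)
  stopifnot(inherits(s, "spectrum_set"))
  meta <- s$metadata
  if (task == "age_within_part") {
    keep <- meta$part == subset
    labels_all <- meta$age_class
  } else {
    keep <- meta$age_class == subset
    labels_all <- meta$part
  }
  if (!any(keep, na.rm = TRUE)) {
    stop("no samples match subset '", subset, "'", call. = FALSE)
  }
  keep[is.na(keep)] <- FALSE
  sub <- subset_samples(s, keep)
  labels <- factor(labels_all[keep])
  if (nlevels(droplevels(labels)) < 2) {
    stop("task has a single class after filtering", call. = FALSE)
  }
  screen <- screen_configurations(sub, labels, grid)
  sweep_tab <- vip_sweep(sub, labels, screen, grid)
  best <- select_best(sweep_tab)

  months <- NULL
  test_accuracy <- NA_real_
  test_calls <- NULL
  if (!is.null(best$winner)) {
    w <- best$winner
    # refit the winning candidate to obtain test-set class calls
    split <- split_replicates(sub, grid$test_replicate_index)
    is_test <- sub$metadata$replicate_index == grid$test_replicate_index
    Xtr <- run_preprocess(split$train,
                          normalization_config(w$normalization))$intensities
    Xte <- run_preprocess(split$test,
                          normalization_config(w$normalization))$intensities
    ytr_lab <- factor(labels[!is_test])
    fit0 <- fit_pls(Xtr, dummy_code(ytr_lab), w$ncomp, scaling = w$scaling)
    ids <- select_by_vip(vip_scores(fit0), w$vip_cutoff)
    fit <- fit_pls(Xtr[, ids, drop = FALSE], dummy_code(ytr_lab),
                   w$ncomp, scaling = w$scaling, class_labels = ytr_lab)
    pred <- predict(fit, Xte[, ids, drop = FALSE])
    truth <- factor(labels[is_test], levels = levels(pred$class))
    test_calls <- data.frame(sample_id = split$test$metadata$sample_id,
                             truth = truth, call = pred$class,
                             stringsAsFactors = FALSE)
    test_accuracy <- mean(pred$class == truth)
    if (nlevels(droplevels(labels)) == 2 && task == "age_within_part") {
      months <- rmse_to_months(w$rmsep)
    }
  }
  structure(list(task = task, subset = subset, grid = grid,
                 screen = screen, sweep = sweep_tab,
                 winner = best$winner, months = months,
                 test_accuracy = test_accuracy, test_calls = test_calls),
            class = "discrimination_report")
}

#' @export
print.discrimination_report <- function(x, ...) {
  cat(sprintf("<discrimination_report> task=%s subset=%s\n", x$task, x$subset))
  cat(sprintf("  screened %d cells (%d valid), swept %d VIP cells\n",
              nrow(x$screen), sum(x$screen$valid), nrow(x$sweep)))
  if (is.null(x$winner)) {
    cat("  no valid candidate survived the gate (no winner)\n")
  } else {
    w <- x$winner
    cat(sprintf(
      "  winner: %s / %s / A=%d / VIP>%.2g -> %d variables, RMSEP %.4g%s\n",
      w$normalization, w$scaling, w$ncomp, w$vip_cutoff, w$retained, w$rmsep,
      if (!is.null(x$months)) sprintf(" (%.4g months)", x$months) else ""))
    cat(sprintf("  test-replicate accuracy: %.3f\n", x$test_accuracy))
  }
  invisible(x)
}
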