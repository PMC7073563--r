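# Ensemble-of-random-forests feature selection: a stratified model /
# independent-test split, grid-tuned hyperparameters, many stratified
# train/holdout resamples each training its own forest, per-class F1 and
# importance distributions, per-class top-k selection, and Mood's median
# test comparing full versus restricted feature sets.

#' Ensemble configuration
#'
#' Bundles every tunable of the feature-selection procedure. Defaults are
#' the full-scale settings (500 resamples, 75/25 train/holdout within an
#' 80/20 model/independent-test split, mtry grid 1..100, ntree grid
#' \{250, 500, 1000, 2000\}, fivefold CV, top 40 features per class).
#'
#' @param n_iterations Number of resamples (default 500).
#' @param train_fraction Training fraction within each resample (0.75).
#' @param model_fraction Model-set fraction of the initial split (0.8).
#' @param mtry_grid,ntree_grid Hyperparameter grids.
#' @param cv_folds Cross-validation folds for tuning (5).
#' @param top_k Features selected per class (40).
#' @param seed Integer seed fanned out to every stochastic step.
#' @return An `ensemble_config` list.
#' @export
ensemble_config <- function(n_iterations = 500, train_fraction = 0.75,
                            model_fraction = 0.8, mtry_grid = 1:100,
                            ntree_grid = c(250, 500, 1000, 2000),
                            cv_folds = 5, top_k = 40, seed = 1L) {
  assert_fraction(train_fraction)
  assert_fraction(model_fraction)
  if (!length(mtry_grid) || !length(ntree_grid)) {
    abort("Hyperparameter grids must be non-empty.")
  }
  structure(
    list(n_iterations = assert_count(n_iterations),
         train_fraction = train_fraction,
         model_fraction = model_fraction,
         mtry_grid = as.integer(mtry_grid),
         ntree_grid = as.integer(ntree_grid),
         cv_folds = assert_count(cv_folds, 2),
         top_k = assert_count(top_k),
         seed = as.integer(seed)),
    class = "ensemble_config"
  )
}

#' Split samples into a model set and an independent test set
#'
#' Stratified by tumor type: per class the test count is
#' `round((1 - model_fraction) * n_class)` with a minimum of 1, so every
#' class is represented on both sides. The two sets partition the samples.
#'
#' @param meta Sample metadata tibble.
#' @param model_fraction Fraction of each class kept in the model set.
#' @param seed Integer seed.
#' @return List with `model_ids` and `test_ids`.
#' @export
split_model_test <- function(meta, model_fraction = 0.8, seed = 1L) {
  assert_metadata(meta)
  assert_fraction(model_fraction)
  tab <- table(meta$tumor_type)
  if (any(tab < 2)) {
    abort(sprintf("Class '%s' has fewer than 2 samples.",
                  names(tab)[which.min(tab)]))
  }
  with_seed(seed, {
    test_ids <- character(0)
    for (cl in names(tab)) {
      ids <- meta$sample_id[meta$tumor_type == cl]
      n_test <- max(round((1 - model_fraction) * length(ids)), 1L)
      n_test <- min(n_test, length(ids) - 1L)
      test_ids <- c(test_ids, sample(ids, n_test))
    }
    list(model_ids = setdiff(meta$sample_id, test_ids),
         test_ids = sort(test_ids))
  })
}

# Stratified fold assignment: shuffle each class and deal round-robin.
.stratified_folds <- function(labels, k) {
  fold <- integer(length(labels))
  for (cl in levels(labels)) {
    idx <- sample(which(labels == cl))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

.fit_forest <- function(x, y, mtry, ntree, importance = FALSE) {
  randomForest::randomForest(x = x, y = y, mtry = mtry, ntree = ntree,
                             importance = importance)
}

#' Tune random-forest hyperparameters by stratified cross-validation
#'
#' Evaluates every (mtry, ntree) grid point by mean macro-F1 over stratified
#' k-fold cross-validation on the supplied samples; ties resolve to the
#' smallest ntree, then the smallest mtry. Grid points with
#' `mtry > n_features` are skipped.
#'
#' @param B LVs x samples score matrix (features in rows).
#' @param labels Factor of tumor types, aligned with `colnames(B)`.
#' @param config An [ensemble_config()].
#' @return List with `mtry`, `ntrees` and the full `grid` tibble of mean CV
#'   macro-F1 scores.
#' @export
tune_hyperparams <- function(B, labels, config = ensemble_config()) {
  assert_named_matrix(B, "B")
  labels <- droplevels(as.factor(labels))
  stopifnot(length(labels) == ncol(B))
  x <- t(B)
  grid <- expand.grid(mtry = config$mtry_grid, ntrees = config$ntree_grid)
  grid <- grid[grid$mtry <= nrow(B), , drop = FALSE]
  if (!nrow(grid)) abort("Every grid point has mtry > n_features.")
  with_seed(config$seed, {
    fold <- .stratified_folds(labels, config$cv_folds)
    score <- vapply(seq_len(nrow(grid)), function(g) {
      f1 <- vapply(seq_len(config$cv_folds), function(k) {
        tr <- fold != k
        if (length(unique(labels[tr])) < nlevels(labels)) return(NA_real_)
        fit <- .fit_forest(x[tr, , drop = FALSE], labels[tr],
                           grid$mtry[g], grid$ntrees[g])
        pred <- predict(fit, x[!tr, , drop = FALSE])
        mean(f1_by_class(labels[!tr], pred, levels(labels)))
      }, numeric(1))
      mean(f1, na.rm = TRUE)
    }, numeric(1))
  })
  grid$mean_macro_f1 <- score
  best <- order(-score, grid$ntrees, grid$mtry)[1L]
  list(mtry = grid$mtry[best], ntrees = grid$ntrees[best],
       grid = tibble::as_tibble(grid))
}

#' Train an ensemble of random forests over stratified resamples
#'
#' For each of `n_iterations` stratified train/holdout resamples (sampled
#' without replacement) a forest is trained at the tuned (mtry, ntrees).
#' Per-class F1 (one-vs-rest, from the multiclass confusion matrix) is
#' recorded on the designated evaluation set — the resample's holdout part,
#' or a fixed independent test set — together with per-class permutation
#' importance (mean decrease in class-wise accuracy under feature
#' permutation, the forest's raw importance) and Gini importance for every
#' feature. A resample whose training part misses a class is redrawn (at
#' most 100 times).
#'
#' @param B LVs x samples score matrix covering the model-set samples.
#' @param labels Factor of tumor types aligned with `colnames(B)`.
#' @param features LV ids to use as features (default: all rows of `B`).
#' @param config An [ensemble_config()]; `mtry`/`ntrees` override the
#'   config when given.
#' @param evaluate_on `"holdout"` (each resample's 25%) or `"independent"`.
#' @param mtry,ntrees Tuned hyperparameters (defaults: floor(sqrt(p)), 500).
#' @param independent_B,independent_labels Evaluation data for
#'   `evaluate_on = "independent"`.
#' @return An `lv_ensemble`: `f1` (iteration x class), `importance_permutation`
#'   (iteration x class x feature), `importance_gini` (iteration x feature),
#'   plus the settings used.
#' @export
run_ensemble <- function(B, labels, features = rownames(B),
                         config = ensemble_config(),
                         evaluate_on = c("holdout", "independent"),
                         mtry = NULL, ntrees = NULL,
                         independent_B = NULL, independent_labels = NULL) {
  assert_named_matrix(B, "B")
  evaluate_on <- match.arg(evaluate_on)
  labels <- droplevels(as.factor(labels))
  stopifnot(length(labels) == ncol(B))
  if (!all(features %in% rownames(B))) {
    abort("`features` must be a subset of the rows of `B`.")
  }
  mtry <- mtry %||% max(1L, floor(sqrt(length(features))))
  mtry <- min(mtry, length(features))
  ntrees <- ntrees %||% 500L
  if (evaluate_on == "independent") {
    if (is.null(independent_B) || is.null(independent_labels)) {
      abort("Independent evaluation needs `independent_B` and `independent_labels`.")
    }
    xi <- t(independent_B[features, , drop = FALSE])
    yi <- factor(as.character(independent_labels), levels = levels(labels))
  }

  x <- t(B[features, , drop = FALSE])
  classes <- levels(labels)
  n_it <- config$n_iterations
  f1 <- matrix(NA_real_, n_it, length(classes),
               dimnames = list(NULL, classes))
  imp_perm <- array(NA_real_, c(n_it, length(classes), length(features)),
                    dimnames = list(NULL, classes, features))
  imp_gini <- matrix(NA_real_, n_it, length(features),
                     dimnames = list(NULL, features))

  with_seed(config$seed, {
    for (it in seq_len(n_it)) {
      for (try in seq_len(100L)) {
        tr_idx <- stratified_split(labels, config$train_fraction)
        if (length(unique(labels[tr_idx])) == length(classes) &&
            length(tr_idx) < length(labels)) break
        if (try == 100L) abort("Could not draw a resample covering all classes.")
      }
      fit <- .fit_forest(x[tr_idx, , drop = FALSE], labels[tr_idx],
                         mtry, ntrees, importance = TRUE)
      if (evaluate_on == "holdout") {
        ev_x <- x[-tr_idx, , drop = FALSE]
        ev_y <- labels[-tr_idx]
      } else {
        ev_x <- xi
        ev_y <- yi
      }
      pred <- predict(fit, ev_x)
      f1[it, ] <- f1_by_class(ev_y, pred, classes)
      imp <- randomForest::importance(fit, scale = FALSE)
      imp_perm[it, , ] <- t(imp[, classes, drop = FALSE])
      imp_gini[it, ] <- imp[, "MeanDecreaseGini"]
    }
  })

  structure(
    list(f1 = f1, importance_permutation = imp_perm,
         importance_gini = imp_gini, classes = classes,
         features = features, mtry = mtry, ntrees = ntrees,
         evaluate_on = evaluate_on, n_iterations = n_it,
         seed = config$seed),
    class = "lv_ensemble"
  )
}

#' @export
print.lv_ensemble <- function(x, ...) {
  cat(sprintf(
    "<lv_ensemble> %d iterations, %d features, mtry %d, ntrees %d, evaluated on %s\n",
    x$n_iterations, length(x$features), x$mtry, x$ntrees, x$evaluate_on))
  med <- apply(x$f1, 2L, median)
  cat("  median F1:", paste(sprintf("%s %.2f", names(med), med),
                            collapse = ", "), "\n")
  invisible(x)
}

#' @method tidy lv_ensemble
#' @export
tidy.lv_ensemble <- function(x, ...) {
  tibble::as_tibble(x$f1) |>
    dplyr::mutate(iteration = dplyr::row_number()) |>
    tidyr::pivot_longer(-"iteration", names_to = "class", values_to = "f1")
}

#' @method glance lv_ensemble
#' @export
glance.lv_ensemble <- function(x, ...) {
  tibble::tibble(
    n_iterations = x$n_iterations,
    n_features = length(x$features),
    mtry = x$mtry,
    ntrees = x$ntrees,
    evaluate_on = x$evaluate_on,
    median_macro_f1 = median(rowMeans(x$f1))
  )
}

#' Select top features per class from an ensemble
#'
#' Ranks features per class by their median importance over iterations and
#' takes the top `top_k` per class; ties break by feature id. The default
#' metric is per-class permutation importance (mean decrease in class-wise
#' accuracy), which yields class-specific lists; `"gini"` applies the
#' class-agnostic Gini ranking to every class.
#'
#' @param result An `lv_ensemble`.
#' @param top_k Features per class (default 40).
#' @param metric `"permutation"` or `"gini"`.
#' @return An `lv_selection`: `union` (sorted LV ids), `per_class` (named
#'   list of ranked LV vectors), `medians` (long tibble).
#' @export
select_top_features <- function(result, top_k = 40,
                                metric = c("permutation", "gini")) {
  stopifnot(inherits(result, "lv_ensemble"))
  metric <- match.arg(metric)
  top_k <- assert_count(top_k)
  feats <- result$features
  if (top_k > length(feats)) {
    warn(sprintf("top_k = %d exceeds %d features; capped.", top_k,
                 length(feats)))
    top_k <- length(feats)
  }
  med_gini <- apply(result$importance_gini, 2L, median)
  per_class <- list()
  med_rows <- list()
  for (cl in result$classes) {
    med <- if (metric == "gini") med_gini else
      apply(result$importance_permutation[, cl, , drop = FALSE], 3L, median)
    ord <- order(-med, feats)
    per_class[[cl]] <- feats[ord][seq_len(top_k)]
    med_rows[[cl]] <- tibble::tibble(class = cl, lv = feats,
                                     median_importance = unname(med))
  }
  structure(
    list(union = sort(unique(unlist(per_class, use.names = FALSE))),
         per_class = per_class,
         medians = dplyr::bind_rows(med_rows),
         metric = metric, top_k = top_k),
    class = "lv_selection"
  )
}

#' @export
print.lv_selection <- function(x, ...) {
  cat(sprintf("<lv_selection> top %d per class by %s importance; union of %d LVs\n",
              x$top_k, x$metric, length(x$union)))
  invisible(x)
}

#' Mood's median test
#'
#' Pools the two samples, counts values above versus at-or-below the pooled
#' median per sample, and applies a chi-square test without continuity
#' correction to the 2x2 table. Degenerate tables (a zero margin, e.g. all
#' values identical) return p = 1.
#'
#' @param x,y Numeric vectors.
#' @return List with `statistic` (chi-square), `p_value`, and the 2x2
#'   `table`.
#' @export
mood_median_test <- function(x, y) {
  if (!length(x) || !length(y)) abort("Both samples must be non-empty.")
  m <- median(c(x, y))
  tab <- rbind(x = c(above = sum(x > m), at_or_below = sum(x <= m)),
               y = c(above = sum(y > m), at_or_below = sum(y <= m)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(list(statistic = 0, p_value = 1, table = tab))
  }
  ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, table = tab)
}

#' Compare per-class F1 distributions of two ensembles
#'
#' Applies Mood's median test per class to the full-feature and
#' restricted-feature F1 distributions and reports both medians and the
#' two-sided p-value.
#'
#' @param f1_full,f1_restricted Iteration x class F1 matrices with matching
#'   class columns (e.g. the `f1` component of two `lv_ensemble`s).
#' @return Tibble: class, median_full, median_restricted, p_value.
#' @export
compare_restricted <- function(f1_full, f1_restricted) {
  if (inherits(f1_full, "lv_ensemble")) f1_full <- f1_full$f1
  if (inherits(f1_restricted, "lv_ensemble")) {
    f1_restricted <- f1_restricted$f1
  }
  classes <- intersect(colnames(f1_full), colnames(f1_restricted))
  if (!length(classes)) abort("No shared classes.")
  purrr::map_dfr(classes, function(cl) {
    mt <- mood_median_test(f1_full[, cl], f1_restricted[, cl])
    tibble::tibble(class = cl,
                   median_full = median(f1_full[, cl]),
                   median_restricted = median(f1_restricted[, cl]),
                   statistic = mt$statistic,
                   p_value = mt$p_value)
  })
}
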