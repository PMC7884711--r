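#' Model configuration and decision thresholds
#'
#' `model_config()` collects the regressor settings: number of selected
#' features, forest size, seed, and where feature ranking happens.
#' `selection_mode = "nested"` (default) ranks features inside each training
#' fold, avoiding selection leakage into cross-validation metrics;
#' `"global"` ranks once on the full data before the folds are formed, the
#' reading of the original workflow, and is kept for reproducing its printed
#' metrics (its leakage risk is documented in the methods vignette).
#'
#' @param n_features number of top-ranked features the model uses.
#' @param n_trees trees in the forest (default 500).
#' @param seed integer seed; all forest randomness derives from it.
#' @param selection_mode `"nested"` or `"global"`.
#' @param mtry features tried per split; default `floor(n_features / 3)`.
#' @param nodesize minimum terminal node size (default 5).
#' @return An object of class `"model_config"`.
#' @export
model_config <- function(n_features = 250L, n_trees = 500L, seed = 1L,
                         selection_mode = c("nested", "global"),
                         mtry = NULL, nodesize = 5L) {
  selection_mode <- match.arg(selection_mode)
  stopifnot(n_features >= 1L, n_trees >= 1L, nodesize >= 1L)
  structure(list(n_features = as.integer(n_features),
                 n_trees = as.integer(n_trees), seed = as.integer(seed),
                 selection_mode = selection_mode,
                 mtry = if (is.null(mtry)) NULL else as.integer(mtry),
                 nodesize = as.integer(nodesize)),
            class = "model_config")
}

#' @rdname model_config
#' @param efficiency_cutoff_log10 efficient/inefficient cutoff on log10
#'   penetration intensity (default 2.5; boundary counts as efficient).
#' @param toxicity_cutoff_pct cytotoxic/safe cutoff on the max-OD ratio in
#'   percent (default 50; boundary counts as safe).
#' @export
thresholds <- function(efficiency_cutoff_log10 = 2.5,
                       toxicity_cutoff_pct = 50) {
  stopifnot(is.finite(efficiency_cutoff_log10), is.finite(toxicity_cutoff_pct))
  structure(list(efficiency_cutoff_log10 = efficiency_cutoff_log10,
                 toxicity_cutoff_pct = toxicity_cutoff_pct),
            class = "thresholds")
}

#' Rank features by absolute Pearson correlation with the target
#'
#' One entry per feature; constant features get `r = 0`. Ordering is by
#' `|r|` descending with ties broken by canonical feature (column) order, so
#' rankings are stable across runs.
#'
#' @param X_t transformed feature matrix (peptides x features).
#' @param y_t log10 penetration efficiencies, aligned with rows of `X_t`.
#' @return A data frame of class `"feature_ranking"` with columns `feature`,
#'   `r`, `abs_r`, ordered by `abs_r` descending.
#' @export
rank_features <- function(X_t, y_t) {
  stopifnot(is.matrix(X_t), nrow(X_t) >= 3L)
  if (length(y_t) != nrow(X_t)) stop("X_t and y_t are not aligned",
                                     call. = FALSE)
  r <- suppressWarnings(as.numeric(cor(X_t, y_t)))
  r[!is.finite(r)] <- 0
  o <- order(-abs(r), seq_along(r))
  structure(data.frame(feature = colnames(X_t)[o], r = r[o],
                       abs_r = abs(r)[o], stringsAsFactors = FALSE),
            class = c("feature_ranking", "data.frame"))
}

#' @rdname rank_features
#' @param ranking a `feature_ranking` data frame.
#' @param n how many top features to keep.
#' @return `select_top()`: character vector of the first `n` feature names.
#' @export
select_top <- function(ranking, n) {
  stopifnot(inherits(ranking, "feature_ranking"))
  if (n < 1L || n > nrow(ranking))
    stop("n out of range [1, ", nrow(ranking), "]", call. = FALSE)
  ranking$feature[seq_len(n)]
}

#' Fit the random-forest regressor
#'
#' Bootstrap-aggregated variance-reduction regression trees with per-split
#' feature subsampling (`mtry = n_features / 3` by default, unrestricted
#' depth, terminal nodes of at least `nodesize`). Fully reproducible given
#' the config seed; predictions are averages of training targets and hence
#' bounded by the training-target range.
#'
#' @param X_sel selected-feature matrix (rows = peptides, columns =
#'   `config$n_features` features).
#' @param y_t log10 efficiencies.
#' @param config a [model_config()].
#' @return An object of class `"cpp_forest"`.
#' @export
fit_regressor <- function(X_sel, y_t, config = model_config()) {
  stopifnot(is.matrix(X_sel), nrow(X_sel) >= 2L,
            length(y_t) == nrow(X_sel))
  mtry <- if (is.null(config$mtry)) max(1L, ncol(X_sel) %/% 3L)
          else config$mtry
  set.seed(config$seed)
  trees <- rf_fit_cpp(X_sel, as.numeric(y_t), config$n_trees, mtry,
                      config$nodesize)
  structure(list(trees = trees, feature_names = colnames(X_sel),
                 y_range = range(y_t), config = config),
            class = "cpp_forest")
}

#' @rdname fit_regressor
#' @param object a fitted `cpp_forest`.
#' @param newdata matrix with (at least) the model's feature columns.
#' @param ... unused.
#' @export
predict.cpp_forest <- function(object, newdata, ...) {
  if (!is.matrix(newdata)) newdata <- as.matrix(newdata)
  if (!is.null(colnames(newdata)) && !is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  out <- rf_predict_cpp(object$trees, newdata)
  names(out) <- rownames(newdata)
  out
}

#' Classify log10 efficiencies at the cutoff
#'
#' @param values finite log10 penetration efficiencies.
#' @param cutoffs a [thresholds()] object.
#' @return Character vector of `"efficient"` (value >= cutoff, boundary
#'   inclusive) or `"inefficient"`.
#' @export
classify <- function(values, cutoffs = thresholds()) {
  stopifnot(all(is.finite(values)))
  ifelse(values >= cutoffs$efficiency_cutoff_log10, "efficient",
         "inefficient")
}

#' k-fold cross-validation of the selection + forest pipeline
#'
#' Rows are partitioned into `k` near-equal folds by a seeded shuffle. For
#' each fold, features are ranked and selected per
#' `config$selection_mode`, a forest is trained on the remaining rows, and
#' out-of-fold predictions are recorded. Metrics are computed on the pooled
#' out-of-fold predictions: `R2 = 1 - SS_res / SS_tot`, RMSE, and the
#' percentage of peptides whose thresholded prediction matches the
#' thresholded truth.
#'
#' @param X_t transformed feature matrix.
#' @param y_t log10 efficiencies.
#' @param config a [model_config()].
#' @param k number of folds (default 10).
#' @param seed seed for the fold shuffle.
#' @param cutoffs a [thresholds()] object.
#' @param fold_assignment optional integer vector in `1..k` overriding the
#'   shuffle (used by [sweep_n()] to share folds across the grid).
#' @return An object of class `"cv_report"`: `fold_assignment`, `oof_pred`,
#'   `r_squared`, `rmse`, `accuracy_pct`, `k`, `selected_features` (list,
#'   one character vector per fold), `config`.
#' @export
cross_validate <- function(X_t, y_t, config = model_config(), k = 10L,
                           seed = config$seed, cutoffs = thresholds(),
                           fold_assignment = NULL) {
  n <- nrow(X_t)
  if (k > n) stop("k = ", k, " exceeds the number of rows (", n, ")",
                  call. = FALSE)
  if (config$n_features > ncol(X_t))
    stop("n_features exceeds the number of available features",
         call. = FALSE)
  if (is.null(fold_assignment)) {
    set.seed(seed)
    fold_assignment <- integer(n)
    fold_assignment[sample.int(n)] <- rep(seq_len(k), length.out = n)
  }
  stopifnot(length(fold_assignment) == n)
  ranking_full <- if (config$selection_mode == "global")
    rank_features(X_t, y_t) else NULL
  oof <- rep(NA_real_, n)
  sel_by_fold <- vector("list", k)
  for (j in seq_len(k)) {
    test <- fold_assignment == j
    ranking <- if (is.null(ranking_full))
      rank_features(X_t[!test, , drop = FALSE], y_t[!test])
    else ranking_full
    sel <- select_top(ranking, config$n_features)
    sel_by_fold[[j]] <- sel
    fold_cfg <- config
    fold_cfg$seed <- config$seed + j
    fit <- fit_regressor(X_t[!test, sel, drop = FALSE], y_t[!test], fold_cfg)
    oof[test] <- predict(fit, X_t[test, sel, drop = FALSE])
  }
  resid <- y_t - oof
  r2 <- 1 - sum(resid^2) / sum((y_t - mean(y_t))^2)
  acc <- 100 * mean(classify(oof, cutoffs) == classify(y_t, cutoffs))
  names(oof) <- rownames(X_t)
  names(fold_assignment) <- rownames(X_t)
  structure(list(fold_assignment = fold_assignment, oof_pred = oof,
                 r_squared = r2, rmse = sqrt(mean(resid^2)),
                 accuracy_pct = acc, k = as.integer(k),
                 selected_features = sel_by_fold, config = config),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "<cv_report> %d-fold CV, %d features (%s selection): R2 = %.3f, RMSE = %.3f, accuracy = %.1f%%\n",
    x$k, x$config$n_features, x$config$selection_mode, x$r_squared, x$rmse,
    x$accuracy_pct))
  invisible(x)
}

#' Sweep the number of selected features
#'
#' Runs one [cross_validate()] per grid value with a shared fold
#' assignment, and returns the grid value with the highest out-of-fold R2
#' (ties go to the smaller n).
#'
#' @param X_t,y_t as in [cross_validate()].
#' @param grid candidate feature counts (default 50, 100, ..., 500).
#' @param config a [model_config()]; its `n_features` is overridden.
#' @param k,seed,cutoffs as in [cross_validate()].
#' @return A list with `best_n` and `table` (data frame `n`, `r_squared`,
#'   `rmse`, `accuracy_pct`).
#' @export
sweep_n <- function(X_t, y_t, grid = seq(50L, 500L, by = 50L),
                    config = model_config(), k = 10L, seed = config$seed,
                    cutoffs = thresholds()) {
  if (any(grid > ncol(X_t)))
    stop("grid values exceed the number of features", call. = FALSE)
  n <- nrow(X_t)
  set.seed(seed)
  fold_assignment <- integer(n)
  fold_assignment[sample.int(n)] <- rep(seq_len(k), length.out = n)
  rows <- lapply(grid, function(g) {
    cfg <- config
    cfg$n_features <- as.integer(g)
    rep_ <- cross_validate(X_t, y_t, cfg, k = k, cutoffs = cutoffs,
                           fold_assignment = fold_assignment)
    data.frame(n = g, r_squared = rep_$r_squared, rmse = rep_$rmse,
               accuracy_pct = rep_$accuracy_pct)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$n), , drop = FALSE]
  rownames(tab) <- NULL
  best <- tab$n[order(-tab$r_squared, tab$n)][1]
  list(best_n = best, table = tab)
}
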