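#' Train a penetration-efficiency model bundle from a screen
#'
#' Convenience wrapper over the full training path: featurize the screen,
#' fit the log/normalization transform, rank features against log10
#' intensity, select the top `config$n_features`, and fit the forest. The
#' returned bundle carries everything needed to score new sequences.
#'
#' @param screen a `cpp_screen` data frame with non-missing positive
#'   `intensity_au` (rows with missing intensity are dropped).
#' @param config a [model_config()].
#' @param aaindex scale battery, see [load_aaindex()].
#' @return An object of class `"model_bundle"`: `forest`, `transform`,
#'   `features` (selected names), `ranking`, `config`, `version`.
#' @export
train_model <- function(screen, config = model_config(),
                        aaindex = load_aaindex()) {
  screen <- screen[!is.na(screen$intensity_au), , drop = FALSE]
  X <- featurize_set(screen, aaindex)
  tr <- fit_transform(X, screen$intensity_au)
  ranking <- rank_features(tr$X_t, tr$y_t)
  sel <- select_top(ranking, config$n_features)
  fit <- fit_regressor(tr$X_t[, sel, drop = FALSE], tr$y_t, config)
  structure(list(forest = fit, transform = tr$params, features = sel,
                 ranking = ranking, config = config,
                 version = as.character(utils::packageVersion("cppscreen"))),
            class = "model_bundle")
}

#' @rdname train_model
#' @param bundle a `model_bundle`.
#' @param peptides list of `peptide` objects (or a `cpp_screen`).
#' @return `predict_peptides()`: named numeric vector of predicted log10
#'   penetration intensities (A.U.).
#' @export
predict_peptides <- function(bundle, peptides, aaindex = load_aaindex()) {
  stopifnot(inherits(bundle, "model_bundle"))
  X <- featurize_set(peptides, aaindex)
  X_t <- apply_transform(bundle$transform, X)
  predict(bundle$forest, X_t[, bundle$features, drop = FALSE])
}

#' Persist and reload a model bundle
#'
#' The bundle is written as a single JSON archive: a manifest (package
#' version, config, selected feature names, transform parameters) plus a
#' portable serialization of every tree (node matrices). Numbers are
#' written at full precision so a reloaded bundle reproduces predictions
#' bit-for-bit.
#'
#' @param bundle a `model_bundle` from [train_model()].
#' @param path output `.json` path.
#' @export
save_model_bundle <- function(bundle, path) {
  stopifnot(inherits(bundle, "model_bundle"))
  # doubles as %.17g strings: decimal text that round-trips IEEE doubles
  # exactly, which plain JSON numbers (15 digits in jsonlite) do not
  dbl <- function(x) sprintf("%.17g", as.numeric(x))
  payload <- list(
    package = "cppscreen", version = bundle$version,
    config = unclass(bundle$config), features = bundle$features,
    transform = list(kind = bundle$transform$kind,
                     normalization = bundle$transform$normalization,
                     names = names(bundle$transform$center),
                     center = dbl(bundle$transform$center),
                     scale = dbl(bundle$transform$scale),
                     target_log_base = bundle$transform$target_log_base,
                     feature_names = bundle$transform$feature_names),
    y_range = dbl(bundle$forest$y_range),
    trees = lapply(bundle$forest$trees, function(t) list(
      var = as.integer(t[, "var"]), split = dbl(t[, "split"]),
      left = as.integer(t[, "left"]), right = as.integer(t[, "right"]),
      pred = dbl(t[, "pred"]))))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model_bundle
#' @export
load_model_bundle <- function(path) {
  pl <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                           simplifyMatrix = TRUE)
  if (!identical(pl$package, "cppscreen"))
    stop("not a cppscreen model bundle: ", path, call. = FALSE)
  cfg <- pl$config
  config <- model_config(cfg$n_features, cfg$n_trees, cfg$seed,
                         cfg$selection_mode,
                         mtry = cfg$mtry, nodesize = cfg$nodesize)
  tr <- pl$transform
  params <- structure(list(kind = tr$kind, normalization = tr$normalization,
                           center = stats::setNames(as.numeric(tr$center),
                                                    tr$names),
                           scale = stats::setNames(as.numeric(tr$scale),
                                                   tr$names),
                           target_log_base = tr$target_log_base,
                           feature_names = tr$feature_names),
                      class = "transform_params")
  raw_trees <- pl$trees
  if (is.data.frame(raw_trees))
    raw_trees <- lapply(seq_len(nrow(raw_trees)), function(i)
      lapply(raw_trees, function(col) col[[i]]))
  trees <- lapply(raw_trees, function(t) {
    m <- cbind(var = as.numeric(t$var), split = as.numeric(t$split),
               left = as.numeric(t$left), right = as.numeric(t$right),
               pred = as.numeric(t$pred))
    m
  })
  forest <- structure(list(trees = trees, feature_names = pl$features,
                           y_range = as.numeric(pl$y_range),
                           config = config),
                      class = "cpp_forest")
  structure(list(forest = forest, transform = params,
                 features = pl$features, ranking = NULL, config = config,
                 version = pl$version),
            class = "model_bundle")
}
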