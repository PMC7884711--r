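test_that("rank_features matches the direct Pearson oracle", {
  set.seed(101)
  X <- matrix(rnorm(5 * 3), 5, 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- rnorm(5)
  rk <- rank_features(X, y)
  oracle <- vapply(1:3, function(j) pearson_oracle(X[, j], y), numeric(1))
  expect_equal(rk$r[match(colnames(X), rk$feature)], oracle,
               tolerance = 1e-12)
  expect_true(all(diff(rk$abs_r) <= 1e-15))

  # exact +1 / -1 alignment ranks first
  X2 <- cbind(X, exact = y, neg = -y)
  rk2 <- rank_features(X2, y)
  expect_equal(rk2$feature[1], "exact")
  expect_equal(rk2$r[1], 1)
  rk3 <- rank_features(cbind(X, neg = -y), y)
  expect_equal(rk3$feature[1], "neg")
  expect_equal(rk3$r[1], -1)

  # constant features get r = 0 (not NA)
  rk4 <- rank_features(cbind(X, const = 1), y)
  expect_equal(rk4$r[rk4$feature == "const"], 0)
  expect_error(rank_features(X, y[1:3]), "aligned")
})

test_that("select_top is a stable prefix with canonical tie-break", {
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  y <- rnorm(10)
  X[, "c"] <- X[, "a"]  # identical |r|: canonical column order wins
  rk <- rank_features(X, y)
  expect_equal(select_top(rk, 3), rk$feature[1:3])
  ia <- which(rk$feature == "a"); ic <- which(rk$feature == "c")
  expect_lt(ia, ic)
  expect_equal(select_top(rk, 1), rk$feature[1])
  expect_error(select_top(rk, 4), "out of range")
  expect_error(select_top(rk, 0), "out of range")
})

test_that("forest: seeded determinism, range bound, near-interpolation", {
  set.seed(3)
  n <- 60
  X <- matrix(rnorm(n * 8), n, 8, dimnames = list(NULL, paste0("f", 1:8)))
  y <- X[, 1] * 2 + X[, 2] + rnorm(n, sd = 0.1)
  cfg <- model_config(n_features = 8, n_trees = 150, seed = 9, nodesize = 2)
  fit1 <- fit_regressor(X, y, cfg)
  fit2 <- fit_regressor(X, y, cfg)
  expect_identical(predict(fit1, X), predict(fit2, X))

  pin <- predict(fit1, X)
  r2_in <- 1 - sum((y - pin)^2) / sum((y - mean(y))^2)
  expect_gt(r2_in, 0.9)  # deep trees near-interpolate in-sample

  Xfar <- matrix(rnorm(200 * 8, sd = 5), 200, 8,
                 dimnames = list(NULL, paste0("f", 1:8)))
  pfar <- predict(fit1, Xfar)
  expect_true(all(pfar >= min(y) - 1e-12 & pfar <= max(y) + 1e-12))
})

test_that("cross_validate: fold structure, metrics vs brute force", {
  tr <- get_transformed(40L)
  cfg <- model_config(n_features = 30, n_trees = 80, seed = 5)
  cv <- cross_validate(tr$X_t, tr$y_t, cfg, k = 7)
  sizes <- table(cv$fold_assignment)
  expect_length(sizes, 7L)
  expect_lte(max(sizes) - min(sizes), 1L)       # near-equal folds
  expect_false(anyNA(cv$oof_pred))              # each row oof exactly once

  resid <- tr$y_t - cv$oof_pred
  expect_equal(cv$rmse, sqrt(mean(resid^2)), tolerance = 1e-12)
  expect_equal(cv$r_squared,
               1 - sum(resid^2) / sum((tr$y_t - mean(tr$y_t))^2),
               tolerance = 1e-12)
  # accuracy equals a brute-force confusion count at the 2.5 cutoff
  acc <- 100 * mean((cv$oof_pred >= 2.5) == (tr$y_t >= 2.5))
  expect_equal(cv$accuracy_pct, acc, tolerance = 1e-12)
  expect_error(cross_validate(tr$X_t, tr$y_t, cfg, k = 41), "exceeds")
})

test_that("nested selection sees no test-fold information", {
  set.seed(77)
  n <- 30; k <- 3
  fold <- rep(1:k, each = n / k)
  y <- rnorm(n)
  X <- matrix(rnorm(n * 4), n, 4)
  X[, 1] <- y + rnorm(n, sd = 0.1)          # honest signal everywhere
  leak <- rnorm(n)
  leak[fold == 1] <- y[fold == 1]           # perfect only on fold-1 test rows
  X <- cbind(X, leak)
  colnames(X) <- c("signal", "n1", "n2", "n3", "leak")
  cv <- cross_validate(X, y, model_config(n_features = 1, n_trees = 30,
                                          seed = 2, selection_mode = "nested"),
                       k = k, fold_assignment = fold)
  expect_false("leak" %in% cv$selected_features[[1]])
  expect_equal(cv$selected_features[[1]], "signal")
})

test_that("shuffled targets give no skill", {
  tr <- get_transformed(40L)
  cfg <- model_config(n_features = 30, n_trees = 60, seed = 5)
  set.seed(123)
  r2 <- vapply(1:3, function(i) {
    cross_validate(tr$X_t, sample(tr$y_t), cfg, k = 5, seed = i)$r_squared
  }, numeric(1))
  expect_lt(mean(r2), 0.1)
})

test_that("sweep_n shares folds and picks argmax with smaller-n ties", {
  tr <- get_transformed(40L)
  cfg <- model_config(n_trees = 60, seed = 5)
  sw <- sweep_n(tr$X_t, tr$y_t, grid = c(20L, 60L), config = cfg, k = 5)
  expect_true(sw$best_n %in% c(20L, 60L))
  expect_equal(sw$table$n, c(20L, 60L))
  expect_equal(sw$best_n, sw$table$n[which.max(sw$table$r_squared)])
  sw1 <- sweep_n(tr$X_t, tr$y_t, grid = 20L, config = cfg, k = 5)
  expect_equal(sw1$best_n, 20L)
  expect_error(sweep_n(tr$X_t, tr$y_t, grid = c(50L, 10000L), config = cfg),
               "exceed")
})

test_that("classify applies the inclusive 2.5 cutoff", {
  expect_equal(classify(c(log10(4043), log10(13), 2.5, 2.4999999)),
               c("efficient", "inefficient", "efficient", "inefficient"))
  expect_error(classify(c(1, NA)))
})

test_that("model bundle persists and reloads bit-for-bit", {
  sim <- get_sim(40L)
  bundle <- train_model(sim$screen,
                        model_config(n_features = 40, n_trees = 50, seed = 4))
  f <- withr::local_tempfile(fileext = ".json")
  save_model_bundle(bundle, f)
  b2 <- load_model_bundle(f)
  peps <- screen_peptides(sim$screen)
  expect_identical(predict_peptides(bundle, peps),
                   predict_peptides(b2, peps))
  expect_identical(b2$features, bundle$features)
  expect_equal(b2$config$n_features, bundle$config$n_features)
})
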