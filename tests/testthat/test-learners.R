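# Regressors, composite loss, parameter audit and evaluation metrics.

linear_dataset <- function(n = 500, sigma = 0.1, seed = 42) {
  w <- numeric(140)
  w[1] <- 3
  make_synthetic_dataset(n, weights = w, sigma = sigma, seed = seed)
}

test_that("composite loss is linear in alpha with the documented endpoints", {
  expect_equal(composite_loss(1, 0, 0.3), 0)
  expect_equal(composite_loss(0.5, 10, 1), 0.5)     # alpha = 1 ignores RMSE
  expect_equal(composite_loss(0.9, 1.2, 0), 1.2)    # alpha = 0 is plain RMSE
  expect_equal(composite_loss(0.8, 1.5, 0.7), 0.59)
  # linearity: the midpoint alpha gives the midpoint loss
  l_lo <- composite_loss(0.6, 2, 0.2)
  l_hi <- composite_loss(0.6, 2, 0.8)
  expect_equal(composite_loss(0.6, 2, 0.5), (l_lo + l_hi) / 2)
  expect_error(composite_loss(0.5, 1, 1.5), "alpha")
})

test_that("the parameter count reproduces the four printed audit values", {
  expect_identical(count_dnn_parameters(140), 159601L)
  expect_identical(count_dnn_parameters(280), 215601L)
  expect_identical(count_dnn_parameters(2422), 1072401L)
  expect_identical(count_dnn_parameters(2562), 1128401L)
})

test_that("the built network's parameter arrays match the closed-form count", {
  set.seed(1)
  for (d in sample(2:3000, 20)) {
    par <- plifr:::init_dnn(d, dnn_config())
    expect_equal(plifr:::dnn_parameter_audit(par), count_dnn_parameters(d),
                 info = paste("input dim", d))
  }
})

test_that("evaluation metrics match their definitions on worked examples", {
  ds <- make_labeled_dataset(c("a", "b"), matrix(0, 2, 1), c(0, 0))
  r <- plifr:::regression_metrics(c(3, 4), c(0, 0))
  expect_equal(r$rmse, sqrt(25 / 2))
  expect_equal(r$mae, 3.5)
  # perfect and shifted predictions
  y <- c(1, 2, 3, 4)
  p0 <- plifr:::regression_metrics(y, y)
  expect_equal(p0$rmse, 0)
  expect_equal(p0$mae, 0)
  expect_equal(p0$pcc, 1)
  p1 <- plifr:::regression_metrics(y + 1, y)
  expect_equal(p1$rmse, 1)
  expect_equal(p1$mae, 1)
  expect_equal(p1$pcc, 1)
})

test_that("metrics agree with the independent library implementations", {
  set.seed(7)
  for (k in 1:5) {
    p <- rnorm(60)
    y <- 0.5 * p + rnorm(60)
    r <- plifr:::regression_metrics(p, y)
    expect_equal(r$rmse, sqrt(mean((p - y)^2)), tolerance = 1e-12)
    expect_equal(r$mae, mean(abs(p - y)), tolerance = 1e-12)
    expect_equal(r$pcc, cor(p, y), tolerance = 1e-10)
    expect_equal(r$spearman, cor(p, y, method = "spearman"), tolerance = 1e-10)
    ct <- cor.test(p, y)
    expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)
  }
})

test_that("random forest recovers a planted linear signal on held-out data", {
  sp <- split_dataset(linear_dataset(), 0.8, seed = 1)
  model <- train_rf(sp$train, rf_config(n_estimators = 100, seed = 1))
  rep_ <- evaluate(model, sp$valid)
  expect_gt(rep_$pcc, 0.9)
  expect_lt(rep_$rmse, 0.5)
})

test_that("forest training is deterministic and degenerates gracefully", {
  sp <- split_dataset(linear_dataset(n = 120), 0.8, seed = 2)
  m1 <- train_rf(sp$train, rf_config(n_estimators = 50, seed = 9))
  m2 <- train_rf(sp$train, rf_config(n_estimators = 50, seed = 9))
  expect_identical(predict(m1, sp$valid), predict(m2, sp$valid))
  # constant labels: warning and constant predictions
  const <- make_labeled_dataset(sp$train$ids, sp$train$features,
                                rep(5, nrow(sp$train$features)))
  expect_warning(mc <- train_rf(const, rf_config(seed = 1)), "constant")
  expect_true(all(abs(predict(mc, sp$valid) - 5) < 1e-9))
})

test_that("a one-tree ensemble equals its single tree's predictions", {
  sp <- split_dataset(linear_dataset(n = 150), 0.8, seed = 3)
  m <- train_rf(sp$train, rf_config(n_estimators = 1, seed = 4))
  agg <- predict(m, sp$valid)
  per_tree <- predict(m$fit, data = as.data.frame(sp$valid$features),
                      predict.all = TRUE, num.threads = 1)$predictions
  expect_equal(agg, drop(per_tree), tolerance = 1e-12)
})

test_that("sqrt feature sampling restricts mtry", {
  sp <- split_dataset(linear_dataset(n = 120), 0.8, seed = 5)
  m <- train_rf(sp$train, rf_config(n_estimators = 20, max_features = "sqrt",
                                    seed = 1))
  expect_equal(m$fit$mtry, floor(sqrt(140)))
  m2 <- train_rf(sp$train, rf_config(n_estimators = 20, seed = 1))
  expect_equal(m2$fit$mtry, 140)
})

test_that("the deep network selects the epoch with minimal validation loss", {
  sp <- split_dataset(linear_dataset(n = 300), 0.8, seed = 6)
  cfg <- dnn_config(max_epochs = 12, patience = 12, seed = 1)
  model <- train_dnn(sp$train, sp$valid, cfg)
  h <- model$history
  expect_equal(h$valid_loss[model$best_epoch], min(h$valid_loss))
  expect_equal(model$n_parameters, count_dnn_parameters(140))
  # reproducibility under the same seed
  model2 <- train_dnn(sp$train, sp$valid, cfg)
  expect_equal(predict(model, sp$valid), predict(model2, sp$valid),
               tolerance = 1e-12)
  # alpha = 0 reduces selection to the min-validation-RMSE epoch
  m0 <- train_dnn(sp$train, sp$valid,
                  dnn_config(max_epochs = 10, patience = 10, alpha = 0,
                             seed = 2))
  expect_equal(m0$best_epoch, which.min(m0$history$valid_rmse))
})

test_that("the null baseline predicts the training mean", {
  tr <- make_labeled_dataset(c("a", "b"), matrix(rnorm(4), 2, 2), c(0, 2))
  te <- make_labeled_dataset(c("c", "d"), matrix(rnorm(4), 2, 2), c(1, 1))
  rep_ <- baseline_null(tr, te)
  expect_equal(rep_$rmse, 0)           # mean 1 equals both test labels
  expect_true(is.na(rep_$pcc))         # constant predictions: PCC absent
  te2 <- make_labeled_dataset(c("c", "d"), matrix(rnorm(4), 2, 2), c(0, 2))
  expect_equal(baseline_null(tr, te2)$rmse, 1)
  # constant labels give a zero-error null model
  trc <- make_labeled_dataset(c("a", "b"), matrix(rnorm(4), 2, 2), c(3, 3))
  tec <- make_labeled_dataset(c("c", "d"), matrix(rnorm(4), 2, 2), c(3, 3))
  expect_equal(baseline_null(trc, tec)$rmse, 0)
})

test_that("prediction guards reject mismatched feature sets and dictionaries", {
  dir <- toy_index_dir(n = 10, seed = 31)
  idx <- read_complex_index(file.path(dir, "index.csv"))
  mols <- lapply(idx$ligand_path, read_ligand)
  dict <- build_fragment_dictionary(mols)
  ds <- featurize_index(idx, "ifp+frag", dictionary = dict)
  set.seed(1)
  ds$labels <- ds$labels + rnorm(10, 0, 0.01)  # break label ties
  model <- train_rf(ds, rf_config(n_estimators = 10, seed = 1))
  other_dict <- build_fragment_dictionary(list(ethanol_mol()))
  ds_other <- featurize_index(idx, "ifp+frag", dictionary = other_dict)
  expect_error(predict(model, ds_other), "dictionary mismatch")
  ds_ifp <- featurize_index(idx, "ifp")
  expect_error(predict(model, ds_ifp), "feature-set mismatch")
})
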