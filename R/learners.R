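# Regressors and evaluation: bagged random forest, composite
# correlation/error loss, parameter audit, mean-predictor baseline.

#' Random-forest configuration
#'
#' @param n_estimators Number of bagged trees (the study grid is 100-500 in
#'   steps of 100; any B >= 1 is accepted).
#' @param max_features `"auto"` (all features, the historic meaning of the
#'   scikit-learn 0.22 vintage) or `"sqrt"`.
#' @param seed Integer seed fixing the bootstrap and split randomness.
#' @return An `rf_config` list.
#' @export
rf_config <- function(n_estimators = 100,
                      max_features = c("auto", "sqrt"), seed = 1) {
  max_features <- match.arg(max_features)
  stopifnot(n_estimators >= 1)
  structure(list(n_estimators = as.integer(n_estimators),
                 max_features = max_features, seed = as.integer(seed)),
            class = "rf_config")
}

#' Train a random-forest affinity model
#'
#' Bagged ensemble of regression trees (via [ranger::ranger()]); the
#' prediction is the mean of the individual tree predictions. Reproducible
#' for a given configuration seed.
#'
#' @param train A `labeled_dataset` with at least 10 rows.
#' @param cfg An [rf_config()].
#' @return An `affinity_model` (kind `"rf"`) carrying the configuration,
#'   feature-set signature and fragment-dictionary hash.
#' @export
train_rf <- function(train, cfg = rf_config()) {
  stopifnot(inherits(train, "labeled_dataset"), inherits(cfg, "rf_config"))
  if (nrow(train$features) < 10) stop("need at least 10 training rows")
  if (sd(train$labels) == 0) warning("training labels are constant")
  p <- ncol(train$features)
  mtry <- if (cfg$max_features == "auto") p else max(1L, floor(sqrt(p)))
  fit <- ranger::ranger(
    x = train$features, y = train$labels,
    num.trees = cfg$n_estimators, mtry = mtry,
    seed = cfg$seed, num.threads = 1
  )
  new_affinity_model(kind = "rf", fit = fit, config = cfg, train = train)
}

new_affinity_model <- function(kind, fit, config, train, extra = list()) {
  structure(c(list(
    kind = kind, fit = fit, config = config,
    feature_set = train$feature_set,
    feature_names = colnames(train$features),
    dictionary_hash = dictionary_hash(train$dictionary),
    n_train = nrow(train$features)
  ), extra), class = "affinity_model")
}

#' Predict binding affinity
#'
#' @param object An `affinity_model`.
#' @param newdata A `labeled_dataset` or a numeric feature matrix with the
#'   model's columns. Feature-set signature and fragment-dictionary hash are
#'   checked and a mismatch is an error.
#' @param ... Unused.
#' @return Numeric vector of predicted pKd/pKi.
#' @export
predict.affinity_model <- function(object, newdata, ...) {
  if (inherits(newdata, "labeled_dataset")) {
    if (newdata$feature_set != object$feature_set) {
      stop("feature-set mismatch: model was trained on '", object$feature_set,
           "', data holds '", newdata$feature_set, "'")
    }
    h <- dictionary_hash(newdata$dictionary)
    if (!identical(h, object$dictionary_hash)) {
      stop("fragment-dictionary mismatch: model hash ", object$dictionary_hash,
           " vs data hash ", h)
    }
    newdata <- newdata$features
  }
  newdata <- as.matrix(newdata)
  if (!is.null(object$feature_names) &&
      !identical(colnames(newdata), object$feature_names)) {
    if (is.null(colnames(newdata)) && ncol(newdata) == length(object$feature_names)) {
      colnames(newdata) <- object$feature_names
    } else {
      stop("feature columns do not match the model's feature names")
    }
  }
  switch(object$kind,
    rf = predict(object$fit, data = as.data.frame(newdata),
                 num.threads = 1)$predictions,
    dnn = dnn_forward_predict(object, newdata),
    null = rep(object$fit$mean, nrow(newdata)),
    stop("unknown model kind: ", object$kind)
  )
}

#' Composite model-selection loss
#'
#' `alpha * (1 - PCC) + (1 - alpha) * RMSE`. Linear in `alpha`: the
#' endpoints reduce to `1 - PCC` (`alpha = 1`) and plain RMSE (`alpha = 0`).
#'
#' @param pcc Pearson correlation of predictions vs labels.
#' @param rmse Root-mean-square error.
#' @param alpha Weight in `[0, 1]`.
#' @return The loss value (vectorized over its arguments).
#' @export
composite_loss <- function(pcc, rmse, alpha) {
  if (any(alpha < 0 | alpha > 1)) stop("alpha must lie in [0, 1]")
  alpha * (1 - pcc) + (1 - alpha) * rmse
}

#' Count the learnable parameters of the dense network
#'
#' Dense weights and biases of the 400/200/100/1 stack plus four parameters
#' per hidden unit for batch normalization (scale, shift and the two running
#' statistics): for input dimension `d` this is
#' `(d*400+400) + (400*200+200) + (200*100+100) + (100+1) + 4*(400+200+100)`.
#'
#' @param input_dim Feature dimension (>= 1).
#' @param hidden_units Hidden layer widths (fixed stack, default
#'   `c(400, 200, 100)`).
#' @return Integer parameter count (e.g. 159601 for `input_dim = 140`).
#' @export
count_dnn_parameters <- function(input_dim, hidden_units = c(400, 200, 100)) {
  stopifnot(input_dim >= 1)
  dims <- c(input_dim, hidden_units, 1)
  dense <- sum(dims[-length(dims)] * dims[-1] + dims[-1])
  as.integer(dense + 4 * sum(hidden_units))
}

# Metrics implemented from their definitions (RMSE, MAE, Pearson with a
# two-sided t-transform p-value, Spearman as Pearson on ranks).
regression_metrics <- function(pred, obs) {
  stopifnot(length(pred) == length(obs))
  n <- length(obs)
  rmse <- sqrt(mean((pred - obs)^2))
  mae <- mean(abs(pred - obs))
  pcc <- p_value <- sp <- NA_real_
  if (n >= 2 && sd(pred) > 0 && sd(obs) > 0) {
    pcc <- sum((pred - mean(pred)) * (obs - mean(obs))) /
      ((n - 1) * sd(pred) * sd(obs))
    if (n > 2 && abs(pcc) < 1) {
      tstat <- pcc * sqrt((n - 2) / (1 - pcc^2))
      p_value <- 2 * pt(-abs(tstat), df = n - 2)
    } else if (n > 2) {
      p_value <- 0
    }
    rp <- rank(pred); ro <- rank(obs)
    if (sd(rp) > 0 && sd(ro) > 0) {
      sp <- sum((rp - mean(rp)) * (ro - mean(ro))) /
        ((n - 1) * sd(rp) * sd(ro))
    }
  }
  structure(list(rmse = rmse, mae = mae, pcc = pcc, p_value = p_value,
                 spearman = sp, n = n),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("n = %d  RMSE = %.4f  MAE = %.4f  PCC = %s (p = %s)  Sp = %s\n",
              x$n, x$rmse, x$mae,
              ifelse(is.na(x$pcc), "NA", sprintf("%.4f", x$pcc)),
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 3)),
              ifelse(is.na(x$spearman), "NA", sprintf("%.4f", x$spearman))))
  invisible(x)
}

#' Evaluate a model on a labeled dataset
#'
#' Reports RMSE, MAE, Pearson correlation with its two-sided p-value, and
#' the Spearman rank correlation. Correlations are reported as `NA` when
#' undefined (fewer than two rows, or constant predictions/labels).
#'
#' @param model An `affinity_model`.
#' @param test A `labeled_dataset` matching the model's feature-set
#'   signature and dictionary.
#' @return An `evaluation_report`.
#' @export
evaluate <- function(model, test) {
  regression_metrics(predict(model, test), test$labels)
}

#' Mean-predictor null baseline
#'
#' Predicts the training-label mean for every test row -- a documented
#' stand-in null model against which feature-driven models are compared.
#' Its Pearson correlation is undefined (constant predictions) and reported
#' as `NA`.
#'
#' @param train,test `labeled_dataset` objects.
#' @return An `evaluation_report` with the null model attached as the
#'   `"model"` attribute.
#' @export
baseline_null <- function(train, test) {
  model <- new_affinity_model(kind = "null",
                              fit = list(mean = mean(train$labels)),
                              config = NULL, train = train)
  rep_ <- regression_metrics(predict(model, test), test$labels)
  attr(rep_, "model") <- model
  rep_
}

#' Write an evaluation report to JSON
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_evaluation_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}
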