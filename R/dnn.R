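# Dense feed-forward regressor: input -> 400 -> 200 -> 100 -> 1 with batch
# normalization, ReLU and dropout after every hidden layer, trained by
# SGD with momentum and inverse-time learning-rate decay, L2 weight penalty,
# and per-epoch model selection by the composite loss on the validation set.
# Implemented in plain matrix arithmetic; the network is small enough that
# this trains in seconds on the problem sizes used here.

#' Deep-network configuration
#'
#' The hidden stack is fixed at 400/200/100 units. The optimizer is SGD with
#' learning rate 0.001, inverse-time decay 1e-6 per update and momentum 0.9;
#' tunable regularizers are the dropout rate (0.1-0.6), the composite-loss
#' weight `alpha` (0.1-1.0) and the batch size (64/128/256).
#'
#' @param dropout Dropout rate after each hidden layer.
#' @param alpha Composite-loss weight, see [composite_loss()].
#' @param batch_size Minibatch size.
#' @param learning_rate,decay,momentum SGD hyperparameters.
#' @param l2 L2 penalty on dense weights (not biases or batch-norm terms).
#' @param max_epochs Training epochs (upper bound).
#' @param patience Early-stopping patience: stop when the best validation
#'   composite loss has not improved for this many epochs.
#' @param standardize Standardize features to train-set mean/variance; the
#'   constants are stored with the model.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return A `dnn_config` list with `hidden_units = c(400, 200, 100)`.
#' @export
dnn_config <- function(dropout = 0.1, alpha = 0.7, batch_size = 64,
                       learning_rate = 0.001, decay = 1e-6, momentum = 0.9,
                       l2 = 1e-6, max_epochs = 50, patience = 10,
                       standardize = TRUE, seed = 1) {
  stopifnot(dropout >= 0, dropout < 1, alpha >= 0, alpha <= 1,
            batch_size >= 1, max_epochs >= 1)
  structure(list(
    hidden_units = c(400L, 200L, 100L), dropout = dropout, alpha = alpha,
    batch_size = as.integer(batch_size), learning_rate = learning_rate,
    decay = decay, momentum = momentum, l2 = l2,
    max_epochs = as.integer(max_epochs), patience = as.integer(patience),
    standardize = standardize, seed = as.integer(seed)
  ), class = "dnn_config")
}

# He-initialized parameter set; BN scale/shift plus running statistics.
init_dnn <- function(input_dim, cfg) {
  dims <- c(input_dim, cfg$hidden_units, 1L)
  L <- length(dims) - 1
  par <- list(W = vector("list", L), b = vector("list", L),
              gamma = vector("list", L - 1), beta = vector("list", L - 1),
              run_mean = vector("list", L - 1), run_var = vector("list", L - 1))
  for (l in seq_len(L)) {
    par$W[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], sd = sqrt(2 / dims[l])),
                         dims[l], dims[l + 1])
    par$b[[l]] <- numeric(dims[l + 1])
    if (l < L) {
      par$gamma[[l]] <- rep(1, dims[l + 1])
      par$beta[[l]] <- numeric(dims[l + 1])
      par$run_mean[[l]] <- numeric(dims[l + 1])
      par$run_var[[l]] <- rep(1, dims[l + 1])
    }
  }
  par
}

dnn_parameter_audit <- function(par) {
  sum(vapply(par$W, length, numeric(1))) +
    sum(vapply(par$b, length, numeric(1))) +
    sum(vapply(par$gamma, length, numeric(1))) +
    sum(vapply(par$beta, length, numeric(1))) +
    sum(vapply(par$run_mean, length, numeric(1))) +
    sum(vapply(par$run_var, length, numeric(1)))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.9

dnn_forward_train <- function(par, X, cfg) {
  L <- length(par$W)
  cache <- list(inputs = vector("list", L))
  a <- X
  for (l in seq_len(L - 1)) {
    cache$inputs[[l]] <- a
    z <- sweep(a %*% par$W[[l]], 2, par$b[[l]], "+")
    mu <- colMeans(z)
    v <- colMeans(sweep(z, 2, mu)^2)
    xhat <- sweep(sweep(z, 2, mu), 2, sqrt(v + BN_EPS), "/")
    bn <- sweep(sweep(xhat, 2, par$gamma[[l]], "*"), 2, par$beta[[l]], "+")
    relu <- pmax(bn, 0)
    mask <- if (cfg$dropout > 0) {
      matrix(rbinom(length(relu), 1, 1 - cfg$dropout), nrow(relu)) /
        (1 - cfg$dropout)
    } else 1
    a <- relu * mask
    cache[[paste0("bn", l)]] <- list(mu = mu, v = v, xhat = xhat, bn = bn,
                                     mask = mask)
    par$run_mean[[l]] <- BN_MOMENTUM * par$run_mean[[l]] + (1 - BN_MOMENTUM) * mu
    par$run_var[[l]] <- BN_MOMENTUM * par$run_var[[l]] + (1 - BN_MOMENTUM) * v
  }
  cache$inputs[[L]] <- a
  cache$yhat <- drop(sweep(a %*% par$W[[L]], 2, par$b[[L]], "+"))
  cache$par <- par  # carries updated running stats
  cache
}

dnn_backward <- function(par, cache, y, cfg) {
  L <- length(par$W)
  m <- length(y)
  g <- list(W = vector("list", L), b = vector("list", L),
            gamma = vector("list", L - 1), beta = vector("list", L - 1))
  delta <- matrix(2 * (cache$yhat - y) / m, ncol = 1)
  g$W[[L]] <- t(cache$inputs[[L]]) %*% delta + cfg$l2 * par$W[[L]]
  g$b[[L]] <- colSums(delta)
  da <- delta %*% t(par$W[[L]])
  for (l in rev(seq_len(L - 1))) {
    bn <- cache[[paste0("bn", l)]]
    drelu <- (da * bn$mask) * (bn$bn > 0)
    g$gamma[[l]] <- colSums(drelu * bn$xhat)
    g$beta[[l]] <- colSums(drelu)
    dxhat <- sweep(drelu, 2, par$gamma[[l]], "*")
    t1 <- sweep(dxhat, 2, colMeans(dxhat))
    t2 <- sweep(bn$xhat, 2, colMeans(dxhat * bn$xhat), "*")
    dz <- sweep(t1 - t2, 2, sqrt(bn$v + BN_EPS), "/")
    g$W[[l]] <- t(cache$inputs[[l]]) %*% dz + cfg$l2 * par$W[[l]]
    g$b[[l]] <- colSums(dz)
    if (l > 1) da <- dz %*% t(par$W[[l]])
  }
  g
}

dnn_forward_eval <- function(par, X) {
  L <- length(par$W)
  a <- X
  for (l in seq_len(L - 1)) {
    z <- sweep(a %*% par$W[[l]], 2, par$b[[l]], "+")
    xhat <- sweep(sweep(z, 2, par$run_mean[[l]]), 2,
                  sqrt(par$run_var[[l]] + BN_EPS), "/")
    a <- pmax(sweep(sweep(xhat, 2, par$gamma[[l]], "*"), 2,
                    par$beta[[l]], "+"), 0)
  }
  drop(sweep(a %*% par$W[[L]], 2, par$b[[L]], "+"))
}

dnn_forward_predict <- function(model, X) {
  if (!is.null(model$standardization)) {
    X <- sweep(sweep(X, 2, model$standardization$mean), 2,
               model$standardization$sd, "/")
  }
  dnn_forward_eval(model$fit, X)
}

#' Train the deep-network affinity model
#'
#' Architecture: input, then three dense blocks
#' (Dense 400/200/100 -> batch norm -> ReLU -> dropout), then a linear
#' output unit. Optimized by minibatch SGD on the mean squared error with
#' momentum 0.9 and inverse-time learning-rate decay. After every epoch the
#' composite loss `alpha*(1-PCC) + (1-alpha)*RMSE` is computed on the
#' validation set, and the returned model is the epoch with the minimal
#' validation loss (this is the model-selection criterion, not the gradient
#' objective). Features are standardized with train-set constants stored in
#' the model. Training aborts with diagnostics if the loss becomes
#' non-finite.
#'
#' @param train,valid `labeled_dataset` objects; `valid` must be non-empty.
#' @param cfg A [dnn_config()].
#' @return An `affinity_model` (kind `"dnn"`) with the selected epoch's
#'   parameters, the per-epoch `history` data frame, `best_epoch`, and the
#'   parameter-count audit `n_parameters`.
#' @export
train_dnn <- function(train, valid, cfg = dnn_config()) {
  stopifnot(inherits(train, "labeled_dataset"),
            inherits(valid, "labeled_dataset"))
  if (!nrow(valid$features)) stop("validation set must be non-empty")
  X <- train$features
  y <- train$labels
  ctr <- if (cfg$standardize) colMeans(X) else numeric(ncol(X))
  scl <- if (cfg$standardize) {
    s <- apply(X, 2, sd); s[s == 0] <- 1; s
  } else rep(1, ncol(X))
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  Vs <- sweep(sweep(valid$features, 2, ctr), 2, scl, "/")

  with_seed(cfg$seed, {
    par <- init_dnn(ncol(X), cfg)
    vel <- rapply(par[c("W", "b", "gamma", "beta")],
                  function(x) x * 0, how = "replace")
    step <- 0
    best <- list(loss = Inf, epoch = NA_integer_, par = NULL)
    hist <- data.frame()
    n <- nrow(Xs)
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = cfg$batch_size)
      for (s in starts) {
        rows <- ord[s:min(s + cfg$batch_size - 1, n)]
        if (length(rows) < 2) next  # batch norm needs a batch
        cache <- dnn_forward_train(par, Xs[rows, , drop = FALSE], cfg)
        par <- cache$par
        g <- dnn_backward(par, cache, y[rows], cfg)
        step <- step + 1
        lr <- cfg$learning_rate / (1 + cfg$decay * step)
        for (fld in c("W", "b", "gamma", "beta")) {
          for (l in seq_along(g[[fld]])) {
            if (is.null(g[[fld]][[l]])) next
            vel[[fld]][[l]] <- cfg$momentum * vel[[fld]][[l]] - lr * g[[fld]][[l]]
            par[[fld]][[l]] <- par[[fld]][[l]] + vel[[fld]][[l]]
          }
        }
      }
      vp <- dnn_forward_eval(par, Vs)
      vrmse <- sqrt(mean((vp - valid$labels)^2))
      vpcc <- if (sd(vp) > 0 && sd(valid$labels) > 0)
        regression_metrics(vp, valid$labels)$pcc else 0
      vloss <- composite_loss(vpcc, vrmse, cfg$alpha)
      if (!is.finite(vloss)) {
        stop("training diverged at epoch ", epoch,
             " (validation RMSE = ", format(vrmse), ")")
      }
      hist <- rbind(hist, data.frame(epoch = epoch, valid_rmse = vrmse,
                                     valid_pcc = vpcc, valid_loss = vloss))
      if (vloss < best$loss) best <- list(loss = vloss, epoch = epoch, par = par)
      if (epoch - best$epoch >= cfg$patience) break
    }
    model <- new_affinity_model(
      kind = "dnn", fit = best$par, config = cfg, train = train,
      extra = list(
        standardization = if (cfg$standardize) list(mean = ctr, sd = scl),
        history = hist, best_epoch = best$epoch,
        n_parameters = dnn_parameter_audit(best$par)
      )
    )
    model
  })
}
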