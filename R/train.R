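#' Backpropagation training configuration
#'
#' Defaults chosen for small designed-experiment data: full-batch gradient
#' descent with momentum 0.9 and a MATLAB-style adaptive learning rate
#' (multiplied by `lr_inc` after an improving epoch; a step that raises the
#' batch loss by more than `max_perf_inc` is rejected and the rate is
#' multiplied by `lr_dec`), at most `max_epochs` epochs, early stopping
#' with `patience` epochs on an internal validation split of
#' `val_fraction`, and `n_restarts` random restarts keeping the best model
#' by validation RMSE.
#'
#' @param max_epochs Maximum training epochs per restart.
#' @param learning_rate Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param val_fraction Fraction of training records held out internally
#'   for early stopping; splits smaller than 10 records train against
#'   their own loss instead.
#' @param n_restarts Random restarts.
#' @param init_scale Half-width of the uniform weight initialization,
#'   scaled by `1/sqrt(fan-in)`.
#' @param lr_inc,lr_dec,max_perf_inc Adaptive learning-rate parameters.
#' @param seed Seed controlling initialization and the validation split.
#' @return A `train_config` list.
#' @export
train_config <- function(max_epochs = 2000, learning_rate = 0.01,
                         momentum = 0.9, patience = 100,
                         val_fraction = 0.15, n_restarts = 3,
                         init_scale = 0.5, lr_inc = 1.05, lr_dec = 0.7,
                         max_perf_inc = 1.04, seed = 1) {
  cfg <- list(max_epochs = as.integer(max_epochs),
              learning_rate = learning_rate, momentum = momentum,
              patience = as.integer(patience),
              val_fraction = val_fraction,
              n_restarts = as.integer(n_restarts),
              init_scale = init_scale, lr_inc = lr_inc, lr_dec = lr_dec,
              max_perf_inc = max_perf_inc, seed = as.integer(seed))
  stopifnot(all(vapply(cfg, function(v) is.numeric(v) && v > 0,
                       logical(1))))
  structure(cfg, class = "train_config")
}

#' Train the network on a training partition
#'
#' Optionally Box-Cox transforms the target, fits min-max input scalers
#' and a mean/half-range target scaler on the training records only, then
#' runs backpropagation (see [train_config()]) from `n_restarts` seeded
#' random initializations, returning the restart/epoch combination with the
#' best internal-validation RMSE. The returned model never fits worse on
#' its training data than the initial random network.
#'
#' @param X Training inputs (matrix or data frame; any number of columns).
#' @param y Training target in original units.
#' @param hidden_n Hidden-layer size (positive integer). Fewer than
#'   `6 * hidden_n` training records trigger an overparameterization
#'   warning.
#' @param cfg A [train_config()].
#' @param lambda Optional Box-Cox exponent for the target (`NULL` = none).
#' @return A fitted `mlp_model` with attached scalers and `lambda`; its
#'   `fit` element records epochs, validation RMSE and the restart used.
#' @export
train_mlp <- function(X, y, hidden_n, cfg = train_config(), lambda = NULL) {
  stopifnot(hidden_n >= 1)
  hidden_n <- as.integer(hidden_n)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X)
  if (n < 2) stop("need at least 2 training records", call. = FALSE)
  if (n < 6 * hidden_n) {
    warning("fewer than 6 records per hidden neuron (", n, " for ",
            hidden_n, "): network is heavily overparameterized",
            call. = FALSE)
  }
  z <- if (is.null(lambda)) y else boxcox_transform(y, lambda)
  scalers <- fit_scalers(X, z)
  # A constant target has the exact bias-only solution: all-zero weights
  # predict the target mean. Skip training.
  if (var(z) == 0) {
    model <- new_mlp_model(matrix(0, hidden_n, ncol(X)),
                           rep(0, hidden_n), rep(0, hidden_n), 0,
                           scalers = scalers, lambda = lambda,
                           inputs = colnames(X), seed = cfg$seed)
    model$fit <- list(epochs = 0L, val_rmse_scaled = 0,
                      train_rmse_scaled = 0, init_rmse_scaled = 0,
                      restart = NA, final_lr = cfg$learning_rate,
                      degenerate = "constant-target")
    return(model)
  }
  Xs <- scale_inputs(scalers, X)
  zs <- scale_target(scalers, z)

  n_val <- floor(cfg$val_fraction * n)
  if (n >= 10 && n_val >= 1) {
    val_idx <- with_seed(cfg$seed, sample.int(n, n_val))
    tr_idx <- setdiff(seq_len(n), val_idx)
  } else {
    val_idx <- integer(0)
    tr_idx <- seq_len(n)
  }
  Xtr <- Xs[tr_idx, , drop = FALSE]; ztr <- zs[tr_idx]
  Xval <- Xs[val_idx, , drop = FALSE]; zval <- zs[val_idx]

  p <- ncol(X)
  best <- NULL
  for (r in seq_len(cfg$n_restarts)) {
    init <- with_seed(cfg$seed + r, list(
      W1 = matrix(runif(hidden_n * p, -cfg$init_scale, cfg$init_scale) /
                    sqrt(p), hidden_n, p),
      b1 = runif(hidden_n, -cfg$init_scale, cfg$init_scale) / sqrt(p),
      w2 = runif(hidden_n, -cfg$init_scale, cfg$init_scale) /
        sqrt(hidden_n),
      b2 = runif(1, -cfg$init_scale, cfg$init_scale)
    ))
    fit <- mlp_train_cpp(Xtr, ztr, Xval, zval,
                         init$W1, init$b1, init$w2, init$b2,
                         cfg$learning_rate, cfg$momentum,
                         cfg$max_epochs, cfg$patience,
                         cfg$lr_inc, cfg$lr_dec, cfg$max_perf_inc)
    if (!is.null(fit$error)) {
      stop("training diverged at epoch ", fit$epoch, ": ", fit$error,
           call. = FALSE)
    }
    if (is.null(best) || fit$best_val_rmse < best$best_val_rmse) {
      best <- fit
      best$restart <- r
    }
  }
  # Guarantee the returned network beats its random initialization on the
  # training loss; fall back to the train-best epoch if validation-best
  # does not (can happen on degenerate targets).
  train_rmse_val_best <- rmse(ztr, mlp_forward_scaled(
    new_mlp_model(best$W1, best$b1, best$w2, best$b2, inputs = colnames(X)),
    Xtr))
  use_train_best <- train_rmse_val_best > best$init_train_rmse
  W1 <- if (use_train_best) best$W1_train else best$W1
  b1 <- if (use_train_best) best$b1_train else best$b1
  w2 <- if (use_train_best) best$w2_train else best$w2
  b2 <- if (use_train_best) best$b2_train else best$b2
  model <- new_mlp_model(W1, b1, w2, b2, scalers = scalers,
                         lambda = lambda, inputs = colnames(X),
                         seed = cfg$seed)
  model$fit <- list(epochs = best$epochs,
                    val_rmse_scaled = best$best_val_rmse,
                    train_rmse_scaled = best$best_train_rmse,
                    init_rmse_scaled = best$init_train_rmse,
                    restart = best$restart, final_lr = best$final_lr)
  model
}
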