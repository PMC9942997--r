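new_fit_report <- function(response, family, pooled, per_fold, predictions,
                           plan, extra = list()) {
  structure(c(list(response = response, family = family, pooled = pooled,
                   per_fold = per_fold, predictions = predictions,
                   plan_hash = cv_plan_hash(plan)),
              extra),
            class = "fit_report")
}

#' @export
print.fit_report <- function(x, ...) {
  cat(sprintf("%s fit report for %s\n", x$family, x$response))
  print(x$pooled, row.names = FALSE)
  invisible(x)
}

pooled_metrics <- function(pred_df) {
  do.call(rbind, lapply(split(pred_df, pred_df$subset), function(d) {
    data.frame(subset = d$subset[1],
               r2 = r_squared(d$observed, d$predicted),
               rmse = rmse(d$observed, d$predicted),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
}

per_fold_metrics <- function(pred_df) {
  test <- pred_df[pred_df$subset == "test", ]
  keys <- unique(test[, c("replicate", "fold")])
  do.call(rbind, lapply(seq_len(nrow(keys)), function(i) {
    d <- test[test$replicate == keys$replicate[i] &
                test$fold == keys$fold[i], ]
    data.frame(replicate = keys$replicate[i], fold = keys$fold[i],
               test_r2 = r_squared(d$observed, d$predicted),
               test_rmse = rmse(d$observed, d$predicted),
               n_test = nrow(d))
  }))
}

#' Cross-validated evaluation of the network
#'
#' For every replicate and fold of the plan, fits scalers and trains the
#' network on the training folds only, then predicts the held-out fold.
#' Headline metrics pool the predictions across all folds and replicates
#' (per-fold test metrics are also returned); by default they are computed
#' in original response units, after inverting the target scaling and the
#' Box-Cox transform.
#'
#' The Box-Cox exponent is, by default, fitted once on the full response
#' vector (`boxcox = "pooled"`) — the procedure the study followed, at the
#' cost of a mild information leak into the folds. `boxcox = "per_fold"`
#' refits the exponent on each training partition; `"none"` disables the
#' transform.
#'
#' @param data Data frame holding the input columns and the response.
#' @param response Response column name (or canonical name, e.g. "YIELD").
#' @param hidden_n Hidden-layer size.
#' @param plan A cross-validation plan from `make_cv_plan()` matching
#'   `nrow(data)`.
#' @param cfg A training configuration from `train_config()`; fold-level
#'   training seeds are derived from `cfg$seed` deterministically.
#' @param boxcox One of "pooled", "per_fold", "none".
#' @param metrics_scale Compute metrics on the "original" response scale
#'   (default) or on the Box-Cox-"transformed" scale.
#' @param inputs Input column names.
#' @param keep_models Keep the per-fold fitted models (for audits).
#' @return A `fit_report`: `pooled` (train/test R2 and RMSE), `per_fold`,
#'   `predictions` (one row per record per replicate per subset), the
#'   plan hash, `hidden_n` and `lambda`.
#' @export
crossval_evaluate <- function(data, response, hidden_n, plan,
                              cfg = train_config(),
                              boxcox = c("pooled", "per_fold", "none"),
                              metrics_scale = c("original", "transformed"),
                              inputs = substrate_components(),
                              keep_models = FALSE) {
  boxcox <- match.arg(boxcox)
  metrics_scale <- match.arg(metrics_scale)
  response <- response_column(response)
  stopifnot(inherits(plan, "cv_plan"), nrow(data) == plan$n_records,
            response %in% names(data), all(inputs %in% names(data)))
  X <- as.matrix(as.data.frame(data)[, inputs, drop = FALSE])
  y <- data[[response]]
  lambda_pooled <- if (boxcox == "pooled") boxcox_mle(y)$lambda else NULL

  preds <- list()
  models <- list()
  for (r in seq_len(plan$n_replicates)) {
    for (f in seq_len(plan$k)) {
      test_idx <- plan$folds[[r]][[f]]
      train_idx <- setdiff(seq_len(plan$n_records), test_idx)
      lambda <- switch(boxcox,
                       pooled = lambda_pooled,
                       per_fold = boxcox_mle(y[train_idx])$lambda,
                       none = NULL)
      fold_cfg <- cfg
      fold_cfg$seed <- cfg$seed + 100L * r + f
      model <- tryCatch(
        train_mlp(X[train_idx, , drop = FALSE], y[train_idx], hidden_n,
                  fold_cfg, lambda = lambda),
        error = function(e) {
          stop("replicate ", r, ", fold ", f, ": ", conditionMessage(e),
               call. = FALSE)
        })
      if (keep_models) models[[paste(r, f, sep = ".")]] <- model
      pr_tr <- mlp_forward(model, X[train_idx, , drop = FALSE])
      pr_te <- mlp_forward(model, X[test_idx, , drop = FALSE])
      obs_tr <- y[train_idx]; obs_te <- y[test_idx]
      if (metrics_scale == "transformed" && !is.null(lambda)) {
        pr_tr <- boxcox_transform(pmax(pr_tr, 1e-12), lambda)
        pr_te <- boxcox_transform(pmax(pr_te, 1e-12), lambda)
        obs_tr <- boxcox_transform(obs_tr, lambda)
        obs_te <- boxcox_transform(obs_te, lambda)
      }
      preds[[length(preds) + 1L]] <- data.frame(
        replicate = r, fold = f,
        index = c(train_idx, test_idx),
        subset = rep(c("train", "test"),
                     c(length(train_idx), length(test_idx))),
        observed = c(obs_tr, obs_te),
        predicted = c(pr_tr, pr_te))
    }
  }
  pred_df <- do.call(rbind, preds)
  out <- new_fit_report(response, "MLP-GA", pooled_metrics(pred_df),
                        per_fold_metrics(pred_df), pred_df, plan,
                        extra = list(hidden_n = hidden_n,
                                     lambda = lambda_pooled,
                                     boxcox = boxcox,
                                     metrics_scale = metrics_scale))
  if (keep_models) out$models <- models
  out
}
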