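#' Bidirectional stepwise linear regression
#'
#' The baseline model family: ordinary least squares on linear terms of
#' the four substrate components, with classical bidirectional selection.
#' Each step first adds the excluded variable with the smallest partial-F
#' p-value if it is at most `p_enter`, then drops the included variable
#' with the largest p-value above `p_remove` (never the variable just
#' added). Candidate additions that would make the design matrix singular
#' — inevitably the fourth compositional component alongside the intercept
#' — are skipped. Terminates when no addition or removal is possible, with
#' a hard cap of `max_steps` steps.
#'
#' @param data Data frame with the input columns and the response.
#' @param response Response column name (or canonical name).
#' @param p_enter Entry threshold on the partial-F p-value (default 0.05).
#' @param p_remove Removal threshold (default 0.10); must be at least
#'   `p_enter`.
#' @param max_steps Safety cap on selection steps.
#' @param inputs Candidate input columns.
#' @return A `stepwise_model`: the final `lm` fit, `selected` variables,
#'   coefficients and a per-step `trace` (step, action, variable, p-value).
#' @export
stepwise_fit <- function(data, response, p_enter = 0.05, p_remove = 0.10,
                         max_steps = 50,
                         inputs = substrate_components()) {
  stopifnot(p_enter <= p_remove)
  response <- response_column(response)
  data <- as.data.frame(data)
  stopifnot(response %in% names(data), all(inputs %in% names(data)))
  if (nrow(data) < 10) stop("need at least 10 records", call. = FALSE)
  y <- data[[response]]
  if (var(y) == 0) stop("constant response: nothing to fit", call. = FALSE)

  selected <- character(0)
  trace <- data.frame(step = integer(0), action = character(0),
                      variable = character(0), p_value = numeric(0),
                      stringsAsFactors = FALSE)
  fit_formula <- function(vars) {
    rhs <- if (length(vars)) paste(vars, collapse = " + ") else "1"
    lm(stats::as.formula(paste(response, "~", rhs)), data = data)
  }
  # partial-F p-value of each term of a fit (1-df terms: squared-t F test)
  term_p <- function(fit, vars) {
    s <- summary(fit)$coefficients
    vapply(vars, function(v) {
      if (!v %in% rownames(s)) return(NA_real_)
      tval <- s[v, "t value"]
      df <- fit$df.residual
      pf(tval^2, 1, df, lower.tail = FALSE)
    }, numeric(1))
  }

  for (step in seq_len(max_steps)) {
    changed <- FALSE
    added_this_step <- NA_character_
    # forward
    candidates <- setdiff(inputs, selected)
    if (length(candidates)) {
      pvals <- vapply(candidates, function(v) {
        fit <- fit_formula(c(selected, v))
        if (any(is.na(coef(fit)))) return(NA_real_) # singular: skip
        term_p(fit, v)
      }, numeric(1))
      ok <- which(!is.na(pvals) & pvals <= p_enter)
      if (length(ok)) {
        add <- candidates[ok[which.min(pvals[ok])]]
        selected <- c(selected, add)
        added_this_step <- add
        trace <- rbind(trace, data.frame(step = step, action = "add",
                                         variable = add,
                                         p_value = min(pvals[ok],
                                                       na.rm = TRUE)))
        changed <- TRUE
      }
    }
    # backward
    if (length(selected)) {
      fit <- fit_formula(selected)
      pvals <- term_p(fit, selected)
      droppable <- selected[!is.na(pvals) & pvals > p_remove]
      if (!is.na(added_this_step)) {
        droppable <- setdiff(droppable, added_this_step)
      }
      if (length(droppable)) {
        pv <- pvals[match(droppable, selected)]
        drop_v <- droppable[which.max(pv)]
        selected <- setdiff(selected, drop_v)
        trace <- rbind(trace, data.frame(step = step, action = "drop",
                                         variable = drop_v,
                                         p_value = max(pv)))
        changed <- TRUE
      }
    }
    if (!changed) break
    if (step == max_steps) {
      stop("stepwise selection did not terminate within ", max_steps,
           " steps; trace: ",
           paste(trace$action, trace$variable, collapse = ", "),
           call. = FALSE)
    }
  }
  fit <- fit_formula(selected)
  structure(list(fit = fit, selected = selected,
                 coefficients = coef(fit), response = response,
                 p_enter = p_enter, p_remove = p_remove, trace = trace),
            class = "stepwise_model")
}

#' @export
predict.stepwise_model <- function(object, newdata, ...) {
  unname(predict(object$fit, newdata = as.data.frame(newdata)))
}

#' @export
print.stepwise_model <- function(x, ...) {
  cat(sprintf("Stepwise linear model for %s: %s\n", x$response,
              if (length(x$selected)) paste(x$selected, collapse = " + ")
              else "(intercept only)"))
  print(x$coefficients)
  invisible(x)
}

#' Serialize a stepwise model
#'
#' JSON rendering of the selection outcome: retained variables,
#' coefficients, thresholds and the per-step trace.
#'
#' @param model A `stepwise_model` from [stepwise_fit()].
#' @return A JSON string.
#' @export
stepwise_json <- function(model) {
  jsonlite::toJSON(list(
    response = model$response,
    selected = model$selected,
    coefficients = as.list(model$coefficients),
    p_enter = model$p_enter, p_remove = model$p_remove,
    trace = model$trace
  ), auto_unbox = TRUE, digits = NA, dataframe = "columns")
}

#' Cross-validated evaluation of the stepwise baseline
#'
#' Re-runs the stepwise selection on each training partition of the plan
#' (so selection itself is cross-validated) and predicts the held-out
#' fold; metrics are pooled exactly as in [crossval_evaluate()], on
#' original response units. The report includes a selection-stability
#' table: the fraction of fold fits in which each variable was retained.
#'
#' @inheritParams crossval_evaluate
#' @param p_enter,p_remove Stepwise thresholds.
#' @return A `fit_report` with family `"SR"`, plus `selection_stability`.
#' @export
sr_crossval <- function(data, response, plan, p_enter = 0.05,
                        p_remove = 0.10,
                        inputs = substrate_components()) {
  response <- response_column(response)
  stopifnot(inherits(plan, "cv_plan"), nrow(data) == plan$n_records)
  data <- as.data.frame(data)
  preds <- list()
  sel_count <- stats::setNames(numeric(length(inputs)), inputs)
  n_fits <- 0L
  for (r in seq_len(plan$n_replicates)) {
    for (f in seq_len(plan$k)) {
      test_idx <- plan$folds[[r]][[f]]
      train_idx <- setdiff(seq_len(plan$n_records), test_idx)
      model <- tryCatch(
        stepwise_fit(data[train_idx, , drop = FALSE], response,
                     p_enter = p_enter, p_remove = p_remove,
                     inputs = inputs),
        error = function(e) {
          stop("replicate ", r, ", fold ", f, ": ", conditionMessage(e),
               call. = FALSE)
        })
      sel_count[model$selected] <- sel_count[model$selected] + 1
      n_fits <- n_fits + 1L
      preds[[length(preds) + 1L]] <- data.frame(
        replicate = r, fold = f,
        index = c(train_idx, test_idx),
        subset = rep(c("train", "test"),
                     c(length(train_idx), length(test_idx))),
        observed = data[[response]][c(train_idx, test_idx)],
        predicted = c(predict(model, data[train_idx, , drop = FALSE]),
                      predict(model, data[test_idx, , drop = FALSE])))
    }
  }
  pred_df <- do.call(rbind, preds)
  new_fit_report(response, "SR", pooled_metrics(pred_df),
                 per_fold_metrics(pred_df), pred_df, plan,
                 extra = list(selection_stability = sel_count / n_fits,
                              p_enter = p_enter, p_remove = p_remove))
}
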