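#' Min-max rescale to the unit interval
#'
#' `(v - min) / (max - min)`, the convention used to report variable
#' sensitivity ratios: the most important input maps to 1, the least to 0.
#' An all-equal input is degenerate; it returns all 0.5 with the
#' `unstable` attribute set.
#'
#' @param values Numeric vector of length at least 2.
#' @return Rescaled vector with a logical `unstable` attribute.
#' @export
rescale_unit_interval <- function(values) {
  if (length(values) < 2) stop("need at least 2 values", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values", call. = FALSE)
  rng <- range(values)
  if (rng[1] == rng[2]) {
    return(structure(rep(0.5, length(values)), unstable = TRUE))
  }
  structure((values - rng[1]) / (rng[2] - rng[1]), unstable = FALSE)
}

#' Leave-one-input-out variable sensitivity (VSE/VSR)
#'
#' Quantifies the importance of each substrate component for one response
#' of a fitted network. The baseline is the RMSE, over all records, of the
#' network trained with all inputs. The variable sensitivity error VSE of
#' an input is the all-records RMSE of the network with that input
#' "nonexistent": by default retrained from scratch on the remaining
#' inputs at the same hidden size (`mode = "retrain"`); alternatively the
#' baseline network with that input clamped to its training mean
#' (`mode = "ablate"`). VSR is VSE divided by the baseline RMSE — higher
#' means more important — and the VSRs are min-max rescaled to `[0, 1]`
#' for reporting.
#'
#' Because the four components sum to 100, any three of them encode the
#' fourth; on such data a truly informative input can still be compensated
#' for after removal, which caps how far VSRs can spread. The report
#' carries an `unstable` flag when the VSRs differ by less than 5%.
#'
#' @inheritParams crossval_evaluate
#' @param hidden_n Hidden-layer size (typically the architecture chosen by
#'   the GA for this response).
#' @param mode `"retrain"` (default) or `"ablate"`.
#' @param lambda Optional Box-Cox exponent for the response.
#' @return A `sensitivity_report`: data frame with one row per input
#'   (`input`, `vse`, `vsr`, `rescaled_vsr`), plus attributes
#'   `baseline_rmse`, `mode`, `hidden_n`, `response`, `unstable`.
#' @export
variable_sensitivity <- function(data, response, hidden_n,
                                 mode = c("retrain", "ablate"),
                                 cfg = train_config(), lambda = NULL,
                                 inputs = substrate_components()) {
  mode <- match.arg(mode)
  response <- response_column(response)
  stopifnot(response %in% names(data), all(inputs %in% names(data)))
  if (length(inputs) < 2) stop("need at least 2 inputs", call. = FALSE)
  if (nrow(data) < 20) {
    stop("need at least 20 records for a sensitivity analysis",
         call. = FALSE)
  }
  X <- as.matrix(as.data.frame(data)[, inputs, drop = FALSE])
  y <- data[[response]]
  baseline_model <- train_mlp(X, y, hidden_n, cfg, lambda = lambda)
  baseline_rmse <- rmse(y, mlp_forward(baseline_model, X))
  if (baseline_rmse == 0) {
    stop("baseline RMSE is zero: VSR undefined", call. = FALSE)
  }
  vse <- vapply(inputs, function(v) {
    if (mode == "retrain") {
      keep <- setdiff(inputs, v)
      m <- train_mlp(X[, keep, drop = FALSE], y, hidden_n, cfg,
                     lambda = lambda)
      rmse(y, mlp_forward(m, X[, keep, drop = FALSE]))
    } else {
      X2 <- X
      X2[, v] <- mean(X[, v])
      rmse(y, mlp_forward(baseline_model, X2))
    }
  }, numeric(1))
  vsr <- vse / baseline_rmse
  resc <- rescale_unit_interval(vsr)
  spread_unstable <- (max(vsr) - min(vsr)) < 0.05 * min(vsr) ||
    attr(resc, "unstable")
  out <- data.frame(input = inputs, vse = unname(vse), vsr = unname(vsr),
                    rescaled_vsr = unname(as.numeric(resc)),
                    stringsAsFactors = FALSE)
  structure(out, baseline_rmse = baseline_rmse, mode = mode,
            hidden_n = hidden_n, response = response,
            unstable = spread_unstable,
            class = c("sensitivity_report", "data.frame"))
}

#' @export
print.sensitivity_report <- function(x, ...) {
  cat(sprintf("Sensitivity of %s (mode %s, %d hidden neurons, baseline RMSE %.4g)%s\n",
              attr(x, "response"), attr(x, "mode"), attr(x, "hidden_n"),
              attr(x, "baseline_rmse"),
              if (isTRUE(attr(x, "unstable"))) " [unstable: VSRs within 5%]"
              else ""))
  NextMethod()
}
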