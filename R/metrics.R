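#' Coefficient of determination
#'
#' `R^2 = 1 - SS_res / SS_tot`, with the total sum of squares taken about
#' the observed mean. Unbounded below; 1 for a perfect fit; 0 for a model
#' no better than the mean.
#'
#' @param observed,predicted Numeric vectors of equal length (at least 2).
#' @return A single number.
#' @export
r_squared <- function(observed, predicted) {
  check_metric_args(observed, predicted)
  if (var(observed) == 0) {
    stop("R^2 is undefined for a constant observed vector", call. = FALSE)
  }
  1 - sum((observed - predicted)^2) / sum((observed - mean(observed))^2)
}

#' Root mean square error
#'
#' @inheritParams r_squared
#' @return RMSE in the units of the response.
#' @export
rmse <- function(observed, predicted) {
  check_metric_args(observed, predicted)
  sqrt(mean((observed - predicted)^2))
}

check_metric_args <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("`observed` and `predicted` must have equal length", call. = FALSE)
  }
  if (length(observed) < 2) {
    stop("need at least 2 observations", call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(!is.finite(predicted))) {
    stop("non-finite values in metric inputs", call. = FALSE)
  }
  invisible(TRUE)
}
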