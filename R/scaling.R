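#' Fit input/target scalers on a training partition
#'
#' Inputs are mapped to `[-1, 1]` by min-max (required by the saturating
#' tansig hidden layer); the target is centred by its mean and divided by
#' its half-range. Scalers must be fitted on the training partition only —
#' test records outside the training range map outside `[-1, 1]` and are
#' passed through unclipped.
#'
#' @param X Numeric matrix of inputs (records x variables), training rows.
#' @param y Optional numeric target vector (training rows), typically
#'   already Box-Cox transformed. A constant target gets half-range 1 so a
#'   bias-only network remains representable.
#' @return A `scaler_set` with per-column `min`/`max` for inputs and
#'   `center`/`halfrange` for the target.
#' @export
fit_scalers <- function(X, y = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("empty training partition", call. = FALSE)
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  const <- maxs <= mins
  if (any(const)) {
    stop("constant input column(s): ",
         paste(colnames(X)[const], collapse = ", "), call. = FALSE)
  }
  out <- list(min = mins, max = maxs, columns = colnames(X))
  if (!is.null(y)) {
    hr <- (max(y) - min(y)) / 2
    out$center <- mean(y)
    out$halfrange <- if (hr > 0) hr else 1
  }
  structure(out, class = "scaler_set")
}

#' Apply / invert the fitted scalers
#'
#' @param scalers A `scaler_set` from [fit_scalers()].
#' @param X Input matrix to scale (any rows; columns must match).
#' @return `scale_inputs()` maps each column affinely so the training min
#'   is -1 and the training max is +1; `unscale_inputs()` inverts it
#'   exactly. `scale_target()`/`unscale_target()` do the same for the
#'   target via mean/half-range.
#' @export
scale_inputs <- function(scalers, X) {
  X <- as.matrix(X)
  if (!is.null(scalers$columns) && !is.null(colnames(X))) {
    X <- X[, scalers$columns, drop = FALSE]
  }
  sweep(sweep(X, 2, scalers$min), 2,
        (scalers$max - scalers$min) / 2, "/") - 1
}

#' @rdname scale_inputs
#' @export
unscale_inputs <- function(scalers, X) {
  sweep(sweep(as.matrix(X) + 1, 2, (scalers$max - scalers$min) / 2, "*"),
        2, scalers$min, "+")
}

#' @rdname scale_inputs
#' @param y Target values to scale or unscale.
#' @export
scale_target <- function(scalers, y) (y - scalers$center) / scalers$halfrange

#' @rdname scale_inputs
#' @export
unscale_target <- function(scalers, y) y * scalers$halfrange + scalers$center
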