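#' Construct a feedforward network model object
#'
#' A three-layer regression network: inputs, one hyperbolic-tangent
#' (tansig) hidden layer of `nrow(W1)` neurons, and a linear (purelin)
#' output. The object optionally carries the input/target scalers and the
#' Box-Cox exponent with which its targets were transformed, so that
#' prediction returns original response units.
#'
#' @param W1 Hidden weights, `hidden_n x n_inputs`.
#' @param b1 Hidden biases, length `hidden_n`.
#' @param w2 Output weights, length `hidden_n`.
#' @param b2 Output bias (scalar).
#' @param scalers Optional `scaler_set`; `NULL` means the network operates
#'   directly on its inputs/outputs (used for hand-built networks).
#' @param lambda Optional Box-Cox exponent applied to the target before
#'   scaling; `NULL` means none.
#' @param inputs Input column names (defaults to the four substrate
#'   components).
#' @param seed Training seed, for provenance.
#' @return An `mlp_model`.
#' @export
new_mlp_model <- function(W1, b1, w2, b2, scalers = NULL, lambda = NULL,
                          inputs = substrate_components(), seed = NA) {
  W1 <- as.matrix(W1)
  stopifnot(length(b1) == nrow(W1), length(w2) == nrow(W1),
            length(b2) == 1, ncol(W1) == length(inputs))
  if (!all(is.finite(W1)) || !all(is.finite(b1)) ||
      !all(is.finite(w2)) || !is.finite(b2)) {
    stop("all weights must be finite", call. = FALSE)
  }
  structure(list(W1 = W1, b1 = as.numeric(b1), w2 = as.numeric(w2),
                 b2 = as.numeric(b2), hidden_n = nrow(W1),
                 inputs = inputs, scalers = scalers, lambda = lambda,
                 seed = seed),
            class = "mlp_model")
}

# Raw network output on already-scaled inputs.
mlp_forward_scaled <- function(model, Xs) {
  H <- tanh(sweep(Xs %*% t(model$W1), 2, model$b1, "+"))
  drop(H %*% model$w2) + model$b2
}

#' Predict from a fitted network
#'
#' Applies the input scaling, the tansig/purelin forward pass, then inverts
#' the target scaling and the Box-Cox transform, returning predictions in
#' original response units. Vectorized over records.
#'
#' @param model An `mlp_model`.
#' @param X Matrix or data frame of inputs; must contain the model's input
#'   columns (in order, for unnamed matrices).
#' @return Numeric vector of predictions.
#' @export
mlp_forward <- function(model, X) {
  stopifnot(inherits(model, "mlp_model"))
  if (is.data.frame(X)) {
    miss <- setdiff(model$inputs, names(X))
    if (length(miss)) {
      stop("missing input column(s): ", paste(miss, collapse = ", "),
           call. = FALSE)
    }
    X <- as.matrix(X[, model$inputs, drop = FALSE])
  } else {
    X <- as.matrix(X)
    if (ncol(X) != length(model$inputs)) {
      stop("expected ", length(model$inputs), " input columns, got ",
           ncol(X), call. = FALSE)
    }
    if (!is.null(colnames(X))) X <- X[, model$inputs, drop = FALSE]
  }
  Xs <- if (is.null(model$scalers)) X else scale_inputs(model$scalers, X)
  z <- mlp_forward_scaled(model, Xs)
  if (!is.null(model$scalers) && !is.null(model$scalers$center)) {
    z <- unscale_target(model$scalers, z)
  }
  if (!is.null(model$lambda)) z <- boxcox_inverse(z, model$lambda)
  z
}

#' @export
predict.mlp_model <- function(object, newdata, ...) mlp_forward(object, newdata)

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("MLP regressor: %d-%d-1 (tansig/purelin)%s%s\n",
              ncol(x$W1), x$hidden_n,
              if (is.null(x$lambda)) "" else
                sprintf(", Box-Cox lambda %.2f", x$lambda),
              if (is.na(x$seed)) "" else sprintf(", seed %s", x$seed)))
  invisible(x)
}

#' Serialize / restore a model bundle
#'
#' The JSON bundle holds the weights, scalers, Box-Cox exponent, hidden
#' size and training seed — everything [mlp_forward()] needs.
#'
#' @param model An `mlp_model`.
#' @param path Output (or input) JSON path.
#' @return `write_mlp_json()` returns `path` invisibly; `read_mlp_json()`
#'   returns the restored `mlp_model`.
#' @export
write_mlp_json <- function(model, path) {
  payload <- list(W1 = model$W1, b1 = model$b1, w2 = model$w2,
                  b2 = model$b2, inputs = model$inputs,
                  lambda = model$lambda, seed = model$seed,
                  scalers = if (is.null(model$scalers)) NULL else
                    unclass(model$scalers))
  writeLines(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                           digits = NA, null = "null")),
             path)
  invisible(path)
}

#' @rdname write_mlp_json
#' @export
read_mlp_json <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  scalers <- if (is.null(p$scalers)) NULL else {
    s <- p$scalers
    if (!is.null(s$min)) s$min <- unlist(s$min)
    if (!is.null(s$max)) s$max <- unlist(s$max)
    structure(s, class = "scaler_set")
  }
  new_mlp_model(p$W1, p$b1, p$w2, p$b2, scalers = scalers,
                lambda = p$lambda, inputs = p$inputs, seed = p$seed)
}
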