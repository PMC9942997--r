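#' Box-Cox power transform
#'
#' `(x^lambda - 1) / lambda` for `lambda != 0`, `log(x)` at `lambda = 0`
#' (the transform is continuous in lambda at 0; lambdas within 1e-12 of
#' zero use the log branch).
#'
#' @param x Positive numeric vector.
#' @param lambda Transform exponent.
#' @return Transformed vector.
#' @export
boxcox_transform <- function(x, lambda) {
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Box-Cox requires strictly positive finite data", call. = FALSE)
  }
  if (abs(lambda) < 1e-12) log(x) else (x^lambda - 1) / lambda
}

#' Invert the Box-Cox transform
#'
#' For `lambda != 0` the inverse `(lambda * z + 1)^(1/lambda)` is defined
#' only where `lambda * z + 1 > 0`; out-of-range predictions (possible for
#' an unbounded regressor) are clamped to the boundary so the inverse maps
#' to a vanishingly small positive value rather than NaN.
#'
#' @param z Transformed values.
#' @param lambda Transform exponent used forward.
#' @return Values on the original scale.
#' @export
boxcox_inverse <- function(z, lambda) {
  if (abs(lambda) < 1e-12) return(exp(z))
  base <- pmax(lambda * z + 1, 1e-12)
  base^(1 / lambda)
}

# Profile log-likelihood of the normal model for Box-Cox at one lambda.
boxcox_loglik <- function(x, lambda) {
  z <- boxcox_transform(x, lambda)
  s2 <- mean((z - mean(z))^2)
  n <- length(x)
  -n / 2 * log(s2) + (lambda - 1) * sum(log(x))
}

#' Maximum-likelihood Box-Cox exponent by grid search
#'
#' Maximizes the standard Box-Cox profile log-likelihood over the grid
#' `seq(lower, upper, by = step)`. Exact likelihood ties are broken toward
#' the lambda closest to 1 (i.e. toward "no transform").
#'
#' @param x Positive numeric vector of length at least 3 and not constant.
#' @param lower,upper,step Grid bounds and spacing (defaults -5, 5, 0.01).
#' @return A `boxcox_fit` list: `lambda`, `log_lik` at the optimum, and the
#'   grid specification.
#' @export
boxcox_mle <- function(x, lower = -5, upper = 5, step = 0.01) {
  if (length(x) < 3) stop("need at least 3 observations", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0)) {
    stop("Box-Cox requires strictly positive finite data", call. = FALSE)
  }
  if (var(x) == 0) {
    stop("constant vector: Box-Cox exponent is degenerate", call. = FALSE)
  }
  grid <- seq(lower, upper, by = step)
  ll <- vapply(grid, function(l) boxcox_loglik(x, l), numeric(1))
  best <- which(ll == max(ll))
  if (length(best) > 1) {
    best <- best[order(abs(grid[best] - 1), grid[best])][1]
  }
  structure(list(lambda = grid[best], log_lik = ll[best],
                 grid = c(lower = lower, upper = upper, step = step),
                 n = length(x)),
            class = "boxcox_fit")
}

#' @export
print.boxcox_fit <- function(x, ...) {
  cat(sprintf("Box-Cox fit: lambda = %.2f (log-lik %.3f, grid [%g, %g] by %g)\n",
              x$lambda, x$log_lik, x$grid["lower"], x$grid["upper"],
              x$grid["step"]))
  invisible(x)
}
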