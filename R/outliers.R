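#' PCA-based outlier screen
#'
#' Flags records whose Hotelling-style score distance — computed on the
#' leading principal components explaining at least `var_explained` of the
#' variance of the column-standardized data — exceeds the mean plus
#' `n_sd` standard deviations of the score distances. The screen only
#' flags; it never drops records.
#'
#' @param X Numeric matrix or data frame (records x variables), at least
#'   3 records. Constant columns are ignored (they carry no structure).
#' @param var_explained Minimum cumulative variance of the retained
#'   components (default 0.95).
#' @param n_sd Flagging threshold in standard deviations (default 3).
#' @return A `pca_screen` list: logical `flag`, numeric `distance` per
#'   record, `n_components` retained, and the threshold used.
#' @export
pca_outlier_screen <- function(X, var_explained = 0.95, n_sd = 3) {
  X <- as.matrix(as.data.frame(X)[vapply(as.data.frame(X), is.numeric,
                                         logical(1))])
  if (nrow(X) < 3) stop("need at least 3 records", call. = FALSE)
  sds <- apply(X, 2, sd)
  keep <- sds > 0
  if (!any(keep)) stop("all columns constant: nothing to screen",
                       call. = FALSE)
  Xs <- scale(X[, keep, drop = FALSE])
  pc <- prcomp(Xs, center = FALSE, scale. = FALSE)
  ev <- pc$sdev^2
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= var_explained)[1]
  scores <- pc$x[, seq_len(k), drop = FALSE]
  d <- sqrt(rowSums(sweep(scores^2, 2, ev[seq_len(k)], "/")))
  thr <- mean(d) + n_sd * sd(d)
  flag <- if (sd(d) == 0) rep(FALSE, length(d)) else d > thr
  structure(list(flag = flag, distance = d, n_components = k,
                 threshold = thr, var_explained = var_explained,
                 n_sd = n_sd),
            class = "pca_screen")
}

#' @export
print.pca_screen <- function(x, ...) {
  cat(sprintf("PCA outlier screen: %d/%d records flagged (%d components, threshold %.3f)\n",
              sum(x$flag), length(x$flag), x$n_components, x$threshold))
  invisible(x)
}
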