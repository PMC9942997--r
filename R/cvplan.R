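#' Replicated k-fold cross-validation plan
#'
#' Builds the evaluation plan used throughout the package: `n_replicates`
#' independent shuffles of the record indices, each split into `k`
#' contiguous folds whose sizes differ by at most one. The plan is a
#' deterministic function of `(n_records, seed)`; model families compared
#' under the same plan see byte-identical fold memberships.
#'
#' @param n_records Number of records (at least `k`).
#' @param seed RNG seed.
#' @param k Folds per replicate (default 5).
#' @param n_replicates Independent shuffles (default 10).
#' @return A `cv_plan`: `folds[[r]][[f]]` holds the indices of the records
#'   held out in fold `f` of replicate `r`.
#' @export
make_cv_plan <- function(n_records, seed, k = 5, n_replicates = 10) {
  if (n_records < k) {
    stop("need at least k = ", k, " records", call. = FALSE)
  }
  sizes <- rep(n_records %/% k, k)
  extra <- n_records %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1
  ends <- cumsum(sizes)
  starts <- c(1, head(ends, -1) + 1)
  folds <- with_seed(seed, {
    lapply(seq_len(n_replicates), function(r) {
      ord <- sample.int(n_records)
      lapply(seq_len(k), function(f) sort(ord[starts[f]:ends[f]]))
    })
  })
  structure(list(n_records = n_records, k = k,
                 n_replicates = n_replicates, seed = seed, folds = folds),
            class = "cv_plan")
}

#' Restrict a plan to its first replicates
#'
#' Used during architecture search, where the fitness of a candidate
#' network is scored with a single cross-validation replicate for cost and
#' the winner is re-scored with the full plan.
#'
#' @param plan A `cv_plan`.
#' @param n_replicates How many leading replicates to keep.
#' @return A `cv_plan` with the same folds, truncated.
#' @export
restrict_plan <- function(plan, n_replicates) {
  stopifnot(inherits(plan, "cv_plan"),
            n_replicates >= 1, n_replicates <= plan$n_replicates)
  plan$folds <- plan$folds[seq_len(n_replicates)]
  plan$n_replicates <- n_replicates
  plan
}

#' Serialize a plan to JSON / hash it for audit
#'
#' `cv_plan_json()` renders the replicate -> fold -> indices structure as
#' JSON; `cv_plan_hash()` is the md5 of that rendering, recorded in fit
#' reports so that a comparison between model families can assert it used
#' identical folds.
#'
#' @param plan A `cv_plan`.
#' @return A JSON string, or a 32-character md5 hash.
#' @export
cv_plan_json <- function(plan) {
  jsonlite::toJSON(list(n_records = plan$n_records, k = plan$k,
                        n_replicates = plan$n_replicates, seed = plan$seed,
                        folds = plan$folds),
                   auto_unbox = TRUE)
}

#' @rdname cv_plan_json
#' @export
cv_plan_hash <- function(plan) {
  object_hash(list(plan$n_records, plan$k, plan$n_replicates, plan$folds))
}

#' @export
print.cv_plan <- function(x, ...) {
  cat(sprintf("CV plan: %d-fold x %d replicates over %d records (seed %d)\n",
              x$k, x$n_replicates, x$n_records, x$seed))
  invisible(x)
}
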