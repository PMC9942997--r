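#' Generator configuration for synthetic replicates
#'
#' @param n_replicates Replicate bags simulated per substrate (default 12,
#'   the trial's replication).
#' @param seed RNG seed; recorded in the dataset's provenance.
#' @param max_redraws Attempts allowed when rejecting draws that violate
#'   positivity or the period ordering before erroring.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_replicates = 12, seed = 42,
                             max_redraws = 1000) {
  stopifnot(n_replicates >= 2, max_redraws >= 1)
  structure(list(n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 noise_family = "gaussian",
                 truncation = "reject-redraw-at-0",
                 max_redraws = as.integer(max_redraws)),
            class = "generator_config")
}

#' Standard deviation implied by a standard error
#'
#' The summary table reports the standard error of a mean over `n`
#' replicates; the per-replicate standard deviation is `se * sqrt(n)`.
#'
#' @param se Standard error (response units); non-negative.
#' @param n Replicate count behind the reported mean; at least 1.
#' @return Standard deviation in the same units. Vectorized.
#' @export
sd_from_se <- function(se, n) {
  if (any(!is.finite(se)) || any(se < 0)) {
    stop("`se` must be finite and non-negative", call. = FALSE)
  }
  if (any(n < 1)) stop("`n` must be at least 1", call. = FALSE)
  se * sqrt(n)
}

# Gaussian draws truncated to (0, Inf) by rejection (redraw, never clip).
draw_positive <- function(n, mean, sd, max_redraws) {
  x <- rnorm(n, mean, sd)
  if (sd == 0) return(x)
  for (i in seq_len(max_redraws)) {
    bad <- which(x <= 0)
    if (!length(bad)) return(x)
    x[bad] <- rnorm(length(bad), mean, sd)
  }
  if (any(x <= 0)) {
    stop("positivity rejection did not converge within ", max_redraws,
         " redraws", call. = FALSE)
  }
  x
}

#' Simulate replicate-level observations from a trial summary
#'
#' Emulates the per-bag data behind a summary table: for every substrate
#' and response, draws `n_replicates` independent Gaussian observations
#' with the reported mean and standard deviation `se * sqrt(n)` (using the
#' summary's own `n`, so that the noise level reflects the original
#' replication regardless of how many replicates are simulated).
#' Non-positive draws are rejected and redrawn. Records whose cultivation
#' periods violate SRP <= DPHF <= DFFH <= TCP have those four responses
#' redrawn jointly, up to `max_redraws` rounds.
#'
#' Responses are drawn independently within a record: the summary reports
#' no cross-response covariance, and none is invented.
#'
#' @param summary A summary table as returned by
#'   [substrate_trial_summary()].
#' @param cfg A [generator_config()].
#' @return A `replicate_dataset` with `nrow(summary) * n_replicates`
#'   records and full generator provenance (identical seed, identical
#'   dataset).
#' @export
generate_replicates <- function(summary = substrate_trial_summary(),
                                cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  resp <- response_info()
  mean_cols <- paste0(tolower(resp$name), "_mean")
  se_cols <- paste0(tolower(resp$name), "_se")
  stopifnot(all(c(mean_cols, se_cols) %in% names(summary)))
  if (any(!is.finite(as.matrix(summary[, se_cols])))) {
    stop("summary standard errors must all be finite", call. = FALSE)
  }
  if (any(as.matrix(summary[, mean_cols]) <= 0)) {
    stop("all response means must be positive to generate positive ",
         "replicates", call. = FALSE)
  }
  n <- cfg$n_replicates
  with_seed(cfg$seed, {
    rows <- lapply(seq_len(nrow(summary)), function(i) {
      draws <- list()
      for (j in seq_len(nrow(resp))) {
        nm <- tolower(resp$name[j])
        sdev <- sd_from_se(summary[[se_cols[j]]][i], summary$n[i])
        draws[[nm]] <- draw_positive(n, summary[[mean_cols[j]]][i], sdev,
                                     cfg$max_redraws)
      }
      # joint redraw of the four period responses where ordering fails
      for (round in seq_len(cfg$max_redraws)) {
        bad <- which(draws$dphf < draws$srp | draws$dffh < draws$dphf |
                       draws$tcp < draws$dffh)
        if (!length(bad)) break
        for (nm in c("srp", "dphf", "dffh", "tcp")) {
          mcol <- paste0(nm, "_mean"); scol <- paste0(nm, "_se")
          sdev <- sd_from_se(summary[[scol]][i], summary$n[i])
          draws[[nm]][bad] <- draw_positive(length(bad),
                                            summary[[mcol]][i], sdev,
                                            cfg$max_redraws)
        }
      }
      if (any(draws$dphf < draws$srp | draws$dffh < draws$dphf |
                draws$tcp < draws$dffh)) {
        stop("period ordering rejection did not converge for substrate ",
             summary$label[i], call. = FALSE)
      }
      data.frame(label = summary$label[i],
                 bs_pct = summary$bs_pct[i], hs_pct = summary$hs_pct[i],
                 wb_pct = summary$wb_pct[i], rb_pct = summary$rb_pct[i],
                 replicate_id = seq_len(n),
                 srp_days = draws$srp, dphf_days = draws$dphf,
                 dffh_days = draws$dffh, yield_g = draws$yield,
                 be_pct = draws$be, tcp_days = draws$tcp,
                 nfb_count = draws$nfb,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    new_replicate_dataset(out, provenance = list(
      generator = "gaussian-replicates",
      n_replicates = n, seed = cfg$seed,
      noise_family = cfg$noise_family,
      truncation = cfg$truncation,
      n_substrates = nrow(summary)
    ))
  })
}

#' Linear benchmark with known ground truth
#'
#' Generates a table of four substrate-style inputs and one synthetic
#' response `y = intercept + sum(coefficients * x) + N(0, noise_sd)`, for
#' validating the sensitivity and stepwise-regression stages against a
#' known truth.
#'
#' With `compositional = TRUE` (the default) inputs are drawn uniformly on
#' the simplex of non-negative percentages summing to 100, matching real
#' substrate data. Note that on the simplex any three inputs determine the
#' fourth, so coefficient vectors are identified only up to the constraint
#' (adding a constant to all four coefficients changes nothing). Set
#' `compositional = FALSE` for independent uniform inputs on `[0, 100]`,
#' under which a zero coefficient is genuinely uninformative — use this
#' variant when a test needs an identifiable irrelevant input.
#'
#' @param coefficients Numeric length-4 vector of true coefficients, in
#'   component order bs, hs, wb, rb.
#' @param intercept True intercept.
#' @param noise_sd Gaussian noise standard deviation; non-negative.
#' @param n_records Number of records (at least 10).
#' @param seed RNG seed.
#' @param compositional Draw inputs on the 100% simplex (default) or
#'   independently.
#' @return A data frame with the four input columns and `y`; the truth is
#'   stored in the `provenance` attribute.
#' @export
generate_linear_benchmark <- function(coefficients, intercept = 0,
                                      noise_sd = 1, n_records = 100,
                                      seed = 1, compositional = TRUE) {
  stopifnot(length(coefficients) == 4, n_records >= 10)
  if (!is.finite(noise_sd) || noise_sd < 0) {
    stop("`noise_sd` must be non-negative", call. = FALSE)
  }
  with_seed(seed, {
    if (compositional) {
      g <- matrix(rexp(4 * n_records), ncol = 4)
      x <- 100 * g / rowSums(g)
    } else {
      x <- matrix(runif(4 * n_records, 0, 100), ncol = 4)
    }
    colnames(x) <- SUBSTRATE_COLS
    y <- intercept + drop(x %*% coefficients) +
      rnorm(n_records, 0, noise_sd)
    out <- data.frame(x, y = y)
    attr(out, "provenance") <- list(
      generator = "linear-benchmark", coefficients = coefficients,
      intercept = intercept, noise_sd = noise_sd, seed = seed,
      compositional = compositional
    )
    out
  })
}
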