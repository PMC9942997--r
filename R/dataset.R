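#' Registry of cultivation responses
#'
#' Metadata for the seven responses recorded per cultivation bag: spawn run
#' period (SRP), days to pinhead formation (DPHF), days to first harvest
#' (DFFH), number of fruiting bodies (NFB), fresh yield, biological
#' efficiency (BE) and total cultivation period (TCP). Six of the seven are
#' modelled; NFB is carried as data only.
#'
#' @return A data frame with columns `name`, `column` (the replicate-table
#'   column holding the observation), `unit`, `direction` (the side of the
#'   response a grower wants) and `modeled`.
#' @export
response_info <- function() {
  data.frame(
    name      = c("SRP", "DPHF", "DFFH", "NFB", "YIELD", "BE", "TCP"),
    column    = c("srp_days", "dphf_days", "dffh_days", "nfb_count",
                  "yield_g", "be_pct", "tcp_days"),
    unit      = c("days", "days", "days", "count/bag", "g/bag", "%", "days"),
    direction = c("minimize", "minimize", "minimize", "maximize",
                  "maximize", "maximize", "minimize"),
    modeled   = c(TRUE, TRUE, TRUE, FALSE, TRUE, TRUE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Names of the six modelled responses
#' @return Character vector: SRP, DPHF, DFFH, YIELD, BE, TCP.
#' @export
modeled_responses <- function() {
  info <- response_info()
  info$name[info$modeled]
}

# Map a response name (e.g. "YIELD") to its replicate-table column
# ("yield_g"). Column names pass through unchanged.
response_column <- function(response) {
  info <- response_info()
  vapply(response, function(r) {
    if (r %in% info$name) info$column[match(r, info$name)] else r
  }, character(1), USE.NAMES = FALSE)
}

#' Biological efficiency of a cultivation bag
#'
#' BE (%) is the fresh fruiting-body mass harvested from a bag divided by
#' the dry mass of the substrate in that bag, times 100. The trial packed
#' 825 g of substrate mixture at 70% moisture per bag, so the nominal dry
#' mass is 825 x 0.30 = 247.5 g; those values are the defaults.
#'
#' @param fresh_yield Fresh fruiting-body mass per bag (g); non-negative.
#' @param substrate_wet_mass Wet substrate mass packed per bag (g); positive.
#' @param moisture_fraction Moisture content of the packed substrate as a
#'   fraction in `[0, 1)`.
#' @return Biological efficiency in percent (unrounded; round at report
#'   time). Vectorized over `fresh_yield`.
#' @examples
#' biological_efficiency(99.7) # 40.28..., prints as 40.3 at one decimal
#' @export
biological_efficiency <- function(fresh_yield, substrate_wet_mass = 825,
                                  moisture_fraction = 0.70) {
  if (!is.numeric(fresh_yield) || any(!is.finite(fresh_yield))) {
    stop("`fresh_yield` must be finite numeric", call. = FALSE)
  }
  if (any(fresh_yield < 0)) {
    stop("`fresh_yield` must be non-negative", call. = FALSE)
  }
  if (length(substrate_wet_mass) != 1 || !is.finite(substrate_wet_mass) ||
      substrate_wet_mass <= 0) {
    stop("`substrate_wet_mass` must be a single positive number",
         call. = FALSE)
  }
  if (length(moisture_fraction) != 1 || !is.finite(moisture_fraction) ||
      moisture_fraction < 0) {
    stop("`moisture_fraction` must be a fraction in [0, 1)", call. = FALSE)
  }
  if (moisture_fraction >= 1) {
    stop("`moisture_fraction` >= 1 leaves zero dry mass", call. = FALSE)
  }
  100 * fresh_yield / (substrate_wet_mass * (1 - moisture_fraction))
}

#' Summary of the 16-substrate cultivation trial
#'
#' Loads the embedded summary of the wood ear cultivation trial: 16
#' substrate formulations built from beech sawdust (BS), hornbeam sawdust
#' (HS), wheat bran (WB) and rice bran (RB), with the mean and standard
#' error (n = 12 replicate bags) of each of the seven recorded responses,
#' plus the substrate C/N ratio (carried as metadata, not modelled).
#'
#' @return A data frame of 16 rows with columns `label`, the four
#'   composition percentages, `cn_ratio`, `n`, and `<response>_mean` /
#'   `<response>_se` pairs for srp, dphf, dffh, nfb, yield, be and tcp.
#' @export
substrate_trial_summary <- function() {
  path <- system.file("extdata", "substrate_trial_summary.csv",
                      package = "woodear", mustWork = TRUE)
  out <- read.csv(path, stringsAsFactors = FALSE)
  validate_compositions(out)
  class(out) <- c("substrate_summary", "data.frame")
  out
}

# Shared composition check: the four components of every row must be
# non-negative and sum to 100 within 1e-9.
validate_compositions <- function(df, tol = 1e-9) {
  comp <- as.matrix(df[, SUBSTRATE_COLS, drop = FALSE])
  if (any(comp < 0)) {
    stop("negative substrate component percentages", call. = FALSE)
  }
  bad <- which(abs(rowSums(comp) - 100) > tol)
  if (length(bad)) {
    stop("substrate compositions do not sum to 100 at row(s): ",
         paste(head(bad, 10), collapse = ", "), call. = FALSE)
  }
  invisible(df)
}
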