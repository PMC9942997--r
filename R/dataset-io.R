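# Replicate-table schema. `nfb_count` is optional (NFB is carried as data
# only and some user tables omit it).
REPLICATE_REQUIRED <- c("label", SUBSTRATE_COLS, "replicate_id",
                        "srp_days", "dphf_days", "dffh_days",
                        "yield_g", "be_pct", "tcp_days")
REPLICATE_OPTIONAL <- "nfb_count"

new_replicate_dataset <- function(df, provenance = list()) {
  rownames(df) <- NULL
  attr(df, "provenance") <- provenance
  class(df) <- c("replicate_dataset", "data.frame")
  df
}

#' @export
print.replicate_dataset <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat(sprintf("replicate dataset: %d records, %d substrates\n",
              nrow(x), length(unique(x$label))))
  if (length(prov)) {
    cat("provenance:", jsonlite::toJSON(prov, auto_unbox = TRUE), "\n")
  }
  NextMethod()
}

#' Read a replicate-level cultivation table
#'
#' Reads a per-bag observation table in the package's CSV schema: `label`,
#' the four composition percentages (`bs_pct`, `hs_pct`, `wb_pct`,
#' `rb_pct`), `replicate_id`, and the observed responses (`srp_days`,
#' `dphf_days`, `dffh_days`, `yield_g`, `be_pct`, `tcp_days`, optionally
#' `nfb_count`). If a JSON provenance sidecar (`<path>.json`) exists it is
#' attached to the returned dataset.
#'
#' Missing or unknown columns raise a schema error naming them;
#' compositions not summing to 100 raise a validation error listing the
#' offending row indices. Violations of the within-record ordering
#' SRP <= DPHF <= DFFH <= TCP, or non-positive observations, raise a
#' warning (user data may legitimately be messy; the generator never is).
#'
#' @param path CSV file path.
#' @return A `replicate_dataset` (data frame plus provenance attribute).
#' @export
read_replicate_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REPLICATE_REQUIRED, names(df))
  if (length(missing_cols)) {
    stop("replicate table schema error; missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), c(REPLICATE_REQUIRED, REPLICATE_OPTIONAL))
  if (length(extra)) {
    stop("replicate table schema error; unknown column(s): ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  validate_compositions(df)
  check_record_invariants(df)
  keep <- intersect(c(REPLICATE_REQUIRED, REPLICATE_OPTIONAL), names(df))
  df <- df[, keep]
  prov <- list(source = path)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    prov <- jsonlite::fromJSON(sidecar, simplifyVector = TRUE)
  }
  new_replicate_dataset(df, provenance = prov)
}

#' Write a replicate-level cultivation table
#'
#' Writes the dataset in canonical column order, with a JSON provenance
#' sidecar at `<path>.json` when the dataset carries provenance. A
#' write/read round trip reproduces the values to full precision.
#'
#' @param dataset A `replicate_dataset` or compatible data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_replicate_csv <- function(dataset, path) {
  keep <- intersect(c(REPLICATE_REQUIRED, REPLICATE_OPTIONAL),
                    names(dataset))
  df <- as.data.frame(dataset)[, keep]
  # full-precision round trip: serialize numerics at 17 significant digits
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) format(x, digits = 17,
                                                scientific = FALSE,
                                                trim = TRUE))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  prov <- attr(dataset, "provenance")
  if (length(prov)) {
    writeLines(as.character(jsonlite::toJSON(prov, auto_unbox = TRUE,
                                             digits = NA)),
               paste0(path, ".json"))
  }
  invisible(path)
}

check_record_invariants <- function(df) {
  pos_cols <- intersect(c("srp_days", "dphf_days", "dffh_days", "yield_g",
                          "be_pct", "tcp_days", "nfb_count"), names(df))
  nonpos <- vapply(pos_cols, function(cl) any(df[[cl]] <= 0), logical(1))
  if (any(nonpos)) {
    warning("non-positive observations in column(s): ",
            paste(pos_cols[nonpos], collapse = ", "), call. = FALSE)
  }
  bad <- df$dphf_days < df$srp_days | df$dffh_days < df$dphf_days |
    df$tcp_days < df$dffh_days
  if (any(bad)) {
    warning(sum(bad), " record(s) violate SRP <= DPHF <= DFFH <= TCP",
            call. = FALSE)
  }
  invisible(df)
}
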