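# Canonical order of the four compositional substrate components
# (percent by dry mass, summing to 100).
SUBSTRATE_COLS <- c("bs_pct", "hs_pct", "wb_pct", "rb_pct")

#' Names of the compositional input columns
#'
#' The four substrate components, in canonical order: beech sawdust (BS),
#' hornbeam sawdust (HS), wheat bran (WB) and rice bran (RB), each a
#' percentage of substrate dry mass. Every modelling function in the
#' package expects these column names.
#'
#' @return Character vector of length 4.
#' @export
substrate_components <- function() SUBSTRATE_COLS
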