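#!/usr/bin/env Rscript
# Step 4 — narrative report over the study tables.
#
# Reads the tables written by step 3 and summarizes what the comparison
# found: how much out-of-sample accuracy the GA-tuned network gains over
# the stepwise linear baseline per response, and which substrate
# components each response is most sensitive to. Writes
# results/summary.md.

library(woodear)

fm <- read_study_csv("results/study/fit_metrics.csv")
sens <- read_study_csv("results/study/sensitivity.csv")

lines <- c("# Substrate modelling study: summary",
           "",
           sprintf("Config hash `%s`, seed %d.", attr(fm, "config_hash"),
                   attr(fm, "seed")),
           "",
           "## Out-of-sample accuracy (pooled over 5-fold x 10-replicate CV)",
           "",
           "| response | MLP-GA test R2 | SR test R2 | MLP-GA test RMSE | SR test RMSE | hidden |",
           "|---|---|---|---|---|---|")
for (resp in modeled_responses()) {
  m <- fm[fm$response == resp & fm$family == "MLP-GA", ]
  s <- fm[fm$response == resp & fm$family == "SR", ]
  lines <- c(lines, sprintf("| %s | %.3f | %.3f | %.3f | %.3f | %d |",
                            resp, m$test_r2, s$test_r2, m$test_rmse,
                            s$test_rmse, m$hidden_n))
}
lines <- c(lines, "",
           "## Most influential substrate component per response",
           "",
           "| response | ranking by rescaled VSR |", "|---|---|")
for (resp in modeled_responses()) {
  d <- sens[sens$response == resp, ]
  d <- d[order(-d$rescaled_vsr), ]
  lines <- c(lines, sprintf(
    "| %s | %s |", resp,
    paste(sprintf("%s (%.3f)", sub("_pct", "", d$input), d$rescaled_vsr),
          collapse = " > ")))
}

dir.create("results", showWarnings = FALSE)
writeLines(lines, "results/summary.md")
cat(lines, sep = "\n")
cat("\nwrote results/summary.md\n")
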