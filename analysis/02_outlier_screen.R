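#!/usr/bin/env Rscript
# Step 2 — PCA outlier screen of the simulated replicates.
#
# Records are scored by their Hotelling-style distance on the principal
# components explaining >= 95% of the variance of the standardized
# response matrix; a record further than mean + 3 SD is flagged. The
# screen only flags (no record is dropped): with 192 records, roughly
# half a flag is expected by chance even from perfectly clean data.

library(woodear)

dataset <- read_replicate_csv("results/replicates.csv")
resp_cols <- c("srp_days", "dphf_days", "dffh_days", "yield_g", "be_pct",
               "tcp_days")
screen <- pca_outlier_screen(dataset[, resp_cols])

print(screen)
out <- data.frame(index = seq_len(nrow(dataset)), label = dataset$label,
                  replicate_id = dataset$replicate_id,
                  distance = screen$distance, flagged = screen$flag)
write.csv(out, "results/outlier_screen.csv", row.names = FALSE)
cat(sprintf("threshold %.3f on %d components; %d record(s) flagged\n",
            screen$threshold, screen$n_components, sum(screen$flag)))
if (any(screen$flag)) {
  print(out[out$flagged, ], row.names = FALSE)
}
cat("wrote results/outlier_screen.csv\n")
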