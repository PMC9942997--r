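#!/usr/bin/env Rscript
# Step 3 — fit and compare the model families.
#
# For each of the six modelled responses: fit the Box-Cox exponent, let
# the genetic algorithm pick the hidden-layer size (cross-validated RMSE
# as fitness, cached per size), evaluate the winning network and the
# bidirectional stepwise regression baseline under one shared 5-fold x
# 10-replicate cross-validation plan, and compute leave-one-input-out
# sensitivity (VSE/VSR) of the final network. All tables land in
# results/study/.

library(woodear)

config <- study_config(seed = 42, data = "results/replicates.csv",
                       out_dir = "results/study")
result <- run_full_study(config)

cat("\n")
print(result)
cat("\nSensitivity (rescaled VSR by response):\n")
wide <- reshape(result$sensitivity[, c("response", "input",
                                       "rescaled_vsr")],
                idvar = "response", timevar = "input",
                direction = "wide")
names(wide) <- sub("rescaled_vsr\\.", "", names(wide))
print(wide, row.names = FALSE, digits = 3)
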