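#!/usr/bin/env Rscript

# Step 3: screening performance of each approach on its own receptor.
# For every receptor and class, the retained SB, LB and SBLB ensembles are
# screened against the receptor's actives plus the opposite class as
# decoys; recall, specificity and MCC are tabulated ("ND" when the MCC
# denominator vanishes). By construction every retained model retrieves
# zero decoys, so FP = 0 and Sp = 1 throughout; recall varies with how much
# of the actives' variability (dropped features, distractors) the ensembles
# absorbed.
#
# Reads results/pipeline.rds; writes results/performance.csv.

library(pharmselect)

results <- readRDS("results/pipeline.rds")
perf <- performance_table(results)
write.csv(perf, "results/performance.csv", row.names = FALSE, quote = FALSE)
print(perf)

sblb <- perf[perf$approach == "SBLB", ]
message(sprintf("SBLB: mean recall %.3f, min recall %.3f, all Sp = %s",
                mean(sblb$R), min(sblb$R),
                paste(unique(sblb$Sp), collapse = "/")))
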