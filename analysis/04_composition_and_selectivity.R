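#!/usr/bin/env Rscript

# Step 4: model composition and cross-receptor selectivity.
#  - feature-type distribution and feature-count histogram of the retained
#    SBLB models, agonist vs antagonist composition comparison
#    (Mann-Whitney per type, BH-adjusted), and the correlation between
#    ensemble size and dataset size (Kendall tau-b);
#  - the cross-screening matrix: every SBLB ensemble against every dataset
#    (off-diagonal recalls expose any cross-receptor promiscuity).
#
# Reads results/pipeline.rds + results/benchmark.rds; writes
# results/composition.csv, results/composition_tests.csv,
# results/cross_screen.csv.

library(pharmselect)

results <- readRDS("results/pipeline.rds")
bench <- readRDS("results/benchmark.rds")

all_models <- list(); ago <- list(); anta <- list()
ens_sizes <- integer(0); ds_sizes <- integer(0)
for (key in names(results)) {
  mem <- results[[key]]$ensembles$SBLB$members
  all_models <- c(all_models, mem)
  if (grepl("agonist$", key) && !grepl("antagonist$", key)) {
    ago <- c(ago, mem)
  } else {
    anta <- c(anta, mem)
  }
  ens_sizes <- c(ens_sizes, length(mem))
  ds_sizes <- c(ds_sizes, length(results[[key]]$actives$ligands))
}

st <- composition_stats(all_models)
write.csv(data.frame(type = names(st$type_fractions),
                     fraction = round(st$type_fractions, 4L),
                     count = st$type_counts),
          "results/composition.csv", row.names = FALSE, quote = FALSE)
message(sprintf("feature count per model: median %s; type fractions: %s",
                st$median_features,
                paste(sprintf("%s %.1f%%", names(st$type_fractions),
                              100 * st$type_fractions), collapse = ", ")))

cmp <- compare_composition(ago, anta)
if (!is.null(cmp)) {
  write.csv(cmp, "results/composition_tests.csv", row.names = FALSE,
            quote = FALSE)
  sig <- cmp$type[cmp$p_adjusted < 0.05]
  message("agonist vs antagonist composition, significant types (BH<0.05): ",
          if (length(sig)) paste(sig, collapse = ", ") else "none")
}

kt <- kendall_tau(ds_sizes, ens_sizes)
message(sprintf("ensemble size vs dataset size: Kendall tau = %s (p = %s)",
                format(kt$tau, digits = 3L), format(kt$p_value, digits = 3L)))

ensembles <- lapply(results, function(r) r$ensembles$SBLB)
datasets <- lapply(results, function(r) r$actives)
m <- cross_screen(ensembles, datasets)
write.csv(round(m, 3L), "results/cross_screen.csv", quote = FALSE)
off <- m[row(m) != col(m)]
message(sprintf("cross-screen: diagonal mean %.3f, off-diagonal mean %.3f (max %.3f)",
                mean(diag(m)), mean(off), max(off)))
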