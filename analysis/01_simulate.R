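#!/usr/bin/env Rscript

# Step 1: generate the synthetic benchmark that stands in for a
# nuclear-receptor ligand/structure collection: 6 pseudo-receptors, each
# with an agonist archetype (20 ligands) and an antagonist archetype
# (10 ligands), one pseudo-complex per class, 0.3 A feature jitter, a
# planted non-essential feature per archetype dropped by a quarter of the
# actives, and 0-2 peripheral distractor features per ligand.
#
# Writes bench/ (SDF + PDB + manifest) and results/benchmark.rds.

library(pharmselect)

seed <- 7L
dir.create("results", showWarnings = FALSE)
bench <- generate_benchmark(n_receptors = 6L, n_agonists = 20L,
                            n_antagonists = 10L, jitter_sigma = 0.3,
                            seed = seed, out_dir = "results/bench")
saveRDS(bench, "results/benchmark.rds")

man <- bench$manifest
message(sprintf("benchmark: %d receptors, %d ligands (%d droppers, %d with distractors)",
                length(bench$receptors), nrow(man),
                sum(nzchar(man$dropped)), sum(man$n_extra > 0)))
message("wrote results/bench/ and results/benchmark.rds")
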