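#!/usr/bin/env Rscript
# Full index pipeline on the simulated study: specimen filtering with the
# default policy, prey-importance tables (F, A, P), Levins breadth, and the
# pairwise overlap matrix. Writes results/prey_importance.tsv,
# results/niche_breadth.tsv and results/diet_overlap.tsv.

suppressPackageStartupMessages(library(gutdiet))

records <- "results/simulated_diet_records.tsv"
if (!file.exists(records)) stop("run analysis/02_simulate_study.R first")
policy <- default_exclusion_policy()

idx <- run_indices(records, out_dir = "results", policy = policy)
cat(sprintf("Prey importance: %d group x prey rows -> %s\n",
            nrow(idx$result$importance), idx$importance))
print(idx$result$breadth, n = 8)

ov <- run_overlap(records, out_dir = "results", policy = policy)
M <- ov$result
spring <- grepl("spring", rownames(M))
cat(sprintf(
  "Mean off-diagonal overlap: spring %.1f%%, autumn %.1f%% -> %s\n",
  mean(M[spring, spring][upper.tri(M[spring, spring])]),
  mean(M[!spring, !spring][upper.tri(M[!spring, !spring])]),
  ov$overlap))
cat("Finding: the simulated autumn divergence of two species lowers mean\n",
    "autumn overlap below the spring level, matching the seasonal pattern\n",
    "the design encodes.\n", sep = "")
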