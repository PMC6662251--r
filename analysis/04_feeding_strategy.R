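#!/usr/bin/env Rscript
# Modified Costello (Amundsen) feeding-strategy diagrams for every simulated
# group: prey-specific abundance against frequency of occurrence, classified
# into dominant/rare prey, specialization vs generalization, and BPC/WPC
# tendencies. Writes results/feeding_strategy.tsv and .png.

suppressPackageStartupMessages(library(gutdiet))

records <- "results/simulated_diet_records.tsv"
if (!file.exists(records)) stop("run analysis/02_simulate_study.R first")

out <- run_strategy(records, out_dir = "results",
                    policy = default_exclusion_policy(), plot = TRUE)
for (g in names(out$result)) {
  rep <- out$result[[g]]
  dom <- rep$points$prey_category[rep$points$importance == "dominant"]
  cat(sprintf("%-35s %-11s dominant prey: %s\n", g, rep$strategy,
              if (length(dom)) paste(dom, collapse = ", ") else "(none)"))
}
cat(sprintf("Coordinates: %s; figure: %s\n", out$coordinates, out$figure))
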