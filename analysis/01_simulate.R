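#!/usr/bin/env Rscript
# Stage 1 — synthetic phenomic experiment.
#
# Generates the full set of inputs the downstream stages consume: plate
# intensity time series for gemcitabine and cytarabine dose series with
# replicate reference cultures, planted enhancer/suppressor strains and a
# handful of no-growth strains, plus ground truth for later comparison.
# Outputs land in results/01_simulate/.

library(phenodgi)
library(data.table)

out_dir <- "results/01_simulate"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

# Study-scale dose series and reference replication; the mutant panel and
# reference count are sized for a desk-scale run (the full screen's ~5000
# strains would change nothing but runtime). 12 planted enhancers (L slope
# > 0), 6 planted suppressors (L slope < 0), 2 strains that never grow,
# remainder null.
planted <- list(
  shifts = data.frame(strain = sprintf("yko_%04d", 1:6),
                      cpp = "L", value = rep(c(2, -1.5), each = 3)),
  slopes = rbind(
    data.frame(strain = sprintf("yko_%04d", 1:12), drug = "gemcitabine",
               cpp = "L", value = 0.45),
    data.frame(strain = sprintf("yko_%04d", 1:8), drug = "cytarabine",
               cpp = "L", value = 0.14),
    data.frame(strain = sprintf("yko_%04d", 13:18), drug = "gemcitabine",
               cpp = "L", value = -0.25)))

config <- simulation_config(
  seed = 20260923L,
  n_mutant_strains = 120,
  n_knockdown_strains = 12,
  n_reference_cultures = 96,
  planted_effects = planted,
  no_growth_fraction = 2 / 132)

sim <- generate_plate_experiment(config)
write_tsv_table(sim$timeseries, file.path(out_dir, "timeseries.tsv"))
write_tsv_table(sim$truth, file.path(out_dir, "ground_truth.tsv"))

message(sprintf("simulated %d cultures x %d timepoints (%d rows)",
                nrow(unique(sim$timeseries[, .(plate, row, col, drug, dose)])),
                length(config$timepoints), nrow(sim$timeseries)))
message(sprintf("planted: %d enhancer, %d suppressor, %d no-growth strains",
                sum(sim$truth[cpp == "L" & drug == "gemcitabine"]$true_class
                    == "enhancer"),
                sum(sim$truth[cpp == "L" & drug == "gemcitabine"]$true_class
                    == "suppressor"),
                length(unique(sim$truth[no_growth == TRUE]$strain))))
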