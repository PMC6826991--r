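#!/usr/bin/env Rscript
# Stage 4 — recursive EM clustering of interaction profiles.
#
# Clusters the 4-column z-score profiles (gemcitabine/cytarabine x K/L)
# by BIC-selected Gaussian mixtures, recursing into each cluster, and
# writes leaf memberships plus a display ordering per leaf.

library(phenodgi)
library(data.table)

out_dir <- "results/04_remc"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

prof <- read_tsv_table("results/03_interaction/profiles.tsv")
tree <- remc(prof, k_candidates = 1:8, n_init = 3, seed = 20260923L,
             min_size = 8, max_depth = 4)
mem <- remc_membership(tree)
write_tsv_table(mem, file.path(out_dir, "clusters.tsv"))

ordering <- mem[, .(gene = order_for_display(
  list(members = gene), prof)), by = cluster_name]
write_tsv_table(ordering, file.path(out_dir, "display_order.tsv"))

message(sprintf("%d strains in %d leaf clusters (max depth %d)",
                nrow(mem), uniqueN(mem$cluster_name), max(mem$depth)))
print(mem[, .N, by = cluster_name][order(-N)])
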