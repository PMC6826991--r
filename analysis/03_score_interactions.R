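#!/usr/bin/env Rscript
# Stage 3 — drug-gene interaction scoring.
#
# Shift-corrected dose regression per culture and CPP, z-scores against the
# replicate reference cultures (knockdowns against their own stratum), and
# enhancer/suppressor calls at |z| >= 2. Reports recovery of the planted
# truth and writes the interaction table plus the REMc profile matrix.

library(phenodgi)
library(data.table)

out_dir <- "results/03_interaction"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cpp <- read_tsv_table("results/02_fit/cpp.tsv")
truth <- read_tsv_table("results/01_simulate/ground_truth.tsv")

res <- rbindlist(lapply(c("gemcitabine", "cytarabine"), function(d)
  score_interactions(cpp, d)))
write_tsv_table(res, file.path(out_dir, "interactions.tsv"))

prof <- profile_matrix(split(res, res$drug))
write_tsv_table(prof, file.path(out_dir, "profiles.tsv"))

# recovery vs planted truth (mutants only, per drug)
cls <- unique(res[strain_class != "reference",
                  .(strain, drug, called = class)])
cmp <- merge(unique(truth[cpp == "L", .(strain, drug, true_class)]),
             cls, by = c("strain", "drug"))
for (d in unique(cmp$drug)) {
  cm <- cmp[drug == d]
  message(sprintf(
    "%s: %d/%d planted enhancers, %d/%d suppressors recovered; %d/%d nulls quiet",
    d,
    cm[true_class == "enhancer" & called == "enhancer", .N],
    cm[true_class == "enhancer", .N],
    cm[true_class == "suppressor" & called == "suppressor", .N],
    cm[true_class == "suppressor", .N],
    cm[true_class == "none" & called == "none", .N],
    cm[true_class == "none", .N]))
}
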