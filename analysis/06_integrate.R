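#!/usr/bin/env Rscript
# Stage 6 — pharmacogenomic integration.
#
# Builds a synthetic yeast-human homology map and cell-line panel in which
# half of the classified yeast genes' homologs carry a concordant planted
# expression-sensitivity effect, then calls UES/OES hits per tissue
# stratum and summarizes conservation.

library(phenodgi)
library(data.table)

out_dir <- "results/06_integration"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

res <- read_tsv_table("results/03_interaction/interactions.tsv")
yeast_cls <- unique(res[strain_class %in% c("knockout", "knockdown"),
                        .(strain, drug, class)])
genes <- unique(yeast_cls$strain)

hom <- generate_homology_map(genes, seed = 20260923L)
write_tsv_table(hom, file.path(out_dir, "homology.tsv"))

all_hits <- list()
for (d in c("gemcitabine", "cytarabine")) {
  cls_d <- yeast_cls[drug == d & class %in% c("enhancer", "suppressor")]
  ph <- merge(cls_d, hom[, .(strain = yeast, human)], by = "strain")
  set.seed(20260923L + match(d, c("gemcitabine", "cytarabine")))
  ph <- ph[runif(.N) < 0.5]  # 50% planted conservation
  planted <- if (nrow(ph)) data.frame(
    gene = ph$human,
    direction = ifelse(ph$class == "enhancer", "UES", "OES"),
    effect_size = 0.6) else NULL
  pd <- generate_pharmaco_dataset(
    200, unique(hom$human), tissues = c("HaL", "lung", "other"),
    planted = planted, drug = d,
    seed = 20260923L + 10L + match(d, c("gemcitabine", "cytarabine")))
  assoc <- rbindlist(lapply(c("all", "HaL", "lung"), function(st)
    associate_expression(pd$expression, pd$sensitivity, pd$tissues,
                         stratum = st, drug = d)))
  all_hits[[d]] <- call_hits(yeast_cls[drug == d], hom, assoc, alpha = 0.05)
}
hits <- rbindlist(all_hits)
write_tsv_table(hits, file.path(out_dir, "hits.tsv"))

cons <- summarize_conservation(hits, yeast_cls)
write_tsv_table(cons, file.path(out_dir, "conservation.tsv"))
message(sprintf("%d UES/OES hits across drugs and strata", nrow(hits)))
print(cons)
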