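#!/usr/bin/env Rscript
# Stage 2 — growth-curve fitting.
#
# Fits the logistic model to every culture's intensity series and writes
# the cell proliferation parameter (CPP) table: carrying capacity K,
# maximum specific growth rate r, time to half carrying capacity L.

library(phenodgi)
library(data.table)

out_dir <- "results/02_fit"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

ts <- read_tsv_table("results/01_simulate/timeseries.tsv")
cpp <- fit_cpp_table(ts)
write_tsv_table(cpp, file.path(out_dir, "cpp.tsv"))

message(sprintf("fitted %d cultures: %d converged, %d no-growth",
                nrow(cpp), sum(cpp$converged), sum(cpp$no_growth)))
grown <- cpp[no_growth == FALSE]
message(sprintf("reference K at dose 0: %.1f +/- %.1f (n = %d)",
                grown[strain_class == "reference" & dose == 0, mean(K)],
                grown[strain_class == "reference" & dose == 0, sd(K)],
                grown[strain_class == "reference" & dose == 0, .N]))
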