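# phenodgi — yeast phenomic drug–gene interaction analysis

`phenodgi` implements the quantitative analysis behind yeast phenomic
screens of drug cytotoxicity: a genome-wide knockout/knockdown (YKO/KD)
collection is grown on agar arrays across a drug dose series, each culture
is imaged into a growth curve, and every gene is scored for whether its
loss **enhances** or **suppresses** the drug's effect. The package targets
dCK-activated nucleoside analogs (gemcitabine, cytarabine) and carries the
analysis through to cancer pharmacogenomics: yeast enhancers point at human
homologs whose *under*-expression tracks drug sensitivity in cell lines
(UES), suppressors at homologs whose *over*-expression does (OES).

The pipeline, each stage a set of plain functions over `data.table`s:

1. **Growth curves** — each culture's intensity series is fit to the
   logistic model `G(t) = K / (1 + exp(-r (t - l)))`, giving the cell
   proliferation parameters (CPPs): carrying capacity `K`, maximum
   specific growth rate `r`, and `L`, the time to half carrying capacity.
2. **Interaction scores** — with `Y_i` the mutant CPP and `R_i` the mean
   over the replicate reference cultures at dose `D_i`: `K_i = Y_i − R_i`,
   the drug-free difference (`shift`) `K_0` is subtracted
   (`L_i = K_i − K_0`), a least-squares line `L_i = A + B·D_i` is fit, and
   `INT = A + B·D_max` is standardized into a z-score against the
   reference-culture INT distribution (knockdown strains against their own
   stratum). Enhancers: `z_L ≥ 2` or `z_K ≤ −2`; suppressors: `z_L ≤ −2`
   or `z_K ≥ 2`.
3. **REMc** — recursive EM clustering of the z-score profiles
   (BIC-selected diagonal Gaussian mixtures, recursing into each cluster),
   with lineage-encoded cluster names.
4. **Enrichment / GTA** — hypergeometric GO-term enrichment of clusters
   against the tested background, and GO-term averaging
   (`GTA value` = mean z of a term's genes, `GTA score = |value| − SD`,
   filters at 2).
5. **Integration** — per-gene expression↔sensitivity association in cell
   lines (standardized regression coefficient, two-sided t test) joined to
   yeast classes via a yeast–human homology map to call UES/OES hits per
   tissue stratum.

A first-class synthetic-data generator (`generate_plate_experiment()` and
friends) emulates the screen — 384-culture arrays, 768 replicate reference
cultures, gemcitabine doses 0–30 and cytarabine 0–100 µg/mL, planted
shifts, interaction slopes and no-growth strains — with ground truth
returned for recovery testing. See `vignettes/phenodgi-methods.Rmd` for
the model, the value rules (no-growth, `Y_i max`), parameter defaults and
design rationale.

## Worked example

Score a small synthetic screen end to end:

```r
library(phenodgi)

planted <- list(slopes = data.frame(strain = "yko_0001",
                                    drug = "gemcitabine",
                                    cpp = "L", value = 0.2))
cfg <- simulation_config(seed = 7, n_mutant_strains = 5,
                         n_reference_cultures = 8, noise_sd = 0,
                         planted_effects = planted)
sim <- generate_plate_experiment(cfg)
cpp <- fit_cpp_table(sim$timeseries)
res <- score_interactions(cpp, "gemcitabine")
res[strain == "yko_0001" & cpp == "L", .(shift, A, B, INT)]
#>    shift     A     B   INT
#>    <num> <num> <num> <num>
#> 1:     0     0   0.2     6
```

The planted strain's L parameter was displaced by 0.2 h per µg/mL; over
the gemcitabine series (0, 5, 10, 20, 30 µg/mL) the recovered regression
is exactly `A = 0`, `B = 0.2`, so `INT = 0.2 × 30 = 6` hours of
drug-specific growth delay at the top dose — the planted effect, recovered
from raw time series through curve fitting, shift correction and dose
regression.

GO-term averaging over published per-gene scores (ESCRT-0 complex, genes
VPS27 and HSE1, gemcitabine K z-scores −8.1 and −3.3):

```r
pub <- read_tsv_table(system.file("extdata",
  "published_interaction_zscores.tsv", package = "phenodgi"))
gta(c("VPS27", "HSE1"), setNames(pub$gem_K, pub$gene), term = "ESCRT-0")
#>       term gta_value   gta_sd gta_score n_genes n_missing passes_filter
#>     <char>     <num>    <num>     <num>   <int>     <int>        <lgcl>
#> 1: ESCRT-0      -5.7 3.394113  2.305887       2         0          TRUE
```

A GTA value of −5.7 (capacity lost under drug when these genes are
deleted) with GTA score 2.3 > 2: the complex passes both filters as a
gemcitabine-buffering module.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/06_integrate.R` run a complete
desk-scale study (120 knockouts, 12 knockdowns, 96 reference cultures,
both drugs, planted enhancers/suppressors, 50% planted homolog
conservation), writing each stage's tables under `results/`. From a run of
stage 3:

```
gemcitabine: 12/12 planted enhancers, 6/6 suppressors recovered; 106/114 nulls quiet
```

and stage 5 ranks the planted GO term first by GTA
(`T_planted_enhancers`, gemcitabine-L GTA value 42.1, GTA score 41.2).
`run_pipeline(pipeline_config(...), out_dir)` performs the same chain in
one call and writes a manifest of MD5-hashed outputs; identical config and
seed reproduce identical hashes.

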