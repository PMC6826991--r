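---
title: "Scoring drug–gene interaction from yeast phenomic screens: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring drug-gene interaction from yeast phenomic screens: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenodgi)
library(data.table)
```

## The problem

Quantitative high-throughput cell array phenotyping (Q-HTCP) images
hundreds of agar-arrayed yeast cultures over time, turning each culture
into a growth curve. Screening a genome-wide knockout/knockdown (YKO/KD)
collection across a drug dose series then asks, for every gene: does
deleting it change the dose response relative to the parental reference
strain? Genes whose loss *increases* cytotoxicity are deletion
**enhancers** (they normally buffer the drug); genes whose loss
*decreases* cytotoxicity are deletion **suppressors** (they normally
promote drug effect). This package implements that analysis for
dCK-activated nucleoside analogs (gemcitabine, cytarabine), through to the
projection of yeast calls onto cancer cell-line pharmacogenomics via
yeast–human homology.

## Growth model and CPPs

Each culture's intensity series is fit by least squares to the logistic
model

$$G(t) = \frac{K}{1 + e^{-r(t - l)}},$$

giving the cell proliferation parameters (CPPs): carrying capacity $K$
(intensity units), maximum specific growth rate $r$ (h$^{-1}$), and $L$,
the time (h) at which half of $K$ is reached ($G(L) = K/2$ by the
functional form). $K$ and $L$ are the phenotypes used for interaction
scoring; $r$ is fitted and reported but not used for classification, as it
is the least identifiable of the three on noisy plate data.

Numerical choices:

* **Initialization.** $K_0$ = series maximum; $r_0$ and $l_0$ from a
  linear regression of $\log(p/(1-p))$ on time, $p = y/K_0$ clamped to
  $[0.02, 0.98]$ — exact for noise-free logistic data, which is why
  noiseless parameter recovery is essentially at machine precision.
  Fitting is Levenberg–Marquardt (`minpack.lm`) inside the box
  $K \in (0, 2\max y]$, $r \in (0, 10]$, $l \in [-24, 2 t_{max}]$, with up
  to 5 deterministic jittered restarts on failure.
* **No-growth rule.** A culture is no-growth when its maximum intensity
  stays strictly below a floor (5% of the plate-median final intensity
  when fitting whole plates) or its max/initial fold change stays strictly
  below 1.5. The strict inequalities make the printed threshold itself
  actionable ("exactly at threshold" = growth). No-growth cultures carry
  $K = r = 0$ and an unobserved $L$.
* **Background.** The three-parameter logistic has no additive offset, so
  subtracting an agar background before fitting is supported
  (`background = "min2"`) but **off by default**: the synthetic generator
  emits pure logistic signal, for which any subtraction (which necessarily
  removes part of $G(0) > 0$) would bias $K$. For real plate images with a
  nonzero agar baseline, enable it.

## Interaction scoring

With $D_i$ the dose series (starting at $D_0 = 0$), $Y_i$ the mutant CPP
and $R_i$ the mean CPP of the replicate reference cultures at $D_i$:

1. $K_i = Y_i - R_i$;
2. the **shift** $K_0 = Y_0 - R_0$ — the drug-independent effect of the
   gene deletion — is subtracted from the whole series:
   $L_i = K_i - K_0$ (so $L_0 = 0$ by construction);
3. ordinary least squares $L_i = A + B D_i$ over all doses including
   $D_0$;
4. the interaction value $\mathrm{INT} = A + B \, D_{max}$;
5. z-scores: knockouts are standardized by the mean and SD of INT over
   the replicate reference cultures; knockdown (DAmP) strains by the
   knockdown stratum's own mean and SD, since their CPP distribution
   differs from the reference strain.

Value rules applied before scoring: no-growth cultures take $Y_i = 0$ for
$K$ and $r$; for $L$ — whose value diverges as growth vanishes — a
culture that grew without drug but not at $D_i$, or whose observed $L$
exceeds it, takes $Y_i^{max}$, the largest observed value among cultures
whose carrying capacity lies within 2 reference SDs below the reference
mean at that dose. A strain that fails to grow *without* drug has no
defined interaction; its profile carries the conventional sentinel score
0.0001 into clustering, flagged so heatmaps can mark it.

Classification at threshold $z = 2$ (inclusive): enhancer if
$z_L \ge 2$ or $z_K \le -2$; suppressor if $z_L \le -2$ or $z_K \ge 2$;
if both rule sets fire the call is `"conflict"`, a case the scoring rules
leave open and which we flag for review rather than resolve silently.

Design points worth stating: the regression keeps the $(0, 0)$ anchor
point and an estimated (not forced-zero) intercept, since INT is
explicitly evaluated as $A + B D_{max}$; all SDs are sample SDs ($n-1$);
and in a perfectly noise-free stratum (reference SD exactly 0) values at
the stratum mean standardize to 0 while any other value has no defined
z — this keeps the zero-noise identity simulation exact instead of
erroring.

## REMc

Interaction profiles (columns: z for each drug × CPP in {K, L}; shift
columns are carried for display but never clustered) are clustered by a
Gaussian mixture with **diagonal covariances**, fitted by EM with
restarts, with the number of components chosen by BIC over $k = 1..10$;
clustering then recurses into each cluster until the selected model has
one component, fewer than `min_size = 8` members remain, or depth 4 is
reached. Names encode the lineage (root `"1"`, children `"1-0"`,
`"1-0-2"`, ...); the original tool's id semantics are not documented
precisely enough to claim identity, so ours are defined here and kept
deterministic. BIC replaces the cross-validated likelihood of the original
Weka module as a deterministic, widely understood criterion. The EM is
implemented in the package (rather than delegated) so every run exposes
its per-iteration log-likelihood trace; the test suite verifies monotone
traces on every run and cross-checks component recovery against mclust as
an independent implementation. Within-cluster display order is
average-linkage hierarchical clustering on Euclidean distance, with
members pre-sorted by name so identical profiles have a deterministic
order.

## Enrichment and GTA

Cluster function is summarized two ways:

* **Hypergeometric enrichment** of each GO term in a cluster against the
  background of *all genes tested in the experiment* (not the genome —
  the screened set defines the sampling frame). $p = P(X \ge k)$ for $k$
  term genes in a cluster of $n$ from $M$ term genes among $N$ tested.
  Bonferroni-adjusted values are reported alongside raw ones, since the
  original tool's internal correction is version-dependent.
* **GO-term averaging (GTA)**: per term, the mean interaction z-score of
  its genes (GTA value), their sample SD, and the GTA score
  $|\text{GTA value}| - \text{SD}$; a term passes when
  $|\text{GTA value}| > 2$ *and* GTA score $> 2$ (both strict). K and L
  scores are averaged and reported separately. With two-gene terms whose
  inputs are printed at one decimal, a recomputed mean can sit exactly
  between printed roundings; the worked ESCRT-0 example in the tests uses
  the three means that are exactly recomputable and skips the one that is
  rounding-ambiguous.

GO-graph propagation (annotating genes to ancestor terms) is not applied:
annotations are taken as given, which matches flat curated files; callers
wanting propagated annotations can expand the table before passing it in.

## Pharmacogenomic integration

For each human gene, drug sensitivity (a continuous AAC-like value) is
regressed on expression, both standardized within the tissue stratum, so
the standardized coefficient equals the Pearson correlation; two-sided
p-values come from the t distribution. A yeast deletion **enhancer**
matched by homology to a human gene with *negative* coefficient at
$p < 0.05$ is a **UES** call (underexpression sensitivity); a
**suppressor** matched to a *positive* coefficient is **OES**. Strata are
label filters (all tissues, hematopoietic and lymphoid, lung). Raw
p-values are used at $\alpha = 0.05$, matching the original analysis; no
multiplicity correction is applied by default. A single association model
serves both "differential expression" and "drug sensitivity" — the two
phrases describe one regression here, a reading we fixed deliberately
since the alternative (two separate tests) is underdetermined.

## The synthetic generator

The generator emulates the screen's stated conditions: 384-culture arrays,
768 replicate reference cultures, gemcitabine doses 0/5/10/20/30 and
cytarabine doses 0/10/25/50/100 µg/mL, imaging every 2.5 h over 0–48 h
(the protocol's "every 2–3 hours"). Reference logistic parameters default
to $K = 200$, $r = 0.3$, $l = 10$; per-drug dose responses slow growth
(L rises, K falls with dose), more steeply per µg/mL for gemcitabine,
mirroring the stronger growth inhibition reported for that drug. Planted
effects enter exactly where the scoring model looks for them: shifts
displace a CPP at every dose; interaction slopes displace it linearly in
dose, so a planted L slope $b$ yields a known $\mathrm{INT} = b D_{max}$.
Noise is additive i.i.d. Gaussian on intensity (SD 5 ≈ 2.5% of reference
$K$) — the imaging noise level is not published, so this default is a
realistic placeholder chosen once, not a calibrated value. No-growth
strains emit noise around zero. Negative intensities are clamped at zero,
a negligible distortion at the default noise level.

What the generator does **not** emulate — and hence what passing tests do
not demonstrate about real data: spatial plate effects and edge artifacts,
non-Gaussian or heteroscedastic imaging noise, dose-dependent noise,
pipetting failures other than total no-growth, and any real biology in the
GO/homology/cell-line fixtures (annotation tables, homology classes and
expression effects are sampled, not curated). Recovery rates measured here
are upper bounds for real screens.

## Problem sizes and determinism

Everything is a pure function of (config, seed): generators restore the
caller's RNG state, EM restarts and REMc node seeds are derived
deterministically, and a pipeline re-run reproduces byte-identical output
hashes. The validation suite exercises the pipeline at desk scale — 1000
null mutants against 768 reference cultures for calibration, 500 curves
for parameter recovery, 100 replicate screens for planted-enhancer
recovery, 100 seeds for cluster recovery — sizes chosen so the full suite
runs in minutes on one CPU while keeping Monte Carlo error well inside
each acceptance band. One statistical caveat is documented rather than
hidden: with 1000 mutants and 768 references the mean of the null z
distribution has sampling SD ≈ 0.048 *per CPP*, so a ±0.1 band on a
single CPP is only a ~2σ statement; the calibration check therefore
evaluates the pooled K and L z distribution.

## Known limitations

* The logistic model has no lag or diauxie terms; strongly non-logistic
  curves fit poorly and surface as high RSS, not as a model switch.
* `Y_i^max` depends on the reference SD of K at each dose; with very few
  reference cultures the 2-SD qualification window is itself noisy.
* Diagonal-covariance mixtures cannot represent correlated cluster
  shapes; full covariance would need many more members per component at
  4 dimensions.
* The conflict class (enhancer and suppressor rules both firing) is
  reported, not resolved; at small reference counts a few percent of true
  enhancers land there through a drifting K z-score.
* Homology-based transfer treats every homolog pair independently;
  many-to-many families therefore multiply hits rather than aggregate
  evidence.
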