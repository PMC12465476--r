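---
title: "Methods: kidney-specific cfDNA methylation markers, from atlas screen to diagnostic model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: kidney-specific cfDNA methylation markers, from atlas screen to diagnostic model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(renomark)
```

## The problem

Cell-free DNA (cfDNA) in plasma is released by dying cells throughout the
body. Its nucleotide sequence is (host) genome-wide identical across
tissues, but its DNA methylation pattern is not: each cell type leaves a
characteristic methylation fingerprint. A genomic block that is methylated
only in kidney cells therefore acts as a kidney-injury dosimeter — every
methylated copy of that block found in plasma came from a dying kidney
cell. `renomark` implements the full computational chain needed to build
and evaluate such an assay for kidney-allograft monitoring:

1. **Marker discovery** (`screen_markers`, `select_panel`): scan a
   multi-tissue methylation atlas for blocks methylated specifically in
   kidney compartments and unmethylated in blood, and assemble a 10-target
   digital PCR panel (9 markers + the albumin internal control).
2. **Quantification** (`poisson_concentration`, `quantify_reactions`):
   turn positive-partition counts from multiplex digital PCR into copy
   numbers and albumin-normalised levels, with control validation,
   reproducibility summaries and a limit-of-detection model for bisulfite
   conversion loss.
3. **Diagnostics** (`fit_logistic`, `build_signature`, `compare_models`):
   model biopsy outcomes (rejection, any Banff lesion) from an epigenetic
   signature, eGFR and DSA, and compare predictor combinations by ROC/AUC.

Because the real atlas (tens of millions of blocks across 21 purified cell
types in triplicate), real plates and the real patient cohort are not
shipped with the package, seeded generators (`gen_atlas`,
`gen_dpcr_plate`, `gen_cohort`) emulate their statistical structure and
emit machine-readable truth tables, so every stage can be tested by
recovery of planted truth.

## Marker screen

The atlas is a blocks × samples matrix of beta values (methylation
fractions in [0, 1]; 0 is data — fully unmethylated — never missing).
Blocks use 0-based half-open coordinates (BED convention). Before
screening, `filter_blocks_by_replication()` keeps only blocks observed in
at least `min_replicates` (default 2) replicates of **every** group,
mirroring a screen that operates on blocks available in ≥ 2 replicates of
all 21 anatomical regions.

Scoring works on per-group mean betas. For a target compartment
(pan-renal = all five kidney subcompartments; renal endothelial; renal
epithelial including podocytes) a block's score is:

* `target_min_beta` — the *minimum* over target groups of the group mean:
  the worst-case methylation in the compartment the assay must detect;
* `background_max_beta` — the *maximum* over non-blood background groups:
  the worst-case off-target methylation;
* `blood_max_beta` — the maximum over blood groups, held to its own,
  stricter cap because leukocyte DNA dominates plasma cfDNA;
* `margin = target_min_beta − background_max_beta` — the worst-case
  separation a single-locus assay gets to work with.

A block passes when `target_min_beta ≥ tau_target` (default 0.5),
`background_max_beta ≤ tau_background` (0.15), `blood_max_beta ≤
tau_blood` (0.05) and `margin ≥ min_margin` (0.3). The thresholds are
deliberate design choices, exposed in `screen_config()`: the dPCR probes
count *methylated* copies, so a usable marker must be strongly methylated
in its compartment and near-zero in blood; only hypermethylated-in-target
markers are panel-eligible (a `direction` field reports the sign for
completeness). Specificity is enforced against each background group's own
mean (per-group max), not against a pooled background mean — the stricter
reading, since one highly methylated off-target tissue is enough to
confound a single-locus assay. Replicates enter only through the group
mean and the replication filter; read counts are not pooled.

Passing blocks are ranked by margin (descending, ties broken by block id
for determinism) and `select_panel()` takes the top 1/6/2 per compartment
(pan-renal/endothelial/epithelial), de-duplicating a block that passes two
screens into the compartment where its margin is larger (tie → pan-renal),
then appends the albumin control.

## Digital PCR model

With `N` partitions and `k` positives, molecules distribute approximately
Poisson, so the mean copies per partition is `λ = −ln(1 − k/N)` and copies
per reaction is `λN`. A saturated reaction (`k = N`) is a hard error, not
`+∞`: the sample must be diluted and re-run, and silently propagating an
infinite concentration would poison downstream ratios. The 95% CI is a
Wilson score interval on `k/N` transformed through `−ln(1 − ·)`; Wilson
was chosen because it stays sensible at `k = 0` (lower bound exactly 0,
finite upper bound), where a Wald interval collapses. Marker levels are
reported as `100 × marker copies / albumin copies` — the albumin assay
counts total genomes regardless of methylation, so the ratio is the
percentage of genomes in the tube that carry the (methylated) marker.
Ratios above 100% are flagged but never clipped.

Control wells are validated by operationalising the "methylation rate" of
a methylated control as its albumin ratio, accepted in the 58–98% band;
unmethylated controls tolerate 0 positive partitions per marker by
default. Channel/coupling layout is metadata only: inputs are already
per-assay positive counts, and amplitude declustering is out of scope.

Bisulfite conversion destroys a fraction `ℓ` of input DNA (validated
range 0.67–0.80 here). Under independent binomial thinning with retention
`r = 1 − ℓ` and per-copy detection probability `q`, `P(detect) = 1 −
(1 − rq)^n0` for `n0` input copies, and the expected surviving copies are
`n0·r·q`. The limit of detection inverts this analytically
(`estimate_lod`), with an optional Monte-Carlo dilution series as a
cross-check. Two anchor arithmetic facts the package reproduces: 0.03 ng
of human gDNA is `0.03 × 1000 / 3.3 ≈ 9.09` haploid genome equivalents
(the 3.3 pg haploid genome weight is the `copies_from_mass` default), and
10 input copies at 67% loss leave 3.3 expected copies — inside a 1–4 copy
detection-limit band.

## Diagnostic models

Logistic regressions are maximum-likelihood binomial GLM fits (IRLS,
tolerance 1e-8, ≤ 100 iterations). Marker levels are right-skewed and
contain zeros, so they enter as `log10(x + δ)` with `δ` = half the
smallest nonzero level of that marker (overridable). eGFR enters per
1 mL/min/1.73m²; the OR per 10 units is reported alongside for
readability. Tube type (EDTA/PAXgene) is carried as a covariate but not in
default models. Complete separation (|coefficient| > 15 on the transformed
scale) flags the fit unreliable and suppresses its CI.

The **epigenetic signature** is the linear predictor of one joint logistic
fit of the markers univariately associated with the outcome at
`alpha = 0.05`. Univariate p-values are raw — **no multiple-testing
correction is applied**, deliberately, to mirror a development-cohort
presentation; the signature should be read as an in-sample construction.

ROC curves sweep thresholds over the unique scores; the AUC is computed by
Mann–Whitney pair counting (ties ½, via midranks) and checked to equal the
trapezoidal curve area to 1e-12. `compare_models()` reports apparent
(in-sample) AUCs for combined (eGFR + DSA + signature), clinical
(eGFR + DSA) and signature-only models — plus markers-only and DSA-only
for the any-lesion outcome. Apparent AUCs are the default because that is
how a development cohort is presented; stratified k-fold cross-validation
is available (`cv_folds`) but off by default. Note one subtlety the test
suite documents: in-sample ML maximises likelihood, not AUC, so a nested
larger model's apparent AUC can trail its submodel's by a hair (observed
~0.002); dominance of the combined model is therefore asserted
stochastically across seeds, not as an identity.

## Synthetic data: what it emulates, and what it does not

`gen_atlas()` builds 21 groups × 3 replicates: five kidney subcompartments
(tubular/glomerular epithelium, podocytes, peritubular/glomerular
endothelium), five blood cell groups and eleven other organs, with group
roles declared in `default_group_roster()` (never inferred from names).
Planted markers draw target-group betas from Beta(50, 2) (mean ≈ 0.96),
non-blood background from Beta(2, 50) (mean ≈ 0.04) and blood from
Beta(1, 99) (mean 0.01): the planted truth is a *blood-negative* marker,
because that is the object the screen is designed to find — a planted
"marker" that failed blood negativity would be a mislabelled truth table,
not a harder test. Null blocks share one Beta-distributed mean across all
samples (concentration 30), so they carry realistic between-replicate
noise but no compartment signal. Missingness (default 5%) is applied to
null blocks; planted blocks are emitted fully observed so that the truth
table always lists discoverable markers — recovery tests then measure the
screen, not the missingness lottery. Consequently planted-marker recovery
is evaluated on the post-filter atlas, matching a screen restricted to
sufficiently replicated blocks.

`gen_dpcr_plate()` draws positives as `Binomial(N, 1 − exp(−copies/N))` —
exactly the partition model the quantifier inverts — so round-trip
recovery isolates estimator bias. `gen_cohort()` enforces the cohort
bookkeeping *exactly* rather than sampling it: 170 records, 44 rejections
(24 ABMR / 13 TCMR / 7 mixed), 34 rejections among 89 indication and 10
among 76 surveillance biopsies, with 5 records left context-unlabeled
(the declared context counts cover 165 of 170 records; the generator
reproduces that bookkeeping as stated rather than reconciling it). Planted
effects are invented but directionally faithful and front-and-centre in
`cohort_gen_spec()`: endothelial markers ×3 in ABMR/mixed, the pan-renal
marker ×2 in any rejection, all markers ×1.5 in non-rejection lesions
(25% of non-rejection biopsies), eGFR −12 under rejection, DSA prevalence
60% in ABMR/mixed vs 15% otherwise, baseline marker levels log-normal
(meanlog log 0.5, sdlog 0.8, in percent of albumin). Optional counting
noise pushes each level through a simulated reaction so measurement
variance can be separated from biological variance.
`gen_logistic_cohort()` is the companion generator for
coefficient-recovery tests: it draws predictors first and the outcome from
a logistic model, so the planted coefficients are exactly the estimand.

What the generators do **not** emulate: real marginal beta distributions
or inter-block correlation of the atlas, inter-marker correlation in
patients, assay cross-talk, pre-analytical tube effects, or population
structure of eGFR/DSA. Passing recovery tests therefore demonstrates the
*algorithms* are correct under their stated models — not that the assay's
clinical performance generalises.

## Numerical choices and problem sizes

Determinism: every generator is a pure function of its spec and seed;
screens break margin ties by block id; the pipeline logs config digests
and seeds so any run is reproducible. Degenerate inputs are hard errors
with named offenders (saturated reactions, constant predictors, unmatched
sample columns, infeasible cohort splits). Betas are serialised at 6
decimals, making write→read→write byte-idempotent.

Test and acceptance runs use desk-scale problem sizes chosen to leave
Monte-Carlo error well below the asserted tolerances: 2,000-null-block
atlases over 20 seeds for recovery (the real 15.7-million-block scale is
supported but not exercised in tests), 100 simulated plates and 1,000
reactions for bias/CI coverage, 10,000 trials per point for the LoD grid,
and 100 seeds of 170-patient cohorts for coefficient-recovery and
AUC-dominance rates. Reproducibility of albumin ratios is summarised on
triplicate simulated plates at 20,000 partitions with a 30,000-copy
albumin input and marker ratios of 0.1–1% — a gDNA-scale input at
blood-background-like methylation levels, where counting noise is the
only variance source; the resulting mean SD is ≈ 0.02–0.04 percentage
points, consistent with a sub-0.05% reproducibility claim.

## Worked example

```{r example, eval = FALSE}
library(renomark)

# discover markers on a synthetic atlas and assemble the panel
sim <- gen_atlas(atlas_gen_spec(seed = 7))
atlas <- filter_blocks_by_replication(sim$atlas, min_replicates = 2)
screens <- lapply(default_target_specs(),
                  function(sp) screen_markers(atlas, sp))
panel <- select_panel(screens)

# simulate and diagnose a cohort
cohort <- gen_cohort(cohort_gen_spec(seed = 7))$records
compare_models(cohort, "rejection")
```

Or end to end from the command line (see `inst/cli/renomark.R`):

```sh
Rscript inst/cli/renomark.R all --seed 1 --out renomark_out
```

## Known limitations

* The screen treats blocks as given; it neither calls methylation from
  reads nor defines block boundaries.
* Reference-based deconvolution of multi-organ injury signals is not
  implemented; markers with known secondary tissue signals (e.g. a lung or
  liver component) are reported as-is.
* The signature and all default AUCs are in-sample; external validation
  machinery beyond optional k-fold CV is out of scope.
* Banff lesion sub-scores, survival endpoints and longitudinal modeling
  are not covered — outcomes are the two binary labels.
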