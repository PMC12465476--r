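# renomark

Non-invasive detection of kidney-allograft injury from plasma cell-free
DNA (cfDNA) methylation. `renomark` implements the three computational
layers such an assay needs, as a tested R package:

1. **Marker discovery.** Every cell type leaves a characteristic DNA
   methylation fingerprint. Given a block-level methylation atlas (beta
   values for purified tissues/cell types in replicate), the screen finds
   blocks methylated specifically in kidney compartments — pan-renal,
   renal endothelial, renal epithelial — and unmethylated everywhere
   else, most strictly in blood cells (the dominant background of plasma
   cfDNA). A block passes when

   `min_target(mean β) ≥ τ_t`, `max_background(mean β) ≤ τ_b`,
   `max_blood(mean β) ≤ τ_bl`, and
   `margin = min_target − max_background ≥ m`,

   with defaults τ_t = 0.5, τ_b = 0.15, τ_bl = 0.05, m = 0.3. Passing
   blocks, ranked by margin, populate a 10-target digital PCR panel:
   9 kidney markers (1 pan-renal + 6 endothelial + 2 epithelial) plus the
   albumin (ALB) internal control.

2. **Digital PCR quantification.** With `k` of `N` partitions positive,
   copies per partition are `λ = −ln(1 − k/N)`, copies per reaction `λN`,
   with a Wilson-score CI transformed through `−ln(1 − ·)`. Marker levels
   are reported as `100 × marker / albumin` copies — the percentage of
   genomes in the sample carrying the methylated marker. Includes control
   validation (methylated controls accepted at 58–98%), replicate-SD
   reproducibility, and a limit-of-detection model for bisulfite
   conversion loss: `P(detect) = 1 − (1 − rq)^n0` with retention
   `r = 1 − loss`.

3. **Diagnostic modeling.** Univariate and multivariate logistic
   regression (odds ratios, Wald CIs/p-values) of biopsy outcomes
   (rejection, any Banff lesion) on eGFR, DSA and marker levels
   (log10-transformed); an *epigenetic signature* built from the markers
   univariately associated with the outcome; ROC/AUC comparison of
   combined vs clinical vs signature-only models.

Seeded generators (`gen_atlas`, `gen_dpcr_plate`, `gen_cohort`) emulate
the atlas, plates and a 170-patient transplant cohort (44 rejections:
24 ABMR / 13 TCMR / 7 mixed) with truth tables, so every layer is tested
by planted-truth recovery.

## Worked example

```r
library(renomark)

# 1. discover markers on a synthetic atlas and assemble the panel
sim    <- gen_atlas(atlas_gen_spec(seed = 7))
atlas  <- filter_blocks_by_replication(sim$atlas, min_replicates = 2)
screens <- lapply(default_target_specs(),
                  function(sp) screen_markers(atlas, sp))
select_panel(screens)
#>      assay_name  block_id             role channel_id
#> 1         CTDP1 blk000218        pan_renal          1
#> 2        ARID3A blk001491      endothelial          2
#> ...
#> 10          ALB      <NA> internal_control         10

# 2. quantify a digital PCR reaction: 1904 positives of 20000 partitions
poisson_concentration(k = 1904, N = 20000, v_nl = 0.91)
#>      k     N p_hat lambda copies_per_reaction copies_per_ul  ci_low ci_high
#> 1 1904 20000 0.095    0.1             2000.83        109.94 1912.82 2092.67

# 3. diagnose a synthetic cohort
cohort <- gen_cohort(cohort_gen_spec(seed = 7))$records
compare_models(cohort, "rejection")
#> Apparent AUC, outcome 'rejection':
#>      model   auc
#>   combined 0.877
#>   clinical 0.806
#>  signature 0.841
```

The panel recovers exactly the planted marker blocks (compare against
`sim$truth`); ~2000 copies from a 9.5% positive fraction is the Poisson
correction at work (2000.8, not 1904); and the combined
eGFR + DSA + signature model outperforms both the clinical model and the
signature alone — the structural finding the synthetic cohort's planted
effects are designed to reproduce.

A command-line wrapper covers the same stages
(`simulate-atlas | screen | simulate-plate | quantify | simulate-cohort |
diagnose | all`):

```sh
Rscript inst/cli/renomark.R all --seed 1 --out renomark_out
```

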