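# petspio

Multimodal quantification of CNS microglial activation and macrophage
infiltration for combined TSPO-PET and SPIO-MRI mouse studies, validated
end to end on synthetic phantom cohorts with known ground truth.

## The scientific problem

In the relapsing-remitting EAE mouse (a model of multiple sclerosis),
activated microglia and infiltrating macrophages can be tracked in vivo by
two complementary modalities: PET with a TSPO radioligand, and T2\*-weighted
MRI after injection of superparamagnetic iron oxide (SPIO) nanoparticles,
which phagocytic cells take up to produce punctate hypointense lesions. The
per-animal, per-region summary statistics are:

* **SUVR** — standardized uptake value ratio. Voxelwise
  `SUV = C_t / (D / W)` with tissue activity `C_t` (MBq/cm³), injected dose
  `D` (MBq) and body weight `W` (g); frames acquired 20–50 min
  post-injection are summed; each atlas region's mean SUV is divided by the
  (unaffected) neocortex mean.
* **SPIO-Vol** — `100 × (labelled voxels in region) / (region voxels)`,
  where labels come from histogram-mode thresholding
  (`intensity < mode − k·σ`, robust median/MAD estimates, `k = 3`) of the
  bias-corrected, brain-extracted MRI.

Group contrasts use the two-sided Mann-Whitney test (exact by enumeration
for pooled samples ≤ 14 without ties); correlations with the 0–4 clinical
score and between modalities use tie-aware Spearman rank correlation.

The package is aimed at preclinical imaging methodologists: it provides the
full processing chain — fiducial-landmark rigid/affine registration with
volume resampling, SUV/SUVR quantification, bias-field correction, brain
extraction, hypointensity labelling, fluorescence co-localization and
perivascular co-expression quantification, and the nonparametric report —
plus a seedable phantom generator so every stage can be tested against
recorded ground truth without any external data.

## Worked example

One fully seeded in-silico study — 7 EAE vs 5 control animals, dynamic PET
with 0.9 mm PSF and 5% noise, misaligned SPIO-MRI with a 20% coil bias
field — processed from raw phantom volumes to the final report:

```r
library(petspio)
res <- run_pipeline(run_config(seed = 1, out_dir = "run1"))
print(res$results)
#> <results_report> group contrasts (alpha = 0.05 ):
#>        metric          region mean_eae   sd_eae mean_ctr   sd_ctr p_value
#>          SUVR       neocortex    1.000 0.000113    1.000 0.000216 0.53030
#>          SUVR caudate_putamen    1.224 0.071109    1.093 0.067063 0.01768
#>          SUVR     hippocampus    1.509 0.074545    1.371 0.092599 0.00505
#>          SUVR        thalamus    1.520 0.122692    1.179 0.087980 0.00253
#>          SUVR      cerebellum    2.254 0.173510    1.880 0.118461 0.00505
#>          SUVR       brainstem    1.888 0.158127    1.400 0.071196 0.00253
#>  SPIO_Vol_pct       neocortex    0.455 0.425799    0.491 0.514162 0.87626
#>  SPIO_Vol_pct caudate_putamen    7.083 4.814633    0.900 1.509249 0.02275
#>  SPIO_Vol_pct     hippocampus    4.597 2.563035    2.757 1.725850 0.19231
#>  SPIO_Vol_pct        thalamus    9.166 5.209438    2.207 2.136194 0.02204
#>  SPIO_Vol_pct      cerebellum   14.853 6.100106    4.323 1.459613 0.00505
#>  SPIO_Vol_pct       brainstem    8.011 4.028507    0.649 0.389242 0.00253
```

Reading the output: hindbrain regions show the strongest EAE elevation in
both modalities (e.g. cerebellum SUVR 2.25 vs 1.88, p = 0.005; SPIO-Vol
14.9% vs 4.3%, p = 0.005), the reference region shows none by construction,
and the quantified values recover each animal's generated ground truth
within the pipeline's tolerances (SUVR within 10% under PSF and noise,
SPIO-Vol within ±1.5 percentage points). Pooled Spearman correlations for
the same run:

```r
subset(res$results$correlations, region == "cerebellum")
#>    comparison            metric     region   rho  p_value  n
#>         vs_CS              SUVR cerebellum 0.913 3.30e-05 12
#>         vs_CS      SPIO_Vol_pct cerebellum 0.924 1.71e-05 12
#>  SUVR_vs_SPIO SUVR~SPIO_Vol_pct cerebellum 0.993 1.30e-10 12
```

The run directory contains `cohort.csv`, `suvr.csv`, `spiovol.csv`,
`registration.csv`, `group_stats.csv`, `correlations.csv`, a markdown
summary and a manifest with per-file checksums; two runs with the same seed
are byte-identical. A thin command-line wrapper lives at
`inst/cli/petspio-run.R` (`Rscript petspio-run.R --config run.yaml`).

Individual stages are ordinary functions: `generate_atlas()`,
`generate_cohort()`, `estimate_rigid()`, `estimate_affine()`, `resample()`,
`compute_suv()`, `sum_window()`, `compute_suvr()`, `extract_brain()`,
`correct_bias()`, `label_spio()`, `spio_fractional_volume()`,
`coloc_percent()`, `perivascular_coexpression()`, `mann_whitney()`,
`spearman_rank()`, `build_results()`. The methods vignette
(`vignettes/methods.Rmd`) documents the models, parameters and design
decisions.

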