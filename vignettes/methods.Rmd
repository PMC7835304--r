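---
title: "Quantifying neuroinflammation phantoms: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying neuroinflammation phantoms: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(petspio)
```

## The problem this package addresses

Combined TSPO-PET and iron-oxide (SPIO) T2\*-weighted MRI is used to track
microglial activation and macrophage infiltration in the brain of mice with
experimental autoimmune encephalomyelitis (EAE), the standard rodent model
of multiple sclerosis. Two quantities summarise each animal:

* **SUVR** — the standardized uptake value ratio. Activity frames are
  converted to SUV (tissue activity in MBq/cm³ divided by injected dose per
  body weight), the late frames are summed, and each atlas region's mean SUV
  is normalised to the neocortex (or to its unaffected part when cortical
  lesions are present).
* **SPIO-Vol** — the fractional volume (%) of a region occupied by voxels
  labelled as SPIO uptake sites, i.e. punctate hypointensities on the
  bias-corrected T2\* image.

Group contrasts (symptomatic EAE vs control) use the two-sided Mann-Whitney
test; associations with the 0–4 clinical disability score (CS) and between
the two modalities use Spearman rank correlation, pooling both groups.

Real cohorts of this kind are small (here 7 EAE vs 5 controls) and the
underlying images are not publicly deposited, so the package is validated
end to end on *synthetic phantom cohorts with recorded ground truth*: every
processing stage (registration, resampling, bias correction, brain
extraction, thresholding, VOI statistics) is exercised against quantities
known by construction.

## The processing chain

For each animal the pipeline (`run_pipeline()`) performs:

1. **Rigid MRI-to-PET co-registration** from six skull-fixed fiducials
   (eyes, mandibular condyles, cochleae): the closed-form least-RMS
   (Kabsch/Procrustes) fit with a reflection guard. The problem posed —
   "the rigid transform minimising the RMS distance between paired
   landmarks" — has this unique closed-form optimum, which is why no
   iterative optimiser is used.
2. **Affine normalisation to atlas space**, an ordinary least-squares
   12-parameter landmark fit. Intensity-based nonlinear warping is
   deliberately out of scope: for schematic phantoms whose frames differ by
   a rigid or mildly affine motion, the landmark affine is exact, fast and
   deterministic.
3. **SPIO quantification in native MRI space**: Otsu-threshold brain
   extraction (largest connected component, ball-radius-1 closing, hole
   filling), log-domain polynomial bias-field correction, and
   histogram-mode thresholding of hypointensities. The binary label volume
   is then propagated to atlas space with nearest-neighbour resampling for
   VOI accounting. Segmenting *before* resampling matters: trilinear
   interpolation makes the noise spatially inhomogeneous (voxels mix 1–8
   source voxels) and darkens the brain rim, which inflates the
   hypointensity tail; on crisp native intensities the threshold model
   holds.
4. **PET quantification in atlas space**: duration-weighted summation of
   the 20–50 min frames, SUV conversion, VOI means over the propagated
   atlas labels, SUVR referenced to the neocortex. If SPIO labels fall
   inside the reference region, those voxels are excluded from the
   reference mean (the "unaffected neocortex" rule); the mask is an
   explicit input, not an automatic lesion detector, because no objective
   criterion for "evidence of cortical lesions" exists.
5. **Reporting**: per-region mean ± SD by group, Mann-Whitney p (exact by
   enumeration when the pooled sample is ≤ 14 without ties, else the normal
   approximation with tie and continuity correction — the method used is
   recorded), pooled Spearman correlations with CS and between modalities.
   Region-wise p-values are uncorrected by default, mirroring the reporting
   convention for small exploratory cohorts; a Holm option exists. Pooling
   EAE and controls inflates rank correlations whenever the groups
   separate; this is the convention being reproduced and is stated, not
   endorsed.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| `psf_fwhm_mm` | 0.9 | mm | effective reconstruction resolution of a small-animal PET system at desk scale |
| `pet_noise_sd` | 0.05 | fraction of reference activity | post-reconstruction PET noise, approximately Gaussian on activity |
| `mri_noise_sd` | 0.05 | fraction of tissue intensity | tissue SNR ≈ 20 for a 3D GRE acquisition |
| `bias_amplitude` | 0.2 | fraction | 20% peak receiver-coil inhomogeneity |
| `lesion_contrast` | 0.7 | fraction | punctate T2\* dropout to 30% of tissue signal |
| `spio_k` | 3.0 | robust sigmas | lower cut below the tissue mode; the Gaussian 3σ tail (0.13%) bounds false positives |
| `spio_min_cluster` | 2 | voxels | suppresses single-voxel noise; lesions are punctate but multi-voxel at 0.25 mm |
| `misalign_rot_deg`, `misalign_trans_mm` | 3, 0.5 | deg, mm | inter-session repositioning with a head holder |
| `landmark_jitter_mm` | 0.05 | mm (per coordinate) | manual fiducial identification error |

The SPIO threshold rule itself is a documented stand-in: the histogram
model is the simplest one consistent with labelling hypointense sites — a
single dominant tissue mode with robust location/scale (median, MAD) and a
`k·σ` lower cut, with `k` exposed. Similarly, whether SPIO-Vol denominators
should be brain-masked or full atlas VOIs is ambiguous; full atlas VOIs are
used.

## What the phantom emulates — and what it does not

`generate_atlas()` builds a schematic brain: an ellipsoid partitioned into
neocortex, caudate/putamen, hippocampus, thalamus, cerebellum and brainstem
by nested ellipsoids and axis splits, plus six fiducials outside the brain.
Geometry is *not* anatomical; what matters for validating the
quantification chain is that labels exist, are disjoint, and have
controlled contrasts. Region thickness was chosen generously relative to
the PET point-spread function, because VOI means carry an irreducible
partial-volume bias of roughly `0.4·σ/w` per open face (σ ≈ 0.38 mm for the
0.9 mm FWHM kernel, `w` the region width): at the default 64³ × 0.25 mm
grid the worst-case SUVR bias is ≈ 8% (cerebellum, which faces background),
within the 10% recovery band; substantially thinner hindbrain slabs would
not be.

The SPIO-MRI is synthesised directly on its own acquisition grid, whose
world pose differs from the atlas/PET frame by the random rigid
misalignment: each MRI voxel centre is mapped through the misalignment and
given crisp tissue/lesion membership, exactly as a scanner samples the
object on its grid. No generation-time interpolation is applied — that
would blur the punctate lesions once before the pipeline resamples them a
second time, an artefact of simulation rather than physics. Lesions are
spherical clusters of radius 1–3 voxels, rejection-sampled wholly inside
their region and one voxel clear of the brain surface (uptake sites are
parenchymal/perivascular; a surface notch would also defeat hole-filling
during brain extraction). Realized fractional volumes are recorded exactly
from the atlas-grid mask, so requested fractions that punctate clusters
cannot hit exactly are never silently wrong.

The bias field is the exponential of a random second-order polynomial,
centred and scaled so its peak deviation over the brain equals
`bias_amplitude`, then normalised to mean 1 — smooth, strictly positive,
coil-like. Background noise is folded (absolute value), emulating the
Rician floor of magnitude images.

Not modelled: MR physics (no TE/TR/T2\* or k-space), PET kinetics (frames
are stationary; the 20–50 min window of this tracer is treated as
equilibrium), partial-volume tissue mixtures, anatomy, and the 24 h delay
between PET and MRI sessions (both modalities see the same disease state).
Passing tests therefore demonstrate correctness of the *quantification
chain* under controlled conditions, not robustness to anatomical variation
or acquisition artefacts beyond those listed.

## The cohort model

Each animal draws a latent severity factor `s ~ N(0,1)`; region-level
values mix `s` with independent noise (loading 0.8), so SUVR elevation,
lesion burden and clinical score rise together and the pipeline has a
recoverable correlation structure. Marginals match the configured group
means and SDs: normal for SUVR (ratios with coefficients of variation
around 0.1), gamma via a Gaussian copula for SPIO-Vol — lesion burdens are
non-negative with SDs comparable to their means (e.g. 0.5 ± 0.5, 9.0 ±
8.1), which a normal distribution cannot represent without truncation.
The default effect profile uses group means/SDs on the scale reported for
symptomatic PLP-EAE cohorts; these are realistic *settings*, not
replication targets, since per-animal source data are not available.

Clinical scores map from mean lesion burden through a monotone link,
quantised to the 0.5-step 0–4 scale; controls are sham-immunised and score
0. With the default quantised link, rank order of CS equals rank order of
burden only up to quantisation ties; the strictly-monotone-link invariant
is tested with a continuous link.

Two power properties of these conditions are worth recording. At 7 vs 5
with a two-sided exact test, the cerebellum SUVR separation (2.4 ± 0.2 vs
1.9 ± 0.3) has true power ≈ 0.805 — just above the 0.8 design target, so
estimates of it need several thousand replicates to be stable. The
thalamus SPIO-Vol separation (7.3 ± 5.5 vs 1.6 ± 1.7) cannot reach 0.8
under any realistic marginal with those moments; it is also the weakest
group finding in this model system, and the validation suite asserts power
only over the strongly affected regions while reporting the thalamus value.

## Numerical choices

* **Resampling**: trilinear for intensities, nearest-neighbour for labels
  and masks; points on the upper grid face are clamped into the last cell;
  out-of-field voxels become 0/background.
* **Summed frames** are implemented as a duration-weighted mean — equal to
  the plain mean for equal frames up to a constant factor, which cancels in
  SUVR, and robust to unequal frame schedules.
* **Bias fit**: least squares on log-intensity with one reweighting pass
  that down-weights residuals below −2 robust SDs (lesions are low
  outliers); the field is normalised to mean 1 over the mask so correction
  preserves the intensity scale.
* **Thresholding** uses median/MAD rather than mean/SD so the tissue-mode
  estimate is insensitive to the lesion tail; the labelling is invariant to
  global intensity scaling by construction.
* **Degenerate inputs** error loudly rather than returning silent NaN:
  empty regions, collinear landmarks, non-positive intensities under a log
  fit, zero-spread histograms, empty co-localization denominators (flagged
  undefined, never 0).
* **Determinism**: every generator draws from one integer seed through a
  scoped RNG (`withr::with_seed`), leaving global RNG state untouched;
  `NULL` seeds let a caller (the cohort generator) thread one stream
  through sub-generators.

## Validation problem sizes

The test suite validates registration recovery on 100 random transforms;
bias-field and SUVR recovery on 64³ phantoms; SPIO labelling on constructed
N(100, 5) scenes with contrast-0.7 lesions and on registered misaligned
phantoms; Mann-Whitney exactness against full enumeration for every group
size with pooled n ≤ 14; type-I error on 500 null cohorts; and power and
pooled correlations on 3000 simulated cohorts at 7 vs 5. End-to-end
determinism is checked by byte-comparing the result files of two identically
seeded runs.

## Known limitations

* Landmark-based affine normalisation stands in for intensity-based
  nonlinear spatial normalisation; adequate for phantoms, not for real
  anatomy.
* The histogram-threshold rule and cluster filter are plausible stand-ins
  for an unspecified procedure; `k` and the minimum cluster size are
  exposed for sensitivity analysis.
* Fluorescence quantification assumes two registered channels and round,
  non-overlapping cells; real micrograph segmentation and stain unmixing
  are out of scope.
* Pooled-group correlations inherit the group-separation inflation noted
  above.
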