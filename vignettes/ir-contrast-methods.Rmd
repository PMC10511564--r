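---
title: "Modelling lesion-to-liver contrast in unenhanced inversion-recovery liver MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling lesion-to-liver contrast in unenhanced inversion-recovery liver MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ircontrast)
```

## The problem

During MR-guided thermoablation of liver tumours, gadolinium contrast agent
is deliberately withheld before treatment, and on the standard unenhanced
T1-weighted spoiled gradient-echo sequence (VIBE) many malignant lesions are
barely distinguishable from the surrounding parenchyma.  Magnitude-
reconstructed Look-Locker inversion-recovery (IR) images acquired at a
ladder of inversion times (TI) offer a contrast dial for free: because
malignant lesions have substantially longer T1 than liver parenchyma, there
are inversion times at which the parenchyma is suppressed while the lesion
still carries signal.

`ircontrast` is a simulation and analysis package for exactly this setting.
It models the signal physics, generates synthetic cohorts whose population
parameters match a published interventional cohort (44 patients, 51
lesions), renders noisy image series, measures lesion-to-liver contrast the
way a radiologist's ROI workflow would, runs the corresponding
repeated-measures statistical battery, and predicts contrast-optimal
inversion times for arbitrary tissue pairs.

## Signal models

The magnitude Look-Locker IR signal is the standard three-parameter model

$$S(TI) = |A - B\,e^{-TI/T_1^*}|,$$

with equilibrium amplitude $A$, inversion amplitude $B$, and apparent
relaxation time $T_1^*$.  Ideal inversion with an unperturbed recovery is
the special case $B/A = 2$, $T_1^* = T_1$.  The three-parameter form is
used deliberately instead of the two-parameter $|1 - 2e^{-TI/T_1}|$: the
continuous Look-Locker readout drives recovery toward a reduced apparent
steady state, which both shortens $T_1^*$ and shifts the contrast optimum
toward shorter TI — the central qualitative feature the simulator must be
able to reproduce.

Two knobs control the readout in simulation:

* `kappa` ($\kappa$, default **1.4**): apparent relaxation is
  $T_1^* = T_1/\kappa$.  Vendor readout details (flip angle train, beat
  scheme) are not published, so the compression factor is exposed rather
  than hard-coded; 1.4 is a typical magnitude for Look-Locker readouts at
  these flip angles.
* `b_over_a` ($B/A$, default **2.0**): the inversion amplitude ratio.

These are independent knobs by design.  Note that classical Look-Locker
theory ties them together: a readout-perturbed recovery has
$B/A = 1 + T_1/T_1^* = 1 + \kappa$, so a *physically self-consistent*
simulation would pair $\kappa = 1.4$ with $B/A = 2.4$, and then the
Look-Locker correction $T_1 = T_1^*(B/A - 1)$ recovers the true $T_1$
exactly.  With the default pairing ($\kappa = 1.4$, $B/A = 2$) the
corrected T1 systematically underestimates true T1 by the factor
$(B/A-1)/\kappa \approx 0.71$.  We keep both defaults as stated study
conditions and treat fitted T1 values as internally consistent
measurements: every analysis in the package compares compartments under
the same acquisition, where the common factor cancels.  Users exploring
scanner-faithful T1 estimation should set `b_over_a = 1 + kappa`.

The null point $TI_{null} = T_1^* \ln(B/A)$ (`null_ti()`) is where a
tissue's magnitude signal crosses zero — the mechanism behind parenchyma
suppression.  The VIBE comparator uses the ideally spoiled gradient-echo
steady state (`spgr_signal()`) at the protocol's TR = 3.5 ms and flip angle
10°; TE/T2* decay is intentionally not modelled, because the analysis
depends only on T1-driven contrast.

## The synthetic cohort

`cohort_config()` / `sample_cohort()` emulate the statistical structure of
the study population, not its anatomy:

* **Entities** (lesion counts): colorectal metastases 20, HCC 12, melanoma
  9, breast 5, neuroendocrine 2, pancreatic 1, cholangiocarcinoma 1, uveal
  melanoma 1 — 51 lesions in 44 patients.  Patients per entity follow the
  published table; extra lesions are assigned round-robin within an entity,
  which yields 7 multi-lesion patients rather than the published split of 6
  (one patient carried three lesions); the difference has no effect on any
  lesion-level analysis.
* **Lesion T1**: truncated normal, overall 1187 ± 456 ms, with
  entity-specific distributions for HCC (1063 ± 381) and CRC (1319 ± 545).
* **Parenchyma T1**: sampled once per patient and shared across that
  patient's lesions; overall 654 ± 96 ms, HCC patients 712 ± 115 ms
  (cirrhotic livers run long), CRC patients 609 ± 69 ms.
* **Diameters**: truncated normal on the hard range [6, 41] mm with the
  parent mean calibrated numerically (via `calibrate_tnorm_mu()`) so the
  truncated mean is exactly 19.1 mm.  The parent SD, 8 mm, is a fixed
  package choice consistent with that range.
* **Truncation convention for T1**: symmetric about the mean at
  $\min(3,\,0.99\,\mu/\sigma)$ SDs.  Symmetry keeps the truncated mean
  equal to the printed mean exactly (so calibration checks are honest),
  and the positivity guard keeps every draw physical.
* **Necrosis**: present with probability 0.2 in lesions of at least 15 mm,
  as a concentric core of 0.4 of the lesion diameter with T1 500 ms above
  the lesion's; small metastases rarely show macroscopic necrosis, and the
  ROI logic needs a viable rim to place an ROI in.
* **M0 ratio**: lesion:parenchyma equilibrium signal defaults to 1.0 (no
  proton-density information is available for the cohort); it is a
  configurable sensitivity hook.

Phantoms (`lesion_phantom()`, `render_phantom()`) are single-slice discs: a
circular parenchyma region, one lesion disc at an integer pixel center
(so that even 6-mm lesions survive the ROI rule's erosion margin), an
optional concentric necrotic core, and two small vessels at fixed polar
positions.  Rasterization is pixel-center based (a pixel belongs to a disc
iff its center is inside), 0-based row-major — deterministic and testable.
The default pixel size is the protocol's 400 mm / 256 = 1.5625 mm.

`simulate_series()` evaluates the IR model per pixel at the protocol's
eight TIs (148, 228, 548, 628, 946, 1025, 1343, 1743 ms) and applies
Rician noise as the magnitude of a complex Gaussian perturbation with equal
channel SD (`noise_sigma`, default **0.05** against a unit parenchyma M0,
i.e. SNR 20 — interventional single-shot images are noisy).  The Rician
floor ($\sigma\sqrt{\pi/2}$ where true signal is zero) is exactly the
mechanism that caps measured contrast near the parenchyma null in real
magnitude images, so it is simulated, not corrected away.

What the generator does *not* emulate: 3-D anatomy, respiratory motion,
coil profiles, partial volume beyond binary rasterization, T2*/proton
density variation, and vendor reconstruction details.  Passing tests
therefore demonstrate correctness of the measurement and inference
machinery under the stated signal model — not that real patient LLC values
are reproduced.  The published per-TI LLC magnitudes are patient
measurements shaped by those unmodelled factors; the package targets their
*direction* (short-TI optimum, monotone long-TI decay), which it does
reproduce.

## T1 fitting

`ir_fit()` estimates $(A, B, T_1^*)$ from magnitude samples.  Magnitude
reconstruction destroys the sign of the pre-null samples, so the fit runs a
polarity search: for every candidate flip point $k = 0..n$ the first $k$
samples are negated and the *signed* model $A - Be^{-TI/T_1^*}$ is fitted;
the candidate with the lowest residual sum of squares wins, ties toward
smaller $k$.  Each signed fit profiles out $(A, B)$ — the model is linear
in them for fixed $T_1^*$ — and searches $T_1^*$ on a bounded log grid
(80 points on [50, 5000] ms) refined by golden-section to an absolute
tolerance of $10^{-6}$ ms.  Variable projection makes the fit exact on
noiseless model data and independent of starting values; the test suite
holds it against a brute-force 1-ms grid oracle.

Degenerate inputs are flagged, never thrown mid-map: an all-zero pixel
yields `converged = FALSE`, and `fit_t1_map()` keeps such pixels as flagged
holes so maps stay rectangular.  The corrected T1 is always
$T_1^*(B/A - 1)$, stored alongside the raw parameters.  Rician bias is
deliberately not corrected in the least squares (vendor magnitude fits do
not correct it either); at the package's default SNR this biases long-T1
estimates by a few percent, which is visible in, and accounted for by, the
recovery tolerances.

## ROI placement and the contrast statistic

The study protocol placed ROIs manually ("as large as possible", avoiding
necrosis, vessels and bile ducts, with a parenchyma ROI "of similar size").
`place_rois()` operationalizes this deterministically:

* lesion ROI: the largest inscribed pixel-center disc (integer radius) in
  (lesion − necrosis) after a 1-pixel erosion margin; ties toward the
  smallest (row, col) center;
* parenchyma ROI: a disc of the *same* radius at the parenchyma pixel
  nearest the lesion boundary whose disc contains parenchyma only; same
  tie-break.

Both ROIs are placed once per lesion and frozen across every condition of
its series, mirroring the protocol's "consistent positioning across
series".  The contrast statistic is

$$LLC = \left| \frac{SI_{liver} - SI_{lesion}}{SI_{liver}} \right|,$$

scale-invariant by construction.  It is undefined when $SI_{liver} = 0$,
which can occur only in noise-free simulation at exactly the parenchyma
null; such records are emitted as missing-with-reason and excluded
pairwise downstream, never silently dropped.

## Statistical battery

`run_paper_battery()` reproduces the study's analysis plan on a cohort
table: Shapiro–Wilk screening, two-sided paired t-tests where differences
screen normal, Wilcoxon signed-rank otherwise, a Friedman omnibus across
the nine conditions (eight TIs + VIBE), Dunn–Bonferroni post hocs, a paired
lesion-vs-parenchyma T1 comparison, and HCC/CRC subgroup tables.

Decisions worth recording:

* The source protocol names a "rank sum test for dependent samples", which
  is internally inconsistent (rank-sum is an independent-samples test);
  the dependent-samples context dominates, so the package implements the
  Wilcoxon **signed-rank** test for all paired nonparametric comparisons.
* Signed-rank p-values are exact for $n \le 25$ without ties (signed-rank
  distribution) and for tied data up to $n = 14$ (exhaustive $2^n$ sign
  enumeration with mid-ranks); above that, a normal approximation with
  continuity and tie correction.  Friedman uses the mid-rank, tie-corrected
  chi-square.  Kruskal–Wallis (tie-corrected H via `stats::kruskal.test`)
  switches to exhaustive assignment enumeration for pooled $n \le 8$.
* The Dunn post hoc family defaults to the eight TI-vs-VIBE contrasts
  ($m = 8$), because those are the comparisons the study reports;
  the all-pairs family ($m = 36$) is available via `posthoc = "all_pairs"`.
  Whether the original analysis corrected over 8 or 36 comparisons is not
  stated; neither mode claims to be "what the authors did".
* Degenerate cases are reports, not errors: all-zero differences give
  p = 1 with a note; constant nonzero differences on the parametric route
  give an undefined statistic with a note; cohorts too small for a paired
  test produce a skipped-row with the reason.

## TI planning

`llc_curve()` computes the expected LLC profile for a tissue pair.
Noise-free, it is the closed form, with liver-null grid points flagged
undefined (the curve genuinely diverges there).  With noise, expected LLC
is defined as $E|\bar S_{liv} - \bar S_{les}| / E[\bar S_{liv}]$ over
ROI-mean distributions (ROI size default 50 pixels, matching typical ROI
areas in the pipeline), estimated by Monte-Carlo with a fixed seed — this
matches what the measurement pipeline actually computes, rather than
single-pixel statistics, and is finite everywhere.  `optimal_ti()` takes
the argmax over defined points, ties toward the smallest TI; an identical
tissue pair returns a zero-contrast flag rather than an error.
`scale_to_field()` applies the proportional TI scaling expected at higher
field strength (default factor 1.3 for 1.5 T → 3 T).

The optimizer deliberately does not claim to reproduce the measured
optimum of 228 ms as a *model prediction*: whether the short-TI optimum in
patients is driven by apparent-T1 compression ($\kappa > 1$) or by
inversion imperfection cannot be adjudicated from the published data, so
both knobs stay exposed.

## Reproducibility and problem sizes

One global seed is fanned out to named sub-streams (`derive_seed()`:
a polynomial rolling hash of the stage name folded into the seed modulo
$2^{31}-1$), so the cohort, each lesion's noise, and Monte-Carlo stages
are independently re-runnable.  Fixed (config, acquisition, seed) triples
give bit-identical results, including through the NIfTI/CSV/JSON round
trip (images are stored as float32; after the first quantization the round
trip is lossless).

Default problem sizes used by the package's own experiments: cohort studies
on 96×96 or 128×128 grids (the acquisition FOV/matrix ratio fixes the pixel
size, so smaller grids merely crop the field of view); calibration cohorts
of 5000 lesions; 500 replicates per condition for fit-recovery
experiments; 5000 null replicates for test-level calibration and 2000 for
family-wise error.  These sizes put Monte-Carlo error well below the
tolerances they are compared against.

## Known limitations

* Magnitude least squares without Rician bias correction (by design;
  an optional noise-floor term is a possible future knob).
* The default $\kappa$/$B/A$ pairing is a stated condition, not a
  self-consistent Look-Locker readout (see above).
* Single-slice phantoms, binary labels, no motion: contrast estimates are
  cleaner than interventional reality, which is why statistical power at
  the default SNR should be read qualitatively.
* Entity labels beyond HCC/CRC share the overall T1 distribution; the
  published subgroup information does not support more.
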