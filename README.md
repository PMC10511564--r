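# ircontrast

Simulation and analysis of **lesion-to-liver contrast in unenhanced
inversion-recovery (Look-Locker) liver MRI**, for the planning setting of
MR-guided thermoablation: gadolinium is withheld before treatment, malignant
lesions are hard to see on the standard T1-weighted spoiled gradient-echo
(VIBE) sequence, and magnitude IR images at a ladder of inversion times (TI)
offer tunable T1 contrast instead.

The package is aimed at researchers in quantitative MR and interventional
imaging who want to study, under a controlled signal model, how the choice
of TI drives lesion conspicuity — and at method developers who need a
reproducible synthetic test bed for ROI-based contrast pipelines.

## What it computes

* **Signal models.** Magnitude IR, `S(TI) = |A − B·exp(−TI/T1*)|`, with
  null point `TI_null = T1*·ln(B/A)` and Look-Locker correction
  `T1 = T1*(B/A − 1)`; ideally spoiled gradient echo
  `S = M0·sinα·(1−E1)/(1−cosα·E1)` for the VIBE comparator
  (TR = 3.5 ms, α = 10°).
* **Synthetic cohort.** 44 patients / 51 lesions with the published entity
  mix (20 colorectal metastases, 12 HCC, ...), lesion T1 ~ 1187 ± 456 ms,
  parenchyma T1 ~ 654 ± 96 ms (entity-specific subdistributions for
  HCC/CRC), diameters on [6, 41] mm with mean 19.1 mm; digital single-slice
  phantoms; Rician noise at the protocol's eight TIs
  (148 ... 1743 ms).
* **Measurement.** Three-parameter T1 fitting with polarity restoration
  (`ir_fit`, a classed model object with `coef`/`predict`/`plot`/...
  methods), per-pixel T1 maps, deterministic largest-inscribed-disc ROI
  placement, and the contrast statistic
  `LLC = |(SI_liver − SI_lesion)/SI_liver|`.
* **Inference.** The repeated-measures battery: Shapiro–Wilk routing,
  paired t / Wilcoxon signed-rank (exact small-sample p), tie-corrected
  Friedman omnibus, Dunn–Bonferroni post hocs, Kruskal–Wallis with exact
  enumeration at small n, HCC/CRC subgroups.
* **Planning.** Expected-LLC-vs-TI curves (closed form, or Monte-Carlo
  under Rician noise over ROI means), contrast-optimal TI, and
  field-strength TI scaling (×1.3 for 1.5 T → 3 T).

## Worked example

```r
library(ircontrast)

# fit the magnitude IR model to noiseless samples of a liver-like tissue
fit <- ir_fit(PROTOCOL_TI_MS, ir_magnitude(PROTOCOL_TI_MS, ir_model(1, 2, 654)))
fit
#> Magnitude IR fit (polarity-restored least squares)
#>   A = 1, B = 2, T1* = 654 ms, corrected T1 = 654 ms
#>   RSS = 1.61e-20 over 8 samples; 2 leading sample(s) sign-flipped

# simulate and measure a full synthetic cohort (SNR 20, kappa 1.4, B/A 2)
st <- run_cohort_study(cohort_config(seed = 1), matrix_size = c(96, 96))
st
#> Synthetic IR contrast study: 51 lesions / 44 patients, seed 1
#> Lesion-to-liver contrast by condition (mean +/- SD):
#>   TI148    0.516 +/- 0.306  (n = 51)
#>   TI228    1.932 +/- 3.113  (n = 51)
#>   TI548    0.589 +/- 0.494  (n = 51)
#>   ...
#>   TI1743   0.269 +/- 0.201  (n = 51)
#>   VIBE     0.176 +/- 0.187  (n = 51)

bat <- run_paper_battery(st)
bat
#>   dunn-bonferroni  TI228 vs VIBE   stat = 10.8   p_adj = 2.459e-26 *
#>   dunn-bonferroni  TI1743 vs VIBE  stat = -0.578 p_adj = 1
#>   paired-t         T1 lesion vs T1 parenchyma  stat = 8.13  p = 1.047e-10 *

# forward planning for a tissue pair, with the 3 T scaling
pl <- plan_ti(t1_liver_ms = 654, t1_lesion_ms = 1187, field_factor = 1.3)
pl$optimal_ti_ms   #> 228
pl$scaled_ti_ms    #> 296.4
```

Reading the output: contrast peaks at short TI (228 ms here, where the
parenchyma sits near its null and is additionally regularized by the Rician
noise floor), beats the VIBE comparator significantly at TI 148–1025 ms
after Bonferroni correction, and decays monotonically at long TI where both
tissues approach equilibrium — the same ordering reported for the patient
cohort the simulator is calibrated to.  Absolute LLC magnitudes are
synthetic-model quantities, not reproductions of patient values.

A thin CLI over the same functions lives at
`inst/scripts/ircontrast.R` (`simulate`, `analyze`, `optimize`
subcommands).

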