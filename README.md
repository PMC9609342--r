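# ramanqc

Chemometric calibration for **process Raman spectroscopy** of botanical
water extracts. During reflux extraction of herbal raw material
(e.g. *Salvia miltiorrhiza* / *Ligusticum chuanxiong* extracts), a
portable Raman probe can read the vessel in seconds — but the spectra
only become quality-control numbers through a calibration pipeline.
`ramanqc` implements that pipeline end to end for five product
attributes: danshensu, ferulic acid, rosmarinic acid, salvianolic acid B
(reference method: HPLC-DAD) and soluble solid (oven-drying
gravimetry, `Sc = (W₂ − W₁)/W × 100`).

It is written for chemometricians and PAT engineers who need the whole
chain to be testable:

* **Pretreatment** — replicate averaging, Savitzky–Golay smoothing
  (window 11, cubic, polynomial edges), per-spectrum min–max scaling to
  [0, 1].
* **Outlier screening** — Mahalanobis distance in PCA-score space
  (auto score count, 99.9 % variance, cap 10), iterated mean + 3·sd
  threshold; chi-square rule available.
* **Splitting** — deterministic Kennard–Stone max–min partition, 4:1
  (330 retained samples → 264 calibration / 66 validation).
* **Wavelength selection** — CARS (competitive adaptive reweighted
  sampling: Monte-Carlo rate 0.8, 50 runs, exponentially decreasing
  retention `r_i = a·e^(−k·i)` pinned from all channels to 2, adaptive
  reweighted resampling by |PLS coefficient|, min-RMSECV subset), plus
  UVE, SPA and siPLS comparators.
* **Calibration** — PLSR (SIMPLS), ε-SVR (exact dual QP), and a 1-D CNN
  (conv 32 → BN → maxpool → 4×conv 16 → conv 32 → conv 64, kernel 3,
  flatten, tapering dense stack, linear output; Adam 1e-4, batch 50,
  ≤ 200 epochs, patience 40; per-attribute variants as in the reference
  architecture).
* **Evaluation** — RMSEC/RMSECV/RMSEP and Rc²/Rcv²/Rp² per
  (engine, attribute), as a comparison-table-shaped report.
* **Synthetic process generator** — 7 batches × 3 reflux stages on the
  real sampling schedule (335 samples), saturating extraction kinetics,
  fluorescence baseline, triplicate acquisitions, planted gross
  outliers, soluble solid spanning 418.7–4882.7 µg/mL — so every stage
  is verifiable against known ground truth without factory data.

## Worked example

```r
library(ramanqc)

ds <- generate_dataset(seed = 42)          # the full synthetic campaign
#> <raman_dataset> 335 samples (1005 acquisitions), 1175 channels,
#>                 5 planted outliers, seed 42

smoothed  <- savgol_smooth(average_replicates(ds$spectra))
screening <- flag_outliers(smoothed)       # Mahalanobis, mean+3sd
#> <screening_result> mean3sd rule, threshold 1.390: 5 flagged, 330 retained
#>   flagged: 1-1-5, 1-3-7, 3-3-9, 4-3-9, 6-1-18

spectra <- minmax_scale(screening$retained)
split   <- kennard_stone_split(spectra, ratio = 4)
#> <calibration_split> 264 calibration / 66 validation (ratio 4:1)

refs <- reference_table(ds)
refs <- refs[match(spectra$sample_ids, refs$sample_id), ]
ci <- match(split$calibration_ids, spectra$sample_ids)
vi <- match(split$validation_ids, spectra$sample_ids)
X <- spectra$intensities
y <- refs$rosmarinic_acid

sel <- cars_select(X[ci, ], y[ci], seed = 42)
#> <selection_result> cars: 99 channels selected (best run 4), RMSECV 2.932

model <- fit_plsr(X[ci, sel$selected_indices], y[ci], seed = 42)
pred  <- predict(model, X[vi, sel$selected_indices])
sprintf("Rp2 = %.4f, RMSEP = %.3f ug/mL",
        r_squared(y[vi], pred), rmse(y[vi], pred))
#> "Rp2 = 0.8761, RMSEP = 5.135 ug/mL"
```

The five flagged ids are exactly the generator's planted gross outliers
(`ds$outlier_ids`); 330 samples remain for modelling, split 264/66. The
selection trace (`sel$trace`) shows the fast-screening collapse of the
variable count over the early runs and the fine-screening tail — the
classic CARS diagram. `Rp² = 0.876` on 66 held-out samples means the
CARS-PLSR model explains ~88 % of the held-out variance of rosmarinic
acid; RMSEP is in the analyte's own concentration units.

The whole study — four engines (SPA-SVR, CARS-PLSR, CNN, CARS-CNN) ×
five attributes with all six figures — runs from one config:

```r
res <- run_pipeline(default_config(), out_dir = "run1")
res$report          # 20-row comparison table
```

(The default, full-resolution CNN rows are slow in pure R — hours, not
minutes; see the vignette's "Scaling" section. The test suite runs a
reduced-scale version.)

A command-line interface wraps the same stages
(`inst/cli/ramanqc.R simulate | preprocess | screen | split | select | run`).

## Package layout

```
R/                    implementation (generator, pretreatment, screening,
                      splitting, selectors, engines, evaluation, pipeline)
tests/testthat/       unit + property tests, test-acceptance.R
scripts/acceptance.R  acceptance report
vignettes/            methods & design notes
inst/cli/ramanqc.R    command-line entry point
```
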