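---
title: "ramanqc: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ramanqc: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ramanqc` implements a complete chemometric calibration workflow for
process Raman spectroscopy of botanical water extracts: spectra collected
during multi-stage reflux extraction are turned into quantitative
predictions of four phenolic-acid markers (danshensu, ferulic acid,
rosmarinic acid, salvianolic acid B) and the gravimetric soluble-solid
content. This vignette records the models, the tunable parameters and
their defaults, what the synthetic data generator does and does not
emulate, and the design decisions taken where the methodology left
genuine freedom.

## The pipeline

```
simulate/load -> average replicates -> Savitzky-Golay -> screen (Mahalanobis)
             -> min-max scale -> Kennard-Stone split -> variable selection
             -> calibrate (PLSR / SVR / CNN) -> evaluate (RMSEC/RMSECV/RMSEP)
             -> predict unknown batches
```

Each stage is a pure function of its inputs; `run_pipeline()` ties them
together from one configuration and writes every artifact with a hashed
manifest, so a run is reproducible bit-for-bit from its config and seed.

## Pretreatment

Spectra live on a fixed instrument grid (176–3500 cm⁻¹ at 2.83 cm⁻¹,
1175 channels). Triplicate acquisitions are averaged channel-wise. Two
pretreatment steps follow:

* **Savitzky–Golay smoothing** — local least-squares polynomial fit,
  default window 11 channels, cubic. At 2.83 cm⁻¹ per channel an
  11-channel window spans ~31 cm⁻¹, which attenuates shot noise while
  preserving the ~30–60 cm⁻¹ bands of the extract. Edges are handled by
  the same polynomial fit over an asymmetric window (not truncation), so
  the channel count is unchanged — variable selection needs a stable
  axis. The smoothed value at every interior channel equals an explicit
  local polynomial fit; the test suite asserts this against a brute-force
  oracle at 1e-10.
* **Min–max scaling** — each spectrum is mapped affinely onto [0, 1].
  This removes laser-power and collection-geometry scale differences
  between acquisitions (it is exactly invariant to positive affine
  transforms of a spectrum). We read the methodology's "Minmax" step as
  per-spectrum normalization — the standard partner of S–G smoothing in
  Raman pretreatment — rather than per-channel scaling; per-channel
  scaling would amplify dead channels and is not what normalized process
  spectra look like. No baseline correction is applied, deliberately:
  the reference workflow lists none, and the calibration engines see the
  (smooth, low-frequency) fluorescence baseline as one more component.

## Outlier screening

Abnormal acquisitions are flagged by Mahalanobis distance in a reduced
principal-component score space: the raw channel-space covariance of a
few hundred spectra over ~1000 channels is singular, so distances are
computed on the leading PCA scores, where Mahalanobis distance is
invariant to any invertible affine map — only the dimensionality
matters. Two choices here deserve justification because we changed them
after the first implementation *proved* the obvious defaults wrong:

* **Score count.** An "explain 95% of variance" rule picks only 2
  scores on process-trajectory data, because concentration variation
  dominates overwhelmingly — and spike-type acquisition failures are
  nearly orthogonal to it, i.e. invisible in those 2 scores. The default
  therefore targets 99.9% of variance, capped at 10 scores (in practice:
  the cap), which is also the usual chemometric practice of screening in
  a 10-or-so-dimensional score space.
* **Screening happens before min–max scaling** (after averaging and
  smoothing). Min–max is invariant to amplitude, so normalizing first
  erases the most diagnostic feature of a gross failure — a 10× intensity
  error looks perfectly normal afterwards. It also makes low-signal
  stage-start samples heteroscedastic in the minor score directions,
  inflating false positives. Screening the smoothed, un-normalized
  spectra detects all planted outliers with zero false positives across
  20 seeded replicates.

The default threshold is **mean + 3·sd of the distance distribution,
iterated**: after flagging, mean and sd are recomputed from the
unflagged samples until no new sample exceeds the threshold. Without
iteration, five gross outliers at distance ≈ 18 inflate the threshold to
≈ 8 and mask a milder one at distance ≈ 6 (a textbook masking effect). A
fixed chi-square quantile threshold (`rule = "chi2"`, default 0.999) is
available as the non-iterative alternative.

## Kennard–Stone splitting

The calibration/validation split is the deterministic max–min design:
seed with the two mutually most distant spectra (Euclidean distance on
the preprocessed spectra), then repeatedly add the sample whose minimum
distance to the chosen set is largest. A 4:1 ratio keeps
`floor(4n/5)` calibration samples — 264 of 330, with 66 for validation.
Ties break to the lowest sample index so the split is identical across
platforms. For n ≤ 8 the greedy selection is verified step-by-step
against a brute-force restatement of the max–min rule.

## Variable selection

**CARS** (competitive adaptive reweighted sampling) is the primary
selector. Per sampling run `i = 1…50`: draw `⌈0.8·n⌉` calibration
samples; fit a PLS model on the currently live channels (latent-variable
count by inner 5-fold CV, capped at 10); keep the top `r_i` fraction of
channels by |regression coefficient|, where
`r_i = a·e^(−k·i)` with `a = (p/2)^(1/(N−1))`, `k = log(p/2)/(N−1)` —
the exponentially decreasing schedule pinned so all `p` channels survive
run 1 and exactly 2 survive run `N`; then resample the survivors with
probability ∝ |coefficient| (adaptive reweighted sampling, draws with
replacement, unique survivors kept). Each run's subset is scored by
5-fold RMSECV on the full calibration set (fold assignment fixed across
runs for comparability); the subset with minimal RMSECV wins. The
methodology fixes the Monte-Carlo rate (0.8) and run count (50); the EDF
constants and ARS mechanics follow the canonical published algorithm.
On near-noiseless low-dimensional targets the subset can collapse below
2 variables before run 50; the trace is then truncated with a warning
and the best subset so far returned. `min_vars` restricts the *winning*
run to subsets large enough for a downstream model — the CNN needs at
least its receptive field (16–17 channels; the engine harness uses 20).

The three comparators: **UVE** augments the spectra with artificial
noise channels, computes per-channel stability `mean(b)/sd(b)` of PLS
coefficients under leave-one-out, and removes every real channel whose
|stability| does not beat the noisiest artificial channel. **SPA** grows
minimally collinear chains by successive orthogonal projections (scored
by MLR RMSE on an internal Kennard–Stone hold-out; chains are built from
the spectra alone, so its strength is collinearity reduction, not
response relevance). **siPLS** splits the axis into 20 contiguous
intervals and exhaustively scores all 2- and 3-interval combinations by
PLS RMSECV (budget-guarded at 1e5 combinations; ties break to the first
combination in lexicographic order).

## Calibration engines

All three engines satisfy one fit/predict contract, so a single harness
produces the engines-by-attributes comparison table.

* **PLSR** — SIMPLS, latent variables by minimal 5-fold RMSECV (cap 10).
  With as many components as `rank(X)` SIMPLS reproduces the exact
  least-squares fit; the tests assert equality at 1e-8.
* **SVR** — ε-insensitive kernel regression solved *exactly* as the dual
  quadratic program (`quadprog`), practical because calibration sets are
  a few hundred samples. RBF kernel by default with the "scale"
  bandwidth heuristic `γ = s/(p·var̄(X))`; grid search over cost
  {1, 10, 100} × γ-scale {0.1, 1, 10} × ε {0.01, 0.1} by 5-fold CV.
  Targets are z-scored internally.
* **CNN** — a 1-D convolutional network:
  conv(32, k3, s1)+ReLU → batch-norm → max-pool(k2, s1) →
  4×[conv(16, k3, s1)+ReLU] → conv(32, k3, s1)+ReLU →
  conv(64, k3, s1)+ReLU → flatten → dense stack → 1 linear output.
  Per-attribute variants follow the reference architecture: no pooling
  layer for ferulic acid; three dense layers for ferulic and rosmarinic
  acid, two otherwise. The quoted "3 × 3" filter windows are implemented
  as 1-D kernels of length 3 — spectra are 1-D signals, and reshaping
  them into images would be arbitrary. Dense hidden widths are not
  stated by the methodology; we use tapering (64, 16) and (64, 32, 16),
  small enough for ~264 training samples. Training: mean-squared error,
  Adam at learning rate 1e-4 (reading the garbled "le × −4" as the
  obvious 1e-4), batch 50, at most 200 epochs, early stopping after 40
  epochs without improvement of the training loss (no inner validation
  split is described, so the monitor is the training loss). Targets are
  z-scored; inputs are expected on the [0, 1] preprocessing scale.
  Initialization and batch shuffling are seeded, so training is
  bit-reproducible in a single-threaded run. The network is implemented
  directly in R on BLAS matrix products (im2col convolutions); at
  10²–10³ input channels and &lt;10⁵–10⁶ parameters this is adequate,
  though 1–2 orders of magnitude slower than a dedicated DL framework —
  see "Scaling" below.

## Evaluation

Six figures per engine/attribute: RMSEC and Rc² on the calibration set,
RMSECV and Rcv² from pooled out-of-fold predictions of a seeded 5-fold
cross-validation (refitting the engine per fold), RMSEP and Rp² on the
validation set. R² is the coefficient of determination
`1 − SS_res/SS_tot` — not a squared correlation; a model predicting
worse than the mean scores negative, which real comparison tables do
show. Every cell is traceable to a stored prediction vector, and
recomputing from that vector reproduces the cell bit-for-bit.
`folds = n` is allowed and is leave-one-out (we read the "fold with
fewer than 2 samples" restriction as forbidding *empty* folds; LOO is
standard and the contract's own examples use it).

## The synthetic world

The generator emulates the monitored extraction process so that every
stage has a known ground truth:

* **Sampling frame** — 7 batches × 3 reflux stages (120/90/90 min),
  sampled every 5 min for the first hour and every 10 min after, giving
  48 points per batch; `drop_last` (default on) drops the final slot of
  the last batch to reproduce a 335-sample campaign in which one slot
  went uncollected (the arithmetic otherwise gives 336; which slot was
  missing in the real campaign is unknowable, so it is a flag, not a
  guess).
* **Kinetics** — per component, first-order saturating rise within each
  stage, `c(t) = c_max·yield_s·(1−e^(−rate·t))`, stage yields
  (1, 0.35, 0.15): most of the material extracts in stage 1, with
  diminishing returns after. Batch-to-batch lognormal variation
  (CV 5%) on `c_max`. The soluble-solid trajectory is affinely pinned to
  span 418.7–4882.7 µg/mL across the dataset, the documented range of
  the real campaign; reporting µg/mL for a gravimetric percent assumes
  extract density 1 g/mL (configurable), as the real units otherwise do
  not bridge.
* **Spectra** — linear mixture of five pure-component profiles
  (Gaussian bands; pseudo-Voigt available) on the instrument axis, the
  matrix/solids component carrying the extract's dominant bands at
  1000/1250/1500 cm⁻¹ and the analytes partially overlapping bands so
  selection is non-trivial; a smooth fluorescence-like baseline with
  per-acquisition drift (CV 5%); i.i.d. Gaussian noise; triplicate
  acquisitions per time point.
* **References** — true concentrations with 1% multiplicative Gaussian
  error, mimicking HPLC repeatability; so parameter-recovery ceilings
  are realistic rather than exact.
* **Outliers** — a configurable number (default 5) of gross acquisition
  failures: all replicates of a randomly chosen sample scaled ×10 plus 3
  single-channel spikes. Deliberately unambiguous, as the screening
  stage's job is gross errors, not subtle drift.

What it does **not** emulate: instrument response and wavelength
miscalibration, cosmic rays in normal (non-outlier) spectra, detector
nonlinearity, temperature-dependent band shifts, correlated (pink)
noise, and chemical interferents beyond the five components. A green
test therefore establishes algorithmic correctness and sane statistical
behaviour on data with the right gross structure — not instrument-level
realism.

## Numerical choices

* SIMPLS deflation stops when a score norm falls below 1e-12 of the
  initial covariance scale; component counts are capped by rank.
* The SVR dual adds a 1e-8 ridge to the (singular) QP Hessian; the bias
  is averaged over free support vectors, falling back to the mean
  residual when none is free.
* Batch-norm uses ε = 1e-5 and running-statistics momentum 0.9;
  max-pool ties (equal neighbours) route their gradient to the left
  element.
* Mean + k·sd screening iterates to a fixpoint; all iterations use the
  distances computed once from the full input (the score space is not
  refitted during iteration).
* Kennard–Stone and siPLS break ties to the lowest index; CARS breaks
  ties through its seeded sampling.

## Scaling of the test suite

The full stated world (335 samples × 1175 channels × four engines × five
attributes, each cell cross-validated) is dominated by the full-spectrum
CNN rows: one fit costs ≈ 10⁶ × the per-step cost of a ~74k-wide dense
layer, which in pure R amounts to tens of minutes per fit — hours for
the full grid. A dedicated DL framework would be 1–2 orders of magnitude
faster; within this package the end-to-end acceptance test therefore
runs a reduced world chosen by fixed a-priori rules: **preserve the
study's channel-to-sample ratio (p/n ≈ 4.5)** — the regime that makes
variable selection matter — and **preserve the outlier contamination
rate (~1.5%)** — a mean + 3·sd rule saturates by construction once a
tenth of the samples are gross outliers — while shrinking n (1 batch,
47 samples, 147-channel axis, 1 planted outlier) and capping CNN
training at 60 epochs in the cross-validated cells. The structural
claims (report completeness, screening recovery, split arithmetic) are
scale-free; the selection-versus-full-spectrum comparison is
scale-sensitive and is asserted at the reduced scale with that caveat
recorded here and in the test itself. At this scale the CARS-CNN wins
decisively on some attributes and narrowly loses on others; whether the
reduced world meets the "4 of 5 attributes" ordering is reported
honestly by the test rather than tuned for.

## Known limitations

* The CNN is trained single-threaded in R; it is deterministic but
  slow, and the architecture's parameter count grows linearly with the
  input length through the flatten layer, so full-spectrum CNNs at 1175
  channels are expensive by construction.
* SPA builds chains from the spectra alone; on data whose informative
  channels are not geometrically distinguished it selects conservative,
  sometimes very small subsets.
* The screening stage assumes gross, isolated failures; slow drift or
  batch-level contamination would need robust-covariance methods (MCD),
  which are intentionally out of scope.
* Reference values are modelled as conditionally independent
  measurements; real HPLC errors correlate across analytes within a run.
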