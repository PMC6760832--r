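---
title: "Calibration models for overlapping UV spectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calibration models for overlapping UV spectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chemocal)
```

## The problem

Pyridostigmine bromide (PR) and its two related substances — impurity A,
its carbamate precursor-like congener, and impurity B, its degradation
product — have nearly coincident UV spectra (absorption maxima at 270, 262
and 329 nm on the 200–350 nm grid). At the impurity proportions relevant
for quality control (impurities at roughly 1–3 % of the drug level), no
single wavelength isolates PR, so PR is quantified by regressing its
concentration on the full spectrum. `chemocal` implements the six standard
variants of that regression — PLS1 and linear ε-SVR, each on zero-order,
first-derivative, or OPLS-filtered spectra — together with the experimental
designs, the hyperparameter-selection machinery, and the recovery
statistics used to compare them.

## The synthetic-data generator

No instrument spectra for this system are publicly deposited, so the
package generates spectra from a physical forward model:

* **Beer–Lambert additivity.** A mixture's absorbance at wavelength λ is
  the concentration-weighted sum of pure-component absorptivities. The
  noiseless generator is exactly linear in the concentrations
  (superposition holds to machine precision), which is also the modeling
  assumption of every linear calibration model in the package.
* **Band models.** Each pure component is a sum of Gaussian bands in
  wavelength. The defaults place the main bands at 270/262/329 nm with a
  weaker short-wavelength band each, so that the PR and impurity-A spectra
  overlap strongly (cosine similarity ≈ 0.94) while impurity B is more
  distinct — the qualitative overlap structure of the real system. Band
  widths and heights are the package's own stand-ins: absorptivities are
  scaled so 10 µg/mL of a pure component peaks at roughly 0.2–0.6 AU,
  inside the Beer–Lambert validity range.
* **Noise.** Additive i.i.d. Gaussian noise per wavelength, default
  σ = 0.002 AU — a realistic noise floor for a double-beam UV instrument.
  One integer seed makes noisy generation bit-reproducible, and the
  generator restores the caller's RNG state.
* **Designs.** `build_calibration_design()` returns the 16-mixture
  4-level/3-factor calibration design (levels coded −2/−1/+1/+2; every
  analyte visits each level in exactly 4 mixtures), and
  `build_test_design()` the 9 independent validation mixtures inside the
  calibration space.

What the generator deliberately does **not** emulate: baseline drift,
wavelength-registration error, stray light, detector saturation,
heteroscedastic or correlated noise, and deviations from Beer–Lambert
additivity at high absorbance. Tests passing on synthetic data therefore
demonstrate correctness of the algorithms and the noiseless-limit recovery
of the design concentrations — not performance on real instrument data.

## Preprocessing

* **Mean centering** is estimated on the calibration set (`fit_center()`)
  and applied frozen (`apply_center()`); it is never re-estimated on test
  data. Inside resampling loops (bootstrap, cross-validation) centering is
  re-estimated on each retained subset, so no information leaks from
  held-out samples.
* **First derivative**: forward finite differences on band midpoints (the
  151-point grid becomes 150) or a same-length Savitzky–Golay smoothed
  derivative (default window 5, polynomial order 2). The derivative is a
  per-spectrum transform, so it is applied before centering; centering is
  then estimated on the derivative representation. Derivatives suppress
  broad baselines and reduce overlap but amplify high-frequency noise,
  which is visible in the D-variants' results.
* **OPLS** removes components whose training scores are orthogonal to the
  response, with the single-response recursion given in `?fit_opls`. The
  default removes one orthogonal component (`n_ortho = 1`) — the usual
  choice for a single response, and configurable. Two numerical details:
  the orthogonal weight is re-orthogonalized against the predictive weight
  a second time (classical Gram–Schmidt twice), which keeps removed scores
  orthogonal to the response at machine precision even for later
  components; and if the orthogonal weight collapses below 1e-12 the
  recursion stops early with a message, storing fewer components.

## PLS1 and the bootstrap LV choice

`fit_pls1()` is the NIPALS PLS1 recursion with X- and y-deflation; the
regression vector is assembled as *W(P'W)⁻¹q*, exploiting that *P'W* is
upper triangular so every truncation of the component sequence is obtained
from one triangular solve. Requesting more components than the attained
rank is an error that names the rank.

`bootstrap_select_lv()` repeats, 1000 times by default: draw ⌈2n/3⌉
calibration rows without replacement (11 of 16) as a bootstrap-training
set, center within it, fit PLS1 at every candidate LV count (default cap
10 = split size − 1), and record the RMSEP on the held-out third. The
chosen count is the smallest whose mean RMSEP is within 1e-6 of the
minimum — a parsimony tie rule that makes the selection deterministic.
The 11/5 split (rounding two thirds up) is a package choice; the split
fraction wording admits either rounding.

A scientific caveat worth knowing: at a very low noise floor the mean
RMSEP curve becomes nearly flat past the chemical rank and can keep
creeping downward by ~1e-4–1e-3 per extra component, because PLS's
Krylov-ordered components approximate the optimal regularized predictor of
noisy spectra only asymptotically. The argmin selection then lands above
the chemical rank of 3 even though a 3-LV model already predicts at the
noise-limited error. As the noise grows toward the impurity signal scale
the selection falls back to — or below — the chemical rank, because the
minor components stop paying for themselves. You can see both regimes
with:

```{r lv-vs-noise, eval = FALSE}
y <- design_response(build_calibration_design(), "PR")
for (sigma in c(0.002, 0.02)) {
  chosen <- sapply(1:10, function(s) {
    sp <- generate_mixture_spectra(build_calibration_design(),
                                   noise = noise_model(sigma, seed = s))
    bootstrap_select_lv(sp, y, max_lv = 10, n_iterations = 200,
                        seed = 100 + s)$chosen_lv
  })
  cat("sigma", sigma, "->", chosen, "\n")
}
```

This is why a flat RMSEP-versus-LV table (step 2 of the analysis workflow)
should be read as "anything on the plateau is equivalent", with the
smallest plateau member the defensible choice.

## Linear ε-SVR

`train_linear_svr()` solves the standard ε-insensitive dual by sequential
minimal optimization over the 2n box variables, with maximal-violator
selection of the first working variable and second-order (best guaranteed
decrease) selection of the second; the inner loop is compiled. The KKT gap
tolerance is 1e-8 for final fits. The bias is the KKT average over free
support vectors; when no coefficient is free the dual pins the bias only
to an interval and the midpoint of the gap bounds is used. ε is
interpreted on the centered concentration scale (µg/mL), consistent with
the centering applied to everything that enters the regressor.

`grid_search_svr()` tunes (ε, C) by k-fold cross validation (default 4
folds of 4 on the 16-mixture set, random partition under a seed): per
fold, center on the retained samples, train at every grid point, predict
the held-out fold, and pool all squared errors into one RMSECV per pair.
Defaults cover ε ∈ 0.01–1 step 0.01 and C ∈ 30–1000 step 10 (9800 pairs).
Two performance-motivated numerical choices, neither affecting the
reported optimum beyond the solver tolerance: the grid is traversed with C
ascending and ε snaking so every solve warm-starts from the nearest
previously solved problem (valid because the feasible box only grows with
C and ε does not enter the constraints), and the search uses a looser KKT
tolerance (1e-5) than final fits, since it only ranks candidates. Ties
within 1e-9 of the minimal RMSECV resolve to the smaller C, then the
smaller ε — the simpler model. On near-flat RMSECV valleys (small ε on
low-noise data) the specific tied C is not meaningful; the valley is.

One structural observation: first-derivative features are roughly an order
of magnitude smaller than zero-order absorbances, so the dual box
constraint C ≤ 1000 can bind for DSVR and leave it underfit relative to
the other variants — the weakest member of the family here, on synthetic
data as in practice.

## Evaluation statistics

`summarize_predictions()` reports per-sample recovery (100·found/taken),
the mean and standard deviation of recoveries, and the RMSE. The SD uses
divisor N (population form) by default because that is the convention of
the reported recovery tables shipped with the package (`sd_divisor = "n-1"`
gives the sample form). One formula —
√(Σ(taken−found)²/N) — serves RMSEC (calibration), RMSEP (test) and
RMSECV (pooled cross-validation errors). The comparison machinery
(`two_sample_t()`, `f_ratio()`, `one_way_anova()`) uses pooled-variance t
(two-tailed), larger-over-smaller variance F (one-tailed) and standard
between/within ANOVA, each with its p = 0.05 critical value; degenerate
inputs (zero variances) are flagged rather than silently propagated.

The shipped reference tables carry the per-sample Taken/Found/%R columns
of the original six-model comparison at their reported precision. Their
test-set footer statistics all recompute correctly from the columns; of
the calibration-set RMSEC footers, only the SVR family's are consistent
with their own columns, and the recomputed (self-consistent) values are
the ones the analysis reports.

## Pipeline and reproducibility

`run_six_model_comparison()` runs any subset of the six variants with all
preprocessing estimated on the calibration set only, hyperparameters
selected per variant (bootstrap LVs for PLS, grid search for SVR), and
both sets evaluated. Within OPLS variants the filter is estimated once on
the full calibration set before the bootstrap runs on the filtered
matrix; re-estimating the filter inside every bootstrap split would also
be defensible but couples the two resampling layers and was not adopted.
Every stochastic stage (generator noise, bootstrap splits, CV folds) is
driven by an explicit integer seed, and runs with identical configurations
are bit-identical, including the output CSVs and the run manifest.

Problem sizes used throughout the package's own studies: 16 calibration
and 9 test mixtures on the 151-point grid, 1000 bootstrap iterations, the
full 9800-point (ε, C) grid, and 10 generator seeds for stochastic
properties.

## Known limitations

* Band shapes and absorptivities are stand-ins; only the band positions
  and overlap structure of the real system are emulated, so absolute
  error magnitudes on synthetic data do not transfer to instrument data.
* The LV-selection argmin is unstable on low-noise plateaus (see above);
  treat the RMSEP-vs-LV table, not the single chosen number, as the
  result.
* Only linear SVR is implemented; the kernelized extension is
  deliberately out of scope, as the experimental design guarantees
  linearity.
* Second and higher derivatives, and scatter-correction preprocessing
  (MSC/SNV), are out of scope — none are used by the six compared models.
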