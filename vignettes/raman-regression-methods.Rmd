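---
title: "Methods: quantitative Raman regression with RamanQuant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantitative Raman regression with RamanQuant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A Raman spectrum of living tissue is a sum of weak, chemically specific
scattering bands sitting on a fluorescence background that is typically
one to two orders of magnitude larger, contaminated by occasional
single-channel cosmic-ray spikes and detector noise. Quantifying an
analyte — here blood glucose from nailfold spectra, in mmol/L — means
removing everything that is not Raman signal and then calibrating a
multivariate regression from a few dozen spectra with 1024 correlated
spectral channels each. This vignette documents the models, the
numerical choices, and what the package's tests do and do not
demonstrate.

# Data model and units

`RamanSpectra` stores the M × N intensity matrix with the wavenumber
axis (strictly increasing, cm⁻¹) and per-spectrum targets; validity is
enforced at construction, so no invalid object can exist. Glucose
targets may be declared in mmol/L or mg/dL; `convertGlucoseUnits()`
uses 1 mmol/L = 18.016 mg/dL (molar mass 180.16 g/mol). The package
works internally in whatever unit the data declares; the simulator
defaults to mmol/L (4.6–10.0, i.e. 82.8–180 mg/dL).

# Preprocessing chain

Stages run in a fixed order; each is skippable. Cropping and
interpolation come first because every later stage assumes the final
grid.

* **Crop** — closed interval `[cropLo, cropHi]`; an interval keeping
  fewer than 3 points is an error.
* **Interpolation** — linear, within the data span only. Extrapolation
  is refused rather than guessed.
* **Median despike** (default window 5 points) — replaces each point by
  its windowed median; nearest-value padding at the edges. A cosmic-ray
  spike occupies one or two channels and is eliminated exactly; real
  bands several channels wide pass through with only slight apex
  clipping. This sets a practical lower bound on the grid: bands must
  span several points (the default 1024-point grid over 800–1800 cm⁻¹
  gives ~1 cm⁻¹ spacing, comfortably finer than any band width).
* **Polynomial baseline** (default) — the iterative clip-to-fit scheme:
  fit a least-squares polynomial, clip the working spectrum to
  `min(spectrum, fit)`, refit, until the background changes by less
  than `tol` of the intensity range or `maxIter` is reached. Clipping
  keeps positive peaks out of the background, so a plain least-squares
  subtraction (which would eat peak height) is avoided. Defaults:
  degree 5, `maxIter = 200`, `tol = 1e-4`. Convergence is geometric but
  slow on noisy data; 1e-4 of the intensity range is reached in a few
  dozen iterations and is below the noise floor of the estimate, while
  much tighter tolerances simply run out the iteration budget without
  changing the result materially. One caveat worth knowing: degrees
  well above the true background order buy flexibility at the price of
  a small polynomial wiggle near the grid edges. On the simulator's
  smooth quadratic-like background, degree 2–3 recovers the pure signal
  to within 2% L2, degree 5 to within ~9%; on real fluorescence of
  unknown shape the flexible default is the safer choice.
* **EMSC** — models each spectrum as `x = b·m + Σₖ pₖ wᵏ + e` against a
  reference `m` (default: the mean spectrum of the data being
  corrected) with polynomial terms in the wavenumber axis normalized to
  [−1, 1] (for conditioning); the corrected spectrum is
  `(x − Σₖ pₖ wᵏ)/b`. A fitted `b ≤ 1e-8` is reported as a degenerate
  fit naming the spectrum rather than silently amplifying noise.
* **Savitzky–Golay smoothing** (default window 11, order 3) — central
  convolution weights from a local least-squares polynomial; mirror
  padding (reflection excluding the edge point) at the boundaries.
  Polynomial trends up to the fit order pass through unchanged in the
  interior.
* **Area normalization** (off by default) — division by the plain sum
  of intensities, giving Σᵢ Iᵢ = 1 exactly and idempotently. On a
  uniform grid this differs from a trapezoid integral only by a
  constant factor; the sum keeps the invariant exact. It is off by
  default because it removes the absolute intensity scale, which the
  calibration may need.

# Split protocol and augmentation

`splitDataset()` first draws the prediction set (default 10 spectra),
then splits the remainder into training and test by fraction (default
0.8). Sizes use `round()` — ties to even — documented because the
fraction times the remainder need not be integral for every N. For the
75-spectrum study layout this yields 52/13/10.

The standard-deviation-shift augmentation needed a concrete formula:
with σ(w) the per-wavenumber standard deviation across the training
spectra, deterministic copy k of spectrum x is `x + cₖ σ`, with
coefficients cycling `+s, −s, +2s, −2s, …` and `s = 0.5` by default.
This is reproducible, and for an even number of copies it preserves the
per-wavenumber mean exactly. A stochastic mode (`x + s·ε⊙σ`, ε i.i.d.
standard normal per wavenumber, seeded) is available for users who
prefer independent perturbations. Augmentation is applied to the
**training partition only**, after splitting: augmenting first would
place shifted copies of test spectra into training and invalidate the
test error. Copies inherit their source's target.

# Model families

**PLSR** is fit by NIPALS with single-response deflation; successive
score vectors are mutually orthogonal, and with as many components as
the rank of centred X the fit coincides with ordinary least squares
(both facts are tested). The component count is the key hyperparameter;
`selectPlsrComponents()` picks the count with the smallest mean
cross-validated MSE (seeded shuffled contiguous-block folds, default 5;
ties go to fewer components). The default ceiling of
`min(20, N − 1 − maxFoldSize, M)` keeps every training fold able to
support the largest count tried.

**ε-SVR** solves the usual dual quadratic program (via libsvm through
`e1071`) behind the package surface: features are standardized to zero
mean/unit variance internally — Gaussian kernels on raw detector-count
scales are degenerate — while ε stays in target units. Predictions use
the package's own dual expansion `g(x) = Σᵢ aᵢ k(svᵢ, x) + b`, which
also covers the zero-support-vector flat solution (every target inside
one ε-tube), a case worth handling explicitly because it is the correct
answer for near-constant targets. `svrOptimalityGap()` recomputes the
primal and dual objectives independently from the stored coefficients;
at the default solver tolerance (1e-3) the relative gap is small for
moderate C and the `|aᵢ| ≤ C` box constraint always holds. For very
large C the solver tolerance should be tightened along with it (the
`tolerance` argument) — the gap scales with C. The default search grids
are C ∈ {0.01…1000} by decades, ε ∈ {0.01, 0.1, 0.5}, γ ∈ {1e-4…1} by
decades.

**MLP**: one hidden layer, `tansig` (≡ tanh) hidden units, identity
(`purelin`) output, trained by full-batch gradient descent with
backpropagation on the MSE of scaled targets. Inputs and targets are
min-max scaled to [−1, 1] — the classic companion of tansig/purelin —
and the inverse map is applied at prediction; a constant feature maps
to a constant and is harmless. Weights initialize uniformly in
[−0.5, 0.5] from the seed, so runs are exactly repeatable. Early
stopping triggers at the first epoch whose training MSE reaches the
loss goal. Defaults: 4 hidden neurons, 100 epochs, learning rate
0.001, goal 1e-4. These are deliberately shallow settings for small
calibration sets; at them the network often underfits 1024-channel
spectra, which is visible in the package's own acceptance numbers and
is a property of the configuration, not a defect of the gradient
computation (which is verified against finite differences).

**1D CNN**: four blocks of same-padded cross-correlation (width 5) →
ReLU → max-pool (width 2, stride 2), with 8/16/32/64 filters, then a
32-unit ReLU dense layer and a single linear output neuron. The input
length must be divisible by 16 (the pooled shrinkage); incompatible
grids are refused with a pointer to `interpolateToGrid()`. Training is
mini-batch Adam (β₁ 0.9, β₂ 0.999, batch 16) for a fixed number of
optimizer steps (default 1000; the step/epoch equivalence is recorded
in the model). The filter counts, kernel width, dense width and
padding mode are architecture choices of this package, config-exposed;
a progress callback receives `(step, loss)` each step and may stop
training, which is the scriptable analogue of an interactive pause
button. All gradients — convolution, pooling routing, dense layers —
are validated against central finite differences at 1e-6 relative
tolerance.

# Evaluation

Six statistics per (y, ŷ) pair: SSE, MSE = SSE/n (divisor n, not
n − 1), RMSE = √MSE, MAE, R² = 1 − SSE/Σ(yᵢ−ȳ)², and the Pearson
correlation COR. R² is negative whenever the model is worse than
predicting the mean — a regime that genuinely occurs with weak in vivo
calibrations and that the reports surface rather than clip. COR is
reported as `NA` when either variance term is zero (e.g. a constant
predictor); R² is `NA` when y itself is constant. The implementation
is checked against a naive summation oracle at 1e-12 on a thousand
random pairs.

# Persistence

A model archive is one JSON document: format tag, integer version,
family, target unit, the preprocessing configuration the model was
trained behind, and the numeric payload with array shapes. Numbers are
written as `%.17g`, which round-trips IEEE doubles exactly — a loaded
model predicts bit-identically. (The same writer backs the spectra
container.) Version or family mismatches and corrupt files produce
explicit errors. No code is serialized, so archives are safe to share.
The one non-deterministic archive field is the creation timestamp;
evaluation reports contain no timestamps, so a seeded run's reports
are byte-reproducible.

# The synthetic dataset

`simulateNailfold()` emulates the structure of a small in vivo glucose
study: 15 subjects × 7 spectra (105 raw), 1024 points over 800–1800
cm⁻¹, and a curated 75-spectrum subset. Each spectrum is the exact sum
of four recorded components:

* fixed tissue bands at 1003/1305/1450/1655 cm⁻¹ — generic Raman
  features (phenylalanine-like, CH-deformation-like, CH₂-bending-like,
  amide-I-like regions) chosen as plumbing, not as a claim about any
  particular tissue;
* a glucose band at 1125 cm⁻¹ (σ = 8 cm⁻¹) with height β·c, β = 1 a.u.
  per mmol/L, c uniform in 4.6–10.0 mmol/L per spectrum;
* a broad smooth background `amp_subject · (1 − 0.55u + 0.15u²)`
  (u the normalized wavenumber), amplitude ~200 a.u. varying ±20% per
  subject — a declared stand-in for fluorescence, whose true functional
  form is not modelled;
* Poisson-count cosmic-ray spikes (rate 0.5/spectrum, 50–150 a.u.) and
  i.i.d. Gaussian noise (SD 0.5 a.u.).

The curated subset keeps the spectra with the smallest injected-noise
norm — an explicit, mechanical stand-in for qualitative quality
screening. Because the ground truth is returned alongside, tests can
verify conservation (components sum to the emitted spectrum exactly),
band-height linearity in c, and end-to-end recovery.

What the simulator does **not** model: photon shot noise (noise is
additive Gaussian, not Poisson), instrument response and wavenumber
calibration drift, subject physiology (targets are independent of the
background), water/matrix interference, and any nonlinearity between
concentration and band height. Passing the recovery tests therefore
shows that the pipeline retrieves a linear, band-localized signal from
under a smooth background at realistic SNR — it does not certify
performance on real nailfold data, where published calibrations of
this kind report far larger errors and even negative held-out R².

# Problem sizes and determinism

The test suite and the acceptance script run at desk scale by design:
the study-sized 75-spectrum layout for protocol checks and model runs,
200 simulated spectra (29 subjects) for the PLSR recovery experiment,
40 two-profile mixtures for the noiseless recovery bound, and reduced
architectures (e.g. 16–128 point grids, 2-block CNNs) for gradient
verification, where finite differences are exact science but O(P²)
work. Every stochastic stage takes an explicit integer seed, and the
orchestration layer derives per-stage seeds from one global seed, so a
configuration file plus a seed reproduces a run byte-for-byte.

# Known limitations

* The MLP optimizer is plain gradient descent (by design, matching the
  classic shallow-network recipe); it can need many more than the
  default 100 epochs on high-dimensional inputs.
* The CNN runs on CPU in plain R; it is sized for hundreds of spectra,
  not tens of thousands.
* EMSC's default reference is the mean of the dataset being corrected;
  when applying an archived model to new data the reference is the new
  data's own mean, which is the standard choice but does couple the
  correction to the prediction batch.
* The SVR duality gap reported by `svrOptimalityGap()` inherits the
  solver tolerance; at extreme C values tighten `tolerance`
  accordingly.
* Only single-response regression is supported (no multi-analyte PLSR,
  no ν-SVR, no classification).
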