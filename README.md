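# RamanQuant

Quantitative regression modelling of Raman spectra, end to end: load
spectra, clean them up, train a calibration model, evaluate it, save it,
and predict on new measurements. The package targets biomedical
chemometrics workflows such as non-invasive blood glucose estimation
from in vivo nailfold spectra, where a weak analyte band (glucose near
1125 cm⁻¹) must be recovered from underneath a strong fluorescence
background, cosmic-ray spikes and detector noise, with only a small
number of calibration spectra.

It is written for spectroscopists and chemometricians who want a
scriptable, fully reproducible alternative to GUI toolboxes: every
stage is a plain R function on an S4 container, every stochastic step
is seeded, and models persist as portable JSON archives.

## What it does

**Data model.** `RamanSpectra` extends `SummarizedExperiment`: an
M × N intensity matrix (one spectrum per column), the M wavenumbers
(cm⁻¹) in `rowData`, per-spectrum regression targets and ids in
`colData`. Spectra load from two-column text files in batches
(`readSpectraBatch()`) or from a single JSON matrix container
(`readSpectraContainer()`), which round-trips bit-exactly.

**Preprocessing** (`runPreprocessChain()`), in fixed order: crop →
interpolate onto a target grid → median despike (cosmic rays) →
baseline correction (iterative "clip-to-fit" polynomial, or EMSC:
x = b·m + Σₖ pₖwᵏ + e against a reference m) → Savitzky–Golay
smoothing → optional area normalization (Σᵢ Iᵢ = 1).

**Partitioning and augmentation.** `splitDataset()` draws a seeded
prediction set (default 10 spectra), then splits the remainder 80/20
into training and test sets. `augmentStdShift()` grows the training
set by a factor (default 4×) with copies displaced by multiples of the
per-wavenumber standard deviation σ(w): copy k of x is x + cₖσ,
cₖ ∈ {+s, −s, +2s, −2s, …} (a stochastic Gaussian-scaled variant is
available).

**Four model families**, common `predict()` contract:

| family | core | fit |
|---|---|---|
| PLSR | Y = X·B + E, NIPALS latent variables | `fitPlsr()`, count chosen by CV (`selectPlsrComponents()`) |
| ε-SVR | min ½‖w‖² + C Σ(ξᵢ+ξᵢ*), \|g(xᵢ)−yᵢ\| ≤ ε + slack | `fitSvr()`, linear/Gaussian kernels, `gridSearchSvr()` |
| MLP | purelin(W₂ tansig(W₁x̃+b₁)+b₂), backprop gradient descent, early stop on a loss goal | `fitMlp()` (defaults: 4 hidden neurons, 100 epochs, lr 0.001, goal 1e-4) |
| 1D CNN | 4 × [conv(same) → ReLU → maxpool(2)] → dense → 1 neuron, Adam | `fitCnn()` (defaults: 1000 steps, lr 0.001, batch 16) |

**Evaluation.** `computeMetrics()` / `evaluateModel()` return the six
standard statistics — SSE, MSE (= SSE/n), RMSE, MAE, R² (may be
negative), and Pearson COR — as an `EvaluationReport`, serializable as
JSON or an aligned text table.

**Persistence.** `saveModel()` / `loadModel()` write one
self-describing JSON archive per model (family tag, format version,
full-precision payload, preprocessing provenance); a loaded model
predicts identically to the saved one, and no executable code is ever
serialized.

**Synthetic data.** `simulateNailfold()` generates a study-sized
dataset — 15 subjects × 7 spectra on a 1024-point 800–1800 cm⁻¹ grid,
glucose targets uniform in 4.6–10.0 mmol/L (82.8–180 mg/dL), a
glucose band at 1125 cm⁻¹, per-subject fluorescence background,
Poisson cosmic-ray spikes, Gaussian noise, and a curated 75-spectrum
subset — returning the exact per-component ground truth alongside, so
recovery can be tested without any external data.

**Orchestration.** `cmdTrain()`, `cmdPredict()`, `cmdSimulate()` run
the whole workflow from one YAML/list configuration, writing model
archives, reports, training curves and a resolved-config snapshot that
reproduces the run byte-for-byte. A thin command-line front end ships
at `inst/cli/ramanquant` (subcommands `simulate`, `train`, `predict`,
`preprocess`, `split`, `augment`, `evaluate`; exit codes 0/1/2).

## Worked example

```r
library(RamanQuant)

sim <- simulateNailfold(simConfig(seed = 1))
sim$curated
#> RamanSpectra: 1024 wavenumber points x 75 spectra
#>   range: 800.0-1800.0 cm^-1
#>   targets [mmol/L]: 75 known, 4.67-9.96

pp    <- runPreprocessChain(sim$curated)          # despike, baseline, smooth
parts <- splitDataset(pp$dataset, splitSpec(nPrediction = 10, seed = 2))
sel   <- selectPlsrComponents(parts$train, seed = 3)
model <- fitPlsr(parts$train, ncomp = sel$ncomp)
model
#> PLSRModel (NIPALS): 2 latent variable(s), 1024 spectral channels

evaluateModel(model, parts$test, "test")
#> partition  n   SSE     MSE     RMSE    MAE     R2      COR
#> test       13  0.3550  0.0273  0.1653  0.1424  0.9877  0.9980
evaluateModel(model, parts$prediction, "prediction")
#> partition   n   SSE     MSE     RMSE    MAE     R2      COR
#> prediction  10  0.2599  0.0260  0.1612  0.1367  0.9824  0.9957
```

The 75 curated spectra split 52/13/10 (train/test/prediction);
cross-validation picks 2 latent variables, and the held-out prediction
set is recovered with RMSE ≈ 0.16 mmol/L and R² ≈ 0.98 — the glucose
information injected by the simulator is fully retrievable once the
background is removed. On real in vivo spectra, with physiological
confounders and far lower signal-to-noise, errors are substantially
larger; the pipeline and reports behave identically.

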