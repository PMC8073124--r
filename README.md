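# irpreproc

Benchmarking preprocessing pipelines for FT-IR absorbance spectra of single
cells.

Infrared microspectroscopy produces one absorbance spectrum per cell —
protein Amide bands, nucleic-acid phosphate bands, lipid CH stretches —
distorted by baseline drift, oscillatory Mie-scattering extinction,
multiplicative scaling, atmospheric CO₂/water-vapor lines, and noise that
scales as 1/√scans. Which denoising, baseline-correction, and
normalization methods are applied, and in what order, decides how well a
downstream classifier or regression model performs. `irpreproc` is a
harness for comparing those choices systematically, for spectroscopists
and chemometricians who want the whole method × parameter grid evaluated
rather than a single hand-picked pipeline.

## What it implements

* **Denoising**: Whittaker/Eilers smoothing
  (min Σ(yᵢ−zᵢ)² + λΣ(Δ²zᵢ)², λ = 2..24), Savitzky–Golay ({2,3} × frames
  11..29), Fourier low-pass (windows {100, 320}).
* **Baseline correction**: Savitzky–Golay second derivative ({2,3} ×
  frames 19..29), rubber-band over nine anchor frequencies, anchored
  polynomial (degrees 3..5), asymmetric least squares (p = 0.1,
  λ = 10⁶..10⁸, weights p / 1−p above/below the baseline), and two
  iterative Mie-extinction EMSC variants whose interferent subspace is a
  PCA compression of van de Hulst extinction curves
  Q(ρ) = 2 − (4/ρ)sin ρ + (4/ρ²)(1 − cos ρ) built from a Kramers–Kronig
  estimate of the reference's refractive-index fluctuation.
* **Normalization**: to the Amide I band at 1656 cm⁻¹ (CON), total sum
  (TSN), probabilistic quotient xₙ = xᵢ / median(xᵢ/xₛ) (PQN).
* **Chemometrics**: per-class Kennard–Stone 75/25 splitting, NIPALS PLS,
  PLS-DA via five one-vs-all indicator models with argmax assignment,
  PLSR on a −2..2 malignancy coding, LOOCV latent-variable selection
  (lowest RMSECV with a local-minimum override; highest accuracy), RMSECV
  / RMSEP / accuracy.
* **Grid runner**: the full 45 × 21 × 3 = 2835 combination grid, model
  and test sets preprocessed independently, optional 32-scan noise pass,
  per-combination caching, PCA exploration and summary tables/plots.
* **Synthetic study generator**: 48 class-structured cell spectra
  (classes of 14/7/7/10/10, 1582 points over 900–3800 cm⁻¹) with
  baseline, fringe, artifact and noise distortions and exact ground truth
  retained for testing — measured spectra of this kind are not publicly
  deposited.

## Worked example

```r
library(irpreproc)

study <- generate_study(seed = 1)
study
#> <spectra_set> 48 spectra x 1582 wavenumbers [900, 3800] cm^-1
#>   classes: 22Rv1:7, Du145:10, LNCaP:10, PC3:7, RWPE-1:14

split <- kennard_stone_split(study)   # deterministic max-min selection
table(split$subset)
#> model  test
#>    34    14

combos <- enumerate_combinations(default_grid())
nrow(combos)
#> [1] 2835

pair <- split_spectra(study, split)
co <- combos[combos$denoise_method == "SG" &
             combos$baseline_method == "ALS" &
             combos$normalize_method == "CON", ][1, ]
run_combination(pair$model, pair$test, co, "classification")
#>   denoise                    baseline                normalize chosen_lv internal external
#> 1 SG(poly_degree=2,frame=11) ALS(lambda=1e+06,p=0.1) CON               5    0.941    0.929
```

The record reads: with Savitzky–Golay denoising (degree 2, 11-point
frame), ALS baseline correction (λ = 10⁶), and Amide I normalization, the
LOOCV on the 34-spectrum calibration set selected 5 latent variables at
94.1% internal accuracy, and the fitted classifier assigned 92.9% of the
14 held-out spectra to the right cell class. The same call with
`task = "regression"` returns RMSECV 0.281 / RMSEP 0.442 on the −2..2
class coding. `run_grid()` produces one such record per combination ×
task; `summarize_mean_errors()`, `summarize_threshold_counts()` and
`summarize_best_decile()` aggregate them, each with a `plot_*`
companion.

A thin CLI over the same functions lives at `inst/cli/irgrid.R`
(`generate`, `addnoise`, `preprocess`, `grid`, `report` subcommands).

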