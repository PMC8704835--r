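# specbase

Baseline correction for Raman spectra by joint subspace estimation, with
the classical correctors, detection metrics and a synthetic benchmark to
compare them.

## The problem

Stand-off Raman detection of chemicals measures a spectrum that is the sum
of sharp Raman peaks, a large smooth fluorescence *baseline*, and noise:

    x = t + b + n,    t = S g + K_bg y_bg,    n ~ N(0, γΣ)

where `S` (p×C) holds known reference spectra of the target analytes and
`K_bg` (p×M) a basis of background-material signatures.  Detectors such as
the adaptive subspace detector (ASD) assume the *corrected* spectrum
`x' = x − b` follows this linear subspace model; baseline residue degrades
them, and classical smoothing-based correctors distort weak peaks at low
signal-to-noise ratio.

`specbase` removes the baseline by spanning it with L **broad Gaussian
vectors** `K_bl` — Gaussians much wider than any Raman peak, centers
pinned to the grid endpoints and equally spaced, width tied to the spacing
so neighbours overlap at exactly 1/2 — and estimating signal and baseline
**jointly** by least squares on the augmented model:

    x = [S, K_bg, K_bl] y' + n,    b̂ = K_bl ŷ_bl,    x' = x − b̂

On the default 375–3500 cm⁻¹ / 947-channel grid with L = 11 this gives a
center spacing of 312.5 cm⁻¹ and a width of ≈265 cm⁻¹.  Five comparator
correctors (iterative median filter, rolling circle filter, ALS, AirPLS,
ArPLS), the RMSME modelling-error metric, the ASD statistic and ROC
evaluation, and a seeded synthetic-scene generator round out the package.

## Worked example

```r
library(specbase)

grid  <- make_grid(375, 3500, 947)                     # survey axis
study <- simulate_study(grid, study_config(n_h1 = 20, n_h0 = 40), seed = 7)
basis <- build_gaussian_basis(grid, 11)

fit <- fit_lsm_baseline(study$h1[[1]]$x, study$refs, study$bg, basis)
print(fit)
#> Joint subspace (LSM) baseline fit
#>   model: C = 7 references, M = 6 background bases, L = 11 Gaussians
#>   condition number of K': 38.8
#>   residual norm: 32.24
#>   reference intensities g:
#>  target  agentB  agentC  agentD  agentE  agentF  agentG
#>  6.2730  0.4229 -0.8262  0.8313  0.4523  0.7627 -0.9664
```

The scene contains the target at intensity ≈6 (signal-to-noise ratio 5
with 20% amplitude jitter); the fitted `target` coefficient recovers it
while the distractor coefficients stay near zero.  `plot(fit)` overlays
the measured spectrum, the estimated baseline and the corrected spectrum;
`fitted()`/`residuals()` return baseline and corrected values.

Correction drops the modelling error to the noise floor and separates the
detection statistic:

```r
m <- rmsme(fit$corrected, study$refs, study$bg)
m$rmsme                                   # 1.048 (raw spectrum: 5.398)

fits_h1 <- correct_batch(lapply(study$h1, `[[`, "x"), study$refs, study$bg, basis)
fits_h0 <- correct_batch(lapply(study$h0, `[[`, "x"), study$refs, study$bg, basis)
t1 <- sapply(fits_h1, function(f) asd_statistic(f$corrected, study$refs, study$bg)$statistic)
t0 <- sapply(fits_h0, function(f) asd_statistic(f$corrected, study$refs, study$bg)$statistic)
round(c(mean_T_present = mean(t1), mean_T_absent = mean(t0)), 3)
#> mean_T_present  mean_T_absent
#>          0.489          0.019
roc_curve(t1, t0)
#> ROC curve: 20 H1 + 40 H0 statistics, AUC = 1.0000
```

The same statistics on the *uncorrected* spectra give AUC 0.47 — the
baseline alone destroys detection on these scenes.

`evaluate_correctors(study)` benchmarks all seven methods (`none`, `imf`,
`rcf`, `als`, `airpls`, `arpls`, `lsm`) in one table of mean RMSME and
AUC; `sweep_gaussian_count(study, c(5, 11, 30))` sweeps the number of
Gaussian vectors.  A command-line front end with `simulate`,
`build-background`, `correct`, `detect`, `roc`, `evaluate` and `sweep-L`
subcommands lives at `inst/cli/specbase.R`
(`Rscript inst/cli/specbase.R correct --method lsm --refs refs.csv
--background bg_basis.csv input.csv -o corrected.csv`).
See the vignette (`vignettes/baseline-correction.Rmd`) for the model,
design rules, generator assumptions and known limitations.

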