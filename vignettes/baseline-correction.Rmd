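---
title: "Baseline correction for Raman spectra by joint subspace estimation"
author: "specbase"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Baseline correction for Raman spectra by joint subspace estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 4)
library(specbase)
```

## The problem

A Raman spectrometer pointed at a surface returns, per wavenumber channel
$\nu_i$ (cm$^{-1}$), an intensity that superposes three things: the sharp
Raman scattering peaks of whatever chemicals are present, a smooth and often
large *baseline* caused chiefly by fluorescence, and instrument noise.
Writing the measured spectrum as a vector $x \in \mathbb{R}^p$,

$$x = t + b + n, \qquad t = S\,g + K_{bg}\,y_{bg}, \qquad
  n \sim \mathcal{N}(0, \gamma\Sigma),$$

where $S$ ($p \times C$) holds known reference spectra of the target
analytes, $K_{bg}$ ($p \times M$) a basis for background-material
signatures, $g$ and $y_{bg}$ the corresponding intensities, $b$ the
baseline, and $\Sigma$ a diagonal matrix of per-channel noise variances.
Downstream detectors assume the *corrected* spectrum $x' = x - b$ follows
this linear subspace model; any baseline residue left in $x'$ violates the
model and costs detection performance.  The package's purpose is to
estimate $b$ while distorting $t$ as little as possible.

## The subspace corrector

Raman peaks are narrower than about 350 cm$^{-1}$; baselines are much
smoother.  The corrector exploits this by spanning baselines with $L$
*broad Gaussian vectors* $K_{bl}$ ($p \times L$), with element
$(i, l) = \exp\!\big(-(\nu_i - m_l)^2 / 2\sigma^2\big)$, and estimating
everything at once by least squares on the augmented model

$$x = [\,S, K_{bg}, K_{bl}\,]\, y' + n
    = K' y' + n, \qquad
  \hat b = K_{bl}\, \hat y_{bl}, \qquad x' = x - \hat b .$$

Because signal and baseline are estimated *jointly*, a weak peak is not
mistaken for baseline the way curvature-based smoothers can at low
signal-to-noise ratio.

The Gaussian design has two rules, both driven by the single integer $L$:

* **Centers.** $m_1 = \nu_1$ and $m_L = \nu_p$ exactly, equally spaced in
  between: $m_l = \nu_1 + (\nu_p - \nu_1)(l-1)/(L-1)$.  Pinning the
  endpoints keeps coefficients stable when the baseline rises toward an
  edge of the measured band.
* **Width.** $\sigma = \Delta m \sqrt{1 / (2\ln 2)}$ with
  $\Delta m = (\nu_p - \nu_1)/(L-1)$, so that each vector decays to exactly
  $1/2$ at its neighbours' centers.  We parameterise the width by the
  $\sigma$ in the exponent; the scale factor is exposed as `width_scale`
  for users who prefer another overlap convention.

On the default survey grid (375–3500 cm$^{-1}$, 947 channels, 3.3 cm$^{-1}$
per channel) and the default $L = 11$ this gives $\Delta m = 312.5$ and
$\sigma \approx 265$ cm$^{-1}$:

```{r design}
g <- make_grid(375, 3500, 947)
gb <- build_gaussian_basis(g, 11)
c(spacing = gb$delta_m, sigma = gb$sigma)
matplot(g$nu, gb$K, type = "l", lty = 1, xlab = "Raman shift (cm^-1)",
        ylab = "basis value")
```

Raising $L$ narrows the Gaussians; once $\sigma$ drops below
$350/(2\ln 2) \approx 250$ cm$^{-1}$ the basis can absorb genuine Raman
peaks, so `gaussian_width()` warns below that floor (a warning, not an
error — the bound is a guideline).

Numerically, `fit_lsm_baseline()` solves the least-squares problem by QR
factorisation of $K'$, never by inverting $K'^\top K'$ (which squares the
condition number).  The linear independence of the blocks is verified: a
condition number above `cond_threshold` (default $10^{10}$) aborts with a
message naming the blocks, rather than silently regularising.  Passing a
`noise_model` switches to generalized least squares by row-scaling with
$1/\sigma_i$; the default is ordinary least squares, matching the detection
model as usually stated.  No nonnegativity constraint is imposed on
coefficients.

## The comparator correctors

Five classical correctors share the `baseline_fit` interface.  Their
default parameters are the survey optima: IMF window 300 cm$^{-1}$ with 5
iterations, RCF radius 100 cm$^{-1}$, and penalties $\lambda = 1000$ (ALS),
$50$ (AirPLS), $200$ (ArPLS) with ALS asymmetry $\alpha = 0.01$.

* **IMF** — iterated sliding-window median.  The window is converted from
  cm$^{-1}$ to an odd channel count; edges are mirror-reflected (the
  classical references are silent on edge policy; reflection avoids edge
  droop).
* **RCF** — the lower envelope traced by a circle rolling beneath the
  spectrum, realised as a grayscale morphological opening with a
  semicircular structuring element.  The element's vertical semi-axis
  defaults to the spectrum's intensity range, making the element a true
  circle in (channel, normalised-intensity) coordinates; any symmetric
  element reproduces affine ramps exactly, and the default bridges peaks
  much narrower than the radius.
* **ALS / AirPLS / ArPLS** — all minimise
  $(x-b)^\top W (x-b) + \lambda\, b^\top D^\top D b$ with $D$ the
  $(p-2)\times p$ second-difference matrix, alternating the banded solve
  `pls_solve()` (sparse Cholesky via Matrix) with a weight update:
  ALS assigns $\alpha$ above the baseline and $1-\alpha$ below, stopping
  when the boolean above/below pattern repeats (a depth-2 history catches
  the 2-cycles this update admits);
  AirPLS zeroes weights above the baseline and uses
  $\exp(j\,d_i/\lVert d^-\rVert_1)$ below, stopping when
  $\lVert d^-\rVert_1 < 0.001\,\lVert x\rVert_1$;
  ArPLS keeps weight 1 below and a logistic weight
  $1/(1+\exp(2(d_i + m_{d^-} - 2\sigma_{d^-})/\sigma_{d^-}))$ above,
  stopping when the weight vector changes by less than $10^{-6}$
  relatively (at most 100 iterations).
  ArPLS presumes noise: on (near) noise-free input the spread
  $\sigma_{d^-}$ collapses and excluded edge channels would make the
  baseline extrapolate away from a curved truth, so when
  $\sigma_{d^-} < 10^{-3}\times$ the intensity range the fit is flagged
  degenerate, hard-threshold weights are substituted and the current
  (already essentially exact) baseline returned.

## Background basis and metrics

`build_background_basis()` follows the standard recipe: baseline-correct a
corpus of background measurements, stack the corrected spectra, and keep
the left singular vectors of the $M$ largest singular values.  Spectra are
*not* mean-centred (the basis must represent the background signal itself),
and each vector's sign is fixed so its largest-magnitude element is
positive.  The corrector used before the SVD is pluggable (default ArPLS);
inside the synthetic study we use a stiff $\lambda = 10^8$ so that the
pre-correction removes only baseline-scale smoothness while substrate
features narrower than the 350 cm$^{-1}$ bound survive into the basis.

Three evaluation tools quantify correction quality downstream:

* **RMSME** (`rmsme()`): the corrected spectrum is refit on
  $K = [S, K_{bg}]$ and the root mean square of the residual
  $n = x' - K\hat y$ reported.  Zero iff $x'$ lies in the known subspace.
* **ASD** (`asd_statistic()`): the GLRT statistic
  $T = (x'^\top P_{K_{bg}}^\perp x' - x'^\top P_K^\perp x') /
  (x'^\top P_K^\perp x')$, computed matrix-free through QR factorisations.
  Nesting of the subspaces makes $T \ge 0$, and the ratio is scale
  invariant.  The target is declared present when $T > \beta$ (the GLRT
  construction: large $T$ means the reference subspace explains extra
  energy).
* **ROC** (`roc_curve()`): thresholds swept over the pooled unique
  statistic values, strictly-greater convention, curve anchored at (0,0)
  and (1,1), AUC by the trapezoid rule.

## What the synthetic generator emulates

Instrument measurements for this problem are not distributable, so
`simulate_study()` generates ground-truth scenes with the exact additive
structure above.  Defaults follow the survey protocol: 500 target and 1000
target-free scenes on the 947-channel grid; a built-in library of $C = 7$
synthetic analyte signatures (the target has a dominant C–H-stretch-like
peak near 2930 cm$^{-1}$ and subpeaks at 500–1700 cm$^{-1}$); an $M = 6$
background basis estimated from a 40-spectrum corpus; heteroscedastic
noise whose variance profile decays smoothly from the low-wavenumber end
(shot-noise-like, median 1 so that $\gamma$ is the median variance).

Choices a user should know about, fixed once as study conditions:

* **SNR 5** — the target peak height equals 5 median noise standard
  deviations: the main peak is plainly visible, the subpeaks (10–55% of
  it) drown in the noise, which is the low-SNR regime of interest.
* **Baselines 2–6× the target peak**, drawn per scene from four families:
  `broad_gauss_mix` (inside the span of $K_{bl}$, for exact-recovery
  checks) and `poly`, `sigmoid`, `exp_decay` (outside it, exercising
  robustness).
* **One measurement site per study.**  A field campaign measures one
  background spot repeatedly; accordingly one realisation of the
  heterogeneous substrate/gas process (band centers jittered with sd 15
  cm$^{-1}$, widths ±20%, heights ±40%, stable O$_2$/N$_2$ lines near 1556
  and 2331 cm$^{-1}$) is shared by all scenes with ±10% per-scene amplitude
  drift, while the basis is estimated from a *held-out* corpus — so every
  spectrum carries the same systematic site-versus-basis mismatch, as
  with real data.

Not emulated: fluorescence photophysics, cosmic-ray spikes, wavelength
calibration error, detector nonlinearity, and real analyte spectra.
Passing benchmarks on these scenes therefore demonstrate correct
estimation under the stated model, not field performance.

## Reading the benchmark, and two honest caveats

`evaluate_correctors()` reports mean RMSME (target and target-free scenes
separately) and ASD AUC per corrector; `sweep_gaussian_count()` sweeps
$L$.  Two structural properties of the RMSME metric on synthetic scenes
deserve emphasis, because they make some orderings differ from what one
sees on instrument data:

1. **RMSME is monotone in the span.**  When the corrector and the metric
   share $K$, the corrected spectrum is $x' = K\hat g + r$ with $r$ the
   joint residual and $r \perp \mathrm{span}(K)$, so the metric returns
   exactly $r$: RMSME at $L$ is the distance from $x$ to
   $\mathrm{span}([S, K_{bg}, K_{bl}(L)])$.  Under the fixed width rule a
   larger $L$ spans smooth functions at least as well, so the $L$-sweep
   decreases toward large $L$ instead of showing an interior minimum; the
   overfitting cost of large $L$ shows up as *distortion of the corrected
   spectrum*, not as modelling error.
2. **Flexible smoothers absorb noise.**  A Whittaker smoother at
   $\lambda = 200$ has far more effective degrees of freedom than 11 broad
   Gaussians and removes part of the *noise* along with the baseline, so
   ArPLS can report an RMSME slightly below the white-noise floor while
   simultaneously destroying the weak target peak.  On these scenes its
   detection AUC falls below even the uncorrected spectra, the clearest
   illustration that modelling error and detection utility are different
   questions — the AUC column is the one that matters for detection.

The subspace corrector is the only method here that is simultaneously at
the noise floor on RMSME and at the top of the AUC column.

For test and acceptance runs the study is scaled to 100 target + 200
target-free scenes (the orderings above are stable at that size, and the
full default study is a one-line change); solver-equivalence checks use
100 random instances at $p \le 60$ against dense oracles.

## Degenerate inputs and numerical conventions

* Grids must be strictly increasing and uniform (tolerance $10^{-9}$
  relative); every operation checks grid identity by the (min, max, $p$)
  triple and fails fast on mismatch.
* `pls_solve` rejects all-zero weights ($D^\top D$ has rank $p-2$).
* `asd_statistic` returns `Inf` with an `in_span` flag when $x'$ lies in
  $\mathrm{span}(K)$, and rejects identically zero input.
* Width/radius parameters given in cm$^{-1}$ convert to channels by
  `round(width / spacing)` with a minimum of 1 (odd counts for medians).
* Tiny negative ASD numerators arising from roundoff on nested
  projections are clamped to zero.
* All generators take seeds and restore the caller's RNG state.

## Limitations

The corrector requires the reference library and background basis — it
cannot run blind, and a background vector resembling a broad Gaussian
makes the augmented model degenerate (reported, not regularised).  The
Gaussian centers are fixed and equally spaced; data-adaptive placement and
non-Gaussian smooth bases are out of scope, as are other correctors (SNIP,
polynomial fitting, wavelets) and detector families beyond the ASD.
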