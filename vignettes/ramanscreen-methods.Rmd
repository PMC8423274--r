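---
title: "Frequency-selective correlation screening of serum Raman spectra: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-selective correlation screening of serum Raman spectra: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ramanscreen)
```

## The problem

Serum is a complex molecular mixture, and its Raman response at 780 nm
excitation is dominated by fluorescence: a broad, smooth background whose
between-measurement variation exceeds the Raman intensity differences one
is actually after. Individual analyte peaks that are prominent in dry
substances flatten out in solution. Any claim that a spectral cohort
carries marker information therefore has to survive three hazards at
once: the background must be removed without destroying the weak peaks;
the model must be expressive enough to pool information across several
frequencies; and the selection of those frequencies from thousands of
candidates must not manufacture correlation out of noise.

`ramanscreen` treats the three hazards as one pipeline with explicit
controls, and ships a generator of synthetic cohorts with known ground
truth so that every stage — and the pipeline end to end — is testable.

## The model

The cohort is an $n \times k$ matrix $\mathbf{S}$: $n$ spectra on a
shared wavenumber grid of $k$ points (default 3371 points over
50–3500 cm$^{-1}$). The column $\vec S_f$ at frequency $f$ is a
*spectral vector*; a laboratory marker $m$ contributes a vector
$\vec L_m$ over the samples where it was measured (markers differ in
availability, so each marker has its own $n_{\mathrm{spectra}}$).

Pairwise correlations
$c_{m,f} = \mathrm{Corr}(\vec L_m, \vec S_f)$ give a per-frequency
information map. They are rarely sufficient on their own — the final
score is the correlation of the marker with a linear combination of
spectral vectors,

$$ c_m = \mathrm{Corr}(\vec L_m,\; \mathbf{S}\,\vec\omega_m), $$

which is invariant to positive rescaling of the weight vector
$\vec\omega_m$, so only the weight *pattern* matters.

### Greedy selection and its controls

Weights are switched on greedily: candidates are visited in descending
$|c_{m,f}|$, each tentatively set to $\omega_f = c_{m,f}$, and kept only
if $c_m$ strictly increases. Two constraints act as the overfitting
controls:

* `max_vectors` (default 9): at most nine non-zero weights;
* `min_weight` (default 0.2): frequencies with $|c_{m,f}| < 0.2$ are
  never eligible. Since weights equal pairwise correlations, the
  eligibility floor and the minimum weight are one parameter.

Eligibility uses the absolute correlation with *signed* weights: a
frequency anti-correlated with the marker enters with a negative weight
and still raises $c_m$. This is the only convention under which the
linear combination benefits from anti-correlated frequencies; a
`positive_only` switch restricts eligibility for sensitivity analysis.

A Monte Carlo weight optimizer (`mc_optimize_weights()`) can fine-tune
the weights after selection — single-weight Gaussian perturbations,
accepted only on improvement. It is off throughout the marker analysis,
deliberately: see the negative control below.

### Significance

The achievable correlation under the null depends on the selection
capacity and the sample size, so significance is judged against a
simulated null: `build_null()` runs the identical protocol (pairwise
correlations, constrained greedy selection) for random target vectors
(default 100, i.i.d. standard normal; a uniform option exists) drawn
against the same spectral matrix, and records the final correlations.
The significance of an observed $c_m$ is

$$ z = \frac{|c_m - \mu|}{\sigma}, $$

with $\mu, \sigma$ the null mean and standard deviation. One null is
needed per combination of the number of non-zero weights and
$n_{\mathrm{spectra}}$. Null replicates for which no frequency reaches
`min_weight` are scored 0 — their best achievable correlation — and
counted, rather than dropped; dropping them would bias $\mu$ upward.

### The negative control

With 50 selectable frequencies, no weight floor and Monte Carlo
optimization, *purely random* target vectors on a filtered 234-spectrum
synthetic cohort reach mean correlations above 0.8
(`overfit_demo()`; the acceptance script recomputes this number). That
is the whole case for the controls: 9 of 3371 frequencies, a 0.2 weight
floor, and no weight optimization keep the same machinery honest.

### Consistency and validation

`subset_stability()` re-derives the model on random subsets (default
40% of the paired samples, 1000 replicates) and reports the mean and
standard deviation of the subset scores; a well-behaved marker has a
subset mean close to the full-data score with a small spread.
Replicates with no eligible frequency are excluded from the summary and
reported as a failure count.

`predict_raw()` transfers trained weights to new spectra
($\mathrm{raw} = \mathbf{S}\vec\omega$); `validate()` correlates raw
predictions with holdout laboratory values and refuses holdout sets that
share sample ids with the training cohort. Concentration scaling for
reference dilution series uses the sum-ratio rule
$s = \sum \mathrm{nominal} / \sum \mathrm{raw}$ over the non-blank
references — not least squares — so the scaled references sum exactly to
the nominal total; a least-squares option exists but is not the default.

## Background filtering

The baseline estimator is asymmetric least squares: minimize

$$ \sum_i w_i (y_i - z_i)^2 + \lambda \sum_i (\Delta^2 z_i)^2, \qquad
   w_i = \begin{cases} p & y_i > z_i \\ 1 - p & y_i \le z_i, \end{cases} $$

iterating the weights to a fixed point. With small $p$ (default 0.001)
the curve fits the lower envelope of the signal, which is what a
fluorescence background under positive Raman peaks requires. Defaults:
$\lambda = 10^5$ (in grid-index units), $p = 0.001$, at most 20
iterations; iteration stops exactly when the weight vector stops
changing, and ties $y_i = z_i$ take the below-curve weight $1-p$.

Numerics: the normal equations are pentadiagonal and are solved sparsely
(`Matrix`); a dense direct solve of the identical reweighted system
serves as the test oracle, with agreement required to $10^{-8}$ on
unit-scale signals (the operator is exactly offset- and
scale-equivariant, so unit scale is the meaningful place to apply an
absolute bound). The penalty is expressed in grid-index units: on a grid
with $r$ times coarser spacing, an equivalent physical stiffness needs
$\lambda$ scaled by $r^{-4}$, which the test helpers do when they work
on reduced grids.

The "rigid vs flexible" trade-off is exposed directly as $\lambda$:
higher stiffness removes less local structure (larger residual energy),
lower stiffness filters more aggressively. The package asserts this
ordering, approximate idempotence of filtering, and — on synthetic
cohorts — that filtering *improves* marker correlations, which is the
operational justification for the step.

## The synthetic cohort generator

`generate_cohort()` emulates the statistical structure the analysis
assumes, not the physics of the instrument:

* **Substances** are sets of Lorentzian lines (the standard shape for
  Raman lines; a Gaussian switch exists) plus a concentration-
  proportional fluorescence offset, so the clean signal is exactly
  linear in concentration. The default panel spans the regimes that
  matter: an abundant protein ("albumin", strong CH-stretch response), a
  strongly fluorescent pigment ("bilirubin"), a dilute small metabolite
  ("creatinine").
* **Concentrations** are log-uniform within configured per-substance
  ranges, with a configured correlation matrix imposed on the
  log-concentrations — clinical analytes are positive, right-skewed and
  co-vary in disease cohorts. Internally the Gaussian copula correlation
  is rank-adjusted ($2\sin(\pi\rho/6)$) so the *realized*
  log-concentration correlations match the configuration without bias;
  a Monte Carlo test checks this at $n = 1000$.
* **Background**: per spectrum, 2–4 broad random Gaussians plus a
  constant, scaled by a magnitude drawn around `background_scale`
  (default 2000 counts) with between-measurement spread
  `background_between_sample_sd` (default 600). The defaults keep the
  mean background above the largest possible Raman peak — the background
  dominates, as it must for the filtering stage to be doing real work.
* **Photobleaching**: a multiplicative attenuation ramping from 1500 to
  3000 cm$^{-1}$ (default 20% at the top), emulating the
  frequency-dependent signal loss of long exposures.
* **Frequency jitter**: each spectrum is shifted by a uniform draw in
  $\pm$`shift_max` (default 5 cm$^{-1}$) and re-interpolated onto the
  fixed grid, emulating day-to-day calibration drift.
* **Noise**: i.i.d. Gaussian counts (default sd 15).
* **Missingness**: optional per-marker fractions of blanked laboratory
  values, reproducing the varying per-marker $n_{\mathrm{spectra}}$ of
  real marker tables.

Everything is reproducible bitwise from the seed. `albumin_series()`
produces a controlled dilution series (one spectrum per concentration,
including blanks) with the same artifact model but single-session
variability: one shared background shape with small magnitude jitter and
no frequency shift by default — a deliberate idealization of a
measurement session on one carrier.

What the generator does *not* emulate: instrument response functions,
cosmic-ray spikes, wavelength-dependent detector efficiency, or any
physical scattering model. Passing tests on synthetic cohorts therefore
show that the pipeline recovers structure *of the assumed form* under
dominant background, jitter and noise — they do not certify performance
on any particular spectrometer's output.

## Numerical and design choices

* Quantitative background/noise magnitudes are not dictated by the
  qualitative regime being emulated; the defaults were fixed once to
  satisfy it (background dominant, peaks hidden in raw spectra but
  recoverable after filtering) and are not tuned per analysis.
* Greedy acceptance uses a strict-increase margin of $10^{-12}$ so float
  noise cannot switch weights on; candidate ties are broken toward the
  lower wavenumber, making runs deterministic.
* The greedy pass visits each candidate once, in order; it does not
  revisit frequencies rejected earlier after later acceptances. A
  revisiting variant could only score higher on training data — and
  would overfit more, so single-pass is also the conservative choice.
* Zero-variance spectral columns yield missing pairwise correlations
  (flagged, not fatal); a zero-variance combined vector makes the score
  undefined rather than arbitrary.
* Correlations require at least 3 paired samples; `pair()` refuses
  markers with fewer.
* Random draws everywhere (generator, nulls, subsets, Monte Carlo
  optimizer) are governed by explicit integer seeds.
* Degenerate inputs fail loudly with the offending sample or line named:
  non-finite intensities, spectra not covering the grid span, malformed
  text lines, non-PSD marker correlation matrices.

## Problem sizes used by the test suite

The suite exercises the full 234 × 3371 configuration where the claim
concerns it (the overfitting negative control and its capped
counterpart). The multi-seed end-to-end checks — embedded-substance
recovery over 20 independent train/holdout cohort pairs, and the
pure-noise control — run at 234 × 800 with the stiffness rescaled as
described above, and use 100 stability replicates per seed; these sizes
were chosen so the whole loop stays quick to iterate on while leaving
the per-seed statistics (z-values near 4.5, train/holdout gaps an order
of magnitude under the asserted bound) far from their thresholds. The
package defaults remain 100 null vectors and 1000 stability replicates.

## Known limitations

* No correction for inter-cohort frequency shifts is implemented: a
  model trained on one cohort is applied to a shifted cohort as-is. With
  few selected frequencies, shifts up to 5 cm$^{-1}$ measurably degrade
  transfer; the generator includes the jitter so this degradation is
  visible in holdout correlations rather than hidden.
* No multiple-testing correction is applied across markers screened in
  one report; the z-values are per-marker descriptive statistics, not
  family-wise error rates.
* The null reuses the observed spectral matrix (random targets, real
  columns), so it conditions on the cohort's spectral covariance rather
  than modelling it.
* No PCA, PLS, penalized regression or spectral deconvolution: at the
  signal-to-noise ratios this pipeline targets, the frequency-selective
  linear model with explicit capacity controls is the more robust tool,
  and those methods are intentionally out of scope.
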