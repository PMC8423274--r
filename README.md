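# ramanscreen

Untargeted screening of clinical laboratory markers against serum Raman
spectra.

Raman spectra of blood serum are dominated by a broad, between-measurement
variable fluorescence background; the sharp Raman lines of dissolved
analytes are buried in it. `ramanscreen` implements a frequency-selective
linear correlation pipeline for exactly this regime, for people evaluating
whether a spectral cohort carries quantitative information about laboratory
markers (bilirubin, albumin, creatinine, composite scores, ...):

1. **Background filtering.** Asymmetric least squares (AsLS) baseline
   estimation per spectrum: minimize
   `Σᵢ wᵢ(yᵢ − zᵢ)² + λ Σᵢ(Δ²zᵢ)²` with `wᵢ = p` where `yᵢ > zᵢ` and
   `1 − p` otherwise, iterated to a fixed point. Small `p` makes the curve
   hug the lower envelope; `λ` is its stiffness. Solved on sparse banded
   normal equations.
2. **Frequency-selective linear model.** With the cohort as an `n × k`
   matrix **S** (rows = samples, columns = spectral vectors `S_f`) and a
   marker vector `L_m`, pairwise correlations `c_{m,f} = Corr(L_m, S_f)`
   seed a greedy selection: weights are switched on at their pairwise
   correlation value, in descending `|c_{m,f}|`, kept only if the combined
   score `c_m = Corr(L_m, S·ω)` strictly increases, capped at
   `max_vectors` (default 9) with a minimum weight of 0.2.
3. **Overfitting controls.** The capacity cap and weight threshold above;
   no weight optimization by default (a Monte Carlo weight optimizer
   exists, and the package can demonstrate why it must stay off: with 50
   frequencies and optimized weights, *purely random* target vectors reach
   mean correlations above 0.8).
4. **Significance.** Random-marker null distributions: the identical
   protocol is run for random target vectors; `z = |c_m − μ|/σ` against
   that null's mean and standard deviation.
5. **Consistency.** Subset-stability resampling: the model is re-derived
   on random 40% subsets (default 1000×) and the subset scores summarized
   as mean/stdev.
6. **Prediction.** Weight transfer to independent spectra
   (`raw = S·ω`), sum-ratio concentration scaling
   (`s = Σ nominal / Σ raw` over reference samples), and validation
   correlations on holdout cohorts with a train/holdout leakage guard.

Because real marker tables are clinical data, the package ships a
synthetic-cohort generator with the statistical structure the analysis
assumes — concentration-dependent Lorentzian peaks under a dominant smooth
fluorescence background, photobleaching, per-spectrum frequency jitter up
to 5 cm⁻¹, correlated marker values — so the whole pipeline is testable
against known ground truth.

## Worked example

```r
library(ramanscreen)

## a synthetic 234-sample serum cohort on the 3371-point grid
cohort <- generate_cohort(cohort_config(seed = 42))

## remove the dominant fluorescence background
filtered <- filter_dataset(cohort$dataset, asls_params())

## train a 9-frequency model for bilirubin
paired <- pair(filtered, cohort$markers, "bilirubin")
model  <- greedy_select(paired, constraints = selection_constraints())
model
#> <predictor_model> marker 'bilirubin': 9 frequencies, training r = 0.914 (n = 234)
#>  index wavenumber    weight
#>   1530   1615.297 0.7146668
#>   1531   1616.320 0.7063231
#>   1529   1614.273 0.6884962
#>   1528   1613.249 0.6572147
#>   1532   1617.344 0.6560792
#>   1174   1250.846 0.6512842
#>   1527   1612.226 0.6420925
#>   1526   1611.202 0.6406546
#>   1524   1609.154 0.6376508
```

The selected frequencies cluster at the generator's bilirubin bands
(1615 and 1250 cm⁻¹): the combination of several near-peak spectral
vectors lifts the score well above the best single pairwise correlation
(0.715 here). Significance, stability and independent validation:

```r
null <- build_null(filtered, n_random = 100, seed = 1)
z_value(model$training_correlation, null)
#> [1] 6.604116

stab <- subset_stability(paired, n_rep = 200, seed = 1)
stab
#> <stability_result> marker 'bilirubin', 200 x 40% subsets: 0.929 / 0.012 (0 failed)

holdout   <- generate_cohort(cohort_config(seed = 4242, id_prefix = "val"))
holdout_f <- filter_dataset(holdout$dataset, asls_params())
val <- validate(model, pair(holdout_f, holdout$markers, "bilirubin"))
val$correlation
#> [1] 0.9024372

report(models = list(bilirubin = model), nulls = list(bilirubin = null),
       stabilities = list(bilirubin = stab),
       validations = list(bilirubin = val))
#> Marker     Pearson  z-value  P40 mean/stdev  n_spectra  Validation  n_val
#> bilirubin  0.914    6.604    0.929 / 0.012   234        0.902       234
```

So the embedded marker trains at r = 0.914, is 6.6 null standard
deviations away from what random targets achieve under the identical
protocol, re-derives consistently on 40% subsets, and transfers to an
independent cohort at r = 0.902. A purely random "marker" run through the
same pipeline lands inside the null (z < 2) and fails validation — the
pattern that separates real from spurious correlations.

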