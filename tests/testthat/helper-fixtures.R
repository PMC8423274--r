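# Shared fixtures. Cohorts are generated in code (no stored data); expensive
# ones are memoised for the session so several test files can share them.

.fixture_cache <- new.env(parent = emptyenv())

memoise_fixture <- function(key, fn) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, fn(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

test_grid <- function(k = 300) seq(50, 3500, length.out = k)

# The AsLS penalty is expressed in grid-index units, so stiffness equivalent
# to the default 1e5 on the 3371-point grid scales with the fourth power of
# the grid-spacing ratio.
scaled_smoothness <- function(k, reference = 1e5, k_ref = 3371) {
  reference * (k / k_ref)^4
}

one_peak_profile <- function(center = 1000, fwhm = 20, amplitude = 1,
                             fluor = 0) {
  substance_profile("probe",
                    peaks = data.frame(center = center, fwhm = fwhm,
                                       amplitude = amplitude),
                    fluorescence_per_unit = fluor)
}

# Mid-sized cohort for generic pipeline tests (fast to generate and filter).
small_cohort <- function() {
  memoise_fixture("small_cohort", function() {
    cfg <- cohort_config(n_samples = 40, grid = test_grid(300), seed = 101)
    ch <- generate_cohort(cfg)
    ch$filtered <- filter_dataset(ch$dataset,
                                  asls_params(smoothness = scaled_smoothness(300)))
    ch
  })
}

# Larger cohort for resampling-behavior tests.
medium_cohort <- function() {
  memoise_fixture("medium_cohort", function() {
    cfg <- cohort_config(n_samples = 120, grid = test_grid(400), seed = 202)
    ch <- generate_cohort(cfg)
    ch$filtered <- filter_dataset(ch$dataset,
                                  asls_params(smoothness = scaled_smoothness(400)))
    ch
  })
}

# Full-size cohort at the working grid used by the end-to-end checks.
cohort_234 <- function(seed, id_prefix = "sample", k = 800) {
  cfg <- cohort_config(n_samples = 234, grid = test_grid(k), seed = seed,
                       id_prefix = id_prefix)
  ch <- generate_cohort(cfg)
  ch$filtered <- filter_dataset(ch$dataset,
                                asls_params(smoothness = scaled_smoothness(k)))
  ch
}

# Build a paired_data object directly from matrices (for toy instances).
toy_paired <- function(values, spectra, grid = seq_len(ncol(spectra)),
                       marker = "toy") {
  ids <- sprintf("s%02d", seq_len(nrow(spectra)))
  pair(spectral_dataset(ids, grid, spectra),
       marker_table(ids, stats::setNames(data.frame(values), marker)),
       marker)
}
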