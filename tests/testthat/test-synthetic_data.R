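test_that("substance_spectrum follows the Lorentzian closed form and is linear in concentration", {
  grid <- seq(900, 1100, by = 1)
  prof <- one_peak_profile(center = 1000, fwhm = 20, amplitude = 1)
  y1 <- substance_spectrum(prof, 1, grid)
  expect_equal(y1[grid == 1000], 1)
  # half height at one half-width from the center
  expect_equal(y1[grid == 1010], 0.5)
  expect_equal(y1[grid == 990], 0.5)
  expect_identical(substance_spectrum(prof, 0, grid), rep(0, length(grid)))
  expect_equal(substance_spectrum(prof, 2, grid), 2 * y1)
  expect_equal(substance_spectrum(prof, 7.25, grid), 7.25 * y1)
  # fluorescence adds a concentration-proportional constant offset
  prof_f <- one_peak_profile(fluor = 3)
  expect_equal(substance_spectrum(prof_f, 2, grid) -
                 substance_spectrum(prof, 2, grid),
               rep(6, length(grid)))
})

test_that("substance_spectrum gaussian option peaks at the same height", {
  grid <- seq(900, 1100, by = 0.5)
  prof <- one_peak_profile(center = 1000, fwhm = 20, amplitude = 2)
  y <- substance_spectrum(prof, 1, grid, shape = "gaussian")
  expect_equal(y[grid == 1000], 2)
  expect_equal(y[grid == 1010], 1)  # FWHM property
})

test_that("profile and spectrum inputs are validated", {
  expect_error(substance_profile("x", data.frame(center = 10, fwhm = 5,
                                                 amplitude = 1)),
               "within \\[50, 3500\\]")
  expect_error(substance_profile("x", data.frame(center = 100, fwhm = -1,
                                                 amplitude = 1)),
               "positive")
  expect_error(substance_profile("x", data.frame(center = numeric(0),
                                                 fwhm = numeric(0),
                                                 amplitude = numeric(0))),
               ">= 1 row")
  prof <- one_peak_profile()
  expect_error(substance_spectrum(prof, 1, numeric(0)), "empty")
  expect_error(substance_spectrum(prof, 1, seq(2000, 3000)), "outside")
  expect_error(substance_spectrum(prof, -1, seq(900, 1100)), "non-negative")
})

test_that("generate_cohort is bitwise reproducible from its seed", {
  cfg <- cohort_config(n_samples = 8, grid = test_grid(120), seed = 55)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$markers$values, b$markers$values)
  expect_identical(a$truth$concentrations, b$truth$concentrations)
  c2 <- generate_cohort(cohort_config(n_samples = 8, grid = test_grid(120),
                                      seed = 56))
  expect_false(identical(a$dataset$matrix, c2$dataset$matrix))
})

test_that("a degenerate artifact-free config reproduces the clean substance spectra", {
  prof <- one_peak_profile(center = 1200, fwhm = 30, amplitude = 2, fluor = 1)
  cfg <- cohort_config(
    n_samples = 5, grid = test_grid(200), substances = list(prof),
    marker_correlation = matrix(1, 1, 1, dimnames = list("probe", "probe")),
    concentration_ranges = data.frame(low = 1, high = 10),
    noise_sd = 0, background_scale = 0, background_between_sample_sd = 0,
    bleaching_slope = 0, shift_max = 0, seed = 9)
  ch <- generate_cohort(cfg)
  for (i in 1:5) {
    expect_equal(ch$dataset$matrix[i, ],
                 substance_spectrum(prof, ch$truth$concentrations[i, 1],
                                    test_grid(200)),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  # laboratory values are the true concentrations
  expect_equal(ch$markers$values$probe, unname(ch$truth$concentrations[, 1]))
})

test_that("generated log-concentrations recover the configured correlation matrix", {
  cfg <- cohort_config(n_samples = 1000, grid = test_grid(60),
                       substances = list(
                         one_peak_profile(600, 30, 1),
                         substance_profile("b", data.frame(center = 1500,
                                                           fwhm = 30,
                                                           amplitude = 1)),
                         substance_profile("c", data.frame(center = 2500,
                                                           fwhm = 30,
                                                           amplitude = 1))),
                       noise_sd = 0, background_scale = 0,
                       background_between_sample_sd = 0, bleaching_slope = 0,
                       shift_max = 0, seed = 314)
  ch <- generate_cohort(cfg)
  emp <- cor(log(ch$truth$concentrations))
  target <- cfg$marker_correlation
  # sampling error of a correlation at n = 1000 is about 0.03
  expect_lt(max(abs(emp - target)), 0.06)
  # concentrations stay inside the configured ranges
  rng <- cfg$concentration_ranges
  for (j in 1:3) {
    expect_true(all(ch$truth$concentrations[, j] >= rng[j, "low"]))
    expect_true(all(ch$truth$concentrations[, j] <= rng[j, "high"]))
  }
})

test_that("a non-PSD marker correlation matrix is rejected", {
  bad <- matrix(c(1, 0.9, -0.9,
                  0.9, 1, 0.9,
                  -0.9, 0.9, 1), 3, 3)
  cfg <- cohort_config(n_samples = 5, grid = test_grid(80),
                       marker_correlation = bad, seed = 1)
  expect_error(generate_cohort(cfg), "positive semi-definite")
})

test_that("the fluorescence background dominates the Raman peaks at default settings", {
  ch <- small_cohort()
  cfg <- cohort_config()
  max_peak_signal <- max(vapply(seq_along(cfg$substances), function(j) {
    max(cfg$substances[[j]]$peaks$amplitude) *
      cfg$concentration_ranges[j, "high"]
  }, 0))
  expect_gt(mean(ch$truth$baselines), max_peak_signal)
})

test_that("concentration structure is recoverable at a peak frequency under low noise", {
  # noise below 10% of the bilirubin 1615 cm^-1 peak's dynamic range
  grid <- test_grid(600)
  cfg <- cohort_config(n_samples = 234, grid = grid, noise_sd = 5, seed = 77)
  ch <- generate_cohort(cfg)
  filt <- filter_dataset(ch$dataset,
                         asls_params(smoothness = scaled_smoothness(600)))
  f <- which.min(abs(grid - 1615))
  r <- cor(filt$matrix[, f], ch$truth$concentrations[, "bilirubin"])
  expect_gt(r, 0.5)
})

test_that("albumin_series produces one spectrum per concentration with monotone offsets", {
  prof <- cohort_config()$substances[[1]]
  ds <- albumin_series(prof, c(0, 5, 10, 20), grid = test_grid(400), seed = 3)
  expect_equal(nrow(ds$matrix), 4L)
  expect_true(all(diff(rowMeans(ds$matrix)) > 0))
  empty <- albumin_series(prof, numeric(0), grid = test_grid(400))
  expect_equal(nrow(empty$matrix), 0L)
  expect_error(albumin_series(prof, c(-1, 2)), ">= 0")
})

test_that("albumin_series peak heights are proportional to concentration without artifacts", {
  grid <- test_grid(500)
  prof <- one_peak_profile(center = 1657, fwhm = 30, amplitude = 1)
  conc <- c(2, 4, 8)
  ds <- albumin_series(prof, conc, grid = grid, noise_sd = 0,
                       background_scale = 0, background_between_sample_sd = 0,
                       bleaching_slope = 0, shift_max = 0)
  f <- which.min(abs(grid - 1657))
  heights <- unname(ds$matrix[, f])
  expect_equal(heights / heights[1], conc / conc[1], tolerance = 1e-12)
})

test_that("per-marker missingness produces the configured n_spectra", {
  cfg <- cohort_config(n_samples = 234, grid = test_grid(80),
                       missing_fraction = c(bilirubin = 13 / 234), seed = 21)
  ch <- generate_cohort(cfg)
  expect_equal(sum(is.na(ch$markers$values$bilirubin)), 13L)
  pd <- pair(ch$dataset, ch$markers, "bilirubin")
  expect_equal(pd$n_spectra, 221L)
})
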