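#' Define a pure substance's spectral signature
#'
#' A substance is modelled as a set of Raman lines plus a concentration-
#' proportional fluorescence offset. Line positions are Raman shifts in
#' cm^-1; amplitudes are CCD counts per concentration unit, so the clean
#' substance signal is exactly linear in concentration.
#'
#' @param name Substance name (used as the marker name in generated cohorts).
#' @param peaks `data.frame` with columns `center` (cm^-1), `fwhm` (cm^-1,
#'   full width at half maximum) and `amplitude` (peak height per
#'   concentration unit). At least one peak is required.
#' @param fluorescence_per_unit Constant intensity offset contributed per
#'   concentration unit, emulating the substance's own fluorescence.
#' @return An object of class `substance_profile`.
#' @examples
#' substance_profile("albumin",
#'   peaks = data.frame(center = 1004, fwhm = 12, amplitude = 1))
#' @export
substance_profile <- function(name, peaks, fluorescence_per_unit = 0) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.data.frame(peaks) || nrow(peaks) < 1L ||
      !all(c("center", "fwhm", "amplitude") %in% names(peaks))) {
    stop("'peaks' must be a data.frame with >= 1 row and columns ",
         "'center', 'fwhm', 'amplitude'")
  }
  if (any(peaks$center < 50 | peaks$center > 3500)) {
    stop("peak centers must lie within [50, 3500] cm^-1")
  }
  if (any(peaks$fwhm <= 0)) stop("peak widths must be positive")
  if (!is.numeric(fluorescence_per_unit) || fluorescence_per_unit < 0) {
    stop("'fluorescence_per_unit' must be a non-negative number")
  }
  structure(
    list(name = name,
         peaks = peaks[, c("center", "fwhm", "amplitude")],
         fluorescence_per_unit = fluorescence_per_unit),
    class = "substance_profile")
}

# Lorentzian line: height `amp` at `center`, half height at center +/- fwhm/2.
lorentzian <- function(x, center, fwhm, amp) {
  g <- (fwhm / 2)^2
  amp * g / ((x - center)^2 + g)
}

gaussian_line <- function(x, center, fwhm, amp) {
  s <- fwhm / (2 * sqrt(2 * log(2)))
  amp * exp(-(x - center)^2 / (2 * s^2))
}

#' Evaluate a substance's clean spectrum at a given concentration
#'
#' Sum of the profile's peaks plus its fluorescence offset, scaled by the
#' concentration. Exactly linear in concentration; a concentration of zero
#' yields the all-zero vector.
#'
#' @param profile A [substance_profile()].
#' @param concentration Non-negative amount, in the profile's units.
#' @param grid Strictly increasing wavenumber vector (cm^-1).
#' @param shape Peak line shape, `"lorentzian"` (the usual model for Raman
#'   lines) or `"gaussian"`.
#' @return Intensity vector of `length(grid)`.
#' @export
substance_spectrum <- function(profile, concentration, grid,
                               shape = c("lorentzian", "gaussian")) {
  shape <- match.arg(shape)
  stopifnot(inherits(profile, "substance_profile"))
  if (length(grid) == 0L) stop("'grid' is empty")
  if (!is.numeric(concentration) || length(concentration) != 1L ||
      concentration < 0) {
    stop("'concentration' must be a single non-negative number")
  }
  span <- range(grid)
  if (any(profile$peaks$center < span[1] | profile$peaks$center > span[2])) {
    stop("peak center outside the span of 'grid' for substance '",
         profile$name, "'")
  }
  line_fun <- if (shape == "lorentzian") lorentzian else gaussian_line
  y <- rep(profile$fluorescence_per_unit, length(grid))
  for (i in seq_len(nrow(profile$peaks))) {
    p <- profile$peaks[i, ]
    y <- y + line_fun(grid, p$center, p$fwhm, p$amplitude)
  }
  concentration * y
}

#' Default serum-like substance panel
#'
#' Three analytes spanning the concentration regimes of clinical serum
#' markers: an abundant protein with strong CH-stretch response
#' ("albumin"), a strongly fluorescent pigment ("bilirubin") and a small
#' dilute metabolite ("creatinine"). Peak positions follow the usual
#' protein/pigment band assignments (phenylalanine ring breathing near
#' 1004 cm^-1, amide I near 1657 cm^-1, CH stretches near 2933 cm^-1, ...).
#'
#' @return List of [substance_profile()] objects.
#' @export
default_substances <- function() {
  list(
    substance_profile(
      "albumin",
      peaks = data.frame(
        center = c(1004, 1450, 1657, 2933),
        fwhm = c(14, 28, 32, 45),
        amplitude = c(0.9, 0.6, 0.7, 1.0)),
      fluorescence_per_unit = 15),
    substance_profile(
      "bilirubin",
      peaks = data.frame(
        center = c(1250, 1615),
        fwhm = c(22, 18),
        amplitude = c(0.12, 0.15)),
      fluorescence_per_unit = 2),
    substance_profile(
      "creatinine",
      peaks = data.frame(
        center = c(680, 846),
        fwhm = c(16, 13),
        amplitude = c(0.05, 0.07)),
      fluorescence_per_unit = 0.3))
}

#' Configuration of a synthetic serum cohort
#'
#' Bundles every knob of the generator: the wavenumber grid, the substance
#' panel, the correlation structure among log-concentrations, and the
#' measurement artifacts (fluorescence background, photobleaching,
#' frequency jitter, detector noise).
#'
#' Defaults emulate the qualitative regime of fluorescence-dominated serum
#' spectra: the smooth background (scale ~2000 counts, varying by ~600
#' counts between measurements) dwarfs the Raman peaks (tens of counts),
#' bleaching attenuates the 1500-3000 cm^-1 region, and each spectrum is
#' shifted by up to 5 cm^-1 of calibration jitter.
#'
#' @param n_samples Number of samples (>= 2).
#' @param grid Wavenumber grid; default 3371 evenly spaced points over
#'   \[50, 3500\] cm^-1.
#' @param substances List of [substance_profile()]s.
#' @param marker_correlation Symmetric unit-diagonal correlation matrix
#'   targeted for the log-concentrations (clinical analytes co-vary in
#'   disease cohorts).
#' @param concentration_ranges Matrix or data.frame with columns `low`,
#'   `high`, one row per substance.
#' @param noise_sd Standard deviation of i.i.d. additive detector noise.
#' @param background_scale Mean magnitude of the fluorescence background.
#' @param background_between_sample_sd Between-measurement standard
#'   deviation of the background magnitude.
#' @param bleaching_slope Fractional attenuation reached at 3000 cm^-1
#'   (ramping up from 1500 cm^-1), emulating photobleaching.
#' @param shift_max Maximum per-spectrum wavenumber jitter (cm^-1).
#' @param peak_shape `"lorentzian"` or `"gaussian"`.
#' @param missing_fraction Optional named vector of per-marker fractions of
#'   laboratory values to blank out (emulates markers not ordered for every
#'   patient).
#' @param id_prefix Prefix for generated sample ids (give training and
#'   holdout cohorts different prefixes so they are disjoint by id).
#' @param seed Integer RNG seed; the whole cohort is reproducible from it.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_samples = 234,
                          grid = seq(50, 3500, length.out = 3371),
                          substances = default_substances(),
                          marker_correlation = default_marker_correlation(),
                          concentration_ranges = default_concentration_ranges(),
                          noise_sd = 15,
                          background_scale = 2000,
                          background_between_sample_sd = 600,
                          bleaching_slope = 0.2,
                          shift_max = 5,
                          peak_shape = c("lorentzian", "gaussian"),
                          missing_fraction = NULL,
                          id_prefix = "sample",
                          seed = 1L) {
  peak_shape <- match.arg(peak_shape)
  if (!is.numeric(n_samples) || n_samples < 2) stop("'n_samples' must be >= 2")
  if (any(diff(grid) <= 0)) stop("'grid' must be strictly increasing")
  if (shift_max < 0) stop("'shift_max' must be >= 0")
  m <- length(substances)
  if (m < 1L) stop("at least one substance is required")
  mc <- as.matrix(marker_correlation)
  if (nrow(mc) != m || ncol(mc) != m) {
    stop("'marker_correlation' must be ", m, "x", m)
  }
  if (!isTRUE(all.equal(mc, t(mc))) || !isTRUE(all.equal(diag(mc), rep(1, m),
                                                         check.attributes = FALSE))) {
    stop("'marker_correlation' must be symmetric with unit diagonal")
  }
  cr <- as.matrix(as.data.frame(concentration_ranges)[, c("low", "high")])
  if (nrow(cr) != m || any(cr[, "low"] <= 0) || any(cr[, "high"] <= cr[, "low"])) {
    stop("'concentration_ranges' needs one row per substance with 0 < low < high")
  }
  structure(
    list(n_samples = as.integer(n_samples), grid = grid,
         substances = substances, marker_correlation = mc,
         concentration_ranges = cr, noise_sd = noise_sd,
         background_scale = background_scale,
         background_between_sample_sd = background_between_sample_sd,
         bleaching_slope = bleaching_slope, shift_max = shift_max,
         peak_shape = peak_shape, missing_fraction = missing_fraction,
         id_prefix = id_prefix, seed = as.integer(seed)),
    class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_marker_correlation <- function() {
  m <- matrix(c(1, -0.4, -0.2,
                -0.4, 1, 0.4,
                -0.2, 0.4, 1), 3, 3)
  dimnames(m) <- list(c("albumin", "bilirubin", "creatinine"),
                      c("albumin", "bilirubin", "creatinine"))
  m
}

#' @rdname cohort_config
#' @export
default_concentration_ranges <- function() {
  data.frame(low = c(18, 3, 40), high = c(55, 450, 650),
             row.names = c("albumin", "bilirubin", "creatinine"))
}

# Correlated concentrations: Gaussians with the rank-adjusted correlation
# 2*sin(pi*rho/6), mapped through pnorm to a log-uniform range. The adjustment
# makes the Pearson correlation of the *log-concentrations* equal the
# configured matrix (Pearson of uniforms from Gaussians is (6/pi)asin(rho/2)).
draw_concentrations <- function(config) {
  m <- length(config$substances)
  rho_z <- 2 * sin(pi * config$marker_correlation / 6)
  ch <- tryCatch(chol(rho_z), error = function(e) {
    stop("'marker_correlation' is not positive semi-definite ",
         "(after rank adjustment)")
  })
  z <- matrix(stats::rnorm(config$n_samples * m), config$n_samples, m) %*% ch
  u <- stats::pnorm(z)
  low <- config$concentration_ranges[, "low"]
  high <- config$concentration_ranges[, "high"]
  conc <- sweep(sweep(u, 2, log(high / low), `*`), 2, log(low), `+`)
  conc <- exp(conc)  # log-uniform in [low, high]
  colnames(conc) <- vapply(config$substances, `[[`, "", "name")
  conc
}

# Smooth per-spectrum fluorescence background: 2-4 broad Gaussians with
# random centers/widths plus a constant, all scaled by a per-measurement
# magnitude drawn around background_scale.
random_baseline <- function(grid, scale, between_sd) {
  mag <- max(scale + stats::rnorm(1, 0, between_sd), 0.05 * scale)
  n_bumps <- sample(2:4, 1)
  span <- range(grid)
  y <- rep(0.3, length(grid))
  for (b in seq_len(n_bumps)) {
    ctr <- stats::runif(1, span[1], span[2])
    wid <- stats::runif(1, 300, 1200)
    amp <- stats::runif(1, 0.2, 1)
    y <- y + amp * exp(-(grid - ctr)^2 / (2 * wid^2))
  }
  mag * y
}

# Photobleaching attenuation: unity below `from`, ramping linearly down to
# (1 - slope) at `to` and held beyond (the loss grows with wavenumber).
bleaching_factor <- function(grid, slope, from = 1500, to = 3000) {
  ramp <- pmin(pmax((grid - from) / (to - from), 0), 1)
  1 - slope * ramp
}

# Wavenumber jitter: the spectrum observed at x is the true signal at
# x - delta; values are re-interpolated back onto the fixed grid.
shift_spectrum <- function(y, grid, delta) {
  if (delta == 0) return(y)
  stats::approx(grid, y, xout = grid - delta, rule = 2)$y
}

#' Generate a synthetic serum cohort
#'
#' Draws correlated concentrations, sums the substance spectra, superposes a
#' dominant smooth fluorescence background, applies photobleaching and
#' per-spectrum frequency jitter, and adds detector noise. The true
#' concentrations are returned as the cohort's "laboratory values".
#'
#' @param config A [cohort_config()].
#' @return List with elements `dataset` (a [spectral_dataset()]), `markers`
#'   (a [marker_table()] of true concentrations) and `truth` (ground-truth
#'   concentrations, realized shifts and baselines).
#' @examples
#' cohort <- generate_cohort(cohort_config(n_samples = 10,
#'   grid = seq(50, 3500, length.out = 300), shift_max = 0, seed = 7))
#' dim(cohort$dataset$matrix)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n <- config$n_samples
  grid <- config$grid
  conc <- draw_concentrations(config)
  bleach <- bleaching_factor(grid, config$bleaching_slope)
  mat <- matrix(0, n, length(grid))
  baselines <- matrix(0, n, length(grid))
  shifts <- numeric(n)
  for (i in seq_len(n)) {
    signal <- rep(0, length(grid))
    for (j in seq_along(config$substances)) {
      signal <- signal + substance_spectrum(config$substances[[j]],
                                            conc[i, j], grid,
                                            shape = config$peak_shape)
    }
    base <- random_baseline(grid, config$background_scale,
                            config$background_between_sample_sd)
    y <- (signal + base) * bleach
    shifts[i] <- if (config$shift_max > 0) {
      stats::runif(1, -config$shift_max, config$shift_max)
    } else 0
    y <- shift_spectrum(y, grid, shifts[i])
    if (config$noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, config$noise_sd)
    mat[i, ] <- y
    baselines[i, ] <- base
  }
  ids <- sprintf("%s_%03d", config$id_prefix, seq_len(n))
  values <- as.data.frame(conc)
  if (!is.null(config$missing_fraction)) {
    for (nm in names(config$missing_fraction)) {
      fr <- config$missing_fraction[[nm]]
      if (!nm %in% names(values) || fr <= 0) next
      n_miss <- min(floor(fr * n), n - 3L)
      values[[nm]][sample.int(n, n_miss)] <- NA_real_
    }
  }
  list(dataset = spectral_dataset(ids, grid, mat),
       markers = marker_table(ids, values),
       truth = structure(list(concentrations = conc, shifts = shifts,
                              baselines = baselines, config = config),
                         class = "synthetic_truth"))
}

#' Generate a concentration-series dataset for one substance
#'
#' Emulates a controlled dilution experiment: one spectrum per requested
#' concentration (including zero for a blank), produced with the same
#' artifact model as [generate_cohort()] but with the low measurement
#' variability of a single session — small background variation and no
#' frequency jitter by default.
#'
#' @param profile A [substance_profile()].
#' @param concentrations Non-negative concentrations, one spectrum each.
#' @param grid Wavenumber grid.
#' @param noise_sd,background_scale,background_between_sample_sd,bleaching_slope,shift_max
#'   Artifact parameters as in [cohort_config()].
#' @param shape Peak line shape.
#' @param seed RNG seed.
#' @return A [spectral_dataset()] with one row per concentration (empty for
#'   an empty concentration list).
#' @export
albumin_series <- function(profile, concentrations,
                           grid = seq(50, 3500, length.out = 3371),
                           noise_sd = 2, background_scale = 500,
                           background_between_sample_sd = 20,
                           bleaching_slope = 0.2, shift_max = 0,
                           shape = c("lorentzian", "gaussian"), seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(inherits(profile, "substance_profile"))
  if (any(concentrations < 0)) stop("'concentrations' must be >= 0")
  set.seed(seed)
  n <- length(concentrations)
  mat <- matrix(0, n, length(grid))
  bleach <- bleaching_factor(grid, bleaching_slope)
  # one measurement session: a single carrier/solvent background shape whose
  # magnitude jitters slightly between acquisitions
  base_shape <- if (background_scale > 0) {
    random_baseline(grid, background_scale, 0)
  } else rep(0, length(grid))
  for (i in seq_len(n)) {
    signal <- substance_spectrum(profile, concentrations[i], grid, shape = shape)
    base <- if (background_scale > 0) {
      base_shape * max(1 + stats::rnorm(1, 0, background_between_sample_sd /
                                          background_scale), 0)
    } else base_shape
    y <- (signal + base) * bleach
    if (shift_max > 0) y <- shift_spectrum(y, grid, stats::runif(1, -shift_max, shift_max))
    if (noise_sd > 0) y <- y + stats::rnorm(length(grid), 0, noise_sd)
    mat[i, ] <- y
  }
  ids <- sprintf("conc_%g", concentrations)
  spectral_dataset(ids, grid, mat)
}
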