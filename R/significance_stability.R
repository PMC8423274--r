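#' Null distribution of correlations for random marker vectors
#'
#' Runs the identical selection protocol (pairwise correlations followed by
#' constrained greedy selection) for `n_random` random marker vectors drawn
#' against the given spectral matrix, and records the final training
#' correlations. One distribution is needed per combination of the number
#' of non-zero weights and the number of spectra; its mean and standard
#' deviation feed [z_value()].
#'
#' Replicates for which no frequency reaches `min_weight` score 0 (their
#' best achievable correlation) and are counted in `n_failed` rather than
#' dropped, so the null is not biased upward.
#'
#' @param dataset A [spectral_dataset()] (background-filtered, as in the
#'   marker analysis).
#' @param constraints [selection_constraints()] — the same used for the
#'   markers.
#' @param n_random Number of random marker vectors (default 100).
#' @param n_spectra Number of rows to use (default all); when smaller, the
#'   first `n_spectra` rows are taken so the null matches a marker's
#'   available-pair count.
#' @param seed RNG seed.
#' @param marker_dist Distribution of the random marker values:
#'   `"normal"` (standard normal) or `"uniform"`.
#' @return An object of class `null_distribution` with `samples`, `mu`,
#'   `sigma`, `n_vectors`, `n_spectra`, `n_failed`, `seed`.
#' @export
build_null <- function(dataset, constraints = selection_constraints(),
                       n_random = 100L, n_spectra = NULL, seed = 1L,
                       marker_dist = c("normal", "uniform")) {
  stopifnot(inherits(dataset, "spectral_dataset"),
            inherits(constraints, "selection_constraints"))
  marker_dist <- match.arg(marker_dist)
  n_all <- nrow(dataset$matrix)
  if (is.null(n_spectra)) n_spectra <- n_all
  if (n_spectra > n_all) stop("'n_spectra' exceeds the number of spectra")
  if (n_spectra < 3L) stop("'n_spectra' must be >= 3")
  S <- dataset$matrix[seq_len(n_spectra), , drop = FALSE]
  set.seed(seed)
  samples <- numeric(n_random)
  n_failed <- 0L
  for (r in seq_len(n_random)) {
    L <- if (marker_dist == "normal") stats::rnorm(n_spectra)
         else stats::runif(n_spectra)
    pd <- structure(list(marker = sprintf("random_%03d", r),
                         sample_ids = dataset$sample_ids[seq_len(n_spectra)],
                         spectra = S, values = L, grid = dataset$grid,
                         n_spectra = n_spectra,
                         provenance = dataset$provenance),
                    class = "paired_data")
    samples[r] <- tryCatch(
      greedy_select(pd, constraints = constraints)$training_correlation,
      error = function(e) {
        n_failed <<- n_failed + 1L
        0
      })
  }
  structure(list(samples = samples, mu = mean(samples),
                 sigma = stats::sd(samples),
                 n_vectors = constraints$max_vectors,
                 n_spectra = n_spectra, n_failed = n_failed,
                 min_weight = constraints$min_weight, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf(
    "<null_distribution> %d random markers, %d vectors, n = %d: mu = %.3f, sigma = %.3f (%d failed)\n",
    length(x$samples), x$n_vectors, x$n_spectra, x$mu, x$sigma, x$n_failed))
  invisible(x)
}

#' Significance z-value of a correlation against a null
#'
#' `z = |c_m - mu| / sigma`, with `mu` and `sigma` taken from the matching
#' random-marker null distribution. The larger z, the lower the chance of
#' obtaining the correlation by chance under the identical protocol.
#'
#' @param c_m Observed training correlation.
#' @param null A [build_null()] result with `sigma > 0`.
#' @return Non-negative scalar.
#' @export
z_value <- function(c_m, null) {
  stopifnot(inherits(null, "null_distribution"))
  if (!is.finite(null$sigma) || null$sigma <= 0) {
    stop("degenerate null distribution: sigma must be > 0")
  }
  abs(c_m - null$mu) / null$sigma
}

#' Subset-stability resampling of a marker's training correlation
#'
#' Repeatedly re-derives the model on random subsets (default 40% of the
#' paired samples, without replacement) and summarizes the subset training
#' correlations. For a well-behaved marker the subset mean is close to the
#' full-data correlation with a small standard deviation.
#'
#' Replicates where no frequency reaches `min_weight` are recorded as
#' failures and excluded from the mean/stdev, with the count reported.
#'
#' @param data A [pair()]ed dataset.
#' @param constraints [selection_constraints()].
#' @param fraction Subset share in (0, 1\]; `1` uses every sample each time.
#' @param n_rep Number of replicates (default 1000).
#' @param seed RNG seed.
#' @return An object of class `stability_result` with `mean`, `stdev`,
#'   `scores`, `n_failed`, `fraction`, `n_rep`.
#' @export
subset_stability <- function(data, constraints = selection_constraints(),
                             fraction = 0.4, n_rep = 1000L, seed = 1L) {
  stopifnot(inherits(data, "paired_data"))
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  if (n_rep < 2L) stop("'n_rep' must be >= 2")
  n <- data$n_spectra
  m <- if (fraction == 1) n else floor(fraction * n)
  if (m < 3L) stop("subset size ", m, " is too small (need >= 3)")
  set.seed(seed)
  scores <- rep(NA_real_, n_rep)
  n_failed <- 0L
  for (r in seq_len(n_rep)) {
    idx <- sample.int(n, m)
    sub <- structure(list(marker = data$marker,
                          sample_ids = data$sample_ids[idx],
                          spectra = data$spectra[idx, , drop = FALSE],
                          values = data$values[idx], grid = data$grid,
                          n_spectra = m, provenance = data$provenance),
                     class = "paired_data")
    scores[r] <- tryCatch(
      greedy_select(sub, constraints = constraints)$training_correlation,
      error = function(e) {
        n_failed <<- n_failed + 1L
        NA_real_
      })
  }
  ok <- scores[!is.na(scores)]
  structure(list(marker = data$marker, fraction = fraction,
                 n_rep = as.integer(n_rep),
                 mean = mean(ok), stdev = stats::sd(ok),
                 scores = scores, n_failed = n_failed, seed = seed),
            class = "stability_result")
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf(
    "<stability_result> marker '%s', %d x %.0f%% subsets: %.3f / %.3f (%d failed)\n",
    x$marker, x$n_rep, 100 * x$fraction, x$mean, x$stdev, x$n_failed))
  invisible(x)
}

#' Overfitting negative control with random target vectors
#'
#' Fits purely random vectors as if they were markers, with relaxed
#' constraints (`n_vectors` selected frequencies, no minimum weight) and
#' optional Monte Carlo weight optimization. High mean correlations here
#' are pure overfitting — the demonstration of why the marker analysis caps
#' the number of vectors, thresholds the weights, and skips weight
#' optimization.
#'
#' @param dataset A [spectral_dataset()].
#' @param n_vectors Number of frequencies the fit may select (e.g. 50).
#' @param optimize Run [mc_optimize_weights()] on each random fit.
#' @param n_random Number of random target vectors.
#' @param mc_steps Monte Carlo proposals per fit when `optimize` is on.
#' @param step_scale Proposal standard deviation.
#' @param seed RNG seed.
#' @return List with `mean`, `stdev`, `samples`, `n_vectors`, `optimize`.
#' @export
overfit_demo <- function(dataset, n_vectors = 50L, optimize = TRUE,
                         n_random = 20L, mc_steps = 2000L, step_scale = 0.1,
                         seed = 1L) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  if (nrow(dataset$matrix) == 0L) stop("empty dataset")
  constraints <- selection_constraints(max_vectors = n_vectors, min_weight = 0)
  n <- nrow(dataset$matrix)
  set.seed(seed)
  samples <- numeric(n_random)
  for (r in seq_len(n_random)) {
    L <- stats::rnorm(n)
    pd <- structure(list(marker = sprintf("random_%03d", r),
                         sample_ids = dataset$sample_ids,
                         spectra = dataset$matrix, values = L,
                         grid = dataset$grid, n_spectra = n,
                         provenance = dataset$provenance),
                    class = "paired_data")
    model <- greedy_select(pd, constraints = constraints)
    if (optimize) {
      model <- mc_optimize_weights(pd, model, steps = mc_steps,
                                   step_scale = step_scale)
    }
    samples[r] <- model$training_correlation
  }
  list(mean = mean(samples), stdev = stats::sd(samples), samples = samples,
       n_vectors = n_vectors, optimize = optimize, n_random = n_random,
       seed = seed)
}
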