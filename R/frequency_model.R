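# Pearson correlation that returns NA (instead of warning/error) when either
# side has zero variance.
safe_cor <- function(x, y) {
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (!is.finite(sx) || !is.finite(sy) || sx == 0 || sy == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Constraints on frequency selection
#'
#' The two overfitting controls of the frequency-selective linear model: a
#' cap on the number of spectral vectors with non-zero weight, and a
#' minimum absolute pairwise correlation below which a frequency is not
#' eligible (since weights equal pairwise correlations, this is also the
#' minimum weight).
#'
#' @param max_vectors Maximum number of selected frequencies (default 9).
#' @param min_weight Minimum |pairwise correlation| for eligibility
#'   (default 0.2).
#' @param positive_only If `TRUE`, only positively correlated frequencies
#'   are eligible (sensitivity analysis; default uses absolute values with
#'   signed weights, so anti-correlated frequencies contribute through
#'   negative weights).
#' @return An object of class `selection_constraints`.
#' @export
selection_constraints <- function(max_vectors = 9L, min_weight = 0.2,
                                  positive_only = FALSE) {
  if (max_vectors < 1) stop("'max_vectors' must be >= 1")
  if (min_weight < 0 || min_weight >= 1) stop("'min_weight' must be in [0, 1)")
  structure(list(max_vectors = as.integer(max_vectors),
                 min_weight = min_weight,
                 positive_only = isTRUE(positive_only)),
            class = "selection_constraints")
}

#' Pairwise correlation of every spectral vector with a marker
#'
#' For each grid frequency f, the Pearson correlation between the column of
#' the spectral matrix at f and the marker vector, over the samples where
#' both exist. Zero-variance columns are flagged `NA` rather than failing.
#'
#' @param data A [pair()]ed dataset.
#' @return An object of class `pairwise_correlations` with `values`
#'   (length-k vector), `wavenumbers`, `marker`, `n_spectra`.
#' @export
pairwise_correlations <- function(data) {
  stopifnot(inherits(data, "paired_data"))
  if (data$n_spectra < 3L) stop("need at least 3 paired samples")
  vals <- suppressWarnings(
    as.numeric(stats::cor(data$values, data$spectra)))
  vals[!is.finite(vals)] <- NA_real_
  structure(list(marker = data$marker, values = vals,
                 wavenumbers = data$grid, n_spectra = data$n_spectra),
            class = "pairwise_correlations")
}

#' Correlation of a marker with a model's weighted spectral combination
#'
#' The model score: the Pearson correlation between the marker vector and
#' `S %*% w` restricted to the selected frequencies. Invariant to positive
#' rescaling of the weights.
#'
#' @param data A [pair()]ed dataset.
#' @param model A [greedy_select()]-style `predictor_model`.
#' @return Scalar correlation, or `NA` if the combined vector has zero
#'   variance.
#' @export
combined_correlation <- function(data, model) {
  stopifnot(inherits(data, "paired_data"), inherits(model, "predictor_model"))
  idx <- model$selected$index
  if (any(idx < 1L | idx > ncol(data$spectra))) {
    stop("selected frequency index outside the spectral matrix")
  }
  v <- as.numeric(data$spectra[, idx, drop = FALSE] %*% model$selected$weight)
  safe_cor(data$values, v)
}

new_predictor_model <- function(marker, index, wavenumber, weight,
                                training_correlation, constraints,
                                n_spectra, provenance = list()) {
  structure(list(marker = marker,
                 selected = data.frame(index = as.integer(index),
                                       wavenumber = wavenumber,
                                       weight = weight),
                 training_correlation = training_correlation,
                 constraints = constraints,
                 n_spectra = n_spectra,
                 provenance = provenance),
            class = "predictor_model")
}

#' @export
print.predictor_model <- function(x, ...) {
  cat(sprintf("<predictor_model> marker '%s': %d frequencies, training r = %.3f (n = %d)\n",
              x$marker, nrow(x$selected), x$training_correlation, x$n_spectra))
  print(x$selected, row.names = FALSE)
  invisible(x)
}

#' Greedy frequency selection under overfitting constraints
#'
#' Candidates are the frequencies whose |pairwise correlation| reaches
#' `min_weight`, visited in descending |pairwise correlation| (ties broken
#' toward the lower wavenumber for reproducibility). Each candidate's weight
#' is tentatively switched on at its pairwise correlation value; it is kept
#' only if the combined correlation strictly increases (by more than 1e-12,
#' to keep float noise from accepting). Selection stops when `max_vectors`
#' weights are on or the candidates are exhausted.
#'
#' @param data A [pair()]ed dataset.
#' @param pc Optional precomputed [pairwise_correlations()].
#' @param constraints [selection_constraints()].
#' @return A `predictor_model` with the selected frequencies, their signed
#'   weights, and the training correlation.
#' @export
greedy_select <- function(data, pc = NULL,
                          constraints = selection_constraints()) {
  stopifnot(inherits(data, "paired_data"),
            inherits(constraints, "selection_constraints"))
  if (is.null(pc)) pc <- pairwise_correlations(data)
  stopifnot(inherits(pc, "pairwise_correlations"))
  cvals <- pc$values
  elig <- if (constraints$positive_only) {
    which(!is.na(cvals) & cvals >= constraints$min_weight)
  } else {
    which(!is.na(cvals) & abs(cvals) >= constraints$min_weight)
  }
  if (length(elig) == 0L) {
    stop("no frequency above min_weight (", constraints$min_weight,
         ") for marker '", data$marker, "'")
  }
  ord <- elig[order(-abs(cvals[elig]), data$grid[elig])]
  n <- data$n_spectra
  v <- numeric(n)
  sel <- integer(0)
  best <- 0
  eps <- 1e-12
  for (f in ord) {
    if (length(sel) >= constraints$max_vectors) break
    cand <- v + cvals[f] * data$spectra[, f]
    sc <- safe_cor(data$values, cand)
    if (!is.na(sc) && sc > best + eps) {
      sel <- c(sel, f)
      v <- cand
      best <- sc
    }
  }
  prov <- data$provenance
  prov$training_ids <- data$sample_ids
  new_predictor_model(data$marker, sel, data$grid[sel], cvals[sel],
                      best, constraints, n, provenance = prov)
}

#' Serialize / restore a predictor model
#'
#' Models are stored as structured JSON text: marker name, selected
#' wavenumbers (cm^-1) and weights, training correlation, constraints and
#' provenance.
#'
#' @param model A `predictor_model`.
#' @param path Output path.
#' @return `write_model` returns the path invisibly; `read_model` the
#'   model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "predictor_model"))
  jsonlite::write_json(
    list(marker = model$marker, selected = model$selected,
         training_correlation = model$training_correlation,
         constraints = unclass(model$constraints),
         n_spectra = model$n_spectra,
         provenance = model$provenance),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  cn <- x$constraints
  new_predictor_model(
    x$marker, x$selected$index, x$selected$wavenumber, x$selected$weight,
    x$training_correlation,
    selection_constraints(cn$max_vectors, cn$min_weight, cn$positive_only),
    x$n_spectra, provenance = x$provenance)
}

#' Monte Carlo fine-tuning of model weights
#'
#' Random single-weight perturbations, accepting only proposals that
#' increase the combined correlation, so the score trace is monotone
#' non-decreasing and the selected frequency set is unchanged. Off by
#' default throughout the marker analysis: fine-tuned weights inflate
#' apparent correlations on small cohorts (see the overfitting negative
#' control), so it exists for that demonstration and for controlled
#' calibration settings.
#'
#' @param data A [pair()]ed dataset.
#' @param model A `predictor_model`.
#' @param steps Number of proposals; `0` returns the model unchanged.
#' @param step_scale Standard deviation of a weight perturbation.
#' @param seed Optional RNG seed.
#' @return The model with updated weights and training correlation.
#' @export
mc_optimize_weights <- function(data, model, steps = 2000L, step_scale = 0.1,
                                seed = NULL) {
  stopifnot(inherits(data, "paired_data"), inherits(model, "predictor_model"))
  if (nrow(model$selected) == 0L) stop("model has no selected frequencies")
  if (steps == 0L) return(model)
  if (!is.null(seed)) set.seed(seed)
  w <- model$selected$weight
  X <- data$spectra[, model$selected$index, drop = FALSE]
  v <- as.numeric(X %*% w)
  best <- safe_cor(data$values, v)
  if (is.na(best)) best <- -Inf
  for (s in seq_len(steps)) {
    j <- sample.int(length(w), 1L)
    delta <- stats::rnorm(1L, 0, step_scale)
    cand <- v + delta * X[, j]
    sc <- safe_cor(data$values, cand)
    if (!is.na(sc) && sc > best) {
      w[j] <- w[j] + delta
      v <- cand
      best <- sc
    }
  }
  model$selected$weight <- w
  model$training_correlation <- best
  model$provenance$mc_steps <- steps
  model
}
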