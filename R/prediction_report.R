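#' Raw model predictions for a dataset
#'
#' For each spectrum, the weighted sum of its intensities at the model's
#' selected frequencies (`S %*% w`), in arbitrary units. Linear in the
#' spectra. The dataset must have been background-filtered with the same
#' parameters as the model's training data — filtering is part of the model
#' contract — unless `check_provenance` is disabled.
#'
#' @param model A `predictor_model`.
#' @param dataset A [spectral_dataset()] on the model's grid.
#' @param check_provenance Refuse datasets whose filter provenance does not
#'   match the model's (default `TRUE`).
#' @return data.frame with `sample_id`, `marker`, `raw_value`.
#' @export
predict_raw <- function(model, dataset, check_provenance = TRUE) {
  stopifnot(inherits(model, "predictor_model"),
            inherits(dataset, "spectral_dataset"))
  idx <- model$selected$index
  if (any(idx < 1L | idx > ncol(dataset$matrix))) {
    stop("dataset grid is smaller than the model's frequency indices; ",
         "interpolate onto the training grid first")
  }
  wn <- dataset$grid[idx]
  if (max(abs(wn - model$selected$wavenumber)) > 1e-6) {
    stop("dataset grid does not match the model's wavenumbers; ",
         "assemble the dataset on the training grid first")
  }
  if (check_provenance) {
    mf <- model$provenance$filter
    df <- dataset$provenance$filter
    if (!identical(mf, df)) {
      stop("background-filter provenance mismatch between model and dataset; ",
           "filter the dataset with the training parameters or set ",
           "check_provenance = FALSE")
    }
  }
  raw <- as.numeric(dataset$matrix[, idx, drop = FALSE] %*% model$selected$weight)
  data.frame(sample_id = dataset$sample_ids, marker = model$marker,
             raw_value = raw, stringsAsFactors = FALSE)
}

#' Fit a concentration scaling from reference samples
#'
#' The sum-ratio rule: `factor = sum(nominal) / sum(raw)` over the
#' designated reference entries (by default those with non-zero nominal
#' concentration), so that the scaled reference values sum exactly to the
#' nominal total. Applied as `scaled = factor * raw` to every entry,
#' including blanks.
#'
#' @param nominal Known concentrations, aligned with `raw`.
#' @param raw Raw predictions from [predict_raw()].
#' @param reference Indices of the entries used to fit the factor
#'   (default: non-zero nominal).
#' @param method `"sum_ratio"` (default) or `"least_squares"`
#'   (zero-intercept regression of nominal on raw).
#' @return An object of class `scaling_fit` with `factor`, `nominal`,
#'   `raw`, `scaled`.
#' @export
fit_scaling <- function(nominal, raw, reference = which(nominal != 0),
                        method = c("sum_ratio", "least_squares")) {
  method <- match.arg(method)
  if (length(nominal) != length(raw)) stop("'nominal' and 'raw' must align")
  if (length(reference) < 1L) stop("need at least one reference entry")
  s <- if (method == "sum_ratio") {
    denom <- sum(raw[reference])
    if (denom == 0) stop("reference raw values sum to zero")
    sum(nominal[reference]) / denom
  } else {
    denom <- sum(raw[reference]^2)
    if (denom == 0) stop("reference raw values are all zero")
    sum(nominal[reference] * raw[reference]) / denom
  }
  if (!is.finite(s)) stop("scaling factor is not finite")
  structure(list(factor = s, nominal = nominal, raw = raw,
                 reference = reference, method = method,
                 scaled = s * raw),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> factor = %.6g (%s, %d reference samples)\n",
              x$factor, x$method, length(x$reference)))
  print(data.frame(nominal = x$nominal, raw = x$raw, scaled = x$scaled),
        row.names = FALSE)
  invisible(x)
}

#' Validate a model on held-out spectra
#'
#' Correlates the model's raw predictions with the laboratory values of an
#' independent cohort. Refuses holdout sets sharing sample ids with the
#' training data (leakage guard) unless `allow_overlap` is set, which
#' exists for consistency checks only.
#'
#' @param model A `predictor_model`.
#' @param holdout A [pair()]ed dataset for the same marker.
#' @param training_ids Sample ids used in training; defaults to the ids
#'   recorded in the model provenance when present.
#' @param allow_overlap Disable the leakage guard (testing only).
#' @return An object of class `validation_result` with `correlation`,
#'   `n_val`.
#' @export
validate <- function(model, holdout, training_ids = NULL,
                     allow_overlap = FALSE) {
  stopifnot(inherits(model, "predictor_model"),
            inherits(holdout, "paired_data"))
  if (is.null(training_ids)) training_ids <- model$provenance$training_ids
  if (!allow_overlap && !is.null(training_ids)) {
    overlap <- intersect(training_ids, holdout$sample_ids)
    if (length(overlap)) {
      stop("holdout overlaps training samples (e.g. '", overlap[1],
           "'); validation requires disjoint cohorts")
    }
  }
  if (holdout$n_spectra < 3L) stop("holdout needs at least 3 samples")
  ds <- spectral_dataset(holdout$sample_ids, holdout$grid, holdout$spectra,
                         provenance = holdout$provenance)
  preds <- predict_raw(model, ds,
                       check_provenance = !is.null(model$provenance$filter))
  r <- safe_cor(preds$raw_value, holdout$values)
  structure(list(marker = model$marker, correlation = r,
                 n_val = holdout$n_spectra),
            class = "validation_result")
}

#' Assemble a per-marker performance report
#'
#' One row per marker that reaches the training-correlation threshold:
#' Pearson training correlation, z-value against its null, subset-stability
#' mean/stdev, number of paired spectra, validation correlation and
#' validation n. Sorted by Pearson descending. Components missing for a
#' marker are rendered as `-` in the formatted table and `NA` in the
#' data.frame.
#'
#' @param models Named list of `predictor_model`s (names = markers).
#' @param nulls Named list of [build_null()] results.
#' @param stabilities Named list of [subset_stability()] results.
#' @param validations Named list of [validate()] results.
#' @param min_pearson Inclusion threshold on the training correlation
#'   (default 0.6).
#' @return data.frame of class `marker_report` with columns `marker`,
#'   `pearson`, `z_value`, `p40_mean`, `p40_stdev`, `n_spectra`,
#'   `validation`, `n_val`.
#' @export
report <- function(models, nulls = list(), stabilities = list(),
                   validations = list(), min_pearson = 0.6) {
  rows <- lapply(names(models), function(m) {
    mod <- models[[m]]
    data.frame(
      marker = m,
      pearson = mod$training_correlation,
      z_value = if (!is.null(nulls[[m]])) {
        z_value(mod$training_correlation, nulls[[m]])
      } else NA_real_,
      p40_mean = if (!is.null(stabilities[[m]])) stabilities[[m]]$mean else NA_real_,
      p40_stdev = if (!is.null(stabilities[[m]])) stabilities[[m]]$stdev else NA_real_,
      n_spectra = mod$n_spectra,
      validation = if (!is.null(validations[[m]])) {
        validations[[m]]$correlation
      } else NA_real_,
      n_val = if (!is.null(validations[[m]])) validations[[m]]$n_val else 0L,
      stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(marker = character(0), pearson = numeric(0),
               z_value = numeric(0), p40_mean = numeric(0),
               p40_stdev = numeric(0), n_spectra = integer(0),
               validation = numeric(0), n_val = integer(0),
               stringsAsFactors = FALSE)
  }
  out <- out[is.na(out$pearson) | out$pearson >= min_pearson, , drop = FALSE]
  out <- out[order(-out$pearson), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("marker_report", "data.frame")
  out
}

#' Render a report as aligned human-readable text
#'
#' Correlations are printed with 3 decimals; absent statistics print as
#' `-`.
#'
#' @param x A [report()] data.frame.
#' @return Character vector of lines.
#' @export
format_report <- function(x) {
  stopifnot(inherits(x, "marker_report"))
  fm <- function(v, fmt = "%.3f") ifelse(is.na(v), "-", sprintf(fmt, v))
  df <- data.frame(
    Marker = x$marker,
    Pearson = fm(x$pearson),
    `z-value` = fm(x$z_value),
    `P40 mean/stdev` = ifelse(is.na(x$p40_mean), "-",
                              paste(fm(x$p40_mean), fm(x$p40_stdev), sep = " / ")),
    n_spectra = x$n_spectra,
    Validation = fm(x$validation),
    n_val = x$n_val,
    check.names = FALSE)
  c(paste(names(df), collapse = "\t"),
    apply(df, 1L, paste, collapse = "\t"))
}

#' @export
print.marker_report <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' Write / read a report CSV
#'
#' Numbers are written with full double precision so that reading the file
#' back reproduces every statistic bit-for-bit.
#'
#' @param x A [report()] data.frame.
#' @param path CSV path.
#' @return `write_report` returns the path invisibly; `read_report` the
#'   report data.frame.
#' @export
write_report <- function(x, path) {
  stopifnot(inherits(x, "marker_report"))
  df <- x
  for (nm in c("pearson", "z_value", "p40_mean", "p40_stdev", "validation")) {
    df[[nm]] <- ifelse(is.na(df[[nm]]), "", sprintf("%.17g", df[[nm]]))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (nm in c("pearson", "z_value", "p40_mean", "p40_stdev", "validation")) {
    df[[nm]] <- as.numeric(df[[nm]])
  }
  df$n_spectra <- as.integer(df$n_spectra)
  df$n_val <- as.integer(df$n_val)
  class(df) <- c("marker_report", "data.frame")
  df
}
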