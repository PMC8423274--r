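#' Asymmetric least squares parameters
#'
#' AsLS estimates the fluorescence baseline by minimizing
#' `sum_i w_i (y_i - z_i)^2 + smoothness * sum_i (d2 z_i)^2`
#' where `d2` is the second difference, iterating
#' `w_i = asymmetry` where `y_i > z_i` and `1 - asymmetry` otherwise.
#' Small `asymmetry` makes the curve hug the lower envelope of the signal
#' (peaks get almost no pull); `smoothness` is the stiffness of the curve.
#'
#' @param smoothness Positive second-difference penalty weight (in grid
#'   units). Larger is stiffer / more "rigid".
#' @param asymmetry Weight for points above the fit, in (0, 0.5).
#' @param max_iter Maximum reweighting iterations.
#' @return An object of class `asls_params`.
#' @export
asls_params <- function(smoothness = 1e5, asymmetry = 0.001, max_iter = 20L) {
  if (!is.numeric(smoothness) || smoothness <= 0) stop("'smoothness' must be > 0")
  if (!is.numeric(asymmetry) || asymmetry <= 0 || asymmetry >= 0.5) {
    stop("'asymmetry' must be in (0, 0.5)")
  }
  if (max_iter < 1) stop("'max_iter' must be >= 1")
  structure(list(smoothness = smoothness, asymmetry = asymmetry,
                 max_iter = as.integer(max_iter)),
            class = "asls_params")
}

# Sparse second-difference penalty t(D) %*% D for signals of length k.
asls_penalty <- function(k) {
  D <- Matrix::bandSparse(k - 2L, k, k = 0:2,
                          diagonals = list(rep(1, k - 2L), rep(-2, k - 2L),
                                           rep(1, k - 2L)))
  Matrix::crossprod(D)
}

#' Estimate the fluorescence baseline of one spectrum
#'
#' Iteratively reweighted penalized least squares on a sparse banded system.
#' Iteration stops as soon as the asymmetric weights stop changing (points
#' on either side of the fit are settled) or after `max_iter` passes. Ties
#' `y == z` take the below-curve weight `1 - asymmetry`.
#'
#' @param intensities Numeric vector (length >= 4, finite).
#' @param params [asls_params()].
#' @param penalty Optional precomputed [Matrix] penalty (internal reuse).
#' @return Baseline vector of the same length.
#' @export
estimate_baseline <- function(intensities, params = asls_params(),
                              penalty = NULL) {
  k <- length(intensities)
  if (k < 4L) stop("need at least 4 points to estimate a baseline")
  if (any(!is.finite(intensities))) stop("non-finite intensities")
  stopifnot(inherits(params, "asls_params"))
  P <- if (is.null(penalty)) asls_penalty(k) else penalty
  lamP <- params$smoothness * P
  w <- rep(1, k)
  z <- intensities
  for (it in seq_len(params$max_iter)) {
    A <- Matrix::Diagonal(x = w) + lamP
    z <- as.numeric(Matrix::solve(A, w * intensities))
    w_new <- ifelse(intensities > z, params$asymmetry, 1 - params$asymmetry)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

#' Subtract the fluorescence background from every spectrum
#'
#' Applies [estimate_baseline()] row-wise and subtracts it. The filter
#' parameters are recorded in the dataset's provenance so that downstream
#' models can verify that prediction inputs were preprocessed identically.
#'
#' @param dataset A [spectral_dataset()].
#' @param params [asls_params()].
#' @param keep_baselines Also return the estimated baselines.
#' @return A background-filtered [spectral_dataset()]; when
#'   `keep_baselines = TRUE` the baselines matrix is attached as
#'   `provenance$baselines`.
#' @export
filter_dataset <- function(dataset, params = asls_params(),
                           keep_baselines = FALSE) {
  stopifnot(inherits(dataset, "spectral_dataset"))
  k <- ncol(dataset$matrix)
  out <- dataset$matrix
  if (nrow(out) > 0L) {
    P <- asls_penalty(k)
    for (i in seq_len(nrow(out))) {
      base <- tryCatch(
        estimate_baseline(dataset$matrix[i, ], params, penalty = P),
        error = function(e) {
          stop("baseline estimation failed for sample '",
               dataset$sample_ids[i], "': ", conditionMessage(e))
        })
      out[i, ] <- dataset$matrix[i, ] - base
    }
  }
  prov <- dataset$provenance
  prov$filter <- list(method = "asls", smoothness = params$smoothness,
                      asymmetry = params$asymmetry, max_iter = params$max_iter)
  if (keep_baselines) prov$baselines <- dataset$matrix - out
  spectral_dataset(dataset$sample_ids, dataset$grid, out, provenance = prov)
}
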