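# Independent oracles, deliberately implemented with dense base-R linear
# algebra and textbook formulas, not through the package's code paths.

# Dense direct solve of the iteratively reweighted penalized system
# underlying AsLS: same weighting rule, full (non-sparse) normal equations.
dense_asls_oracle <- function(y, smoothness, asymmetry, max_iter = 20L) {
  k <- length(y)
  D <- diff(diag(k), differences = 2)
  P <- smoothness * crossprod(D)
  w <- rep(1, k)
  z <- y
  for (it in seq_len(max_iter)) {
    z <- as.numeric(solve(diag(w, k) + P, w * y))
    w_new <- ifelse(y > z, asymmetry, 1 - asymmetry)
    if (identical(w_new, w)) break
    w <- w_new
  }
  z
}

# Textbook Pearson coefficient: centered cross-product over (n-1) sd sd.
pearson_oracle <- function(x, y) {
  n <- length(x)
  sx <- sqrt(sum((x - mean(x))^2) / (n - 1))
  sy <- sqrt(sum((y - mean(y))^2) / (n - 1))
  sum((x - mean(x)) * (y - mean(y))) / ((n - 1) * sx * sy)
}

# Exhaustive best correlation over all subsets of at most `max_size`
# columns, using pairwise correlations as weights (brute force).
exhaustive_best <- function(values, spectra, max_size = 2L) {
  k <- ncol(spectra)
  cvals <- vapply(seq_len(k), function(j) pearson_oracle(values, spectra[, j]),
                  0)
  best <- -Inf
  singles <- seq_len(k)
  subsets <- c(lapply(singles, identity),
               if (max_size >= 2L) combn(k, 2L, simplify = FALSE))
  for (s in subsets) {
    v <- as.numeric(spectra[, s, drop = FALSE] %*% cvals[s])
    if (stats::sd(v) == 0) next
    best <- max(best, stats::cor(values, v))
  }
  best
}
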