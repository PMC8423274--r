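test_that("pairwise correlations match the textbook Pearson formula", {
  set.seed(12)
  S <- matrix(rnorm(20), 5, 4)
  L <- rnorm(5)
  pd <- toy_paired(L, S)
  pc <- pairwise_correlations(pd)
  expected <- vapply(1:4, function(j) pearson_oracle(L, S[, j]), 0)
  expect_lt(max(abs(pc$values - expected)), 1e-12)
  expect_equal(pc$n_spectra, 5L)
})

test_that("a marker equal to a spectral vector correlates 1 there (and -1 when negated)", {
  set.seed(13)
  S <- matrix(rnorm(40), 10, 4)
  pc <- pairwise_correlations(toy_paired(S[, 3], S))
  expect_equal(pc$values[3], 1)
  pc_neg <- pairwise_correlations(toy_paired(-S[, 3], S))
  expect_equal(pc_neg$values[3], -1)
})

test_that("zero-variance spectral vectors are flagged missing, not fatal", {
  set.seed(14)
  S <- cbind(matrix(rnorm(30), 10, 3), 5)
  pc <- pairwise_correlations(toy_paired(rnorm(10), S))
  expect_true(is.na(pc$values[4]))
  expect_false(anyNA(pc$values[1:3]))
})

test_that("combined_correlation matches a direct computation and is scale invariant", {
  set.seed(15)
  S <- matrix(rnorm(60), 15, 4)
  L <- S[, 1] + 0.5 * S[, 2] + rnorm(15, 0, 0.3)
  pd <- toy_paired(L, S)
  w <- c(0.7, 0.4)
  model <- ramanscreen:::new_predictor_model(
    "toy", c(1L, 2L), c(1, 2), w, NA_real_, selection_constraints(), 15L)
  direct <- cor(L, w[1] * S[, 1] + w[2] * S[, 2])
  expect_equal(combined_correlation(pd, model), direct)
  model10 <- model
  model10$selected$weight <- 10 * w
  expect_equal(combined_correlation(pd, model10), direct)
  # single selected vector reduces to its pairwise correlation
  m1 <- ramanscreen:::new_predictor_model(
    "toy", 3L, 3, 0.25, NA_real_, selection_constraints(), 15L)
  expect_equal(combined_correlation(pd, m1), cor(L, S[, 3]))
})

test_that("greedy_select stops at a perfect single-frequency predictor", {
  set.seed(16)
  S <- matrix(rnorm(80), 20, 4)
  pd <- toy_paired(S[, 2], S)
  m <- greedy_select(pd, constraints = selection_constraints(max_vectors = 3,
                                                             min_weight = 0.1))
  expect_equal(nrow(m$selected), 1L)
  expect_equal(m$selected$index, 2L)
  expect_equal(m$training_correlation, 1)
})

test_that("greedy scores sit between the best pairwise value and the exhaustive optimum", {
  set.seed(17)
  for (rep in 1:8) {
    S <- matrix(rnorm(12 * 6), 12, 6)
    L <- S[, 1] - 0.8 * S[, 4] + rnorm(12, 0, 0.5)
    pd <- toy_paired(L, S)
    pc <- pairwise_correlations(pd)
    m <- greedy_select(pd, pc,
                       selection_constraints(max_vectors = 2, min_weight = 0))
    best_single <- max(abs(pc$values))
    best_exhaustive <- exhaustive_best(L, S, max_size = 2L)
    expect_gte(m$training_correlation, best_single - 1e-12)
    expect_lte(m$training_correlation, best_exhaustive + 1e-12)
  }
})

test_that("greedy training correlation is monotone in max_vectors and respects the cap", {
  ch <- small_cohort()
  pd <- pair(ch$filtered, ch$markers, "bilirubin")
  pc <- pairwise_correlations(pd)
  scores <- vapply(c(1, 3, 9), function(mv) {
    m <- greedy_select(pd, pc, selection_constraints(max_vectors = mv,
                                                     min_weight = 0))
    expect_lte(nrow(m$selected), mv)
    m$training_correlation
  }, 0)
  expect_true(all(diff(scores) >= 0))
  # combined score cannot fall below the best selected pairwise value
  m9 <- greedy_select(pd, pc, selection_constraints(max_vectors = 9,
                                                    min_weight = 0))
  expect_gte(m9$training_correlation, max(abs(m9$selected$weight)) - 1e-12)
})

test_that("anti-correlated frequencies contribute through signed weights", {
  set.seed(19)
  S <- matrix(rnorm(200), 50, 4)
  L <- -S[, 1] - S[, 2] + rnorm(50, 0, 0.2)
  pd <- toy_paired(L, S)
  m <- greedy_select(pd, constraints = selection_constraints(max_vectors = 2,
                                                             min_weight = 0.2))
  expect_true(all(m$selected$weight < 0))
  expect_gt(m$training_correlation, max(abs(m$selected$weight)))
  # positive-only eligibility excludes them
  expect_error(
    greedy_select(pd, constraints = selection_constraints(
      max_vectors = 2, min_weight = 0.2, positive_only = TRUE)),
    "no frequency")
})

test_that("greedy_select errors when nothing reaches min_weight", {
  set.seed(20)
  S <- matrix(rnorm(40), 10, 4)
  pd <- toy_paired(rnorm(10), S)
  expect_error(greedy_select(pd, constraints = selection_constraints(
    max_vectors = 3, min_weight = 0.999)), "no frequency above min_weight")
})

test_that("mc_optimize_weights only ever improves the score and keeps the selection", {
  ch <- small_cohort()
  pd <- pair(ch$filtered, ch$markers, "bilirubin")
  m <- greedy_select(pd, constraints = selection_constraints(max_vectors = 5,
                                                             min_weight = 0))
  expect_identical(mc_optimize_weights(pd, m, steps = 0), m)
  opt <- mc_optimize_weights(pd, m, steps = 500, seed = 42)
  expect_gte(opt$training_correlation, m$training_correlation)
  expect_identical(opt$selected$index, m$selected$index)
  expect_equal(combined_correlation(pd, opt), opt$training_correlation)
})

test_that("mc optimization approaches the two-column grid-search optimum", {
  set.seed(21)
  S <- matrix(rnorm(200), 100, 2)
  L <- 0.9 * S[, 1] + 0.45 * S[, 2] + rnorm(100, 0, 0.4)
  pd <- toy_paired(L, S)
  m <- greedy_select(pd, constraints = selection_constraints(max_vectors = 2,
                                                             min_weight = 0))
  # combined correlation only depends on the weight direction: scan angles
  thetas <- seq(0, pi, length.out = 20001)[-20001]
  grid_best <- max(vapply(thetas, function(t) {
    v <- cos(t) * S[, 1] + sin(t) * S[, 2]
    cor(L, v)
  }, 0))
  opt <- mc_optimize_weights(pd, m, steps = 5000, step_scale = 0.1, seed = 8)
  expect_lt(grid_best - opt$training_correlation, 1e-3)
})

test_that("models serialize to JSON and back without loss", {
  ch <- small_cohort()
  pd <- pair(ch$filtered, ch$markers, "bilirubin")
  m <- greedy_select(pd, constraints = selection_constraints(max_vectors = 4,
                                                             min_weight = 0))
  f <- withr::local_tempfile(fileext = ".json")
  write_model(m, f)
  back <- read_model(f)
  expect_equal(back$selected, m$selected)
  expect_equal(back$training_correlation, m$training_correlation)
  expect_equal(back$constraints$max_vectors, m$constraints$max_vectors)
})
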