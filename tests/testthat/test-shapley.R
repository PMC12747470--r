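test_that("Shapley axioms hold under exact enumeration", {
  set.seed(14)
  bg <- matrix(rnorm(50 * 4), ncol = 4,
               dimnames = list(NULL, paste0("f", 1:4)))
  x <- rnorm(4)

  # dummy: a constant model attributes nothing
  ex0 <- shapley_explain(function(X) rep(2.5, nrow(X)), x, bg, method = "exact")
  expect_equal(unname(ex0$attributions), rep(0, 4))
  expect_equal(ex0$base_value, 2.5)

  # additive closed form: f(x) = x1 gives phi1 = x1 - mean(bg1), rest 0
  ex1 <- shapley_explain(function(X) X[, 1], x, bg, method = "exact")
  expect_equal(unname(ex1$attributions[1]), x[1] - mean(bg[, 1]), tolerance = 1e-9)
  expect_equal(unname(ex1$attributions[-1]), rep(0, 3), tolerance = 1e-12)

  # efficiency on a nonlinear model
  f <- function(X) X[, 1] * X[, 2] + sin(X[, 3]) + 0.5 * X[, 4]^2
  ex2 <- shapley_explain(f, x, bg, method = "exact")
  expect_equal(ex2$base_value + sum(ex2$attributions), ex2$prediction,
               tolerance = 1e-6)

  # symmetry: two features entering identically get equal attributions
  g <- function(X) X[, 1] + X[, 2] + X[, 3]^2
  xs <- c(1.3, 1.3, 0.7, -0.2)
  bgs <- bg; bgs[, 2] <- bgs[, 1]
  ex3 <- shapley_explain(g, xs, bgs, method = "exact")
  expect_equal(unname(ex3$attributions[1]), unname(ex3$attributions[2]),
               tolerance = 1e-9)
})

test_that("sampled estimator agrees with exact enumeration within 3 MC errors", {
  set.seed(15)
  bg <- matrix(rnorm(40 * 3), ncol = 3)
  x <- c(0.8, -1.1, 0.4)
  f <- function(X) X[, 1] * X[, 2] - 2 * X[, 3] + 0.3 * X[, 1]^2
  exact <- shapley_explain(f, x, bg, method = "exact")
  samp <- shapley_explain(f, x, bg, method = "sampled",
                          n_permutations = 10000L, seed = 16)
  for (k in 1:3) {
    tol <- max(3 * samp$se[k], 1e-9)
    expect_lt(abs(samp$attributions[k] - exact$attributions[k]), tol)
  }
  # efficiency telescopes exactly even for the sampled estimator
  expect_equal(samp$base_value + sum(samp$attributions), samp$prediction,
               tolerance = 1e-9)
})

test_that("dimension limits are enforced and inactive features attribute zero", {
  bg <- matrix(rnorm(10 * 35), ncol = 35)
  x <- bg[1, ]
  f <- function(X) rowSums(X)
  expect_error(shapley_explain(f, x, bg, method = "exact", exact_limit = 31L),
               "d > 30")
  # instance equal to the background mean in a coordinate -> zero attribution
  bg2 <- matrix(rnorm(20 * 3), ncol = 3)
  x2 <- c(1, mean(bg2[, 2]), -1)
  ex <- shapley_explain(function(X) rowSums(X), x2, bg2, method = "exact")
  expect_equal(unname(ex$attributions[2]), 0)
})

test_that("explanations of classifier predictions satisfy efficiency", {
  mod <- fixture_model()
  ds <- fixture_dataset()
  X <- mofscreen:::featurize_matrix(ds$molecules[1:120])
  inst <- featurize_linker(build_linker("benzene", "nitro"))$values
  f <- function(Z) {
    colnames(Z) <- mofscreen:::feature_names()
    predict_toxicity(mod, Z)$probabilities[, "fatal"]
  }
  ex <- shapley_explain(f, inst, X, method = "sampled",
                        n_permutations = 300L, seed = 17)
  expect_equal(ex$base_value + sum(ex$attributions), ex$prediction,
               tolerance = 1e-9)
  # the planted toxicophore dominates the explanation
  top <- names(sort(abs(ex$attributions), decreasing = TRUE))[1:6]
  expect_true(any(c("nitro", "ring_nitro", "pair_C_N", "count_N", "count_O") %in% top))
})
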