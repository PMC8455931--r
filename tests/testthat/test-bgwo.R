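test_that("sigmoid transfer hits its printed anchor points and symmetry", {
  expect_equal(sigmoid_transfer(0.5), 0.5)
  expect_equal(sigmoid_transfer(1), 1 / (1 + exp(-5)))
  a <- seq(-1, 2, by = 0.13)
  expect_equal(sigmoid_transfer(a) + sigmoid_transfer(1 - a), rep(1, length(a)))
  expect_true(all(diff(sigmoid_transfer(a)) > 0))
})

test_that("binary update thresholds the transferred donor mean", {
  expect_identical(binary_update(1, 1, 1, 0.9), 1L)   # S(1) ~ 0.993
  expect_identical(binary_update(0, 0, 0, 0.5), 0L)   # S(0) ~ 0.007
  expect_identical(binary_update(1, 1, 0, 0), 1L)     # any S >= 0
  expect_error(binary_update(1, 1, 1, 1.5), "\\[0, 1\\]")
  # all-ones donors select with probability S(1), within +/- 0.01 at 1e4 draws
  set.seed(51)
  freq <- mean(binary_update(rep(1, 1e4), rep(1, 1e4), rep(1, 1e4),
                             runif(1e4)))
  expect_lt(abs(freq - sigmoid_transfer(1)), 0.01)
})

test_that("donor bits follow the leader in the exploitation limit", {
  set.seed(52)
  d <- 1e4
  # a = 0: the continuous step collapses onto the leader's own bits
  expect_gt(mean(donor_bits(rep(0, d), rep(1, d), a = 0)), 0.98)
  expect_lt(mean(donor_bits(rep(1, d), rep(0, d), a = 0)), 0.02)
  # leader = position = all-ones, small a: donors heavily biased to 1
  expect_gt(mean(donor_bits(rep(1, d), rep(1, d), a = 0.1)), 0.9)
  # seeded reproducibility
  set.seed(99); a1 <- donor_bits(rep(0, 50), rep(1, 50), a = 1)
  set.seed(99); a2 <- donor_bits(rep(0, 50), rep(1, 50), a = 1)
  expect_identical(a1, a2)
})

test_that("default fitness rewards accuracy first, sparsity second", {
  # two-class fixture, perfectly separable along the first column
  set.seed(53)
  d <- 5
  y2 <- factor(rep(c("a", "b"), each = 30))
  X2 <- matrix(rnorm(60 * d), 60, d)
  X2[, 1] <- X2[, 1] + 8 * (y2 == "b")
  # the informative column alone separates: fitness ~ (1-w)/d
  f1 <- default_fitness(c(TRUE, rep(FALSE, d - 1)), X2, y2, seed = 1)
  expect_lt(f1, 0.01 * 1 / d + 0.02)
  # nested mask with equal (zero) error: smaller mask wins
  f2 <- default_fitness(c(TRUE, TRUE, rep(FALSE, d - 2)), X2, y2, seed = 1)
  err1 <- (f1 - 0.01 * 1 / d) / 0.99
  err2 <- (f2 - 0.01 * 2 / d) / 0.99
  if (abs(err1 - err2) < 1e-12) expect_lt(f1, f2)
  # all-noise columns sit near chance error on balanced labels
  f_noise <- default_fitness(c(FALSE, rep(TRUE, d - 1)), X2, y2, seed = 1)
  expect_gt(f_noise, 0.99 * 0.3)
  # empty mask is repaired with a warning
  set.seed(54)
  expect_warning(default_fitness(rep(FALSE, d), X2, y2, seed = 1),
                 "repaired")
})

test_that("bgwo_select is reproducible, monotone, and recovers planted columns", {
  pf <- planted_feature_matrix(100, 5, 10, effect = 3, seed = 55)
  s1 <- bgwo_select(pf$X, pf$y, pack_size = 5, iters = 12, seed = 3)
  s2 <- bgwo_select(pf$X, pf$y, pack_size = 5, iters = 12, seed = 3)
  expect_identical(s1$mask, s2$mask)
  expect_identical(s1$fitness_trace, s2$fitness_trace)
  expect_true(all(diff(s1$fitness_trace) <= 0))       # elitist bookkeeping
  expect_gte(s1$n_selected, 1)
  expect_identical(s1$n_selected, sum(s1$mask))
  expect_gte(sum(s1$mask[pf$informative]), 4)
  expect_error(bgwo_select(pf$X, rep(1, 100)), "single class")
})

test_that("a degenerate single-wolf, single-iteration run is still defined", {
  pf <- planted_feature_matrix(60, 2, 4, effect = 3, seed = 56)
  s <- bgwo_select(pf$X, pf$y, pack_size = 1, iters = 1, seed = 1)
  expect_gte(s$n_selected, 1)
  expect_length(s$fitness_trace, 1)
})

test_that("selection contracts a synthetic feature matrix without losing accuracy", {
  # planted fixture stands in for the DEAP-like matrix: the contract is
  # contraction plus no material accuracy loss, not an exact column range
  pf <- planted_feature_matrix(120, 5, 27, effect = 1.5, seed = 57)
  before <- svm_cv(pf$X, pf$y, k_folds = 6, seed = 2)
  sel <- bgwo_select(pf$X, pf$y, pack_size = 6, iters = 15, seed = 2)
  expect_lt(sel$n_selected, ncol(pf$X))
  after <- svm_cv(pf$X[, sel$mask, drop = FALSE], pf$y, k_folds = 6, seed = 2)
  expect_gte(after$acc, before$acc - 1)
})
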