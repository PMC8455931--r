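test_that("stratified folds are balanced within one member per class and seeded", {
  y <- rep(1:5, each = 256)                      # 1,280 balanced labels
  f <- stratified_kfold(y, 6, seed = 1)
  expect_true(all(table(f) %in% 213:214))
  per_class <- table(y, f)
  expect_true(all(abs(per_class - mean(per_class)) <= 1))
  expect_identical(stratified_kfold(y, 6, seed = 1), f)
  expect_false(identical(stratified_kfold(y, 6, seed = 2), f))
  expect_warning(stratified_kfold(c(1, 1, 1, 1, 1, 1, 2), 6), "best-effort")
})

test_that("accuracy generalizes (TP+TN)/total to the multiclass trace", {
  expect_equal(accuracy(diag(c(10, 10, 10, 10, 10))), 100)
  expect_equal(accuracy(matrix(4, 5, 5)), 20)
  expect_equal(accuracy(matrix(c(40, 5, 10, 45), 2, 2, byrow = FALSE)), 85)
})

test_that("macro sensitivity/specificity match one-vs-rest hand counts", {
  cm <- matrix(c(40, 10, 5, 45), 2, 2, byrow = TRUE)  # truth in rows
  cc <- 100 * c(40 / 50, 45 / 50)
  expect_equal(macro_sensitivity(cm), mean(cc))
  # class-1 specificity = TN/(TN+FP) = 45/50; class-2 = 40/50
  expect_equal(macro_specificity(cm), mean(100 * c(45 / 50, 40 / 50)))
  # all predictions collapsed to one class, balanced 5-class: macro sen 20
  cm5 <- matrix(0, 5, 5); cm5[, 1] <- 12
  expect_equal(macro_sensitivity(cm5), 20)
  # perfect diagonal
  expect_equal(macro_sensitivity(diag(5) * 7), 100)
  expect_equal(macro_specificity(diag(5) * 7), 100)
})

test_that("indices are invariant under class relabeling", {
  set.seed(61)
  cm <- matrix(rpois(25, 8), 5, 5)
  perm <- sample(5)
  cmp <- cm[perm, perm]
  expect_equal(accuracy(cmp), accuracy(cm))
  expect_equal(macro_sensitivity(cmp), macro_sensitivity(cm))
  expect_equal(macro_specificity(cmp), macro_specificity(cm))
})

test_that("kappa normalizes accuracy by the uniform chance rate", {
  expect_equal(kappa_coefficient(68.24, 5), 0.603)
  expect_equal(kappa_coefficient(62, 2), 0.24)
  expect_equal(kappa_coefficient(100, 3), 1)
  for (k in 2:10) expect_equal(kappa_coefficient(100 / k, k), 0)
  expect_error(kappa_coefficient(50, 1), "k must be")
  expect_error(kappa_coefficient(120, 5), "\\[0, 100\\]")
})

test_that("kappa_table applies the normalization element-wise", {
  tab <- kappa_table(data.frame(accuracy = c(63.31, 58.75, 20),
                                n_classes = c(3, 4, 5)))
  expect_equal(round(tab$kappa, 2), c(0.45, 0.45, 0))
  expect_equal(tab$kappa[2], 0.45)   # exact, not just rounded
})

test_that("svm_cv is perfect on a separable fixture and at chance under permuted labels", {
  set.seed(62)
  X <- rbind(matrix(rnorm(120, 0), 60), matrix(rnorm(120, 6), 60))
  y <- rep(c("a", "b"), each = 60)
  rep_ <- svm_cv(X, y, k_folds = 6, seed = 1)
  expect_equal(rep_$acc, 100)
  expect_equal(rep_$kappa, 1)
  expect_equal(sum(rep_$confusion), 120)
  expect_equal(unname(rowSums(rep_$confusion)), c(60, 60))
  # permutation null: mean accuracy over 20 seeds within 50 +/- 5
  accs <- vapply(1:20, function(s) {
    set.seed(s)
    svm_cv(X, sample(y), k_folds = 6, seed = s)$acc
  }, 0)
  expect_lt(abs(mean(accs) - 50), 5)
})

test_that("svm_cv validates inputs and reports per-fold detail", {
  X <- matrix(rnorm(60), 30, 2)
  y <- rep(1:2, 15)
  X[3, 1] <- NA
  expect_error(svm_cv(X, y), "non-finite")
  X[3, 1] <- 0
  rep_ <- svm_cv(X, y, k_folds = 6, seed = 0)
  expect_length(rep_$per_fold, 6)
  expect_equal(rep_$p_e, 0.5)
  expect_equal(rep_$kappa, kappa_coefficient(rep_$acc, 2))
  s <- summary(rep_)
  expect_identical(names(s), c("acc", "sen", "spe", "kappa", "k", "folds"))
})
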