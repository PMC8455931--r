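#' Stratified k-fold assignment
#'
#' Assigns observations to `k_folds` folds so that within every class the
#' fold counts differ by at most one (round-robin over a seeded shuffle).
#' A class with fewer members than folds triggers a warning and best-effort
#' stratification (some folds simply lack that class).
#'
#' @param y Class labels.
#' @param k_folds Number of folds (default 6).
#' @param seed Integer seed; identical seeds give identical folds.
#' @return Integer vector of fold ids in `1..k_folds`.
#' @export
stratified_kfold <- function(y, k_folds = 6L, seed = 0L) {
  y <- factor(y)
  n <- length(y)
  if (k_folds < 2 || k_folds > n) stop("k_folds must be in [2, n]")
  folds <- integer(n)
  load <- integer(k_folds)   # global fold sizes, kept within +/- 1
  with_rng_seed(seed, {
    for (cl in levels(y)) {
      idx <- which(y == cl)
      if (length(idx) < k_folds) {
        warning(sprintf("class '%s' has %d member(s) for %d folds; best-effort stratification",
                        cl, length(idx), k_folds))
      }
      idx <- idx[sample.int(length(idx))]
      for (i in idx) {
        f <- which.min(load)   # least-loaded fold; cycles within the class
        folds[i] <- f
        load[f] <- load[f] + 1L
      }
    }
  })
  folds
}

# One-vs-rest multiclass RBF SVM on a standardized training set.
# e1071's decision values are oriented by the first factor level seen in
# training; the helper fixes the orientation explicitly.
.ovr_fit <- function(X, y, cost, gamma) {
  lev <- levels(y)
  models <- vector("list", length(lev))
  names(models) <- lev
  for (cl in lev) {
    yb <- factor(ifelse(y == cl, "pos", "rest"), levels = c("pos", "rest"))
    if (length(unique(yb)) < 2L) next  # class absent in this training fold
    models[[cl]] <- e1071::svm(X, yb, kernel = "radial", cost = cost,
                               gamma = gamma, scale = FALSE)
  }
  models
}

.ovr_predict <- function(models, X, lev) {
  scores <- matrix(-Inf, nrow(X), length(lev), dimnames = list(NULL, lev))
  for (cl in lev) {
    m <- models[[cl]]
    if (is.null(m)) next
    pr <- predict(m, X, decision.values = TRUE)
    dv <- attr(pr, "decision.values")
    # column name "pos/rest" means positive values favor "pos"
    if (!startsWith(colnames(dv)[1], "pos")) dv <- -dv
    scores[, cl] <- dv[, 1]
  }
  lev[max.col(scores, ties.method = "first")]
}

#' Multiclass accuracy from a confusion matrix
#'
#' `100 * trace / total`: the fraction of correctly classified observations
#' (the multiclass generalization of (TP + TN) / all).
#'
#' @param confusion Square count matrix, rows = truth, columns = predicted.
#' @return Percent in `[0, 100]`.
#' @export
accuracy <- function(confusion) {
  confusion <- as.matrix(confusion)
  tot <- sum(confusion)
  if (tot == 0) stop("empty confusion matrix")
  100 * sum(diag(confusion)) / tot
}

# Per-class one-vs-rest TP/FP/FN/TN table from a confusion matrix.
.ovr_counts <- function(confusion) {
  confusion <- as.matrix(confusion)
  tp <- diag(confusion)
  fn <- rowSums(confusion) - tp
  fp <- colSums(confusion) - tp
  tn <- sum(confusion) - tp - fn - fp
  data.frame(class = rownames(confusion) %||% seq_along(tp),
             tp = tp, fn = fn, fp = fp, tn = tn)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Macro-averaged sensitivity
#'
#' One-vs-rest recall `TP / (TP + FN)` per class, averaged over classes
#' with non-zero support (zero-support classes are excluded with a
#' warning).
#'
#' @inheritParams accuracy
#' @return Percent.
#' @export
macro_sensitivity <- function(confusion) {
  cc <- .ovr_counts(confusion)
  sup <- cc$tp + cc$fn > 0
  if (!all(sup)) warning("class(es) with zero support excluded from macro sensitivity")
  100 * mean(cc$tp[sup] / (cc$tp[sup] + cc$fn[sup]))
}

#' Macro-averaged specificity
#'
#' One-vs-rest true-negative rate `TN / (TN + FP)` per class, averaged over
#' classes with non-zero support.
#'
#' @inheritParams accuracy
#' @return Percent.
#' @export
macro_specificity <- function(confusion) {
  cc <- .ovr_counts(confusion)
  sup <- cc$tp + cc$fn > 0
  if (!all(sup)) warning("class(es) with zero support excluded from macro specificity")
  100 * mean(cc$tn[sup] / (cc$tn[sup] + cc$fp[sup]))
}

#' Chance-corrected kappa from accuracy
#'
#' `kappa = (Acc/100 - p_e) / (1 - p_e)` with the uniform chance rate
#' `p_e = 1/k` for a `k`-class problem (0.2 for five classes). Note this is
#' an accuracy normalization across class counts, **not** Cohen's kappa
#' with marginal-product chance agreement: it depends only on the accuracy
#' and the number of classes, maps chance-level accuracy to 0 and perfect
#' accuracy to 1.
#'
#' @param acc Accuracy in percent, `[0, 100]`.
#' @param k Number of classes, `>= 2`.
#' @return Kappa in `[-p_e/(1-p_e), 1]`.
#' @export
#' @examples
#' kappa_coefficient(68.24, 5)   # 0.603
kappa_coefficient <- function(acc, k) {
  if (any(k < 2)) stop("k must be >= 2")
  if (any(acc < 0 | acc > 100)) stop("accuracy must be in [0, 100] percent")
  pe <- 1 / k
  (acc / 100 - pe) / (1 - pe)
}

#' Normalize an accuracy table to kappa coefficients
#'
#' Element-wise [kappa_coefficient()] over a table of (accuracy, class
#' count) entries, enabling comparison of classifiers run on different
#' numbers of classes.
#'
#' @param entries Data frame with columns `accuracy` (percent) and
#'   `n_classes`.
#' @return `entries` with a `kappa` column appended.
#' @export
kappa_table <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("accuracy", "n_classes") %in% names(entries)))
  entries$kappa <- kappa_coefficient(entries$accuracy, entries$n_classes)
  entries
}

#' SVM cross-validation report
#'
#' Stratified k-fold cross-validation of a one-vs-rest RBF-kernel SVM.
#' Features are z-scored with statistics fitted on each training fold only;
#' per-fold confusion matrices are aggregated and the four indices
#' (accuracy, macro sensitivity, macro specificity, chance-corrected kappa)
#' computed on the aggregate.
#'
#' @param X Numeric matrix (or `feature_matrix`), observations x features;
#'   all values finite.
#' @param y Class labels aligned to rows.
#' @param k_folds Number of folds (default 6).
#' @param seed Fold seed (default 0).
#' @param cost SVM cost parameter (default 1).
#' @param gamma RBF bandwidth; default `1/ncol(X)` on the standardized
#'   features.
#' @param standardize Z-score features within training folds
#'   (default `TRUE`).
#' @return An object of class `cv_report`: `acc`, `sen`, `spe`, `kappa`,
#'   aggregate `confusion`, `per_fold` (fold accuracies and confusions),
#'   `k`, `p_e`, and the configuration.
#' @export
svm_cv <- function(X, y, k_folds = 6L, seed = 0L, cost = 1, gamma = NULL,
                   standardize = TRUE) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nrow(X) < 2 * k_folds) stop("need at least 2 * k_folds observations")
  if (!all(is.finite(X))) {
    bad <- which(colSums(!is.finite(X)) > 0)
    stop("non-finite feature values in column(s): ",
         paste(head(colnames(X)[bad] %||% bad, 5), collapse = ", "))
  }
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  lev <- levels(y)
  folds <- suppressWarnings(stratified_kfold(y, k_folds, seed))
  agg <- matrix(0L, length(lev), length(lev), dimnames = list(lev, lev))
  per_fold <- vector("list", k_folds)
  for (f in seq_len(k_folds)) {
    tr <- folds != f
    Xtr <- X[tr, , drop = FALSE]; Xte <- X[!tr, , drop = FALSE]
    if (standardize) {
      mu <- colMeans(Xtr)
      sdv <- apply(Xtr, 2, stats::sd)
      sdv[sdv == 0 | !is.finite(sdv)] <- 1
      Xtr <- sweep(sweep(Xtr, 2, mu), 2, sdv, "/")
      Xte <- sweep(sweep(Xte, 2, mu), 2, sdv, "/")
    }
    models <- .ovr_fit(Xtr, y[tr], cost, gamma)
    pred <- .ovr_predict(models, Xte, lev)
    cm <- table(factor(y[!tr], levels = lev), factor(pred, levels = lev))
    agg <- agg + unclass(cm)
    per_fold[[f]] <- list(fold = f, acc = accuracy(cm), confusion = cm)
  }
  k <- length(lev)
  acc <- accuracy(agg)
  structure(list(acc = acc,
                 sen = suppressWarnings(macro_sensitivity(agg)),
                 spe = suppressWarnings(macro_specificity(agg)),
                 kappa = kappa_coefficient(acc, k),
                 confusion = agg, per_fold = per_fold, k = k, p_e = 1 / k,
                 config = list(k_folds = k_folds, seed = seed, cost = cost,
                               gamma = gamma, standardize = standardize)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d-class, %d-fold CV: Acc %.2f%%, Sen %.2f%%, Spe %.2f%%, Kappa %.3f\n",
              x$k, x$config$k_folds, x$acc, x$sen, x$spe, x$kappa))
  invisible(x)
}

#' One-row summary of a cross-validation report
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return Data frame with acc, sen, spe, kappa, k, folds.
#' @export
summary.cv_report <- function(object, ...) {
  data.frame(acc = object$acc, sen = object$sen, spe = object$spe,
             kappa = object$kappa, k = object$k,
             folds = object$config$k_folds)
}
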