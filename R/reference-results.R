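# Reference results from a published DEAP five-class benchmark of the
# TQWT + BGWO + SVM pipeline, shipped so the package's evaluation
# arithmetic (column means, accuracy increases, kappa normalization) can be
# validated against printed values without any data download.

#' Reference per-subject optima (DEAP benchmark)
#'
#' Published per-subject optimal TQWT parameter combinations and the
#' five-class recognition accuracy before and after BGWO selection, for the
#' 32 DEAP subjects (individual parameter sweep, 6-fold CV).
#'
#' @return Data frame: subject, Q, r, J, acc_before, acc_after (percent).
#' @export
ref_subject_optima <- function() {
  data.frame(
    subject = 1:32,
    Q = c(1, 3, 5, 1, 1, 1, 1, 4, 1, 3, 1, 4, 4, 1, 2, 5, 3, 3, 2, 3, 4, 4,
          1, 1, 5, 1, 1, 3, 1, 1, 3, 3),
    r = 3,
    J = c(4, 2, 3, 4, 4, 2, 1, 1, 4, 1, 3, 3, 1, 5, 3, 3, 3, 1, 6, 1, 4, 1,
          3, 3, 6, 6, 1, 1, 4, 1, 1, 3),
    acc_before = c(52.38, 42.86, 89.68, 52.78, 59.52, 82.14, 59.52, 67.86,
                   77.38, 79.76, 57.94, 57.54, 52.38, 57.54, 85.71, 85.32,
                   82.94, 70.24, 68.25, 88.10, 62.70, 51.59, 67.86, 70.24,
                   54.37, 51.98, 55.16, 42.46, 45.63, 67.06, 73.02, 74.60),
    acc_after = c(60.32, 46.03, 90.48, 54.76, 59.92, 83.33, 63.10, 74.21,
                  77.78, 80.56, 58.33, 58.73, 55.95, 59.92, 87.30, 85.71,
                  83.33, 73.41, 69.84, 88.10, 72.22, 55.16, 72.22, 75.40,
                  61.90, 60.32, 57.14, 43.25, 48.41, 75.40, 73.41, 77.78))
}

#' Reference per-sub-band accuracies (DEAP benchmark)
#'
#' Published five-class accuracy of each feature type on each of the five
#' TQWT sub-bands (Q = 3, r = 3, J = 4; cohort-pooled 1,280-trial
#' matrices), before and after BGWO selection.
#'
#' @return Data frame: bgwo (`before`/`after`), feature, SB1..SB5 (percent).
#' @export
ref_subband_accuracy <- function() {
  data.frame(
    bgwo = rep(c("before", "after"), each = 5),
    feature = rep(c("2dif", "2ndif", "HC", "HM", "SampEn"), 2),
    SB1 = c(57.81, 58.98, 55.86, 55.86, 57.42,
            63.67, 67.58, 60.94, 61.33, 63.28),
    SB2 = c(58.20, 58.59, 61.33, 55.47, 58.21,
            63.28, 64.45, 63.67, 61.72, 61.33),
    SB3 = c(58.59, 60.16, 58.59, 56.64, 57.42,
            61.72, 66.41, 61.33, 62.25, 62.11),
    SB4 = c(57.81, 57.42, 59.37, 57.03, 59.77,
            61.36, 63.28, 63.67, 62.25, 63.28),
    SB5 = c(59.38, 56.64, 58.59, 56.25, 57.03,
            62.11, 62.11, 65.62, 63.28, 60.55))
}

#' Reference fused-cohort indices (DEAP benchmark)
#'
#' Published overall accuracy, macro sensitivity, macro specificity and
#' kappa of each feature type when all subjects and sub-bands are fused
#' (1,280 x 160 matrices after BGWO selection).
#'
#' @return Data frame: feature, all_acc, sen, spe, kappa.
#' @export
ref_fusion_summary <- function() {
  data.frame(
    feature = c("2dif", "2ndif", "HC", "HM", "SampEn"),
    all_acc = c(62.1, 62.5, 62.6, 62.4, 62.1),
    sen = c(70.25, 64.19, 62.12, 65.13, 64.40),
    spe = c(81.33, 82.01, 79.29, 68.70, 79.30),
    kappa = c(0.5263, 0.5313, 0.5325, 0.5300, 0.5263))
}

#' Reference cross-method comparison (DEAP benchmark)
#'
#' Published accuracies and kappa coefficients of EEG emotion-recognition
#' methods evaluated on DEAP with different class counts, used to validate
#' the kappa normalization across class counts (one row per
#' accuracy/kappa pair).
#'
#' @return Data frame: method, n_classes, accuracy (percent), kappa.
#' @export
ref_method_comparison <- function() {
  data.frame(
    method = c(rep("corr+NB", 3), rep("LRFS+LSSVM/NB", 2),
               rep("graph-theoretic+SVM/RVM", 4), "MACI", "ReliefF+SVM",
               "FAWT+SVM", rep("mRMR+SVM", 6), "TQWT-BGWO+SVM"),
    n_classes = c(2, 2, 2, 2, 2, 3, 3, 3, 3, 3, 4, 4, 2, 2, 3, 3, 5, 5, 5),
    accuracy = c(62, 57.6, 55.4, 65, 68, 69, 67, 65, 65, 63.31, 58.75,
                 59.06, 73.14, 73.06, 62.33, 60.70, 46.69, 45.32, 68.24),
    kappa = c(0.24, 0.15, 0.11, 0.30, 0.36, 0.54, 0.51, 0.48, 0.48, 0.45,
              0.45, 0.45, 0.46, 0.46, 0.43, 0.41, 0.33, 0.32, 0.603))
}
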