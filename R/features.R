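#' Sample entropy
#'
#' `SampEn = -ln(A/B)` where `B` counts pairs of distinct `m`-length
#' embedding vectors within Chebyshev distance `u` and `A` the same for
#' `(m+1)`-length vectors (self-matches excluded; both orders use `N - m`
#' templates). Larger values mean a less regular, more complex signal.
#'
#' @param x Numeric sequence, length `> m + 1`.
#' @param m Embedding dimension (default 2).
#' @param u Similarity tolerance; defaults to `0.2 * std(x)` with the
#'   population standard deviation, so the feature is scale-invariant.
#' @return Non-negative scalar. A constant signal returns 0 with a warning
#'   (degenerate, no variability); if no `(m+1)`-length pair matches
#'   (`A = 0`) the value is `Inf` with a warning; `B = 0` is an error.
#' @export
#' @examples
#' sample_entropy(sin(1:200 / 3))
sample_entropy <- function(x, m = 2L, u = NULL) {
  x <- as.numeric(x)
  n <- length(x)
  if (n <= m + 1) stop(sprintf("need length > m + 1 = %d, got %d", m + 1, n))
  s <- sd_pop(x)
  if (s == 0) {
    warning("constant signal: sample entropy undefined, returning 0")
    return(0)
  }
  if (is.null(u)) u <- 0.2 * s
  if (u < 0) stop("tolerance u must be >= 0")
  cnt <- sampen_counts(x, as.integer(m), u)
  if (cnt[1] == 0) stop("no m-length template matches (B = 0); increase u")
  if (cnt[2] == 0) {
    warning("no (m+1)-length template matches (A = 0); returning Inf")
    return(Inf)
  }
  -log(cnt[2] / cnt[1])
}

#' Second-order difference mean
#'
#' The signed mean of the lag-2 differences,
#' `mean(x[n+2] - x[n])`, `n = 1..N-2`. The sum telescopes, so the value
#' equals `(x[N] + x[N-1] - x[2] - x[1]) / (N - 2)`. Much of the literature
#' uses the mean absolute lag-2 difference instead; `absolute = TRUE` opts
#' into that variant.
#'
#' @param x Numeric sequence, length `>= 3`.
#' @param absolute Use `mean(|x[n+2] - x[n]|)` instead of the signed mean.
#' @return Scalar.
#' @export
second_diff_mean <- function(x, absolute = FALSE) {
  n <- length(x)
  if (n < 3) stop("need at least 3 samples")
  d <- x[3:n] - x[1:(n - 2)]
  if (absolute) mean(abs(d)) else mean(d)
}

#' Normalized second-order difference mean
#'
#' [second_diff_mean()] divided by the population standard deviation of the
#' sequence; invariant under positive rescaling of the signal.
#'
#' @inheritParams second_diff_mean
#' @return Scalar.
#' @export
norm_second_diff_mean <- function(x, absolute = FALSE) {
  s <- sd_pop(x)
  if (s == 0) stop("constant signal: normalized second difference undefined")
  second_diff_mean(x, absolute) / s
}

#' Hjorth mobility
#'
#' `sqrt(var(diff(x)) / var(x))` with the first discrete difference as the
#' derivative and population variances: an estimate of the mean (angular)
#' frequency of the signal. For a pure sinusoid of digital frequency `w0`
#' the value is `2 sin(w0 / 2)`; for white noise it approaches `sqrt(2)`.
#'
#' @param x Numeric sequence, length `>= 2`, non-constant.
#' @return Non-negative scalar.
#' @export
hjorth_mobility <- function(x) {
  if (length(x) < 2) stop("need at least 2 samples")
  v <- var_pop(x)
  if (v == 0) stop("constant signal: mobility undefined")
  sqrt(var_pop(diff(x)) / v)
}

#' Hjorth complexity
#'
#' `mobility(diff(x)) / mobility(x)`: the bandwidth-like ratio of the mean
#' frequency of the derivative to that of the signal. A single-frequency
#' signal attains the minimum value 1.
#'
#' @param x Numeric sequence, length `>= 3`, with non-degenerate first
#'   differences.
#' @return Scalar `>= 1` up to estimation noise.
#' @export
hjorth_complexity <- function(x) {
  if (length(x) < 3) stop("need at least 3 samples")
  if (var_pop(x) == 0 || var_pop(diff(x)) == 0) {
    stop("degenerate signal: complexity undefined")
  }
  hjorth_mobility(diff(x)) / hjorth_mobility(x)
}

#' The five feature types in canonical order
#'
#' @return Character vector:
#'   `"SampEn"`, `"2dif"`, `"2ndif"`, `"HM"`, `"HC"`.
#' @export
feature_types <- function() c("SampEn", "2dif", "2ndif", "HM", "HC")

.feature_fun <- function(type) {
  switch(type,
         "SampEn" = function(x) sample_entropy(x),
         "2dif"   = function(x) second_diff_mean(x),
         "2ndif"  = function(x) norm_second_diff_mean(x),
         "HM"     = function(x) hjorth_mobility(x),
         "HC"     = function(x) hjorth_complexity(x),
         stop("unknown feature type: ", type))
}

#' Extract per-sub-band features from a recording
#'
#' Decomposes every trial of every channel with the TQWT and evaluates each
#' requested feature on each of the `J + 1` sub-band coefficient sequences.
#' For each feature type the result is a `trials x ((J+1) * channels)`
#' matrix whose columns are ordered sub-band-major (`SB1_Fp1, SB1_AF3, ...,
#' SB2_Fp1, ...`), carrying a complete `(sub-band, channel)` column index
#' and a `(subject, trial)` row index as attributes. Degenerate cells (flat
#' sub-band, infinite entropy) are imputed to 0 and counted; the count is
#' reported via a message when non-zero.
#'
#' @param rec An [eeg_recording()] (typically preprocessed).
#' @param params A [tqwt_params()].
#' @param features Character subset of
#'   `c("SampEn", "2dif", "2ndif", "HM", "HC")`; default all five.
#' @return Named list of `feature_matrix` objects, one per feature type.
#' @export
extract_features <- function(rec, params = tqwt_params(),
                             features = feature_types()) {
  stopifnot(inherits(rec, "eeg_recording"), inherits(params, "tqwt_params"))
  features <- match.arg(features, feature_types(), several.ok = TRUE)
  d <- dim(rec$data)
  n_trials <- d[1]; n_channels <- d[2]
  n_sb <- params$J + 1L
  col_index <- data.frame(
    subband = rep(seq_len(n_sb), each = n_channels),
    channel = rep(rec$channel_names, times = n_sb))
  col_names <- sprintf("SB%d_%s", col_index$subband, col_index$channel)
  row_index <- data.frame(subject = rec$subject_id, trial = seq_len(n_trials))
  mats <- lapply(features, function(f)
    matrix(NA_real_, n_trials, n_sb * n_channels,
           dimnames = list(NULL, col_names)))
  names(mats) <- features
  funs <- lapply(features, .feature_fun)
  degenerate <- 0L
  for (tr in seq_len(n_trials)) {
    for (ch in seq_len(n_channels)) {
      sb <- tqwt_decompose(rec$data[tr, ch, ], params)
      for (b in seq_len(n_sb)) {
        col <- (b - 1L) * n_channels + ch
        seg <- sb$subbands[[b]]
        for (fi in seq_along(features)) {
          val <- suppressWarnings(tryCatch(funs[[fi]](seg),
                                           error = function(e) NA_real_))
          if (!is.finite(val)) {
            degenerate <- degenerate + 1L
            val <- 0
          }
          mats[[fi]][tr, col] <- val
        }
      }
    }
  }
  if (degenerate > 0L) {
    message(sprintf("extract_features: %d degenerate cell(s) imputed to 0",
                    degenerate))
  }
  lapply(mats, function(m)
    structure(m, column_index = col_index, row_index = row_index,
              tqwt = unclass(params), class = c("feature_matrix", "matrix")))
}

#' Fuse feature matrices across subjects and sub-bands
#'
#' Assembles the three layouts used downstream of feature extraction, for a
#' list of per-subject matrices of one feature type:
#' \describe{
#'   \item{`per_subject_subband_fused`}{one subject, all sub-bands:
#'     `trials x ((J+1) * channels)` (40 x 160 at the default settings).}
#'   \item{`per_subband_subject_fused`}{all subjects stacked, a single
#'     sub-band's channels: `(subjects * trials) x channels`
#'     (1,280 x 32 for a 32-subject cohort).}
#'   \item{`all_fused`}{all subjects stacked, all sub-bands:
#'     `(subjects * trials) x ((J+1) * channels)` (1,280 x 160).}
#' }
#'
#' @param matrices A `feature_matrix` or list of them (same feature type and
#'   column layout, one per subject).
#' @param mode One of the three layouts above.
#' @param subband Sub-band number, required for `per_subband_subject_fused`.
#' @return A `feature_matrix` in the requested layout.
#' @export
fuse_features <- function(matrices,
                          mode = c("per_subject_subband_fused",
                                   "per_subband_subject_fused",
                                   "all_fused"),
                          subband = NULL) {
  mode <- match.arg(mode)
  if (inherits(matrices, "feature_matrix")) matrices <- list(matrices)
  stopifnot(length(matrices) >= 1,
            all(vapply(matrices, inherits, TRUE, "feature_matrix")))
  ci <- attr(matrices[[1]], "column_index")
  for (m in matrices[-1]) {
    if (!identical(attr(m, "column_index"), ci)) {
      stop("feature matrices have incompatible column layouts")
    }
  }
  rows <- do.call(rbind, lapply(matrices, function(m) attr(m, "row_index")))
  if (anyDuplicated(rows)) stop("row index collision across subjects")
  if (mode == "per_subject_subband_fused") {
    if (length(matrices) != 1) {
      stop("per_subject_subband_fused expects a single subject's matrix")
    }
    return(matrices[[1]])
  }
  stacked <- do.call(rbind, lapply(matrices, unclass))
  if (mode == "all_fused") {
    return(structure(stacked, column_index = ci, row_index = rows,
                     tqwt = attr(matrices[[1]], "tqwt"),
                     class = c("feature_matrix", "matrix")))
  }
  if (is.null(subband)) stop("`subband` is required for per_subband_subject_fused")
  keep <- which(ci$subband == subband)
  if (length(keep) == 0) stop("no columns for sub-band ", subband)
  structure(stacked[, keep, drop = FALSE],
            column_index = ci[keep, , drop = FALSE], row_index = rows,
            tqwt = attr(matrices[[1]], "tqwt"),
            class = c("feature_matrix", "matrix"))
}
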