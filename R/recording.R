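#' The 32 EEG channel names of the DEAP montage
#'
#' Ordered 10--20 system channel list used by the DEAP recordings (the first
#' 32 channels of each trial; the remaining 8 are peripheral signals).
#'
#' @return Character vector of length 32.
#' @export
#' @examples
#' deap_channels()[1:4]
deap_channels <- function() {
  c("Fp1", "AF3", "F3", "F7", "FC5", "FC1", "C3", "T7",
    "CP5", "CP1", "P3", "P7", "PO3", "O1", "Oz", "Pz",
    "Fp2", "AF4", "Fz", "F4", "F8", "FC6", "FC2", "Cz",
    "C4", "T8", "CP6", "CP2", "P4", "P8", "PO4", "O2")
}

#' Construct an EEG recording object
#'
#' Bundles one subject's trial tensor with its self-assessment ratings.
#' `data` is `trials x channels x samples` in microvolts at sampling rate
#' `fs`; `ratings` is `trials x 4` (valence, arousal, dominance, liking,
#' each on the 1--9 scale).
#'
#' @param data Numeric 3-d array, `n_trials x n_channels x n_samples`.
#' @param ratings Numeric matrix, `n_trials x 4`, values in `[1, 9]`.
#' @param subject_id Identifier for the subject.
#' @param fs Sampling rate in Hz (DEAP preprocessed release: 128).
#' @param channel_names Ordered channel labels; defaults to [deap_channels()]
#'   when the tensor has 32 channels. A mismatch in names warns but proceeds
#'   by position.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, ratings, subject_id = "s01", fs = 128,
                          channel_names = NULL) {
  if (!is.array(data) || length(dim(data)) != 3L) {
    stop("`data` must be a 3-d array (trials x channels x samples)")
  }
  if (!all(is.finite(data))) stop("`data` contains non-finite values")
  d <- dim(data)
  ratings <- as.matrix(ratings)
  if (nrow(ratings) != d[1] || ncol(ratings) != 4L) {
    stop(sprintf("`ratings` must be %d x 4, found %d x %d",
                 d[1], nrow(ratings), ncol(ratings)))
  }
  if (any(ratings < 1 | ratings > 9)) {
    stop("ratings must lie in [1, 9]")
  }
  if (is.null(channel_names)) {
    channel_names <- if (d[2] == 32L) deap_channels() else
      sprintf("ch%02d", seq_len(d[2]))
  }
  if (length(channel_names) != d[2]) {
    stop(sprintf("%d channel names supplied for %d channels",
                 length(channel_names), d[2]))
  }
  if (d[2] == 32L && !identical(channel_names, deap_channels())) {
    warning("channel names differ from the DEAP montage; proceeding by position")
  }
  colnames(ratings) <- c("valence", "arousal", "dominance", "liking")
  structure(list(subject_id = subject_id, data = data, ratings = ratings,
                 fs = fs, channel_names = channel_names),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_recording> subject %s: %d trials x %d channels x %d samples @ %g Hz\n",
              x$subject_id, d[1], d[2], d[3], x$fs))
  invisible(x)
}

#' Validate a recording against the DEAP preprocessed-release invariants
#'
#' Checks the shape contract of the preprocessed DEAP layout: 32 channels,
#' 8,064 samples at 128 Hz (63 s), finite values, ratings in range.
#'
#' @param rec An [eeg_recording()].
#' @param n_trials,n_channels,n_samples,fs Expected dimensions.
#' @return `rec`, invisibly; errors describe expected vs found dimensions.
#' @export
validate_recording <- function(rec, n_trials = 40L, n_channels = 32L,
                               n_samples = 8064L, fs = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- dim(rec$data)
  want <- c(n_trials, n_channels, n_samples)
  if (!all(d == want)) {
    stop(sprintf("recording shape mismatch: expected %s, found %s",
                 paste(want, collapse = " x "), paste(d, collapse = " x ")))
  }
  if (rec$fs != fs) {
    stop(sprintf("sampling rate mismatch: expected %g Hz, found %g Hz", fs, rec$fs))
  }
  if (!all(is.finite(rec$data))) stop("recording contains non-finite values")
  invisible(rec)
}
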