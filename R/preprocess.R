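#' Resample a signal to a lower rate
#'
#' Polyphase anti-aliased resampling (via [signal::resample()]); only
#' downsampling (or the identity) is supported, matching the preprocessing
#' of the 512 Hz raw recordings down to 128 Hz.
#'
#' @param x Numeric signal.
#' @param fs_in,fs_out Input and output sampling rates in Hz,
#'   `fs_in >= fs_out > 0`.
#' @return Numeric vector of length `round(length(x) * fs_out / fs_in)`.
#' @export
resample_signal <- function(x, fs_in, fs_out) {
  if (fs_out <= 0 || fs_in <= 0) stop("sampling rates must be positive")
  if (fs_out > fs_in) stop("upsampling is not supported (fs_out > fs_in)")
  if (fs_out == fs_in) return(x)
  frac <- .rat_approx(fs_out / fs_in)
  y <- signal::resample(x, frac[1], frac[2])
  n_out <- round(length(x) * fs_out / fs_in)
  length(y) <- n_out          # signal::resample may overshoot by < 1 sample
  y[is.na(y)] <- 0
  y
}

# Small continued-fraction rational approximation p/q of a ratio in (0, 1].
.rat_approx <- function(r, tol = 1e-9, max_den = 10000L) {
  for (q in seq_len(max_den)) {
    p <- round(r * q)
    if (p >= 1 && abs(p / q - r) < tol) return(c(p, q))
  }
  stop("cannot express the rate ratio as a small rational number")
}

#' Zero-phase band-pass filter
#'
#' Two-pass (forward--backward) Butterworth band-pass, order `order` per
#' pass, applied with [signal::filtfilt()] so the output has no phase
#' distortion and the same length as the input. Defaults give the 4--45 Hz
#' EEG passband.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param lo,hi Band edges in Hz, `0 < lo < hi < fs/2`.
#' @param order Butterworth design order per edge (default 4).
#' @return Filtered signal, same length as `x`.
#' @export
bandpass_filter <- function(x, fs, lo = 4, hi = 45, order = 4) {
  if (!(lo > 0 && hi > lo)) stop("band edges must satisfy 0 < lo < hi")
  if (hi >= fs / 2) stop(sprintf("upper edge %g Hz must be below Nyquist %g Hz",
                                 hi, fs / 2))
  bf <- signal::butter(order, c(lo, hi) / (fs / 2), type = "pass")
  as.numeric(signal::filtfilt(bf, x))
}

#' Common (whole-brain) average reference
#'
#' Subtracts the instantaneous mean over all channels from every channel,
#' so each output sample has zero mean across channels.
#'
#' @param trial Numeric matrix, `channels x samples`.
#' @return Re-referenced matrix of the same shape.
#' @export
average_reference <- function(trial) {
  trial <- as.matrix(trial)
  if (nrow(trial) < 2L) stop("average reference needs at least 2 channels")
  sweep(trial, 2L, colMeans(trial))
}

#' Preprocess a recording
#'
#' Applies the standard preprocessing chain trial by trial: zero-phase
#' 4--45 Hz band-pass on every channel, then the whole-brain average
#' reference. (Resampling to 128 Hz and ocular-artifact removal are assumed
#' already done, as in the DEAP preprocessed release.)
#'
#' @param rec An [eeg_recording()].
#' @param lo,hi Band edges in Hz.
#' @param order Butterworth order per pass.
#' @return A new [eeg_recording()] with the processed tensor.
#' @export
preprocess_recording <- function(rec, lo = 4, hi = 45, order = 4) {
  stopifnot(inherits(rec, "eeg_recording"))
  d <- dim(rec$data)
  out <- rec$data
  for (tr in seq_len(d[1])) {
    m <- out[tr, , ]
    for (ch in seq_len(d[2])) {
      m[ch, ] <- bandpass_filter(m[ch, ], rec$fs, lo, hi, order)
    }
    out[tr, , ] <- average_reference(m)
  }
  rec$data <- out
  rec
}
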