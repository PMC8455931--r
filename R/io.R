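# DEAP-layout container: a flat little-endian binary file.
#   bytes 1-4   magic "EEGR"
#   int32       format version (1)
#   int32 x 3   n_trials, n_channels, n_samples
#   float64     sampling rate (Hz)
#   float64 x (trials*channels*samples)   data tensor, R column-major order
#                                         with dim (trials, channels, samples)
#   float64 x (trials*4)                  ratings (valence, arousal,
#                                         dominance, liking), column-major
.EEGR_MAGIC <- "EEGR"

#' Write a recording to a DEAP-layout container file
#'
#' Stores the trial tensor and ratings in the flat binary layout documented
#' in the README. A 32-channel recording is padded with 8 all-zero peripheral
#' channels so the file carries the native DEAP 40-channel layout; the reader
#' drops them again, making generator round-trips exact.
#'
#' @param rec An [eeg_recording()].
#' @param path Output file path.
#' @param pad_to_40 Pad 32-channel tensors to 40 channels with zeros
#'   (default `TRUE`, the DEAP file layout).
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path, pad_to_40 = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  data <- rec$data
  d <- dim(data)
  if (pad_to_40 && d[2] == 32L) {
    full <- array(0, dim = c(d[1], 40L, d[3]))
    full[, 1:32, ] <- data
    data <- full
    d <- dim(data)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.EEGR_MAGIC), con)
  writeBin(as.integer(c(1L, d)), con, size = 4L, endian = "little")
  writeBin(as.double(rec$fs), con, size = 8L, endian = "little")
  writeBin(as.double(data), con, size = 8L, endian = "little")
  writeBin(as.double(rec$ratings), con, size = 8L, endian = "little")
  invisible(path)
}

#' Read a DEAP-layout recording
#'
#' Reads the container written by [write_recording()] (or any file following
#' the documented layout), validates the expected shape and returns the first
#' 32 channels (the EEG channels of the DEAP montage) paired with the
#' per-trial ratings in file order.
#'
#' @param path File path.
#' @param subject_id Identifier to attach to the returned recording.
#' @param n_trials,n_samples Expected trial count and samples per trial;
#'   a mismatch is a format error naming expected vs found dimensions.
#' @return An [eeg_recording()] with 32 channels.
#' @export
load_recording <- function(path, subject_id = "s01", n_trials = 40L,
                           n_samples = 8064L) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, .EEGR_MAGIC)) {
    stop(sprintf("not a DEAP-layout container (magic '%s', expected '%s')",
                 magic, .EEGR_MAGIC))
  }
  hdr <- readBin(con, "integer", 4L, size = 4L, endian = "little")
  if (hdr[1] != 1L) stop("unsupported container version ", hdr[1])
  d <- hdr[2:4]
  fs <- readBin(con, "double", 1L, size = 8L, endian = "little")
  if (d[1] != n_trials || d[3] != n_samples) {
    stop(sprintf("recording shape mismatch: expected %d x {32|40} x %d, found %d x %d x %d",
                 n_trials, n_samples, d[1], d[2], d[3]))
  }
  if (!d[2] %in% c(32L, 40L)) {
    stop(sprintf("expected 32 or 40 channels, found %d", d[2]))
  }
  data <- readBin(con, "double", prod(d), size = 8L, endian = "little")
  dim(data) <- d
  ratings <- readBin(con, "double", d[1] * 4L, size = 8L, endian = "little")
  dim(ratings) <- c(d[1], 4L)
  eeg_recording(data[, 1:32, , drop = FALSE], ratings,
                subject_id = subject_id, fs = fs,
                channel_names = deap_channels())
}

#' Map a 1--9 rating to a discrete level
#'
#' Discretizes the 9-point self-assessment scale into three levels: the
#' integer bins 1--3, 4--6 and 7--9 map to -1, 0 and +1. Because DEAP
#' ratings are continuous, the bins are realized as `[1, 4)`, `[4, 7)` and
#' `[7, 9]`, which agree with the integer partition on whole numbers.
#'
#' @param rating Numeric vector of ratings in `[1, 9]`.
#' @param cuts Interior bin boundaries (defaults `c(4, 7)`); a rating below
#'   `cuts[1]` maps to -1, at or above `cuts[2]` to +1, otherwise 0.
#' @return Integer vector of levels in `{-1, 0, 1}`.
#' @export
#' @examples
#' map_rating_to_level(c(2, 5, 9))
map_rating_to_level <- function(rating, cuts = c(4, 7)) {
  if (any(!is.finite(rating)) || any(rating < 1 | rating > 9)) {
    stop("ratings must lie in [1, 9]")
  }
  ifelse(rating < cuts[1], -1L, ifelse(rating < cuts[2], 0L, 1L))
}

#' Map valence/arousal levels to a five-class emotion label
#'
#' The quadrant rule of the five-class valence--arousal scheme:
#' (+1, +1) = 1 happy, (+1, -1) = 2 anger, (-1, -1) = 3 sad,
#' (-1, +1) = 4 relax, and any level equal to 0 = 5 neutral. Note the
#' anger/relax quadrant assignment follows the scheme as published, which is
#' the mirror of the conventional circumplex; `swap_quadrants = TRUE`
#' exchanges the two (happy/sad are unaffected).
#'
#' @param v_level,a_level Integer vectors with values in `{-1, 0, 1}`:
#'   valence and arousal levels from [map_rating_to_level()].
#' @param swap_quadrants Swap the anger and relax quadrants.
#' @return Integer labels in 1..5.
#' @export
#' @examples
#' map_levels_to_emotion(1, 1)    # happy
#' map_levels_to_emotion(0, 1)    # neutral
map_levels_to_emotion <- function(v_level, a_level, swap_quadrants = FALSE) {
  stopifnot(length(v_level) == length(a_level))
  if (!all(v_level %in% c(-1L, 0L, 1L)) || !all(a_level %in% c(-1L, 0L, 1L))) {
    stop("levels must be in {-1, 0, 1}")
  }
  out <- integer(length(v_level))
  out[v_level == 0L | a_level == 0L] <- 5L
  q <- v_level != 0L & a_level != 0L
  anger <- if (swap_quadrants) cbind(-1L, 1L) else cbind(1L, -1L)
  out[q & v_level == 1L & a_level == 1L] <- 1L
  out[q & v_level == anger[1] & a_level == anger[2]] <- 2L
  out[q & v_level == -1L & a_level == -1L] <- 3L
  out[q & v_level == -anger[1] & a_level == -anger[2]] <- 4L
  out
}

#' Emotion class names
#'
#' @return Named character vector mapping labels 1..5 to class names.
#' @export
emotion_classes <- function() {
  c(`1` = "happy", `2` = "anger", `3` = "sad", `4` = "relax", `5` = "neutral")
}

#' Tabulate trial labels for a recording
#'
#' Applies the rating-to-level and level-to-emotion maps to every trial and
#' returns the full label bookkeeping as a data frame (one row per trial),
#' suitable for CSV export with [write_labels_csv()].
#'
#' @param rec An [eeg_recording()].
#' @inheritParams map_levels_to_emotion
#' @return A data.frame with columns subject, trial, valence, arousal,
#'   dominance, liking, level_v, level_a, class.
#' @export
label_trials <- function(rec, swap_quadrants = FALSE) {
  stopifnot(inherits(rec, "eeg_recording"))
  r <- rec$ratings
  lv <- map_rating_to_level(r[, "valence"])
  la <- map_rating_to_level(r[, "arousal"])
  data.frame(subject = rec$subject_id, trial = seq_len(nrow(r)),
             valence = r[, "valence"], arousal = r[, "arousal"],
             dominance = r[, "dominance"], liking = r[, "liking"],
             level_v = lv, level_a = la,
             class = map_levels_to_emotion(lv, la, swap_quadrants),
             row.names = NULL)
}

#' Write a trial-label table to CSV
#'
#' @param labels Data frame from [label_trials()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  write.csv(labels, path, row.names = FALSE)
  invisible(path)
}
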