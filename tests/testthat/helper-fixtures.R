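# Shared fixtures and independent oracles. Cohort fixtures are generated
# once per test run and cached (generation is seeded, so caching does not
# change any value).

.fixture_env <- new.env(parent = emptyenv())

fixture_cohort <- function(n_subjects = 1, effect = 0.5, seed = 101) {
  key <- sprintf("coh_%d_%g_%d", n_subjects, effect, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_cohort(
      synth_config(n_subjects = n_subjects, effect_size = effect, seed = seed))
  }
  .fixture_env[[key]]
}

# A small recording (not DEAP-sized) for fast structural tests.
tiny_recording <- function(n_trials = 3, n_channels = 2, n_samples = 512,
                           seed = 5, zero = FALSE) {
  set.seed(seed)
  data <- if (zero) {
    array(0, dim = c(n_trials, n_channels, n_samples))
  } else {
    array(rnorm(n_trials * n_channels * n_samples),
          dim = c(n_trials, n_channels, n_samples))
  }
  ratings <- matrix(rep(c(8, 8, 5, 5), each = n_trials), n_trials, 4)
  eeg_recording(data, ratings, subject_id = paste0("tiny", seed), fs = 128,
                channel_names = sprintf("ch%d", seq_len(n_channels)))
}

# O(N^2) brute-force sample-entropy template counts (the independent
# oracle for the box-assisted C++ kernel).
brute_sampen_counts <- function(x, m, u) {
  n <- length(x) - m
  B <- 0; A <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)])) <= u) {
        B <- B + 1
        if (abs(x[i + m] - x[j + m]) <= u) A <- A + 1
      }
    }
  }
  c(B = B, A = A)
}

brute_sampen <- function(x, m = 2, u) {
  cnt <- brute_sampen_counts(x, m, u)
  -log(cnt["A"] / cnt["B"])
}

pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

# Dominant FFT frequency (Hz) of a signal.
fft_peak_hz <- function(x, fs) {
  n <- length(x)
  mag <- Mod(fft(x))[2:(n %/% 2)]
  which.max(mag) * fs / n
}
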