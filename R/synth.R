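#' Configuration for the synthetic EEG cohort generator
#'
#' Describes a DEAP-shaped cohort: per-subject trial tensors of
#' `n_trials x n_channels x (fs * duration)` samples with 1--9 ratings.
#' Every trial carries a latent emotion class drawn from
#' `class_distribution`; the class modulates the power of the four
#' classical EEG bands, and the ratings are placed at level-bin centers so
#' the label maps recover the latent class exactly.
#'
#' @param n_subjects Number of subjects (default 4).
#' @param n_trials Trials per subject (default 40).
#' @param n_channels Channels (default 32, the DEAP EEG montage).
#' @param fs Sampling rate in Hz (default 128).
#' @param duration Trial length in seconds (default 63); `fs * duration`
#'   must equal 8,064, the DEAP preprocessed trial length.
#' @param class_distribution Probabilities over the five classes
#'   happy/anger/sad/relax/neutral (default uniform).
#' @param effect_size Relative class-conditioned band-power modulation,
#'   `>= 0` (default 0.5); 0 makes the classes statistically
#'   indistinguishable.
#' @param noise_exponent Spectral slope of the 1/f background (default 1).
#' @param seed Integer seed (default 0).
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 4L, n_trials = 40L, n_channels = 32L,
                         fs = 128, duration = 63,
                         class_distribution = rep(0.2, 5),
                         effect_size = 0.5, noise_exponent = 1, seed = 0L) {
  if (abs(sum(class_distribution) - 1) > 1e-8 || any(class_distribution < 0)) {
    stop("class_distribution must be non-negative and sum to 1")
  }
  if (length(class_distribution) != 5L) {
    stop("class_distribution must have 5 entries (happy, anger, sad, relax, neutral)")
  }
  if (effect_size < 0) stop("effect_size must be >= 0")
  n_samples <- as.integer(round(fs * duration))
  if (n_samples != 8064L) {
    stop(sprintf("fs * duration must give the DEAP trial length 8,064 samples (got %d)",
                 n_samples))
  }
  structure(list(n_subjects = as.integer(n_subjects),
                 n_trials = as.integer(n_trials),
                 n_channels = as.integer(n_channels),
                 fs = fs, duration = duration, n_samples = n_samples,
                 class_distribution = class_distribution,
                 effect_size = effect_size,
                 noise_exponent = noise_exponent, seed = as.integer(seed)),
            class = "synth_config")
}

# Class -> band-power template over (theta, alpha, beta, gamma):
# +1 = elevated, -1 = suppressed, 0 = baseline. Neutral is all-baseline.
.class_band_template <- function() {
  matrix(c( 0,  0,  1,  1,    # happy: beta + gamma up
            0, -1,  1,  0,    # anger: beta up, alpha down
            1,  0,  0,  0,    # sad:   theta up
            0,  1,  0,  0,    # relax: alpha up
            0,  0,  0,  0),   # neutral: baseline
         nrow = 5, byrow = TRUE,
         dimnames = list(unname(emotion_classes()),
                         c("theta", "alpha", "beta", "gamma")))
}

.band_edges <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30), gamma = c(30, 45))
}

# Base per-band amplitudes (microvolt-scale sd) and 1/f background sd.
.band_base_sd <- c(theta = 4, alpha = 5, beta = 4, gamma = 3)
.pink_sd <- 8

# Band-limited Gaussian noise via frequency-domain masking, unit sd.
.band_noise <- function(n, fs, lo, hi) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- as.numeric(f >= lo & f <= hi)
  .spectral_noise(n, amp)
}

# 1/f^(exponent/2) amplitude noise above 1 Hz, unit sd.
.pink_noise <- function(n, fs, exponent) {
  nf <- n %/% 2
  f <- (1:nf) * fs / n
  amp <- ifelse(f >= 1, f^(-exponent / 2), 0)
  .spectral_noise(n, amp)
}

# Real signal with prescribed positive-frequency amplitude profile and
# random phases, normalized to unit population sd.
.spectral_noise <- function(n, amp) {
  nf <- length(amp)
  phases <- runif(nf, 0, 2 * pi)
  spec <- complex(length.out = n)
  spec[2:(nf + 1)] <- amp * exp(1i * phases)
  spec[n:(n - nf + 2)] <- Conj(spec[2:nf])   # mirror (Nyquist left real)
  x <- Re(fft(spec, inverse = TRUE))
  s <- sd_pop(x)
  if (s == 0) return(x)
  x / s
}

# Ratings at level-bin centers so label recovery is exact:
# (valence, arousal) per class; dominance/liking neutral.
.class_ratings <- function(class) {
  va <- rbind(c(8, 8), c(8, 2), c(2, 2), c(2, 8), c(5, 5))[class, , drop = FALSE]
  cbind(va, 5, 5)
}

#' Generate a synthetic DEAP-shaped cohort
#'
#' Each trial is a 1/f background plus band-limited oscillations in the
#' four classical bands (theta 4--8, alpha 8--13, beta 13--30, gamma
#' 30--45 Hz) whose amplitudes are modulated by the trial's latent class
#' through a fixed class-to-band template (happy: beta+gamma up; anger:
#' beta up, alpha down; sad: theta up; relax: alpha up; neutral:
#' baseline), scaled by `effect_size`. Ratings sit at the level-bin
#' centers (2 / 5 / 8), so [label_trials()] recovers the latent class for
#' every trial. Fully reproducible from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List of [eeg_recording()] objects, one per subject; each
#'   carries a `latent_class` attribute with the per-trial classes.
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  template <- .class_band_template()
  edges <- .band_edges()
  n <- config$n_samples
  with_rng_seed(config$seed, {
    lapply(seq_len(config$n_subjects), function(s) {
      classes <- sample.int(5L, config$n_trials, replace = TRUE,
                            prob = config$class_distribution)
      data <- array(0, dim = c(config$n_trials, config$n_channels, n))
      for (tr in seq_len(config$n_trials)) {
        mult <- pmax(1 + config$effect_size * template[classes[tr], ], 0.05)
        for (ch in seq_len(config$n_channels)) {
          x <- .pink_sd * .pink_noise(n, config$fs, config$noise_exponent)
          jit <- exp(rnorm(4, 0, 0.1))
          for (b in seq_along(edges)) {
            x <- x + .band_base_sd[b] * mult[b] * jit[b] *
              .band_noise(n, config$fs, edges[[b]][1], edges[[b]][2])
          }
          data[tr, ch, ] <- x
        }
      }
      rec <- eeg_recording(data, .class_ratings(classes),
                           subject_id = sprintf("synth%02d", s),
                           fs = config$fs)
      attr(rec, "latent_class") <- classes
      rec
    })
  })
}

#' Planted-informative feature matrix
#'
#' A fixture for exercising feature selection: `n_informative` columns
#' carry class-conditioned mean shifts of size `effect` (column `j` is
#' elevated by `effect` for class `((j - 1) mod 5) + 1`), the remaining
#' `n_noise` columns are standard Gaussian noise. Labels cycle through the
#' five classes and are shuffled. Bit-reproducible from `seed`.
#'
#' @param n_rows Observations.
#' @param n_informative Number of informative columns, `>= 1`.
#' @param n_noise Number of pure-noise columns.
#' @param effect Mean shift in units of the noise sd.
#' @param seed Integer seed.
#' @return List with `X` (matrix, informative columns first, named
#'   `inf1..`/`noise1..`), `y` (factor of classes 1..5), and
#'   `informative` (column indices).
#' @export
planted_feature_matrix <- function(n_rows, n_informative = 5L,
                                   n_noise = 27L, effect = 3, seed = 0L) {
  if (n_informative < 1) stop("need at least one informative column")
  d <- n_informative + n_noise
  with_rng_seed(seed, {
    y <- factor(sample(rep_len(1:5, n_rows)), levels = 1:5)
    X <- matrix(rnorm(n_rows * d), n_rows, d)
    for (j in seq_len(n_informative)) {
      cls <- (j - 1L) %% 5L + 1L
      X[, j] <- X[, j] + effect * (as.integer(y) == cls)
    }
    colnames(X) <- c(sprintf("inf%d", seq_len(n_informative)),
                     if (n_noise > 0) sprintf("noise%d", seq_len(n_noise)))
  })
  list(X = X, y = y, informative = seq_len(n_informative))
}
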