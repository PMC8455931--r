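#' Scaling factors of the tunable Q-factor wavelet transform
#'
#' The per-stage frequency-scaling ratios of the oversampled two-channel
#' filter bank: high-pass factor `h = 2/(Q+1)` and low-pass factor
#' `l = 1 - h/r`. The filter bank is oversampled (`l + h > 1`) whenever
#' \eqn{r > 1}.
#'
#' @param Q Quality factor, `Q >= 1`.
#' @param r Total oversampling rate (redundancy), greater than 1.
#' @return Named numeric vector `c(l = , h = )`, both in `(0, 1]`.
#' @export
#' @examples
#' scaling_factors(3, 3)   # l = 5/6, h = 1/2
scaling_factors <- function(Q, r) {
  if (!is.finite(Q) || Q < 1) stop("Q must be >= 1")
  if (!is.finite(r) || r <= 1) stop("r must be > 1")
  h <- 2 / (Q + 1)
  c(l = 1 - h / r, h = h)
}

#' TQWT parameter set
#'
#' Bundles the three tunable parameters of the transform with their derived
#' scaling factors. `Q` controls how oscillatory the wavelet is (center
#' frequency over bandwidth), `r` the redundancy of the filter bank, and `J`
#' the number of two-channel stages; a `J`-stage transform yields `J + 1`
#' sub-bands.
#'
#' @param Q Quality factor, `>= 1`.
#' @param r Oversampling rate, `> 1` (3 is the standard choice).
#' @param J Number of stages, integer `>= 1`.
#' @return An object of class `tqwt_params`.
#' @export
#' @examples
#' tqwt_params(3, 3, 4)
tqwt_params <- function(Q = 3, r = 3, J = 4) {
  sf <- scaling_factors(Q, r)
  if (!is.finite(J) || J < 1 || J != round(J)) stop("J must be an integer >= 1")
  structure(list(Q = Q, r = r, J = as.integer(J),
                 l = unname(sf["l"]), h = unname(sf["h"])),
            class = "tqwt_params")
}

#' @export
print.tqwt_params <- function(x, ...) {
  cat(sprintf("<tqwt_params> Q = %g, r = %g, J = %d  (l = %.4f, h = %.4f)\n",
              x$Q, x$r, x$J, x$l, x$h))
  invisible(x)
}

# Even-length bookkeeping of one analysis stage on a length-N input:
# low-pass output length N0 = 2*round(l*N/2), high-pass N1 = 2*round(h*N/2).
# The transition band has T = (N0+N1-N)/2 - 1 bins per side.
.stage_dims <- function(N, l, h) {
  N0 <- 2 * round(l * N / 2)
  N1 <- 2 * round(h * N / 2)
  list(N = N, N0 = N0, N1 = N1,
       P = (N - N1) / 2, T = (N0 + N1 - N) / 2 - 1)
}

.stage_feasible <- function(dm) {
  dm$T >= 0 && dm$P >= 0 && dm$N0 >= 4 && dm$N0 < dm$N && dm$N1 >= 2
}

# Lengths of the low-pass chain: input lengths of stages 1..J (and the
# final low-pass length as element J+1). Errors if a stage is infeasible.
.chain_lengths <- function(N, l, h, J) {
  lens <- integer(J + 1)
  cur <- N
  for (j in seq_len(J)) {
    lens[j] <- cur
    dm <- .stage_dims(cur, l, h)
    if (!.stage_feasible(dm)) {
      stop(sprintf("stage %d infeasible for signal length %d; max_stages = %d",
                   j, N, .count_stages(N, l, h)))
    }
    cur <- dm$N0
  }
  lens[J + 1] <- cur
  lens
}

.count_stages <- function(N, l, h) {
  J <- 0L
  cur <- N
  repeat {
    dm <- .stage_dims(cur, l, h)
    if (!.stage_feasible(dm)) break
    J <- J + 1L
    cur <- dm$N0
  }
  J
}

#' Maximum feasible decomposition depth
#'
#' Largest number of stages `J` such that every stage of the low-pass chain
#' keeps a valid (even, shrinking, transition-band-capable) length for a
#' signal of `N` samples. Monotone non-decreasing in `N`.
#'
#' @param params A [tqwt_params()] (its `J` is ignored here).
#' @param N Signal length (even, `>= 8`).
#' @return Integer `J_max`.
#' @export
#' @examples
#' max_stages(tqwt_params(3, 3), 8064)   # comfortably >= 4
max_stages <- function(params, N) {
  stopifnot(inherits(params, "tqwt_params"))
  if (N < 8) stop("N must be >= 8")
  .count_stages(if (N %% 2 == 1) N + 1 else N, params$l, params$h)
}

# Daubechies transition function with 2 vanishing moments and its
# power-complement; theta(v)^2 + theta_c(v)^2 = 1 on [0, pi].
.theta <- function(v) 0.5 * (1 + cos(v)) * sqrt(2 - cos(v))
.theta_c <- function(v) 0.5 * (1 - cos(v)) * sqrt(2 + cos(v))

# Positive-frequency weight vectors of one stage (bins 1..N0/2-1 for the
# low-pass channel; the high-pass weights cover original bins P+1..N/2-1).
.stage_weights <- function(dm) {
  tv <- if (dm$T > 0) seq_len(dm$T) * pi / (dm$T + 1) else numeric(0)
  list(w0 = c(rep(1, dm$P), .theta(tv)),
       w1 = c(.theta_c(tv), rep(1, dm$N1 / 2 - 1 - dm$T)))
}

# One analysis stage, unitary DFT convention: splits x into the low-pass
# subband (length N0) and high-pass subband (length N1). Exact tight frame:
# ||v0||^2 + ||v1||^2 = ||x||^2.
.tqwt_afb <- function(x, l, h) {
  N <- length(x)
  dm <- .stage_dims(N, l, h)
  w <- .stage_weights(dm)
  X <- fft(x) / sqrt(N)
  N0 <- dm$N0; N1 <- dm$N1
  V0 <- complex(length.out = N0)
  V1 <- complex(length.out = N1)
  V0[1] <- X[1]
  k <- seq_len(N0 / 2 - 1)
  V0[1 + k] <- X[1 + k] * w$w0
  V0[N0 + 1 - k] <- X[N + 1 - k] * w$w0
  j <- seq_len(N1 / 2 - 1)
  V1[1 + j] <- X[1 + dm$P + j] * w$w1
  V1[N1 / 2 + 1] <- X[N / 2 + 1]
  V1[N1 + 1 - j] <- X[N + 1 - (dm$P + j)] * w$w1
  list(low = Re(fft(V0, inverse = TRUE)) / sqrt(N0),
       high = Re(fft(V1, inverse = TRUE)) / sqrt(N1))
}

# One synthesis stage: exact inverse of .tqwt_afb (conjugate filters; the
# squared weights sum to one on every bin).
.tqwt_sfb <- function(low, high, N) {
  N0 <- length(low); N1 <- length(high)
  dm <- list(N = N, N0 = N0, N1 = N1, P = (N - N1) / 2,
             T = (N0 + N1 - N) / 2 - 1)
  w <- .stage_weights(dm)
  V0 <- fft(low) / sqrt(N0)
  V1 <- fft(high) / sqrt(N1)
  Y <- complex(length.out = N)
  Y[1] <- V0[1]
  k <- seq_len(N0 / 2 - 1)
  Y[1 + k] <- V0[1 + k] * w$w0
  j <- seq_len(N1 / 2 - 1)
  Y[1 + dm$P + j] <- Y[1 + dm$P + j] + V1[1 + j] * w$w1
  Y[N / 2 + 1] <- V1[N1 / 2 + 1]
  kk <- seq_len(N / 2 - 1)
  Y[N + 1 - kk] <- Conj(Y[1 + kk])
  Re(fft(Y, inverse = TRUE)) / sqrt(N)
}

#' Decompose a signal with the tunable Q-factor wavelet transform
#'
#' Iterates the oversampled two-channel filter bank `J` times on the
#' low-pass branch. Sub-bands 1..`J` are the high-pass outputs of stages
#' 1..`J` (highest to lowest frequency); sub-band `J + 1` is the final
#' low-pass output. The transform is a Parseval tight frame: sub-band
#' energies sum to the signal energy, and reconstruction is exact to
#' floating-point round-off.
#'
#' @param x Numeric signal; finite values. Odd lengths are zero-padded by
#'   one sample (recorded and stripped on reconstruction).
#' @param params A [tqwt_params()].
#' @return An object of class `subband_set`: list with `subbands` (list of
#'   `J + 1` numeric vectors), `params`, `original_length`.
#' @export
#' @examples
#' sb <- tqwt_decompose(sin(2 * pi * 10 * (0:1023) / 128), tqwt_params(3, 3, 4))
#' length(sb$subbands)   # 5
tqwt_decompose <- function(x, params = tqwt_params()) {
  stopifnot(inherits(params, "tqwt_params"))
  x <- as.numeric(x)
  if (!all(is.finite(x))) stop("input signal contains non-finite values")
  orig <- length(x)
  if (orig %% 2 == 1) x <- c(x, 0)
  jmax <- .count_stages(length(x), params$l, params$h)
  if (params$J > jmax) {
    stop(sprintf("J = %d exceeds max_stages = %d for signal length %d",
                 params$J, jmax, orig))
  }
  subbands <- vector("list", params$J + 1)
  cur <- x
  for (j in seq_len(params$J)) {
    st <- .tqwt_afb(cur, params$l, params$h)
    subbands[[j]] <- st$high
    cur <- st$low
  }
  subbands[[params$J + 1]] <- cur
  structure(list(subbands = subbands, params = params,
                 original_length = orig),
            class = "subband_set")
}

#' @export
print.subband_set <- function(x, ...) {
  cat(sprintf("<subband_set> %d sub-bands (Q = %g, r = %g, J = %d), lengths: %s\n",
              length(x$subbands), x$params$Q, x$params$r, x$params$J,
              paste(vapply(x$subbands, length, 1L), collapse = ", ")))
  invisible(x)
}

#' Reconstruct a signal from its TQWT sub-bands
#'
#' Perfect-reconstruction synthesis: inverts [tqwt_decompose()] within
#' floating-point round-off (relative error below 1e-8 by a wide margin).
#' Synthesis is linear in the sub-bands, so selectively zeroed sub-band sets
#' reconstruct the corresponding signal components.
#'
#' @param sb A `subband_set` from [tqwt_decompose()] (sub-band coefficient
#'   vectors may be modified, but their lengths must be consistent with the
#'   stored parameters).
#' @return Numeric signal of length `sb$original_length`.
#' @export
tqwt_reconstruct <- function(sb) {
  stopifnot(inherits(sb, "subband_set"))
  p <- sb$params
  N_pad <- sb$original_length + sb$original_length %% 2
  lens <- .chain_lengths(N_pad, p$l, p$h, p$J)
  expect_high <- vapply(seq_len(p$J), function(j)
    .stage_dims(lens[j], p$l, p$h)$N1, numeric(1))
  got <- vapply(sb$subbands, length, 1L)
  want <- c(expect_high, lens[p$J + 1])
  if (length(got) != p$J + 1 || !all(got == want)) {
    stop(sprintf("inconsistent sub-band lengths: expected %s, found %s",
                 paste(want, collapse = ", "), paste(got, collapse = ", ")))
  }
  y <- sb$subbands[[p$J + 1]]
  for (j in rev(seq_len(p$J))) {
    y <- .tqwt_sfb(y, sb$subbands[[j]], lens[j])
  }
  y[seq_len(sb$original_length)]
}

#' Equivalent frequency responses of the J-stage filter bank
#'
#' Evaluates the analytic low-pass response after `J` stages and the
#' equivalent high-pass response of every stage on the `N`-point DFT grid.
#' The level-`J` low-pass response is supported on `|w| <= l^J * pi`; the
#' stage-`j` high-pass response on `[(1-h) l^(j-1) pi, l^(j-1) pi]`, so the
#' pass-band edges shrink geometrically by `l` per stage.
#'
#' @param params A [tqwt_params()].
#' @param N Number of DFT grid points (even).
#' @return List with `omega` (grid in `(-pi, pi]`), `lowpass` (length-`N`
#'   response of the `J`-stage low-pass chain) and `highpass` (list of `J`
#'   length-`N` responses).
#' @export
tqwt_frequency_responses <- function(params, N) {
  stopifnot(inherits(params, "tqwt_params"))
  if (N %% 2 == 1) stop("N must be even")
  l <- params$l; h <- params$h; J <- params$J
  omega <- 2 * pi * (0:(N - 1)) / N
  omega[omega > pi] <- omega[omega > pi] - 2 * pi
  H0 <- function(w) {
    aw <- abs(w)
    out <- numeric(length(w))
    out[aw <= (1 - h) * pi] <- 1
    tr <- aw > (1 - h) * pi & aw < l * pi
    out[tr] <- .theta((aw[tr] - (1 - h) * pi) / (l + h - 1))
    out
  }
  H1 <- function(w) {
    aw <- abs(w)
    out <- numeric(length(w))
    out[aw >= l * pi & aw <= pi] <- 1
    tr <- aw > (1 - h) * pi & aw < l * pi
    out[tr] <- .theta_c((aw[tr] - (1 - h) * pi) / (l + h - 1))
    out
  }
  low <- rep(1, N)
  highs <- vector("list", J)
  for (j in seq_len(J)) {
    highs[[j]] <- H1(omega / l^(j - 1)) * low   # product over m = 0..j-2
    low <- low * H0(omega / l^(j - 1))
  }
  list(omega = omega, lowpass = low, highpass = highs)
}
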