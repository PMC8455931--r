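test_that("scaling factors evaluate to h = 2/(Q+1), l = 1 - h/r", {
  expect_equal(scaling_factors(3, 3), c(l = 1 - 0.5 / 3, h = 0.5))
  expect_equal(scaling_factors(1, 3), c(l = 1 - 1 / 3, h = 1))
  expect_error(scaling_factors(0.5, 3), "Q must be")
  expect_error(scaling_factors(3, 1), "r must be")
  # oversampled filter bank: l + h > 1 across the working range
  for (Q in 1:5) {
    sf <- scaling_factors(Q, 3)
    expect_gt(sf["l"] + sf["h"], 1)
  }
})

test_that("decompose/reconstruct is a tight frame across the (Q, J) grid", {
  set.seed(31)
  for (Q in c(1, 3, 5)) {
    for (J in c(1, 4, 6)) {
      x <- rnorm(8064)
      sb <- tqwt_decompose(x, tqwt_params(Q, 3, J))
      expect_length(sb$subbands, J + 1)
      y <- tqwt_reconstruct(sb)
      expect_lt(sqrt(sum((y - x)^2) / sum(x^2)), 1e-8)
      e_sub <- sum(vapply(sb$subbands, function(s) sum(s^2), 0))
      expect_lt(abs(e_sub - sum(x^2)) / sum(x^2), 1e-8)
    }
  }
})

test_that("the working parameter set yields five sub-bands and zero maps to zero", {
  sb <- tqwt_decompose(rnorm(8064), tqwt_params(3, 3, 4))
  expect_length(sb$subbands, 5)
  sb0 <- tqwt_decompose(rep(0, 1024), tqwt_params(3, 3, 4))
  expect_true(all(vapply(sb0$subbands, function(s) all(s == 0), TRUE)))
  expect_equal(tqwt_reconstruct(sb0), rep(0, 1024))
  expect_error(tqwt_decompose(c(1, NA, 3, 4), tqwt_params()), "non-finite")
})

test_that("synthesis is linear: single-sub-band reconstructions superpose to the signal", {
  set.seed(32)
  x <- rnorm(1024)
  p <- tqwt_params(3, 3, 4)
  sb <- tqwt_decompose(x, p)
  parts <- lapply(seq_along(sb$subbands), function(k) {
    one <- sb
    for (j in seq_along(one$subbands)) {
      if (j != k) one$subbands[[j]] <- one$subbands[[j]] * 0
    }
    tqwt_reconstruct(one)
  })
  expect_equal(Reduce(`+`, parts), x, tolerance = 1e-10)
})

test_that("odd-length input is padded and restored to its original length", {
  set.seed(33)
  x <- rnorm(1023)
  sb <- tqwt_decompose(x, tqwt_params(3, 3, 4))
  expect_identical(sb$original_length, 1023L)
  y <- tqwt_reconstruct(sb)
  expect_length(y, 1023)
  expect_lt(max(abs(y - x)), 1e-10)
})

test_that("max_stages admits the working depth, grows with N, and is a sharp bound", {
  p <- tqwt_params(3, 3)
  expect_gte(max_stages(p, 8064), 4)
  expect_gte(max_stages(p, 16128), max_stages(p, 8064))
  # boundary probe at a short length: J_max succeeds, J_max + 1 raises
  n <- 64
  jm <- max_stages(p, n)
  x <- rnorm(n)
  expect_length(tqwt_decompose(x, tqwt_params(3, 3, jm))$subbands, jm + 1)
  expect_error(tqwt_decompose(x, tqwt_params(3, 3, jm + 1)), "max_stages")
})

test_that("reconstruct validates sub-band structure", {
  sb <- tqwt_decompose(rnorm(512), tqwt_params(3, 3, 3))
  sb$subbands[[2]] <- sb$subbands[[2]][-1]
  expect_error(tqwt_reconstruct(sb), "inconsistent sub-band lengths")
})

test_that("analytic responses obey the support rules of the J-level filters", {
  p1 <- tqwt_params(3, 3, 1)
  r1 <- tqwt_frequency_responses(p1, 256)
  l <- p1$l
  # low-pass after 1 stage vanishes beyond l * pi
  expect_equal(max(abs(r1$lowpass[abs(r1$omega) > l * pi + 1e-9])), 0)
  expect_equal(r1$lowpass[1], 1)        # DC preserved
  # stage-j high-pass is supported on [(1-h) l^(j-1) pi, l^(j-1) pi]:
  # pass-band edges shrink geometrically by l per stage
  p4 <- tqwt_params(3, 3, 4)
  r4 <- tqwt_frequency_responses(p4, 4096)
  expect_equal(r4$lowpass[1], 1)
  for (j in 1:4) {
    hij <- r4$highpass[[j]]
    lo_edge <- (1 - p4$h) * p4$l^(j - 1) * pi
    hi_edge <- p4$l^(j - 1) * pi
    outside <- abs(r4$omega) < lo_edge - 1e-9 | abs(r4$omega) > hi_edge + 1e-9
    expect_equal(max(abs(hij[outside])), 0)
    inside <- abs(r4$omega) > lo_edge + 1e-9 & abs(r4$omega) < hi_edge - 1e-9
    # the product form attenuates the band edges (the previous stage's
    # low-pass transition overlaps), so only a substantial peak is asserted
    expect_gt(max(abs(hij[inside])), 0.75)
  }
})

test_that("sub-band energies are insensitive to even time shifts", {
  set.seed(34)
  # circular shift: DFT magnitudes unchanged, energies exactly preserved
  x <- rnorm(1024)
  p <- tqwt_params(3, 3, 4)
  e0 <- vapply(tqwt_decompose(x, p)$subbands, function(s) sum(s^2), 0)
  xs <- c(x[-(1:2)], x[1:2])
  e2 <- vapply(tqwt_decompose(xs, p)$subbands, function(s) sum(s^2), 0)
  expect_equal(e2, e0, tolerance = 1e-10)
  # non-circular shift of a smoothly windowed oscillation: energies move < 1%
  n <- 2048
  t <- seq_len(n + 4)
  env <- exp(-((t - (n + 4) / 2) / (n / 6))^2)
  sig <- env * sin(2 * pi * 0.11 * t)
  ea <- vapply(tqwt_decompose(sig[1:n], p)$subbands, function(s) sum(s^2), 0)
  eb <- vapply(tqwt_decompose(sig[3:(n + 2)], p)$subbands,
               function(s) sum(s^2), 0)
  expect_lt(max(abs(eb - ea) / sum(ea)), 0.01)
})
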