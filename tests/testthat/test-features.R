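test_that("sample entropy equals the brute-force template-count oracle", {
  x <- c(1, 2, 3, 1, 2, 3, 1, 2, 3, 1)
  u <- 0.2 * pop_sd(x)
  expect_equal(sample_entropy(x), unname(brute_sampen(x, 2, u)))
  set.seed(41)
  for (rep in 1:5) {
    z <- as.numeric(arima.sim(list(ar = 0.8), 150))
    uz <- 0.2 * pop_sd(z)
    expect_equal(sample_entropy(z), unname(brute_sampen(z, 2, uz)))
    expect_gte(sample_entropy(z), 0)  # A <= B by embedding nesting
  }
})

test_that("sample entropy handles degenerate and saturated tolerances", {
  set.seed(42)
  x <- rnorm(100)
  # tolerance above the signal range: every template matches, SampEn = 0
  expect_equal(sample_entropy(x, u = diff(range(x)) + 1), 0)
  expect_warning(v <- sample_entropy(rep(2, 50)), "constant")
  expect_equal(v, 0)
  expect_error(sample_entropy(c(1, 2, 3)), "length")
  # strictly increasing ramp with tiny tolerance: B = 0 is an error
  expect_error(sample_entropy(seq(0, 100, by = 1), u = 1e-6), "B = 0")
})

test_that("second difference mean telescopes and its normalized form is scale-invariant", {
  expect_equal(second_diff_mean(1:10), 2)
  expect_equal(second_diff_mean(rep(7, 10)), 0)
  set.seed(43)
  x <- rnorm(100)
  n <- length(x)
  expect_equal(second_diff_mean(x),
               (x[n] + x[n - 1] - x[2] - x[1]) / (n - 2))
  expect_equal(second_diff_mean(x, absolute = TRUE),
               mean(abs(x[3:n] - x[1:(n - 2)])))
  expect_error(second_diff_mean(c(1, 2)), "3 samples")
  # normalized variant
  expect_equal(norm_second_diff_mean(1:10), 2 / pop_sd(1:10))
  expect_equal(norm_second_diff_mean(5 * x), norm_second_diff_mean(x))
  expect_error(norm_second_diff_mean(rep(1, 10)), "constant")
})

test_that("Hjorth mobility matches closed forms for sinusoids and white noise", {
  w0 <- 0.1
  x <- sin(w0 * (1:10000))
  expect_lt(abs(hjorth_mobility(x) / (2 * sin(w0 / 2)) - 1), 0.02)
  expect_equal(hjorth_mobility(3 * x), hjorth_mobility(x))
  set.seed(44)
  wn <- rnorm(10000)
  expect_lt(abs(hjorth_mobility(wn) / sqrt(2) - 1), 0.05)
  expect_error(hjorth_mobility(rep(1, 10)), "constant")
})

test_that("Hjorth complexity is 1 for a pure tone and composes mobility", {
  x <- sin(0.2 * (1:10000))
  expect_lt(abs(hjorth_complexity(x) - 1), 0.02)
  set.seed(45)
  z <- rnorm(500)
  expect_equal(hjorth_complexity(z),
               hjorth_mobility(diff(z)) / hjorth_mobility(z))
  expect_equal(hjorth_complexity(10 * z), hjorth_complexity(z))
})

test_that("extract_features composes the scalar features over sub-bands and channels", {
  rec <- tiny_recording(n_trials = 2, n_channels = 2, n_samples = 512)
  p <- tqwt_params(3, 3, 4)
  feats <- extract_features(rec, p)
  expect_named(feats, c("SampEn", "2dif", "2ndif", "HM", "HC"))
  expect_identical(dim(feats[["HM"]]), c(2L, 10L))  # (J+1) * channels
  ci <- attr(feats[["HM"]], "column_index")
  expect_identical(nrow(ci), 10L)
  expect_false(anyDuplicated(ci) > 0)
  # spot-check one trial/channel against direct scalar calls
  sb <- tqwt_decompose(rec$data[2, 1, ], p)
  for (b in 1:5) {
    col <- which(ci$subband == b & ci$channel == "ch1")
    seg <- sb$subbands[[b]]
    expect_equal(unname(feats[["SampEn"]][2, col]), sample_entropy(seg))
    expect_equal(unname(feats[["2dif"]][2, col]), second_diff_mean(seg))
    expect_equal(unname(feats[["2ndif"]][2, col]), norm_second_diff_mean(seg))
    expect_equal(unname(feats[["HM"]][2, col]), hjorth_mobility(seg))
    expect_equal(unname(feats[["HC"]][2, col]), hjorth_complexity(seg))
  }
})

test_that("degenerate (flat) sub-bands are imputed to zero with a logged count", {
  rec0 <- tiny_recording(n_trials = 2, n_channels = 2, n_samples = 512,
                         zero = TRUE)
  expect_message(feats <- extract_features(rec0, tqwt_params(3, 3, 2)),
                 "degenerate cell")
  for (f in names(feats)) {
    expect_true(all(feats[[f]] == 0))
  }
})

test_that("feature values on a fixed seed are stable across repeated runs", {
  rec <- tiny_recording(n_trials = 2, n_channels = 1, n_samples = 256, seed = 9)
  a <- extract_features(rec, tqwt_params(3, 3, 3))
  b <- extract_features(rec, tqwt_params(3, 3, 3))
  expect_identical(a, b)
})

test_that("fusion produces the three layouts with consistent indices", {
  recs <- lapply(1:3, function(s)
    tiny_recording(n_trials = 4, n_channels = 2, n_samples = 256, seed = s))
  mats <- lapply(recs, function(r)
    extract_features(r, tqwt_params(3, 3, 3), features = "2dif")[["2dif"]])
  one <- fuse_features(mats[[1]], "per_subject_subband_fused")
  expect_identical(dim(one), c(4L, 8L))             # trials x (J+1)*channels
  all_f <- fuse_features(mats, "all_fused")
  expect_identical(dim(all_f), c(12L, 8L))          # subjects*trials x cols
  expect_identical(nrow(attr(all_f, "row_index")), 12L)
  sb1 <- fuse_features(mats, "per_subband_subject_fused", subband = 1)
  expect_identical(dim(sb1), c(12L, 2L))            # ... x channels
  expect_true(all(attr(sb1, "column_index")$subband == 1))
  # pooling the same subject twice is an index collision
  expect_error(fuse_features(list(mats[[1]], mats[[1]]), "all_fused"),
               "collision")
})
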