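test_that("approximate entropy matches the brute-force pair-count oracle", {
  for (s in 1:25) {
    set.seed(s)
    n <- sample(60:200, 1)
    x <- rnorm(n)
    r <- 0.2 * sd(x)
    expect_equal(approximate_entropy(x, m = 2, tau = 1, r = r),
                 apen_oracle(x, 2, 1, r), tolerance = 1e-12)
  }
  # other embeddings and lags
  for (s in 26:35) {
    set.seed(s)
    x <- rnorm(150)
    m <- sample(1:3, 1); tau <- sample(1:2, 1)
    r <- 0.25 * sd(x)
    expect_equal(approximate_entropy(x, m = m, tau = tau, r = r),
                 apen_oracle(x, m, tau, r), tolerance = 1e-12)
  }
})

test_that("approximate entropy degenerate and regular inputs", {
  expect_identical(approximate_entropy(rep(3.7, 500)), 0)
  # perfectly periodic: every template's continuation is determined
  alt <- rep(c(1, 2), 100)
  # not exactly zero: the count normalizations use M and M - 1 vectors
  expect_lt(approximate_entropy(alt, m = 2, tau = 1, r = 0.5), 1e-4)
  # a periodic signal is more regular than its shuffled version
  set.seed(4)
  per <- rep(sin(2 * pi * (1:25) / 25), 12)
  shuf <- sample(per)
  r <- 0.2 * sd(per)
  expect_lt(approximate_entropy(per, r = r),
            approximate_entropy(shuf, r = r))
  expect_error(approximate_entropy(1:3, m = 2), "too short")
  expect_error(approximate_entropy(rnorm(100), m = 0), "'m'")
})

test_that("DFA recovers the scaling exponents of known generators", {
  alphas_white <- vapply(1:20, function(s) {
    set.seed(s); dfa_alpha(rnorm(8192))$alpha
  }, numeric(1))
  expect_equal(mean(alphas_white), 0.5, tolerance = 0.1)

  alphas_brown <- vapply(1:20, function(s) {
    set.seed(s); dfa_alpha(cumsum(rnorm(8192)))$alpha
  }, numeric(1))
  expect_gt(mean(alphas_brown), 1)
  expect_equal(mean(alphas_brown), 1.5, tolerance = 0.15)

  for (H in c(0.3, 0.8)) {
    alphas <- vapply(1:20, function(s) {
      set.seed(s); dfa_alpha(fgn_spectral(8192, H))$alpha
    }, numeric(1))
    expect_equal(mean(alphas), H, tolerance = 0.1)
  }
})

test_that("DFA rejects degenerate input and returns a usable fit", {
  expect_error(dfa_alpha(rep(1, 500)), "zero variance")
  expect_error(dfa_alpha(rnorm(32)), "at least 64")
  set.seed(1)
  res <- dfa_alpha(rnorm(1024))
  expect_s3_class(res, "dfa_result")
  expect_gte(length(res$box_sizes), 4L)
  expect_length(res$fluctuations, length(res$box_sizes))
  expect_true(all(res$fluctuations > 0))
})

test_that("Welch PSD localizes tones and conserves variance", {
  fs <- 62.5
  t <- (0:2999) / fs
  s <- sin(2 * pi * 2 * t)
  pw <- welch_psd(s, fs)
  expect_equal(pw$frequencies[which.max(pw$psd)], 2, tolerance = 0.15)

  set.seed(7)
  x <- rnorm(20000)
  pw2 <- welch_psd(x, fs)
  df <- pw2$frequencies[2] - pw2$frequencies[1]
  expect_equal(sum(pw2$psd) * df, var(x), tolerance = 0.05)

  pwc <- welch_psd(rep(5, 2000), fs)
  expect_true(all(pwc$psd < 1e-20))
  expect_error(welch_psd(rnorm(100), fs), "shorter than one segment")
})

test_that("band power integrates the PSD over the requested band", {
  fs <- 62.5
  t <- (0:2999) / fs
  pw <- welch_psd(sin(2 * pi * 2 * t), fs)
  total <- average_band_power(pw$frequencies, pw$psd, 0, fs / 2)
  delta <- average_band_power(pw$frequencies, pw$psd, 0.5, 4)
  expect_gte(delta, 0.9 * total)

  # zero PSD integrates to zero in every band
  z <- rep(0, length(pw$psd))
  for (i in seq_len(nrow(default_bands()))) {
    b <- default_bands()[i, ]
    expect_identical(average_band_power(pw$frequencies, z, b$f_lo, b$f_hi), 0)
  }

  # contiguous sub-bands approximately partition the full-range integral;
  # composite Simpson on sub-grids is only near-additive, so test on a
  # smooth (noise) spectrum with a small tolerance
  set.seed(5)
  pn <- welch_psd(rnorm(8000), fs)
  bands <- rbind(default_bands(),
                 data.frame(name = "top", f_lo = 30, f_hi = fs / 2))
  parts <- vapply(seq_len(nrow(bands)), function(i) {
    average_band_power(pn$frequencies, pn$psd, bands$f_lo[i], bands$f_hi[i])
  }, numeric(1))
  tot_n <- average_band_power(pn$frequencies, pn$psd, 0, fs / 2)
  expect_true(all(parts >= 0))
  expect_equal(sum(parts), tot_n, tolerance = 0.05)

  expect_error(average_band_power(pw$frequencies, pw$psd, 40, 50), "Nyquist")
})

test_that("band powers scale quadratically with signal amplitude", {
  set.seed(11)
  x <- rnorm(3000)
  fs <- 62.5
  p1 <- welch_psd(x, fs)
  p2 <- welch_psd(2 * x, fs)
  bands <- default_bands()
  for (i in seq_len(nrow(bands))) {
    a1 <- average_band_power(p1$frequencies, p1$psd,
                             bands$f_lo[i], bands$f_hi[i])
    a2 <- average_band_power(p2$frequencies, p2$psd,
                             bands$f_lo[i], bands$f_hi[i])
    expect_gt(a1, 0)
    expect_equal(a2 / a1, 4, tolerance = 1e-9)
  }
})

test_that("extract_features composes the individual extractors", {
  set.seed(21)
  sl <- list(bin_index = 3L, start_time = 115.2, samples = rnorm(3000),
             fs = 62.5)
  cfg <- tdaf_config()
  row <- extract_features(sl, cfg)
  expect_equal(row$bin_index, 3L)
  expect_equal(row$apen, approximate_entropy(sl$samples, r_coef = 0.02))
  expect_equal(row$dfa_alpha, dfa_alpha(sl$samples)$alpha)
  pw <- welch_psd(sl$samples, 62.5)
  expect_equal(row$abp_delta,
               average_band_power(pw$frequencies, pw$psd, 0.5, 4))
  # determinism
  expect_identical(row, extract_features(sl, cfg))
})

test_that("degenerate windows yield zero entropy and missing DFA, not errors", {
  sl <- list(bin_index = 0L, start_time = 0, samples = rep(2, 3000),
             fs = 62.5)
  row <- extract_features(sl, tdaf_config())
  expect_identical(row$apen, 0)
  expect_true(is.na(row$dfa_alpha))
  expect_lt(row$abp_low, 1e-18)
})
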