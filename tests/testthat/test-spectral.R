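test_that("preprocessing kills linear trends and keeps length", {
  ramp <- seq(0, 10, length.out = 64)
  expect_equal(preprocess_we(ramp), rep(0, 64))
  expect_equal(preprocess_we(rep(3, 32)), rep(0, 32))
  x <- gen_fgn(128, 0.5, seed = 1)
  y <- preprocess_we(x)
  expect_length(y, 128)
  # endpoints are (near) zero after endpoint matching + demeaning + taper
  expect_lt(max(abs(y[c(1, 128)])), max(abs(x)) * 0.1)
  expect_error(preprocess_we(rnorm(8)), "insufficient")
})

test_that("periodogram satisfies Parseval and localizes bin sinusoids", {
  n <- 256
  x <- gen_fgn(n, 0.5, seed = 2)
  pg <- periodogram(x, fs = 1)
  expect_equal(pg$frequencies, (1:(n / 2)) / n)
  A0 <- sum(x)^2
  total <- A0 + 2 * sum(pg$powers[1:(n / 2 - 1)]) + pg$powers[n / 2]
  expect_equal(total, n * sum(x^2), tolerance = 1e-10)

  # pure sinusoid at a bin frequency concentrates in that bin
  k <- 8
  s <- sin(2 * pi * k * (0:(n - 1)) / n)
  ps <- periodogram(s, fs = 1)
  expect_equal(which.max(ps$powers), k)
  expect_gt(ps$powers[k] / sum(ps$powers), 0.999)

  # white noise: flat expected spectrum, near-zero slope
  b <- vapply(1:10, function(seed) {
    pg <- periodogram(gen_fgn(4096, 0.5, seed = seed), fs = 1)
    fit_spectral_exponent(pg$frequencies, pg$powers, fs = 1)$beta
  }, numeric(1))
  expect_lt(abs(mean(b)), 0.15)
})

test_that("exact power-law spectra are fitted exactly and band is enforced", {
  f <- (1:200) / 2000
  fit <- fit_spectral_exponent(f, f^-2, fs = 1)
  expect_equal(fit$beta, 2, tolerance = 1e-10)
  expect_lte(fit$fit_band[2], 1 / 8)
  expect_equal(fit$n_freqs_used, sum(f <= 1 / 8))

  fit3 <- fit_spectral_exponent(f, 5 * f^-0.5, fs = 1)
  expect_equal(fit3$beta, 0.5, tolerance = 1e-10)

  expect_error(fit_spectral_exponent(c(0.2, 0.3), c(1, 1), fs = 1), "fit error")
})

test_that("lowPSD_we recovers beta = 2H+1 (fBm) and 2H-1 (fGn)", {
  # light version at H = 0.5 (the full H-grid runs in the acceptance suite)
  bfbm <- mean(vapply(1:10, function(s) lowpsd_we(gen_fbm(4096, 0.5, seed = s),
                                                  fs = 1)$beta, numeric(1)))
  expect_lt(abs(bfbm - 2), 0.15)
  bfgn <- mean(vapply(1:10, function(s) lowpsd_we(gen_fgn(4096, 0.5, seed = 50 + s),
                                                  fs = 1)$beta, numeric(1)))
  expect_lt(abs(bfgn - 0), 0.15)

  # no frequency above fs/8 enters the regression
  fit <- lowpsd_we(gen_fbm(1024, 0.7, seed = 3), fs = 1)
  expect_lte(fit$fit_band[2], 1 / 8)
})

test_that("signal classification and Hurst conversion follow beta", {
  expect_identical(classify_signal(2), "fBm")
  expect_identical(classify_signal(0), "fGn")
  expect_identical(classify_signal(3.5), "ambiguous")
  expect_identical(classify_signal(1), "ambiguous")

  expect_equal(beta_to_hurst(2, "fBm"), 0.5)
  expect_equal(beta_to_hurst(1.93, "fBm"), 0.465)
  expect_equal(beta_to_hurst(0, "fGn"), 0.5)
  expect_error(beta_to_hurst(1, "ambiguous"), "ambiguous")
  expect_warning(h <- beta_to_hurst(2.9, "fGn"), "clamped")
  expect_lt(h, 1)
})
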