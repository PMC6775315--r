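test_that("fGn matches its closed-form autocovariance and white-noise limit", {
  # H = 0.5 reduces to iid white noise
  y <- gen_fgn(1e5, 0.5, seed = 2)
  expect_lt(abs(cor(y[-1], y[-length(y)])), 0.01)

  # H = 0.8: sample autocovariance at lags 1-10 matches the closed form
  x <- gen_fgn(2^14, 0.8, seed = 1)
  emp <- vapply(1:10, function(k)
    mean(x[seq_len(length(x) - k)] * x[-seq_len(k)]), numeric(1))
  expect_lt(max(abs(emp - fgn_acv(1:10, 0.8))), 0.02)

  # unit-variance normalization at n = 2^16
  expect_equal(var(gen_fgn(2^16, 0.7, seed = 4)), 1, tolerance = 0.02)

  # determinism and argument validation
  expect_identical(gen_fgn(256, 0.3, seed = 9), gen_fgn(256, 0.3, seed = 9))
  expect_error(gen_fgn(256, 1.2), "hurst")
  expect_error(gen_fgn(1, 0.5), "at least 2")
})

test_that("fBm is the cumulative sum of fGn and obeys the H=0.5 variance law", {
  f <- gen_fgn(512, 0.6, seed = 5)
  B <- gen_fbm(512, 0.6, seed = 5)
  expect_equal(diff(c(0, B)), f, tolerance = 1e-12)

  # standard random walk: Var(X_n)/n -> 1 (Monte Carlo over seeds)
  n <- 1024
  v <- mean(vapply(1:300, function(s) gen_fbm(n, 0.5, seed = s)[n]^2,
                   numeric(1))) / n
  expect_equal(v, 1, tolerance = 0.2)

  expect_error(gen_fbm(0, 0.5), "at least 1")
})

test_that("binomial cascade conserves measure and degenerates as a -> 0.5", {
  x <- gen_binomial_cascade(10, 0.75)
  expect_length(x, 1024)
  expect_true(all(x >= 0))
  expect_equal(sum(x), 1, tolerance = 1e-12)

  # a close to 0.5: nearly constant series
  y <- gen_binomial_cascade(8, 0.5 + 1e-9)
  expect_lt(diff(range(y)) / mean(y), 1e-5)

  expect_error(gen_binomial_cascade(10, 0.4), "multiplier")
  expect_error(gen_binomial_cascade(10, 1), "multiplier")
  expect_error(gen_binomial_cascade(4, 0.75), "levels")

  # shuffling preserves the value multiset
  xs <- gen_binomial_cascade(10, 0.75, seed = 1, shuffle = TRUE)
  expect_equal(sort(xs), sort(x))
  expect_false(identical(xs, x))
})

test_that("stable sampler hits its Gaussian limit and skew direction", {
  # alpha = 2 is Normal(location, 2 * scale^2)
  s <- gen_stable(1e5, stable_params(2, 0, 0.06, 0.49), seed = 3)
  expect_lt(abs(var(s) - 2 * 0.06^2) / (2 * 0.06^2), 0.02)
  expect_lt(abs(mean(s) - 0.49), 0.005)

  # alpha = 1.15, skew = 1: heavy right tail, positive sample skewness
  z <- gen_stable(2e4, stable_params(1.15, 1, 1, 0), seed = 6)
  sk <- mean((z - mean(z))^3) / sd(z)^3
  expect_gt(sk, 0)

  expect_identical(gen_stable(100, stable_params(1.5, 0.5, 1, 0), seed = 8),
                   gen_stable(100, stable_params(1.5, 0.5, 1, 0), seed = 8))
  expect_error(gen_stable(10, c(2.5, 0, 1, 0)), "alpha")
  expect_error(gen_stable(10, c(1.5, 2, 1, 0)), "skew")
  expect_error(gen_stable(10, c(1.5, 0, -1, 0)), "scale")
})

test_that("CGM trace emulates the 3-day, 5-minute regime", {
  gs <- gen_cgm_trace(seed = 1)
  expect_s3_class(gs, "glucose_series")
  expect_length(gs, 864)
  expect_equal(gs$dt, 300)
  expect_true(all(gs$values >= 2 & gs$values <= 25))

  # amplitude 0, no meals: constant at baseline
  flat <- gen_cgm_trace(n = 100, amplitude = 0, baseline = 6.5, seed = 1)
  expect_equal(flat$values, rep(6.5, 100))

  # meal bumps raise the trace after the meal time
  m <- gen_cgm_trace(n = 288, amplitude = 0, baseline = 6,
                     meal_times = 3600 * 6, meal_heights = 4, seed = 1)
  expect_gt(max(m$values), 9)

  # fBm roughness with H = 0.5 shows up as spectral exponent near 2
  b <- vapply(1:10, function(s) lowpsd_we(gen_cgm_trace(hurst = 0.5, seed = s))$beta,
              numeric(1))
  expect_equal(mean(b), 2, tolerance = 0.15)

  expect_error(gen_cgm_trace(baseline = -1), "baseline")
  # all-clipped parameters are refused
  expect_error(suppressWarnings(gen_cgm_trace(baseline = 30, amplitude = 0)),
               "degenerate trace")
})
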