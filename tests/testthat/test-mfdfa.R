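test_that("profile integrates the mean-subtracted series", {
  x <- rep(c(1, -1), 16)
  expect_equal(mf_profile(x), rep(c(1, 0), 16))
  expect_equal(mf_profile(rep(7, 20)), rep(0, 20))
  p <- mf_profile(gen_fgn(1000, 0.5, seed = 1))
  expect_equal(p[length(p)], 0, tolerance = 1e-9)
  expect_error(mf_profile(rnorm(10)), "insufficient")
})

test_that("fluctuation function flags perfect detrending as degenerate", {
  t <- seq_len(256)
  quad <- 3 + 0.5 * t - 0.01 * t^2
  fq <- fluctuation_function(quad, scale = 32, order = 2, q_grid = c(-2, 0, 2))
  expect_equal(as.numeric(fq), rep(0, 3))
  expect_equal(attr(fq, "n_degenerate"), 16)
})

test_that("q = 2 column equals an independent plain DFA", {
  for (seed in 1:10) {
    x <- gen_fgn(512, 0.3 + 0.05 * seed, seed = seed)
    prof <- mf_profile(x)
    for (s in c(16, 64)) {
      f2 <- as.numeric(fluctuation_function(prof, s, order = 2, q_grid = 2))
      expect_equal(f2, plain_dfa_f2(x, s, order = 2), tolerance = 1e-8)
    }
  }
})

test_that("q = 0 fluctuation lies between the min and max window RMS", {
  x <- gen_fgn(1024, 0.7, seed = 5)
  prof <- mf_profile(x)
  fq <- as.numeric(fluctuation_function(prof, 32, 2, q_grid = c(-50, 0, 50)))
  # q -> -Inf approaches min RMS, q -> +Inf approaches max RMS
  expect_gte(fq[2], fq[1])
  expect_lte(fq[2], fq[3])
})

test_that("monofractal fGn gives flat H(q) near the true Hurst exponent", {
  r <- mfdfa(gen_fgn(2^14, 0.7, seed = 1), scales = 2^(4:9))
  h2 <- r$hq[r$q_grid == 2]
  expect_lt(abs(h2 - 0.7), 0.1)
  expect_lt(max(abs(r$hq - h2)), 0.15)
  expect_lte(r$delta_h, 0.3)
  # H(q) non-increasing in q up to fit noise
  expect_gte(min(-diff(r$hq)), -0.05)
})

test_that("Legendre transform collapses a constant H(q) to one point", {
  q <- seq(-5, 5, by = 0.5)
  spec <- multifractal_spectrum(rep(0.62, length(q)), q)
  expect_equal(spec$h, rep(0.62, length(q)), tolerance = 1e-12)
  expect_equal(spec$D, rep(1, length(q)), tolerance = 1e-12)
  expect_equal(spectrum_width(spec), 0, tolerance = 1e-12)
  expect_error(multifractal_spectrum(c(1, NA, NA, NA), c(1, 2, 3, 4)),
               "spectrum error")
})

test_that("binomial cascade shows a single-humped spectrum of the right width", {
  x <- gen_binomial_cascade(14, 0.75)
  r <- suppressWarnings(mfdfa(x, scales = 2^(6:12)))
  # D peaks near q = 0 and stays below 1 + tolerance
  expect_lte(max(r$spectrum$D), 1 + 0.05)
  expect_lt(abs(r$spectrum$q[which.max(r$spectrum$D)]), 1)
  # width matches the closed-form Legendre h range
  want <- cascade_dtau(-5, 0.75) - cascade_dtau(5, 0.75)
  expect_lt(abs(r$delta_h - want), 0.2)
  # H(q) monotone non-increasing up to fit noise
  expect_gte(min(-diff(r$hq)), -0.05)
})

test_that("cascade width exceeds monofractal width for matched lengths", {
  dh_casc <- suppressWarnings(mfdfa(gen_binomial_cascade(13, 0.75),
                                    scales = 2^(4:9))$delta_h)
  for (seed in 1:5) {
    dh_mono <- mfdfa(gen_fgn(2^13, 0.7, seed = seed), scales = 2^(4:9))$delta_h
    expect_gt(dh_casc, dh_mono)
  }
})

test_that("mfdfa validates scales and reports per-q fit quality", {
  expect_error(mfdfa(gen_fgn(100, 0.5, seed = 1), scales = c(16, 8)),
               "increasing")
  expect_warning(r <- mfdfa(gen_fgn(300, 0.5, seed = 1),
                            scales = c(16, 32, 64, 512)), "dropped")
  expect_equal(r$scales, c(16, 32, 64))
  expect_true(all(r$fit_r2 > 0.8, na.rm = TRUE))
})
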