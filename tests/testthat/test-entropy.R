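test_that("sample entropy agrees exactly with brute-force pair counting", {
  # tiny alternating series, counts verifiable by enumeration
  x <- rep(c(1, 2), 5)
  expect_equal(as.numeric(sample_entropy(x, m = 2, r_abs = 0.1)),
               brute_sampen(x, 2, 0.1))

  # random series across lengths, m and r
  for (seed in 1:20) {
    n <- 20 + (seed * 7) %% 41
    set.seed(seed)
    x <- rnorm(n)
    m <- 1 + seed %% 3
    r <- 0.1 + 0.2 * ((seed %% 5) / 4)
    got <- sample_entropy(x, m = m, r_abs = r)
    want <- brute_sampen(x, m, r)
    if (is.na(want)) {
      expect_true(is.na(got))
      expect_true(attr(got, "undefined"))
    } else {
      expect_identical(as.numeric(got), want)
    }
  }
})

test_that("constant series and undefined cases are handled explicitly", {
  expect_equal(as.numeric(sample_entropy(rep(3, 50), 2, 0.2)), 0)
  expect_equal(as.numeric(sample_entropy(rep(3, 50), 2, 0)), 0)

  # strictly monotone series with tiny tolerance: no matches at all
  u <- sample_entropy(seq_len(30), 2, 1e-6)
  expect_true(is.na(u))
  expect_true(attr(u, "undefined"))

  expect_error(sample_entropy(rnorm(3), 2, 0.1), "insufficient")
  expect_error(sample_entropy(rnorm(50), 2, -1), "r_abs")
})

test_that("coarse graining takes block means and drops the remainder", {
  expect_equal(coarse_grain(1:5, 2), c(1.5, 3.5))
  x <- gen_fgn(100, 0.5, seed = 3)
  expect_identical(coarse_grain(x, 1), x)
  expect_equal(coarse_grain(x, 100), mean(x))
  # global mean conserved when k divides N
  expect_equal(mean(coarse_grain(x, 5)), mean(x), tolerance = 1e-12)
  expect_error(coarse_grain(1:5, 6), "insufficient")
})

test_that("MSE curve reduces to SampEn at scale 1 and flags guardrails", {
  x <- gen_fgn(500, 0.5, seed = 4)
  curve1 <- mse_curve(x, scales = 1)
  expect_equal(curve1$entropies,
               as.numeric(sample_entropy(x, 2, 0.15 * sd(x))))
  expect_equal(curve1$r_absolute, curve1$r_fraction * curve1$sd_reference)

  # constant series: all entropies 0
  const <- mse_curve(rep(5, 400), scales = 1:5)
  expect_equal(const$entropies, rep(0, 5))

  # guardrail: scale leaving < 10*(m+1) points names admissible scales
  expect_error(mse_curve(rnorm(200), scales = c(1, 10)), "admissible")
})

test_that("long-memory fGn keeps higher MSE than white noise at large scales", {
  # the discriminative premise of multiscale entropy: correlated (1/f-like)
  # signals retain entropy under coarse-graining, white noise does not
  for (seed in 1:10) {
    a <- mse_curve(gen_fgn(2048, 0.95, seed = seed), scales = 1:10)$entropies
    w <- mse_curve(gen_fgn(2048, 0.5, seed = 100 + seed), scales = 1:10)$entropies
    expect_true(all(a[5:10] > w[5:10]))
  }
})
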