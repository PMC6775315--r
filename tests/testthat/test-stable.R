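test_that("stable density matches its closed-form members", {
  g <- seq(-10, 10, by = 0.05)
  # alpha = 2: Normal(delta, 2 * gamma^2)
  expect_lt(max(abs(stable_pdf(g, stable_params(2, 0, 1, 0)) -
                      dnorm(g, 0, sqrt(2)))), 1e-6)
  expect_lt(max(abs(stable_pdf(g, stable_params(2, 0.7, 1.3, -0.4)) -
                      dnorm(g, -0.4, 1.3 * sqrt(2)))), 1e-6)
  # alpha = 1, skew = 0: Cauchy(delta, gamma)
  expect_lt(max(abs(stable_pdf(g, stable_params(1, 0, 1, 0)) -
                      dcauchy(g, 0, 1))), 1e-6)

  # non-negative and unimodal for skew = 0
  f <- stable_pdf(g, stable_params(1.5, 0, 1, 0))
  expect_true(all(f >= 0))
  peak <- which.max(f)
  expect_true(all(diff(f[seq_len(peak)]) >= -1e-12))
  expect_true(all(diff(f[peak:length(f)]) <= 1e-12))
})

test_that("stable density integrates to one across the alpha range", {
  for (a in c(0.8, 1.0, 1.15, 1.5, 2.0)) {
    p <- stable_params(a, if (a < 2) 0.5 else 0, 1, 0)
    I <- integrate(function(z) stable_pdf(z, p), -Inf, Inf,
                   rel.tol = 1e-7, subdivisions = 1000)$value
    expect_lt(abs(I - 1), 1e-3)
  }
})

test_that("stable CDF and quantile are consistent inverses", {
  p <- stable_params(1.15, 1, 0.06, 0.49)
  pr <- c(0.01, 0.1, 0.5, 0.9, 0.99)
  q <- stable_quantile(pr, p)
  expect_false(is.unsorted(q))
  expect_lt(max(abs(stable_cdf(q, p) - pr)), 1e-4)
  # alpha = 1, skew = 0 quantiles match Cauchy
  expect_lt(max(abs(stable_quantile(pr, stable_params(1, 0, 1, 0)) -
                      qcauchy(pr)) / pmax(abs(qcauchy(pr)), 1)), 0.01)
})

test_that("ML fit recovers sampler parameters and the Gaussian limit", {
  for (seed in c(11, 12)) {
    x <- gen_stable(5000, stable_params(1.15, 1, 0.06, 0.49), seed = seed)
    fit <- fit_stable(x)
    expect_lt(abs(fit$alpha - 1.15), 0.1)
    expect_lt(abs(fit$scale - 0.06) / 0.06, 0.2)
  }
  # Gaussian draws push alpha-hat to the upper boundary
  y <- gen_stable(5000, stable_params(2, 0, 1 / sqrt(2), 0), seed = 13)
  expect_gte(fit_stable(y)$alpha, 1.9)

  expect_error(fit_stable(rnorm(10)), "at least 50")
})

test_that("compare_fits prefers the true generating family", {
  x <- gen_stable(3000, stable_params(1.15, 1, 0.06, 0.49), seed = 21)
  cmp <- compare_fits(x)
  expect_s3_class(cmp, "fit_comparison")
  expect_gt(cmp$loglik_stable, cmp$loglik_gaussian)
  expect_identical(cmp$better, "stable")
  expect_false(is.unsorted(cmp$qq_stable$theoretical))

  # Gaussian data: alpha-hat near 2 and only a small likelihood gap
  y <- gen_stable(3000, stable_params(2, 0, 1 / sqrt(2), 0), seed = 22)
  cmpg <- compare_fits(y)
  expect_gt(cmpg$stable$alpha, 1.9)
  expect_lt(abs(cmpg$loglik_stable - cmpg$loglik_gaussian) / 3000, 0.01)

  expect_error(compare_fits(numeric(0)), "insufficient")
})
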