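#' Fractional Gaussian noise by exact circulant embedding
#'
#' Generates a zero-mean, unit-variance stationary Gaussian sequence whose
#' autocovariance at lag k is the exact fGn form
#' \deqn{\gamma(k) = \tfrac12 (|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}),}
#' using the Davies-Harte circulant embedding of the covariance, so the
#' covariance is exact in expectation (no spectral-synthesis approximation).
#' `hurst = 0.5` reduces to white noise.
#'
#' @param n length of the sequence (at least 2).
#' @param hurst Hurst exponent in (0, 1).
#' @param seed integer seed; a fixed seed reproduces the sequence bit for bit.
#' @return Numeric vector of length `n`.
#' @export
gen_fgn <- function(n, hurst, seed = NULL) {
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be at least 2", call. = FALSE)
  if (!is.numeric(hurst) || hurst <= 0 || hurst >= 1)
    stop("hurst must lie in (0, 1)", call. = FALSE)
  k <- 0:n
  g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                abs(k - 1)^(2 * hurst))
  m <- 2L * n
  row1 <- c(g, g[n:2])                      # circulant first row, length 2n
  ev <- Re(fft(row1))
  if (min(ev) < -1e-8 * max(ev))
    stop("circulant embedding not positive definite for this (n, hurst); ",
         "try a larger n", call. = FALSE)
  ev[ev < 0] <- 0
  with_seed(seed, {
    z <- rnorm(m)
    V <- complex(length.out = m)
    V[1] <- sqrt(ev[1]) * z[1]
    V[n + 1] <- sqrt(ev[n + 1]) * z[2]
    kk <- 2:n
    V[kk] <- sqrt(ev[kk] / 2) * complex(real = z[2 * kk - 1],
                                        imaginary = z[2 * kk])
    V[m - kk + 2] <- Conj(V[kk])
    x <- Re(fft(V, inverse = TRUE)) / sqrt(m)
    x[seq_len(n)]
  })
}

#' Fractional Brownian motion
#'
#' Cumulative sum of [gen_fgn()] increments, prepended origin at 0 omitted:
#' the first value is the first increment, so `diff(c(0, gen_fbm(...)))`
#' recovers the fGn exactly.  `hurst = 0.5` gives a standard random walk.
#'
#' @inheritParams gen_fgn
#' @return Numeric vector of length `n` (a nonstationary motion).
#' @export
gen_fbm <- function(n, hurst, seed = NULL) {
  if (as.integer(n) < 1L) stop("n must be at least 1 for fBm output", call. = FALSE)
  cumsum(gen_fgn(max(as.integer(n), 2L), hurst, seed))[seq_len(as.integer(n))]
}

#' Binomial multiplicative cascade
#'
#' Deterministic multifractal oracle series: value k of the length-`2^levels`
#' series is `a^n1 * (1-a)^(levels-n1)` where `n1` counts the ones in the
#' binary expansion of `k-1`.  The series is non-negative and sums to exactly
#' 1 (measure conservation), and its generalized Hurst exponent has the closed
#' form \deqn{H(q) = 1/q - \log(a^q + (1-a)^q)/(q \log 2),} which
#' [binomial_cascade_hq()] evaluates; this is the reference against which the
#' MF-DFA estimator is validated.
#'
#' @param levels number of cascade levels (series length `2^levels`), at least 8.
#' @param a multiplier in (0.5, 1); `a -> 0.5` degenerates to a constant series.
#' @param seed optional seed; used only when `shuffle = TRUE`.
#' @param shuffle randomly permute the series order (destroys the multifractal
#'   correlation structure while keeping the value distribution).
#' @return Numeric vector of length `2^levels`.
#' @export
gen_binomial_cascade <- function(levels, a, seed = NULL, shuffle = FALSE) {
  levels <- as.integer(levels)
  if (is.na(levels) || levels < 8L) stop("levels must be at least 8", call. = FALSE)
  if (!is.numeric(a) || a <= 0.5 || a >= 1)
    stop("cascade multiplier a must lie in (0.5, 1)", call. = FALSE)
  n <- 2L^levels
  # count of one-bits per index via the level-doubling recursion
  ones <- integer(1)                        # ones(0) = 0
  for (i in seq_len(levels)) ones <- c(ones, ones + 1L)
  x <- a^ones * (1 - a)^(levels - ones)
  if (shuffle) x <- with_seed(seed, sample(x))
  x
}

#' Closed-form generalized Hurst exponent of the binomial cascade
#'
#' @param q fluctuation order(s); `q = 0` is evaluated by its limit
#'   `(1 - (a log a + (1-a) log(1-a)) / log 2) ... ` via l'Hopital.
#' @param a cascade multiplier in (0.5, 1).
#' @return `H(q) = 1/q - log(a^q + (1-a)^q) / (q log 2)` (limit at q = 0).
#' @export
binomial_cascade_hq <- function(q, a) {
  hq <- ifelse(abs(q) < 1e-12,
               NA_real_,
               1 / q - log(a^q + (1 - a)^q) / (q * log(2)))
  if (any(abs(q) < 1e-12)) {
    # q -> 0 limit: H(0) = tau'(0) with tau(q) = -log(a^q+(1-a)^q)/log 2,
    # evaluated by a symmetric difference (matches the analytic derivative)
    eps <- 1e-6
    tau <- function(qq) -log(a^qq + (1 - a)^qq) / log(2)
    hq[abs(q) < 1e-12] <- (tau(eps) - tau(-eps)) / (2 * eps)
  }
  hq
}

# Derivative of the cascade mass exponent tau(q) = -log(a^q+(1-a)^q)/log 2;
# this is the Legendre-transform singularity strength h at order q.
binomial_cascade_dtau <- function(q, a) {
  -(a^q * log(a) + (1 - a)^q * log(1 - a)) / ((a^q + (1 - a)^q) * log(2))
}

#' Draws from an alpha-stable law (Chambers-Mallows-Stuck)
#'
#' Samples iid variates from the four-parameter stable family in the S0
#' (continuous-in-alpha) parameterization used by [stable_pdf()]:
#' `alpha = 2` gives a Gaussian with variance `2 * scale^2` regardless of
#' `skew`; `alpha = 1, skew = 0` gives Cauchy(location, scale).
#'
#' @param n number of draws.
#' @param params a [stable_params()] object (or coercible list).
#' @param seed integer seed.
#' @return Numeric vector of length `n`.
#' @export
gen_stable <- function(n, params, seed = NULL) {
  p <- as_stable_params(params)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be at least 1", call. = FALSE)
  alpha <- p$alpha; beta <- p$skew; gam <- p$scale; delta <- p$location
  with_seed(seed, {
    U <- runif(n, -pi / 2, pi / 2)
    W <- rexp(n)
    if (abs(alpha - 1) < 1e-10) {
      Z <- (2 / pi) * ((pi / 2 + beta * U) * tan(U) -
                         beta * log((pi / 2) * W * cos(U) / (pi / 2 + beta * U)))
      delta + gam * Z + (2 / pi) * beta * gam * log(gam)
    } else {
      ta <- tan(pi * alpha / 2)
      B <- atan(beta * ta) / alpha
      S <- (1 + beta^2 * ta^2)^(1 / (2 * alpha))
      Z <- S * sin(alpha * (U + B)) / cos(U)^(1 / alpha) *
        (cos(U - alpha * (U + B)) / W)^((1 - alpha) / alpha)
      # shift from the S1 draw to the S0 location convention
      delta + gam * Z - beta * gam * ta
    }
  })
}

#' Synthetic CGM-like glucose trace
#'
#' Emulates the data regime of a ~3-day sensor wear at 5-minute sampling:
#' a physiological baseline plus fBm-like roughness (spectral exponent near
#' `2*hurst + 1`), optional meal excursions modeled as log-normal-shaped
#' bump kernels, clipped to the plausible 2-25 mmol/L range.  Purely a
#' fixture generator: no glucose-insulin physiology is simulated.
#'
#' @param n number of readings (default 864 = 3 days at 300 s).
#' @param dt sampling interval, seconds.
#' @param hurst Hurst exponent of the fBm roughness component.
#' @param baseline mean glucose level, mmol/L.
#' @param amplitude standard-deviation scale of the fBm component, mmol/L.
#' @param meal_times numeric vector of meal onset times (seconds from start).
#' @param meal_heights peak excursion heights (mmol/L), recycled to match.
#' @param seed integer seed.
#' @param label period label.
#' @return A [glucose_series()].
#' @export
gen_cgm_trace <- function(n = 864, dt = 300, hurst = 0.8, baseline = 7,
                          amplitude = 1.5, meal_times = NULL,
                          meal_heights = 3, seed = NULL, label = "synthetic") {
  n <- as.integer(n)
  if (baseline <= 0) stop("baseline must be > 0", call. = FALSE)
  x <- rep(baseline, n)
  if (amplitude > 0) {
    B <- gen_fbm(n, hurst, seed)
    B <- (B - mean(B)) / max(sd(B), .Machine$double.eps)
    x <- x + amplitude * B
  }
  if (!is.null(meal_times) && length(meal_times)) {
    h <- rep_len(meal_heights, length(meal_times))
    tt <- (seq_len(n) - 1) * dt
    for (i in seq_along(meal_times)) {
      u <- (tt - meal_times[i]) / 3600       # hours since meal
      k <- ifelse(u > 0, exp(-(log(pmax(u, 1e-9)) - log(0.75))^2 / 0.5), 0)
      x <- x + h[i] * k / max(k)
    }
  }
  lo <- sum(x <= 2); hi <- sum(x >= 25)
  x <- pmin(pmax(x, 2), 25)
  if (lo + hi > 0.5 * n)
    stop("degenerate trace: more than half the points clipped to [2, 25] mmol/L",
         call. = FALSE)
  if (lo + hi > 0)
    warning(sprintf("%d of %d points clipped to the [2, 25] mmol/L range",
                    lo + hi, n))
  glucose_series(x, dt = dt, label = label)
}
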