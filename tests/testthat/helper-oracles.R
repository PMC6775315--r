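# Independent reference implementations used as oracles.  These deliberately
# share no code with the package internals: brute-force double loops and
# per-window lm() fits, fast enough only at test sizes.

# Exhaustive O(N^2 * m) sample-entropy pair counting (Richman-Moorman:
# N - m templates for both lengths, self-matches excluded, Chebyshev
# distance, inclusive tolerance).
brute_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  A <- 0L; B <- 0L
  for (i in seq_len(nt - 1)) {
    for (j in (i + 1):nt) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1L
        if (max(abs(x[i:(i + m)] - x[j:(j + m)])) <= r) A <- A + 1L
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Plain DFA (q = 2 only), written independently: explicit per-window lm()
# polynomial fits over the same 2*floor(N/s) windows (from both ends).
plain_dfa_f2 <- function(x, scale, order = 2) {
  prof <- cumsum(x - mean(x))
  N <- length(prof)
  nw <- N %/% scale
  starts <- c((seq_len(nw) - 1) * scale + 1, N - (seq_len(nw)) * scale + 1)
  v <- vapply(starts, function(s0) {
    seg <- prof[s0:(s0 + scale - 1)]
    tt <- seq_len(scale)
    mean(stats::residuals(stats::lm(seg ~ stats::poly(tt, order, raw = TRUE)))^2)
  }, numeric(1))
  sqrt(mean(v))
}

# Conditional match probability for iid unit-variance Gaussian data at
# tolerance r: P(|X - Y| <= r) with X - Y ~ N(0, 2), i.e. erf(r / 2).
gauss_match_prob <- function(r) 2 * pnorm(r / sqrt(2)) - 1

# SampEn of iid N(0,1) data at tolerance r (per extra matched coordinate).
sampen_iid_gauss <- function(r) -log(gauss_match_prob(r))

# Closed-form fGn autocovariance.
fgn_acv <- function(k, H) {
  0.5 * (abs(k + 1)^(2 * H) - 2 * abs(k)^(2 * H) + abs(k - 1)^(2 * H))
}

# Closed-form Legendre singularity strength of the binomial cascade,
# h(q) = dtau/dq with tau(q) = -log2(a^q + (1-a)^q).
cascade_dtau <- function(q, a) {
  -(a^q * log(a) + (1 - a)^q * log(1 - a)) / ((a^q + (1 - a)^q) * log(2))
}

tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}
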