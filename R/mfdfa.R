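#' Profile (integrated, mean-subtracted series)
#'
#' First step of detrended fluctuation analysis: the cumulative sum of the
#' mean-subtracted series.  The last element is 0 up to float error.
#'
#' @param values numeric series, length at least 16.
#' @return Numeric vector, same length.
#' @export
mf_profile <- function(values) {
  x <- series_values(values)
  if (length(x) < 16L) stop("insufficient data: need at least 16 points", call. = FALSE)
  cumsum(x - mean(x))
}

#' q-order fluctuation function at one scale
#'
#' Splits the profile into `floor(N/s)` non-overlapping windows from the
#' start and the same number from the end (so the tail remainder is covered;
#' `2*floor(N/s)` windows total), removes an order-`order` polynomial trend
#' from each, and aggregates the per-window residual variances `v_nu` into
#' \deqn{F_q(s) = \{ \mathrm{mean}_\nu\, v_\nu^{q/2} \}^{1/q}}
#' with the `q = 0` case handled by its logarithmic-average limit
#' `exp(mean(log v)/2)`.  Windows with (numerically) zero residual variance
#' are degenerate — they would blow up negative orders — and are excluded
#' with a warning, their count recorded in the `n_degenerate` attribute; if
#' every window is degenerate all `F_q` are 0 and flagged.
#'
#' @param prof profile from [mf_profile()].
#' @param scale window size `s` (at least `order + 2`).
#' @param order detrending polynomial order (default 2).
#' @param q_grid numeric vector of fluctuation orders.
#' @return Numeric vector `F_q(scale)` aligned with `q_grid`, attribute
#'   `n_degenerate`.
#' @export
fluctuation_function <- function(prof, scale, order = 2, q_grid = seq(-5, 5, by = 0.5)) {
  scale <- as.integer(scale)
  if (scale < order + 2L)
    stop("scale must be at least order + 2", call. = FALSE)
  N <- length(prof)
  nw <- N %/% scale
  if (nw < 1L) stop("scale exceeds series length", call. = FALSE)
  segs <- cbind(matrix(prof[seq_len(nw * scale)], nrow = scale),
                matrix(prof[(N - nw * scale + 1L):N], nrow = scale))
  tt <- seq_len(scale)
  X <- outer(tt, 0:order, `^`)
  res <- qr.resid(qr(X), segs)
  v <- colMeans(res^2)
  degen <- v < .Machine$double.eps
  ndeg <- sum(degen)
  if (ndeg && ndeg < length(v))
    warning(sprintf("%d of %d windows at scale %d have zero residual variance; excluded",
                    ndeg, length(v), scale))
  v <- v[!degen]
  if (!length(v)) {
    fq <- rep(0, length(q_grid))
    attr(fq, "n_degenerate") <- ndeg
    return(fq)
  }
  fq <- vapply(q_grid, function(q) {
    if (abs(q) < 1e-12) exp(mean(log(v)) / 2)
    else mean(v^(q / 2))^(1 / q)
  }, numeric(1))
  attr(fq, "n_degenerate") <- ndeg
  fq
}

#' Generalized Hurst exponent from fluctuation functions
#'
#' Per order q, the OLS slope of `log2 F_q(s)` on `log2 s` over the
#' configured scales is `H(q)`.  Orders with fewer than 3 usable (finite,
#' positive) scales get `NA` with a warning.
#'
#' @param fq_by_scale matrix of `F_q(s)`, rows = scales, columns = q.
#' @param scales integer window sizes (row order).
#' @param q_grid fluctuation orders (column order).
#' @return List with `hq` (slope per q) and `fit_r2` (regression R^2 per q).
#' @export
hurst_q <- function(fq_by_scale, scales, q_grid) {
  stopifnot(nrow(fq_by_scale) == length(scales),
            ncol(fq_by_scale) == length(q_grid))
  ls <- log2(scales)
  hq <- r2 <- rep(NA_real_, length(q_grid))
  for (j in seq_along(q_grid)) {
    f <- fq_by_scale[, j]
    ok <- is.finite(f) & f > 0
    if (sum(ok) < 3L) {
      warning(sprintf("q = %.2f: fewer than 3 usable scales; H(q) set to NA",
                      q_grid[j]))
      next
    }
    y <- log2(f[ok]); xr <- ls[ok]
    fit <- lm(y ~ xr)
    hq[j] <- unname(coef(fit)[2])
    r2[j] <- summary(fit)$r.squared
  }
  list(hq = hq, fit_r2 = r2)
}

#' Multifractal spectrum by Legendre transform
#'
#' Mass exponent `tau(q) = q H(q) - 1`; singularity strength
#' `h(q) = dtau/dq` by central finite differences (one-sided at the ends);
#' spectrum `D(q) = q h(q) - tau(q)`.  A monofractal (constant `H(q) = H`)
#' collapses to the single point `(H, 1)`.
#'
#' @param hq generalized Hurst exponents (finite on >= 3 consecutive orders).
#' @param q_grid the matching fluctuation orders.
#' @return `data.frame` with columns `q`, `tau`, `h`, `D` (rows with
#'   non-finite `hq` dropped).
#' @export
multifractal_spectrum <- function(hq, q_grid) {
  stopifnot(length(hq) == length(q_grid))
  ok <- is.finite(hq)
  if (sum(ok) < 3L)
    stop("spectrum error: need H(q) on at least 3 orders", call. = FALSE)
  q <- q_grid[ok]; H <- hq[ok]
  tau <- q * H - 1
  n <- length(q)
  h <- numeric(n)
  h[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  h[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    h[i] <- (tau[i + 1] - tau[i - 1]) / (q[i + 1] - q[i - 1])
  }
  data.frame(q = q, tau = tau, h = h, D = q * h - tau)
}

#' Width of the multifractal spectrum
#'
#' `delta_h = h_max - h_min` over the finite spectrum points: the headline
#' measure of the degree of multifractality ("local" complexity).
#'
#' @param spectrum output of [multifractal_spectrum()] (or any data frame
#'   with an `h` column).
#' @return Non-negative width.
#' @export
spectrum_width <- function(spectrum) {
  h <- spectrum$h[is.finite(spectrum$h)]
  if (!length(h)) stop("empty spectrum", call. = FALSE)
  max(h) - min(h)
}

#' Multifractal detrended fluctuation analysis
#'
#' Full MF-DFA of a series: profile, q-order fluctuation functions over a
#' scale range, generalized Hurst exponents `H(q)` by log-log regression,
#' mass exponents, Legendre-transform multifractal spectrum and its width.
#' The input is analyzed as-is (no pre-differencing), so for nonstationary
#' glucose-like records `H(q)` near or above 1 is expected and reported
#' unchanged.  `q = 2` reduces to ordinary DFA.
#'
#' @param series a [glucose_series()] or numeric vector.
#' @param q_grid fluctuation orders (default 21 values evenly spaced in
#'   \[-5, 5\]).
#' @param scales integer window sizes, strictly increasing (default
#'   `2^(4:9)` = 16..512).  A scale must admit at least one window from each
#'   end (so scale <= series length; a scale above half the length yields
#'   just 2 partially overlapping windows, which is accepted but makes the
#'   per-scale fluctuation noisy — watch `fit_r2`); larger scales are
#'   dropped with a warning.
#' @param order detrending polynomial order (default 2).
#' @return Object of class `mfdfa`: `q_grid`, `scales`, `fq` (scales x q
#'   matrix), `hq`, `fit_r2`, `tau`, `spectrum` (data frame q/tau/h/D),
#'   `delta_h`, `detrend_order`.
#' @examples
#' r <- mfdfa(gen_fgn(4096, hurst = 0.7, seed = 1), scales = 2^(4:9))
#' r$hq[r$q_grid == 2]    # close to 0.7
#' @export
mfdfa <- function(series, q_grid = seq(-5, 5, by = 0.5), scales = 2^(4:9),
                  order = 2) {
  x <- series_values(series)
  scales <- as.integer(scales)
  if (any(diff(scales) <= 0)) stop("scales must be strictly increasing", call. = FALSE)
  usable <- scales <= length(x)
  if (!all(usable)) {
    warning(sprintf("scales {%s} exceed the series length; dropped",
                    paste(scales[!usable], collapse = ", ")))
    scales <- scales[usable]
  }
  if (length(scales) < 3L)
    stop("need at least 3 usable scales for the log-log fits", call. = FALSE)
  prof <- mf_profile(x)
  fq <- t(vapply(scales, function(s)
    as.numeric(fluctuation_function(prof, s, order = order, q_grid = q_grid)),
    numeric(length(q_grid))))
  hfit <- hurst_q(fq, scales, q_grid)
  spec <- multifractal_spectrum(hfit$hq, q_grid)
  structure(list(q_grid = q_grid, scales = scales, fq = fq,
                 hq = hfit$hq, fit_r2 = hfit$fit_r2,
                 tau = q_grid * hfit$hq - 1,
                 spectrum = spec,
                 delta_h = spectrum_width(spec),
                 detrend_order = order),
            class = "mfdfa")
}

#' @export
print.mfdfa <- function(x, ...) {
  cat(sprintf("<mfdfa> detrend order %d, scales %s\n",
              x$detrend_order, paste(x$scales, collapse = ", ")))
  qs <- c(-5, -2, 0, 2, 5)
  idx <- match(qs, x$q_grid)
  ok <- !is.na(idx)
  cat("  H(q): ", paste(sprintf("H(%g)=%.3f", qs[ok], x$hq[idx[ok]]),
                        collapse = ", "), "\n", sep = "")
  cat(sprintf("  multifractal spectrum width delta_h = %.3f\n", x$delta_h))
  invisible(x)
}

#' @export
plot.mfdfa <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$q_grid, x$hq, type = "b", pch = 16, xlab = "q", ylab = "H(q)", ...)
  plot(x$spectrum$h, x$spectrum$D, type = "b", pch = 16,
       xlab = "h", ylab = "D(h)",
       main = sprintf("delta_h = %.2f", x$delta_h), ...)
  invisible(x)
}
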