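#' Endpoint-match and window a series (the "we" preprocessing)
#'
#' The preprocessing steps of the lowPSD_we spectral-exponent recipe:
#' (e) subtract the straight line through the first and last samples, so both
#' endpoints become zero and the implicit periodic extension has no jump;
#' then remove the residual mean (tapering a nonzero-mean segment would leak
#' DC power into the low-frequency bins the slope is fitted on); finally
#' (w) taper with the parabolic (Welch) window
#' `w_j = 1 - (2j/(N+1) - 1)^2`, `j = 1..N`.
#'
#' @param values numeric vector, length at least 16.
#' @return Preprocessed vector, same length; a linear ramp (or constant) maps
#'   to all zeros.
#' @export
preprocess_we <- function(values) {
  x <- series_values(values)
  n <- length(x)
  if (n < 16L) stop("insufficient data: need at least 16 points", call. = FALSE)
  j <- seq_len(n)
  x <- x - (x[1] + (j - 1) * (x[n] - x[1]) / (n - 1))   # endpoint matching
  x <- x - mean(x)
  w <- 1 - (2 * j / (n + 1) - 1)^2                       # parabolic window
  x * w
}

#' Raw periodogram at positive Fourier frequencies
#'
#' Squared DFT magnitudes `|A_k|^2` at frequencies `k * fs / N`,
#' `k = 1..floor(N/2)`; the zero frequency is excluded.  Unnormalized, so
#' Parseval reads `sum_k |A_k|^2 = N * sum_j x_j^2` over all N bins; any
#' constant normalization leaves the log-log slope unchanged.
#'
#' @param values numeric vector, length at least 16.
#' @param fs sampling frequency in Hz.
#' @return List with `frequencies` (Hz) and `powers`.
#' @export
periodogram <- function(values, fs) {
  x <- series_values(values)
  n <- length(x)
  if (n < 16L) stop("insufficient data: need at least 16 points", call. = FALSE)
  if (!is.numeric(fs) || fs <= 0) stop("fs must be > 0", call. = FALSE)
  A <- fft(x)
  k <- seq_len(n %/% 2)
  list(frequencies = k * fs / n, powers = Mod(A[k + 1])^2)
}

#' Fit the spectral exponent on the low-frequency band
#'
#' Ordinary least squares of `log10(power)` on `log10(frequency)` restricted
#' to `0 < f <= fs/8`; the high-frequency region `(fs/8, fs/2)` is excluded
#' before fitting.  The spectral exponent is `beta = -slope` of the fitted
#' line, i.e. `P(f) ~ c / f^beta`.  Zero-power bins are dropped before
#' taking logs.
#'
#' @param frequencies,powers periodogram output.
#' @param fs sampling frequency in Hz (defines the `fs/8` exclusion).
#' @return An object of class `spectral_fit`: `beta`, `intercept` (log10
#'   power at 1 Hz), `fit_band` (Hz), `n_freqs_used`, `signal_class`
#'   (from [classify_signal()]), `hurst` (from [beta_to_hurst()], `NA` if
#'   the class is ambiguous).
#' @export
fit_spectral_exponent <- function(frequencies, powers, fs) {
  keep <- frequencies > 0 & frequencies <= fs / 8 & powers > 0
  if (sum(keep) < 4L)
    stop("fit error: fewer than 4 usable frequencies in (0, fs/8]", call. = FALSE)
  lf <- log10(frequencies[keep])
  lp <- log10(powers[keep])
  fit <- lm(lp ~ lf)
  beta <- -unname(coef(fit)[2])
  cls <- classify_signal(beta)
  hurst <- if (cls == "ambiguous") NA_real_ else beta_to_hurst(beta, cls)
  structure(list(beta = beta,
                 intercept = unname(coef(fit)[1]),
                 fit_band = range(frequencies[keep]),
                 n_freqs_used = sum(keep),
                 signal_class = cls,
                 hurst = hurst,
                 frequencies = frequencies, powers = powers),
            class = "spectral_fit")
}

#' Spectral exponent of a series by the lowPSD_we procedure
#'
#' Convenience wrapper: [preprocess_we()] then [periodogram()] then
#' [fit_spectral_exponent()].
#'
#' @param series a [glucose_series()] (fs taken as `1/dt`) or numeric vector.
#' @param fs sampling frequency in Hz; required for plain vectors.
#' @return A `spectral_fit` object (see [fit_spectral_exponent()]).
#' @examples
#' fit <- lowpsd_we(gen_fbm(4096, hurst = 0.5, seed = 1), fs = 1)
#' fit$beta   # close to 2 = 2 * 0.5 + 1
#' @export
lowpsd_we <- function(series, fs = NULL) {
  if (inherits(series, "glucose_series")) {
    fs <- fs %||% (1 / series$dt)
    series <- series$values
  }
  if (is.null(fs)) stop("fs must be supplied for a plain numeric series", call. = FALSE)
  pg <- periodogram(preprocess_we(series), fs)
  fit_spectral_exponent(pg$frequencies, pg$powers, fs)
}

#' Classify a signal from its spectral exponent
#'
#' Stationary fractal Gaussian noise has `beta` in (-1, 1); nonstationary
#' fractional Brownian motion has `beta` in (1, 3).  Values outside both
#' ranges — including exactly 1 — are `"ambiguous"`.
#'
#' @param beta finite spectral exponent.
#' @return `"fGn"`, `"fBm"` or `"ambiguous"`.
#' @export
classify_signal <- function(beta) {
  if (!is.numeric(beta) || !is.finite(beta)) stop("beta must be finite", call. = FALSE)
  if (beta > -1 && beta < 1) "fGn" else if (beta > 1 && beta < 3) "fBm" else "ambiguous"
}

#' Convert a spectral exponent to a Hurst exponent
#'
#' Uses `beta = 2H + 1` for fBm-class signals (`H = (beta - 1)/2`) and
#' `beta = 2H - 1` for fGn-class signals (`H = (beta + 1)/2`).  Results
#' outside (0, 1) are clamped into the open interval with a warning.
#'
#' @param beta spectral exponent.
#' @param signal_class `"fGn"` or `"fBm"` (use [classify_signal()]).
#' @return Hurst exponent in (0, 1).
#' @export
beta_to_hurst <- function(beta, signal_class) {
  if (!signal_class %in% c("fGn", "fBm"))
    stop("no Hurst exponent for an ambiguous signal class", call. = FALSE)
  h <- if (signal_class == "fBm") (beta - 1) / 2 else (beta + 1) / 2
  eps <- 1e-6
  if (h <= 0 || h >= 1) {
    warning(sprintf("derived Hurst exponent %.3f outside (0,1); clamped", h))
    h <- min(max(h, eps), 1 - eps)
  }
  h
}

#' @export
print.spectral_fit <- function(x, ...) {
  cat("<spectral_fit> lowPSD_we\n")
  cat(sprintf("  beta = %.2f (%s), fit band %.3g - %.3g Hz (%d frequencies)\n",
              x$beta, x$signal_class, x$fit_band[1], x$fit_band[2],
              x$n_freqs_used))
  if (is.finite(x$hurst))
    cat(sprintf("  Hurst exponent (beta = 2H%+d): H = %.3f\n",
                if (x$signal_class == "fBm") 1L else -1L, x$hurst))
  invisible(x)
}

#' @export
plot.spectral_fit <- function(x, ...) {
  keep <- x$powers > 0
  plot(log10(x$frequencies[keep]), log10(x$powers[keep]),
       xlab = "log10 frequency (Hz)", ylab = "log10 power",
       col = "grey60", pch = 16, cex = 0.5, ...)
  abline(v = log10(x$fit_band[2]), lty = 3)
  abline(a = x$intercept, b = -x$beta, col = "red3", lwd = 2)
  legend("bottomleft", bty = "n",
         legend = sprintf("beta = %.2f (%s)", x$beta, x$signal_class))
  invisible(x)
}
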