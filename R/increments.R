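#' Signed glucose increments
#'
#' First differences of consecutive readings: element i is
#' `value[i+1] - value[i]` (mmol/L per sampling step).
#'
#' @param series a [glucose_series()] or numeric vector, length at least 2.
#' @return Numeric vector one shorter than the input.
#' @export
increments <- function(series) {
  x <- series_values(series)
  if (length(x) < 2L)
    stop("insufficient data: need at least 2 readings to form increments",
         call. = FALSE)
  diff(x)
}

#' Increment magnitude sample
#'
#' One-sided sample of increment magnitudes (all values non-negative) as used
#' by the distribution fits: either the positive increments or the absolute
#' values of the negative increments.
#'
#' @param values non-negative magnitudes (mmol/L).
#' @param sign `"positive"` or `"negative"` (which side the magnitudes came from).
#' @param source_label period identifier.
#' @return An object of class `increment_sample`.
#' @export
increment_sample <- function(values, sign = c("positive", "negative"),
                             source_label = "") {
  sign <- match.arg(sign)
  values <- as.numeric(values)
  if (any(values < 0)) stop("magnitudes must be non-negative", call. = FALSE)
  structure(list(values = values, sign = sign,
                 source_label = as.character(source_label)),
            class = "increment_sample")
}

#' @export
print.increment_sample <- function(x, ...) {
  cat(sprintf("<increment_sample> %s side%s: n = %d, mean = %.4g mmol/L\n",
              x$sign,
              if (nzchar(x$source_label)) paste0(" (", x$source_label, ")") else "",
              length(x$values),
              if (length(x$values)) mean(x$values) else NA_real_))
  invisible(x)
}

sample_values <- function(s) {
  if (inherits(s, "increment_sample")) s$values else as.numeric(s)
}

#' Split signed increments into positive/negative magnitude samples
#'
#' @param incs signed increments (from [increments()]).
#' @param zero_policy what to do with exact zeros (common under CGM
#'   quantization): `"drop"` (default), or count them with the `"positive"`
#'   or `"negative"` side.
#' @param source_label period identifier attached to both samples.
#' @return List with elements `positive` and `negative`, each an
#'   [increment_sample()]; counts satisfy
#'   `|pos| + |neg| + |dropped zeros| = length(incs)`.
#' @export
split_magnitudes <- function(incs, zero_policy = c("drop", "positive", "negative"),
                             source_label = "") {
  zero_policy <- match.arg(zero_policy)
  incs <- as.numeric(incs)
  pos <- incs[incs > 0]
  neg <- -incs[incs < 0]
  zeros <- sum(incs == 0)
  if (zeros && zero_policy == "positive") pos <- c(pos, rep(0, zeros))
  if (zeros && zero_policy == "negative") neg <- c(neg, rep(0, zeros))
  list(positive = increment_sample(pos, "positive", source_label),
       negative = increment_sample(neg, "negative", source_label))
}

#' Gaussian maximum-likelihood fit
#'
#' `mu` is the sample mean and `sigma` the maximum-likelihood standard
#' deviation (population normalization, divisor n).
#'
#' @param sample an [increment_sample()] or numeric vector, at least 2 values.
#' @return List of class `gaussian_params` with elements `mu`, `sigma`.
#' @export
fit_gaussian <- function(sample) {
  x <- sample_values(sample)
  if (length(x) < 2L) stop("insufficient data: need at least 2 values", call. = FALSE)
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (sigma == 0)
    stop("degenerate fit: all values identical (sigma = 0)", call. = FALSE)
  structure(list(mu = mu, sigma = sigma), class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("Gaussian (%.4f, %.4f)  [mu, sigma]\n", x$mu, x$sigma))
  invisible(x)
}

#' Quantile-quantile pairs against a fitted law
#'
#' Pairs the empirical order statistics with the law's quantiles at plotting
#' positions `(i - 0.5) / n`.  Stable quantiles come from numeric inversion
#' of the CDF ([stable_quantile()]).
#'
#' @param sample an [increment_sample()] or numeric vector (non-empty).
#' @param law a [stable_params()] or `gaussian_params` object.
#' @return `data.frame` with columns `theoretical`, `empirical`, sorted and
#'   co-monotone in the theoretical coordinate.
#' @export
qq_points <- function(sample, law) {
  x <- sort(sample_values(sample))
  n <- length(x)
  if (n < 1L) stop("empty sample", call. = FALSE)
  p <- (seq_len(n) - 0.5) / n
  th <- if (inherits(law, "gaussian_params")) {
    qnorm(p, law$mu, law$sigma)
  } else {
    stable_quantile(p, law)
  }
  data.frame(theoretical = th, empirical = x)
}

#' Compare alpha-stable and Gaussian fits on one increment sample
#'
#' Fits both laws by maximum likelihood, records log-likelihoods and Q-Q
#' pairs, and declares the better-fitting law by the higher log-likelihood.
#' (Both models have fixed dimension across samples; no information
#' criterion is applied.)
#'
#' @inheritParams fit_stable
#' @return Object of class `fit_comparison`: `stable`, `gaussian`,
#'   `loglik_stable`, `loglik_gaussian`, `qq_stable`, `qq_gaussian`, `better`.
#' @export
compare_fits <- function(sample) {
  x <- sample_values(sample)
  if (length(x) < 50)
    stop("insufficient data: fit comparison needs at least 50 values",
         call. = FALSE)
  st <- fit_stable(x)
  ga <- fit_gaussian(x)
  ll_s <- attr(st, "loglik")
  ll_g <- sum(dnorm(x, ga$mu, ga$sigma, log = TRUE))
  structure(list(
    stable = st, gaussian = ga,
    loglik_stable = ll_s, loglik_gaussian = ll_g,
    qq_stable = qq_points(x, st), qq_gaussian = qq_points(x, ga),
    better = if (ll_s >= ll_g) "stable" else "gaussian",
    n = length(x),
    source_label = if (inherits(sample, "increment_sample")) sample$source_label else ""
  ), class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("<fit_comparison>",
      if (nzchar(x$source_label)) paste0(" ", x$source_label), "\n", sep = "")
  cat("  "); print(x$stable)
  cat("  "); print(x$gaussian)
  cat(sprintf("  log-likelihood: stable %.2f vs Gaussian %.2f -> %s fits better\n",
              x$loglik_stable, x$loglik_gaussian, x$better))
  invisible(x)
}

#' @describeIn compare_fits Q-Q panels for both laws (diagonal = perfect fit).
#' @param x a `fit_comparison` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.fit_comparison <- function(x, ...) {
  op <- par(mfrow = c(1, 2)); on.exit(par(op))
  plot(x$qq_stable$theoretical, x$qq_stable$empirical,
       xlab = "stable quantiles", ylab = "empirical quantiles",
       main = "alpha-stable", ...)
  abline(0, 1, col = "grey50")
  plot(x$qq_gaussian$theoretical, x$qq_gaussian$empirical,
       xlab = "Gaussian quantiles", ylab = "empirical quantiles",
       main = "Gaussian", ...)
  abline(0, 1, col = "grey50")
  invisible(x)
}
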