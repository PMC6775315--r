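#' Sample entropy (SampEn)
#'
#' The negative natural logarithm of the conditional probability that two
#' subsequences similar for `m` points (within Chebyshev tolerance `r_abs`)
#' remain similar at the next point.  Template matching follows the
#' Richman-Moorman convention: the `N - m` templates of length `m` are the
#' same set extended to length `m + 1`, self-matches are excluded, and the
#' distance is the maximum coordinate difference, compared inclusively
#' (`d <= r`).
#'
#' @param values numeric series (length > m + 1).
#' @param m embedding dimension (template length), default 2.
#' @param r_abs tolerance in the units of `values`.  May be 0, in which case
#'   only exact coincidences match (a constant series then still yields 0).
#' @return SampEn in nats, with attributes `A` and `B` (the pair counts).
#'   When either count is zero the entropy is undefined: the value is `NA`
#'   with attribute `undefined = TRUE` (an explicit flag, not silently
#'   dropped).
#' @examples
#' sample_entropy(rep(3, 50), m = 2, r_abs = 0.1)   # constant series: 0
#' @export
sample_entropy <- function(values, m = 2, r_abs) {
  x <- series_values(values)
  m <- as.integer(m)
  if (m < 1L) stop("m must be at least 1", call. = FALSE)
  if (length(x) <= m + 1L)
    stop("insufficient data: series length must exceed m + 1", call. = FALSE)
  if (!is.numeric(r_abs) || !is.finite(r_abs) || r_abs < 0)
    stop("r_abs must be a finite non-negative tolerance", call. = FALSE)
  cnt <- sampen_counts(x, m, r_abs)
  if (cnt$A == 0 || cnt$B == 0) {
    return(structure(NA_real_, A = cnt$A, B = cnt$B, undefined = TRUE))
  }
  structure(-log(cnt$A / cnt$B), A = cnt$A, B = cnt$B, undefined = FALSE)
}

#' Coarse-grain a series at scale k
#'
#' Non-overlapping block means: output element j is the mean of input
#' elements `(j-1)k + 1 .. jk`; the trailing remainder (fewer than k points)
#' is discarded, so the output length is `floor(N / k)`.
#'
#' @param values numeric series.
#' @param k scale factor (integer >= 1, at most the series length).
#' @return Numeric vector of length `floor(length(values) / k)`.
#' @export
coarse_grain <- function(values, k) {
  x <- series_values(values)
  k <- as.integer(k)
  if (k < 1L) stop("scale factor k must be at least 1", call. = FALSE)
  if (k > length(x))
    stop("insufficient data: scale factor exceeds series length", call. = FALSE)
  if (k == 1L) return(x)
  nb <- length(x) %/% k
  colMeans(matrix(x[seq_len(nb * k)], nrow = k))
}

#' Multiscale sample entropy curve
#'
#' SampEn on coarse-grained versions of the series across scale factors.
#' The tolerance is anchored once to the standard deviation of the original
#' (scale-1) series — `r_absolute = r_fraction * sd(values)` — and held
#' constant across scales, the standard MSE convention: coarse-graining then
#' shrinks the effective variability against a fixed yardstick, which is
#' what makes the curve discriminate correlated from uncorrelated signals.
#'
#' @param series a [glucose_series()] or numeric vector.
#' @param m embedding dimension (default 2).
#' @param r_fraction tolerance as a fraction of the scale-1 SD (default 0.15).
#' @param scales integer scale factors, strictly increasing (default 1:10).
#'   Every scale must leave at least `10 * (m + 1)` coarse-grained points;
#'   offending scales raise an error listing the admissible ones.
#' @return Object of class `mse_curve`: `scales`, `entropies` (NA where
#'   undefined), `undefined` (logical flags), `m`, `r_fraction`,
#'   `r_absolute`, `sd_reference`, and optionally `boot_sd` filled in by the
#'   pipeline's bootstrap.
#' @export
mse_curve <- function(series, m = 2, r_fraction = 0.15, scales = 1:10) {
  x <- series_values(series)
  scales <- as.integer(scales)
  if (any(scales < 1L) || any(diff(scales) <= 0))
    stop("scales must be strictly increasing integers >= 1", call. = FALSE)
  n <- length(x)
  min_pts <- 10L * (m + 1L)
  ok <- (n %/% scales) >= min_pts
  if (!all(ok)) {
    adm <- scales[ok]
    stop(sprintf(
      "scale-range error: scales {%s} leave fewer than %d coarse-grained points (n = %d); admissible scales: {%s}",
      paste(scales[!ok], collapse = ", "), min_pts, n,
      paste(adm, collapse = ", ")), call. = FALSE)
  }
  sd_ref <- sd(x)
  r_abs <- r_fraction * sd_ref
  ent <- rep(NA_real_, length(scales))
  undef <- logical(length(scales))
  for (i in seq_along(scales)) {
    e <- sample_entropy(coarse_grain(x, scales[i]), m = m, r_abs = r_abs)
    ent[i] <- as.numeric(e)
    undef[i] <- isTRUE(attr(e, "undefined"))
  }
  structure(list(scales = scales, entropies = ent, undefined = undef,
                 m = m, r_fraction = r_fraction, r_absolute = r_abs,
                 sd_reference = sd_ref, boot_sd = NULL),
            class = "mse_curve")
}

#' @export
print.mse_curve <- function(x, ...) {
  cat(sprintf("<mse_curve> m = %d, r = %.3g * SD = %.4g\n",
              x$m, x$r_fraction, x$r_absolute))
  df <- data.frame(scale = x$scales,
                   SampEn = round(x$entropies, 4))
  if (!is.null(x$boot_sd)) df$boot_sd <- round(x$boot_sd, 4)
  print(df, row.names = FALSE)
  if (any(x$undefined))
    cat("  (undefined entropies at scales:",
        paste(x$scales[x$undefined], collapse = ", "), ")\n")
  invisible(x)
}

#' @export
plot.mse_curve <- function(x, ..., col = "steelblue4") {
  plot(x$scales, x$entropies, type = "b", pch = 16, col = col,
       xlab = "scale factor", ylab = "sample entropy (nats)", ...)
  if (!is.null(x$boot_sd)) {
    ok <- is.finite(x$entropies) & is.finite(x$boot_sd) & x$boot_sd > 0
    if (any(ok))
      arrows(x$scales[ok], x$entropies[ok] - x$boot_sd[ok],
             x$scales[ok], x$entropies[ok] + x$boot_sd[ok],
             angle = 90, code = 3, length = 0.03, col = col)
  }
  invisible(x)
}
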