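#' Order-preserving random subsample
#'
#' Keeps a uniformly random subset of `round(keep_fraction * N)` points in
#' their original order: the resampling unit behind the ordered-subsequence
#' bootstrap used for the error bars.
#'
#' @param values numeric series (or [glucose_series()]).
#' @param keep_fraction fraction of points retained, in (0, 1].
#' @param seed integer seed.
#' @return Numeric vector of length `round(keep_fraction * N)` with indices
#'   strictly increasing; identical to the input when `keep_fraction = 1`.
#' @export
ordered_subsample <- function(values, keep_fraction = 0.95, seed = NULL) {
  x <- series_values(values)
  if (!is.numeric(keep_fraction) || keep_fraction <= 0 || keep_fraction > 1)
    stop("keep_fraction must lie in (0, 1]", call. = FALSE)
  m <- round(keep_fraction * length(x))
  if (m < 2) stop("keep_fraction leaves fewer than 2 points", call. = FALSE)
  if (m == length(x)) return(x)
  idx <- with_seed(seed, sort(sample.int(length(x), m)))
  x[idx]
}

# Contiguous-window variant: one random window of length round(kf * N).
contiguous_subsample <- function(x, keep_fraction, seed = NULL) {
  m <- round(keep_fraction * length(x))
  if (m == length(x)) return(x)
  start <- with_seed(seed, sample.int(length(x) - m + 1L, 1L))
  x[start:(start + m - 1L)]
}

#' Bootstrap standard deviation of a complexity statistic
#'
#' Evaluates `statistic` on `n_reps` independent order-preserving subsamples,
#' each containing `keep_fraction` of the original points, and reports the
#' standard deviation across replicates — the error-bar construction used by
#' the pipeline for SampEn, H(q), beta and delta_h.  Subsampled series are
#' treated as uniformly sampled (index-based) by the downstream estimators.
#'
#' Two readings of "subsequences containing 95% of the data" are available:
#' `mode = "delete"` (default) removes a uniformly random 5% of points and
#' keeps the rest in order; `mode = "window"` takes one random contiguous
#' 95%-length window per replicate.
#'
#' @param values numeric series or [glucose_series()].
#' @param statistic function mapping a numeric vector to one number (e.g.
#'   SampEn at a scale, H(q) at one q, beta, delta_h).
#' @param n_reps number of replicates (at least 20; default 100).
#' @param keep_fraction retained share of points (default 0.95).
#' @param seed master seed; per-replicate seeds are derived from it
#'   deterministically, so a fixed master seed reproduces the result exactly.
#' @param mode `"delete"` or `"window"` (see above).
#' @param statistic_name label stored in the result.
#' @return Object of class `bootstrap_result`: `statistic_name`,
#'   `replicates`, `sd`, `keep_fraction`, `n_reps`, `seed`, `mode`,
#'   `n_undefined` (replicates that returned `NA`; excluded from the SD).
#'   More than 50% undefined replicates is an error.
#' @export
bootstrap_sd <- function(values, statistic, n_reps = 100, keep_fraction = 0.95,
                         seed = NULL, mode = c("delete", "window"),
                         statistic_name = deparse(substitute(statistic))) {
  mode <- match.arg(mode)
  x <- series_values(values)
  n_reps <- as.integer(n_reps)
  if (n_reps < 20L) stop("n_reps must be at least 20", call. = FALSE)
  seeds <- spawn_seeds(seed %||% 1L, n_reps)
  reps <- vapply(seq_len(n_reps), function(i) {
    xs <- if (mode == "delete") ordered_subsample(x, keep_fraction, seeds[i])
          else contiguous_subsample(x, keep_fraction, seeds[i])
    out <- tryCatch(suppressWarnings(statistic(xs)), error = function(e) NA_real_)
    if (length(out) != 1L || !is.numeric(out)) NA_real_ else as.numeric(out)
  }, numeric(1))
  n_undef <- sum(!is.finite(reps))
  if (n_undef > n_reps / 2)
    stop(sprintf("bootstrap failure: %d of %d replicates undefined",
                 n_undef, n_reps), call. = FALSE)
  structure(list(statistic_name = statistic_name,
                 replicates = reps,
                 sd = sd(reps[is.finite(reps)]),
                 keep_fraction = keep_fraction,
                 n_reps = n_reps,
                 seed = seed,
                 mode = mode,
                 n_undefined = n_undef),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("<bootstrap_result> %s: sd = %.4g (%d reps, keep %.0f%%, mode %s%s)\n",
              x$statistic_name, x$sd, x$n_reps, 100 * x$keep_fraction, x$mode,
              if (x$n_undefined) sprintf(", %d undefined", x$n_undefined) else ""))
  invisible(x)
}

# Replicate whole curves (MSE entropies, H(q), beta, delta_h) over ordered
# subsamples in a single loop so each replicate's estimators share the same
# subsample.  Returns per-element SDs.  Internal: run_period() uses this for
# its error bars.
bootstrap_curves <- function(x, config, seed) {
  n_reps <- config$bootstrap$n_reps
  kf <- config$bootstrap$keep_fraction
  mode <- config$bootstrap$mode
  seeds <- spawn_seeds(seed, n_reps)
  ns <- length(config$mse$scales)
  nq <- length(config$mfdfa$q_grid)
  mse_mat <- matrix(NA_real_, n_reps, ns)
  hq_mat <- matrix(NA_real_, n_reps, nq)
  beta_v <- dh_v <- rep(NA_real_, n_reps)
  for (i in seq_len(n_reps)) {
    xs <- if (mode == "delete") ordered_subsample(x, kf, seeds[i])
          else contiguous_subsample(x, kf, seeds[i])
    mc <- tryCatch(suppressWarnings(
      mse_curve(xs, m = config$mse$m, r_fraction = config$mse$r_fraction,
                scales = config$mse$scales)), error = function(e) NULL)
    if (!is.null(mc)) mse_mat[i, ] <- mc$entropies
    mf <- tryCatch(suppressWarnings(
      mfdfa(xs, q_grid = config$mfdfa$q_grid, scales = config$mfdfa$scales,
            order = config$mfdfa$detrend_order)), error = function(e) NULL)
    if (!is.null(mf)) {
      hq_mat[i, ] <- mf$hq
      dh_v[i] <- mf$delta_h
    }
    sp <- tryCatch(suppressWarnings(lowpsd_we(xs, fs = config$spectral$fs)),
                   error = function(e) NULL)
    if (!is.null(sp)) beta_v[i] <- sp$beta
  }
  col_sd <- function(m) apply(m, 2, function(v) sd(v[is.finite(v)]))
  list(mse_sd = col_sd(mse_mat),
       hq_sd = col_sd(hq_mat),
       beta_sd = sd(beta_v[is.finite(beta_v)]),
       delta_h_sd = sd(dh_v[is.finite(dh_v)]),
       n_reps = n_reps, keep_fraction = kf, mode = mode)
}
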