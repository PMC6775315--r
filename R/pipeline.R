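#' Analysis configuration
#'
#' Bundles the settings of every stage with defaults matching the standard
#' CGM use: MSE with embedding dimension `m = 2` and tolerance r = 0.15 of
#' the series SD over scales 1-10; MF-DFA with detrending order 2, scales
#' `2^4..2^9` and 21 q values in \[-5, 5\]; spectral fitting with the fixed
#' `fs/8` high-frequency exclusion; ordered-subsequence bootstrap with 100
#' replicates keeping 95% of the points.
#'
#' @param mse list: `m`, `r_fraction`, `scales`.
#' @param mfdfa list: `q_grid`, `scales`, `detrend_order`.
#' @param spectral list: `fs` (Hz; `NULL` = take `1/dt` from the series).
#' @param bootstrap list: `n_reps` (0 disables the bootstrap),
#'   `keep_fraction`, `mode` (`"delete"` or `"window"`).
#' @param zero_policy zero-increment handling for [split_magnitudes()].
#' @param seed master seed for all randomness in [run_period()].
#' @return List of class `analysis_config`.
#' @export
analysis_config <- function(mse = list(), mfdfa = list(), spectral = list(),
                            bootstrap = list(), zero_policy = "drop",
                            seed = 1L) {
  cfg <- list(
    mse = utils::modifyList(list(m = 2L, r_fraction = 0.15, scales = 1:10), mse),
    mfdfa = utils::modifyList(list(q_grid = seq(-5, 5, by = 0.5),
                                   scales = 2^(4:9), detrend_order = 2L), mfdfa),
    spectral = utils::modifyList(list(fs = NULL), spectral),
    bootstrap = utils::modifyList(list(n_reps = 100L, keep_fraction = 0.95,
                                       mode = "delete"), bootstrap),
    zero_policy = zero_policy,
    seed = as.integer(seed))
  class(cfg) <- "analysis_config"
  cfg
}

run_stage <- function(name, expr, verbose = FALSE) {
  t0 <- proc.time()[["elapsed"]]
  out <- tryCatch(expr, error = function(e) {
    warning(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
            call. = FALSE)
    structure(list(error = conditionMessage(e)), class = "stage_error")
  })
  if (verbose)
    message(sprintf("[%s] %.2f s", name, proc.time()[["elapsed"]] - t0))
  out
}

#' Run the full complexity analysis on one monitoring period
#'
#' Executes, in order: increment-distribution fits (positive and negative
#' magnitude samples), lowPSD_we spectral fit, multiscale sample entropy,
#' MF-DFA, and the ordered-subsequence bootstrap error bars.  A stage that
#' fails (e.g. too few increments for a stable fit) is recorded as an error
#' entry without aborting the remaining stages.  All randomness derives from
#' `config$seed`, so a fixed seed reproduces the report exactly.
#'
#' @param series a [glucose_series()] (regularized; see [regularize()]).
#' @param config an [analysis_config()].
#' @param verbose print per-stage timings.
#' @return Object of class `period_report` with elements `label`, `config`,
#'   `increments` (list `positive`/`negative` of [compare_fits()] results),
#'   `spectral`, `mse`, `mfdfa`, `bootstrap`.
#' @export
run_period <- function(series, config = analysis_config(), verbose = FALSE) {
  stopifnot(inherits(series, "glucose_series"))
  if (!is_uniform(series))
    stop("series is not uniformly sampled; run regularize() first", call. = FALSE)
  x <- series$values
  n <- length(x)
  if (n %/% max(config$mse$scales) < 10 * (config$mse$m + 1))
    stop(sprintf(
      "series too short (n = %d) for MSE scales up to %d; admissible max scale: %d",
      n, max(config$mse$scales), n %/% (10 * (config$mse$m + 1))), call. = FALSE)

  fs <- config$spectral$fs %||% (1 / series$dt)
  cfg <- config
  cfg$spectral$fs <- fs

  incs <- increments(series)
  sides <- split_magnitudes(incs, zero_policy = config$zero_policy,
                            source_label = series$label)
  inc_fits <- list(
    positive = run_stage("increments/positive",
                         compare_fits(sides$positive), verbose),
    negative = run_stage("increments/negative",
                         compare_fits(sides$negative), verbose))

  spectral <- run_stage("spectral", lowpsd_we(x, fs = fs), verbose)
  mse <- run_stage("mse",
                   mse_curve(x, m = cfg$mse$m, r_fraction = cfg$mse$r_fraction,
                             scales = cfg$mse$scales), verbose)
  mfd <- run_stage("mfdfa",
                   mfdfa(x, q_grid = cfg$mfdfa$q_grid, scales = cfg$mfdfa$scales,
                         order = cfg$mfdfa$detrend_order), verbose)
  boot <- if (cfg$bootstrap$n_reps >= 20) {
    run_stage("bootstrap", bootstrap_curves(x, cfg, seed = cfg$seed), verbose)
  } else NULL
  if (!is.null(boot) && !inherits(boot, "stage_error") &&
      inherits(mse, "mse_curve")) {
    mse$boot_sd <- boot$mse_sd
  }

  structure(list(label = series$label, config = cfg, n = n, dt = series$dt,
                 increments = inc_fits, spectral = spectral, mse = mse,
                 mfdfa = mfd, bootstrap = boot),
            class = "period_report")
}

#' @export
print.period_report <- function(x, ...) {
  cat("<period_report>", if (nzchar(x$label)) paste0(" ", x$label), "\n", sep = "")
  cat(sprintf("  n = %d readings at dt = %g s\n", x$n, x$dt))
  for (side in c("positive", "negative")) {
    f <- x$increments[[side]]
    if (inherits(f, "fit_comparison"))
      cat(sprintf("  %s increments: alpha = %.3f, better fit: %s\n",
                  side, f$stable$alpha, f$better))
  }
  if (inherits(x$spectral, "spectral_fit"))
    cat(sprintf("  spectral: beta = %.2f (%s), H = %.3f\n",
                x$spectral$beta, x$spectral$signal_class, x$spectral$hurst))
  if (inherits(x$mse, "mse_curve"))
    cat(sprintf("  MSE: SampEn(scale 1) = %.3f, mean over scales = %.3f\n",
                x$mse$entropies[1], mean(x$mse$entropies, na.rm = TRUE)))
  if (inherits(x$mfdfa, "mfdfa"))
    cat(sprintf("  MF-DFA: H(2) = %.3f, delta_h = %.3f\n",
                x$mfdfa$hq[match(2, x$mfdfa$q_grid)], x$mfdfa$delta_h))
  invisible(x)
}

# Strip closures/attrs so the report serializes to stable JSON.
report_to_list <- function(r) {
  clean <- function(v) if (is.numeric(v)) unname(as.numeric(v)) else v
  fitc <- function(f) {
    if (!inherits(f, "fit_comparison")) return(list(error = f$error))
    list(stable = unclass(f$stable)[c("alpha", "skew", "scale", "location")],
         gaussian = unclass(f$gaussian),
         loglik_stable = f$loglik_stable,
         loglik_gaussian = f$loglik_gaussian,
         better = f$better, n = f$n)
  }
  sp <- if (inherits(r$spectral, "spectral_fit")) {
    list(beta = r$spectral$beta, intercept = r$spectral$intercept,
         fit_band = clean(r$spectral$fit_band),
         n_freqs_used = r$spectral$n_freqs_used,
         signal_class = r$spectral$signal_class, hurst = r$spectral$hurst)
  } else list(error = r$spectral$error)
  ms <- if (inherits(r$mse, "mse_curve")) {
    list(scales = clean(r$mse$scales), entropies = clean(r$mse$entropies),
         undefined = r$mse$undefined, m = r$mse$m,
         r_fraction = r$mse$r_fraction, r_absolute = r$mse$r_absolute,
         sd_reference = r$mse$sd_reference,
         boot_sd = clean(r$mse$boot_sd))
  } else list(error = r$mse$error)
  mf <- if (inherits(r$mfdfa, "mfdfa")) {
    list(q_grid = clean(r$mfdfa$q_grid), scales = clean(r$mfdfa$scales),
         hq = clean(r$mfdfa$hq), tau = clean(r$mfdfa$tau),
         fit_r2 = clean(r$mfdfa$fit_r2),
         spectrum = as.list(r$mfdfa$spectrum),
         delta_h = r$mfdfa$delta_h,
         detrend_order = r$mfdfa$detrend_order)
  } else list(error = r$mfdfa$error)
  bt <- if (is.null(r$bootstrap)) NULL
        else if (inherits(r$bootstrap, "stage_error")) list(error = r$bootstrap$error)
        else lapply(r$bootstrap, clean)
  cfg <- r$config
  cfg$mse$scales <- clean(cfg$mse$scales)
  cfg$mfdfa$q_grid <- clean(cfg$mfdfa$q_grid)
  cfg$mfdfa$scales <- clean(cfg$mfdfa$scales)
  list(label = r$label, n = r$n, dt = r$dt, config = unclass(cfg),
       increments = list(positive = fitc(r$increments$positive),
                         negative = fitc(r$increments$negative)),
       spectral = sp, mse = ms, mfdfa = mf, bootstrap = bt)
}

#' Serialize a period report to JSON
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files (full-precision numbers, no timestamps).
#'
#' @param report a `period_report` from [run_period()].
#' @param path output file; when `NULL` the JSON string is returned.
#' @return `path` invisibly, or the JSON string.
#' @export
write_report <- function(report, path = NULL) {
  stopifnot(inherits(report, "period_report"))
  js <- jsonlite::toJSON(report_to_list(report), auto_unbox = TRUE,
                         digits = NA, null = "null", na = "null", pretty = TRUE)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Read a period report back from JSON
#' @param path file written by [write_report()].
#' @return A plain list mirroring the report structure.
#' @export
read_report <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

# Accept a period_report or a report JSON path/list.
as_report_list <- function(r) {
  if (inherits(r, "period_report")) return(report_to_list(r))
  if (is.character(r) && length(r) == 1L && file.exists(r)) return(read_report(r))
  if (is.list(r)) return(r)
  stop("cannot interpret report argument", call. = FALSE)
}

verdict_scalar <- function(d) {
  if (!is.finite(d)) return(NA_character_)
  if (d > 0) "increased" else if (d < 0) "decreased" else "none"
}

verdict_vector <- function(d, share = 0.8) {
  d <- d[is.finite(d)]
  if (!length(d)) return(NA_character_)
  if (all(d == 0)) return("none")
  pos <- mean(d > 0)
  if (pos >= share) "increased" else if (pos <= 1 - share) "decreased" else "mixed"
}

#' Compare two period reports
#'
#' Signed differences (B minus A) and directional verdicts for the
#' complexity quantities: spectral exponent beta, per-scale sample entropy,
#' `H(q)` per q, and the multifractal spectrum width delta_h.  A vector
#' quantity is "increased"/"decreased" when at least 80% of its per-element
#' differences share the sign, otherwise "mixed".  The comparison is
#' antisymmetric: swapping the arguments flips all signs and verdicts.
#'
#' @param report_a,report_b `period_report` objects, report lists, or paths
#'   to JSON written by [write_report()].
#' @return Object of class `period_comparison` with per-quantity `diff` and
#'   `verdict` entries plus the labels compared; quantities missing from
#'   either report are listed in `$gaps`.
#' @export
compare_periods <- function(report_a, report_b) {
  a <- as_report_list(report_a)
  b <- as_report_list(report_b)
  gaps <- character(0)
  out <- list(label_a = a$label, label_b = b$label)

  if (is.null(a$spectral$error) && is.null(b$spectral$error)) {
    d <- b$spectral$beta - a$spectral$beta
    out$beta <- list(a = a$spectral$beta, b = b$spectral$beta,
                     diff = d, verdict = verdict_scalar(d))
  } else gaps <- c(gaps, "beta")

  if (is.null(a$mse$error) && is.null(b$mse$error) &&
      identical(as.numeric(a$mse$scales), as.numeric(b$mse$scales))) {
    d <- as.numeric(b$mse$entropies) - as.numeric(a$mse$entropies)
    out$sampen <- list(scales = as.numeric(a$mse$scales), diff = d,
                       verdict = verdict_vector(d))
  } else gaps <- c(gaps, "sampen")

  if (is.null(a$mfdfa$error) && is.null(b$mfdfa$error) &&
      identical(as.numeric(a$mfdfa$q_grid), as.numeric(b$mfdfa$q_grid))) {
    d <- as.numeric(b$mfdfa$hq) - as.numeric(a$mfdfa$hq)
    out$hq <- list(q = as.numeric(a$mfdfa$q_grid), diff = d,
                   verdict = verdict_vector(d))
    dd <- b$mfdfa$delta_h - a$mfdfa$delta_h
    out$delta_h <- list(a = a$mfdfa$delta_h, b = b$mfdfa$delta_h,
                        diff = dd, verdict = verdict_scalar(dd))
  } else gaps <- c(gaps, "hq", "delta_h")

  out$gaps <- gaps
  structure(out, class = "period_comparison")
}

#' @export
print.period_comparison <- function(x, ...) {
  cat(sprintf("<period_comparison> %s -> %s\n",
              x$label_a %||% "A", x$label_b %||% "B"))
  if (!is.null(x$beta))
    cat(sprintf("  beta:    %.3f -> %.3f (%s)\n",
                x$beta$a, x$beta$b, x$beta$verdict))
  if (!is.null(x$sampen))
    cat(sprintf("  SampEn:  mean diff %+0.3f across %d scales (%s)\n",
                mean(x$sampen$diff, na.rm = TRUE), length(x$sampen$diff),
                x$sampen$verdict))
  if (!is.null(x$hq))
    cat(sprintf("  H(q):    mean diff %+0.3f across %d orders (%s)\n",
                mean(x$hq$diff, na.rm = TRUE), length(x$hq$diff),
                x$hq$verdict))
  if (!is.null(x$delta_h))
    cat(sprintf("  delta_h: %.3f -> %.3f (%s)\n",
                x$delta_h$a, x$delta_h$b, x$delta_h$verdict))
  if (length(x$gaps))
    cat("  gaps:", paste(x$gaps, collapse = ", "), "\n")
  invisible(x)
}
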