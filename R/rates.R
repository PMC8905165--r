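## Per-microtubule landing rates, Welch's t-test, motile fractions.

#' Per-microtubule landing rates
#'
#' For each microtubule `i` in the field the rate is
#' `count_i / (length_i * duration)` in events per um per minute;
#' microtubules with no events contribute zero. The mean and s.e.m. are taken
#' over microtubules. With `processive_only` only motile events (column
#' `motile`, or `class == "processive"` for raw landing tables) are counted.
#'
#' @param events Events mapped to microtubules: a `RunEvent` data frame or a
#'   landing table from [sample_landings()]; must have `mt_id`.
#' @param field An `mt_field`.
#' @param duration Observation time in minutes.
#' @param processive_only Count only motile/processive events.
#' @return An object of class `landing_rate_result`: `per_mt_rates`,
#'   `mean_rate`, `sem`, `n_mts`, `processive_only`.
#' @export
landing_rate <- function(events, field, duration, processive_only = FALSE) {
  stopifnot(duration > 0)
  if (any(field$length_um <= 0)) stop("microtubule of zero length", call. = FALSE)
  if (nrow(events) && !all(events$mt_id %in% field$mt_id))
    stop("events reference microtubules absent from the field", call. = FALSE)
  if (processive_only && nrow(events)) {
    keep <- if (!is.null(events$motile)) events$motile
    else if (!is.null(events$class)) events$class == "processive"
    else stop("processive_only needs a 'motile' or 'class' column", call. = FALSE)
    events <- events[keep, , drop = FALSE]
  }
  counts <- table(factor(events$mt_id, levels = field$mt_id))
  rates <- as.numeric(counts) / (field$length_um * duration)
  structure(list(per_mt_rates = rates,
                 mean_rate = mean(rates),
                 sem = stats::sd(rates) / sqrt(length(rates)),
                 n_mts = nrow(field),
                 processive_only = processive_only),
            class = "landing_rate_result")
}

#' @export
print.landing_rate_result <- function(x, ...) {
  cat(sprintf("<landing_rate> %s%.3f +/- %.3f events/(um min), n = %d microtubules\n",
              if (x$processive_only) "processive " else "",
              x$mean_rate, x$sem, x$n_mts))
  invisible(x)
}

#' Welch's two-sample t-test
#'
#' Unequal-variance t-test with Welch-Satterthwaite degrees of freedom,
#' two-sided, as used to compare per-microtubule landing-rate samples.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return An object of class `welch_result`: `t_statistic`, `df`, `p_value`.
#' @export
welch_t_test <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 values", call. = FALSE)
  if (stats::var(a) == 0 && stats::var(b) == 0)
    stop("undefined statistic: both samples have zero variance", call. = FALSE)
  tt <- stats::t.test(a, b, var.equal = FALSE)
  structure(list(t_statistic = unname(tt$statistic),
                 df = unname(tt$parameter),
                 p_value = tt$p.value),
            class = "welch_result")
}

#' @export
print.welch_result <- function(x, ...) {
  cat(sprintf("<welch_t_test> t = %.3f, df = %.2f, p = %.4g\n",
              x$t_statistic, x$df, x$p_value))
  invisible(x)
}

#' Motile fraction with Wilson 95% interval
#'
#' Fraction of (filtered) events classified motile, with the Wilson score
#' interval for a binomial proportion.
#'
#' @param events A `RunEvent` data frame with a logical `motile` column.
#' @return List of class `motile_fraction_result`: `fraction`, `ci95`,
#'   `n_motile`, `n`.
#' @export
motile_fraction <- function(events) {
  if (nrow(events) == 0L) stop("no events", call. = FALSE)
  x <- sum(events$motile); n <- nrow(events)
  ci <- suppressWarnings(stats::prop.test(x, n, correct = FALSE)$conf.int)
  structure(list(fraction = x / n, ci95 = as.numeric(ci),
                 n_motile = x, n = n),
            class = "motile_fraction_result")
}

#' @export
print.motile_fraction_result <- function(x, ...) {
  cat(sprintf("<motile_fraction> %.1f%% (Wilson CI95 [%.1f, %.1f]%%), %d / %d events\n",
              100 * x$fraction, 100 * x$ci95[1], 100 * x$ci95[2],
              x$n_motile, x$n))
  invisible(x)
}
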