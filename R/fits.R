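## Statistical layer: histogram Gaussian fits of velocity distributions,
## survival-curve exponential fits of run lengths / residency times,
## percentile-bootstrap confidence intervals.

#' Fit one or two Gaussians to a histogram of velocities
#'
#' Histograms the raw values at `bin_width` and least-squares fits a sum of
#' `n_components` Gaussians to the bin counts. Component means are reported
#' with their standard errors from the fit covariance; r-squared is computed
#' on the histogram counts. For two components the optimiser is initialised
#' from a 2-means split of the raw values (groups seed the means, s.d.s and
#' amplitudes), which is robust when the modes overlap.
#'
#' @param values Numeric vector (nm/s). Needs n >= 20 for one component,
#'   n >= 40 for two.
#' @param n_components 1 or 2.
#' @param bin_width Histogram bin width (default 20 nm/s).
#' @return An object of class `gaussian_fit`: `n_components`, `means`
#'   (ascending for 2 components), `sds`, `amplitudes`, `sem_of_means`,
#'   `r_squared`, `n`, `bin_width`.
#' @export
histogram_gaussian_fit <- function(values, n_components = 1L, bin_width = 20) {
  n_components <- as.integer(n_components)
  stopifnot(n_components %in% c(1L, 2L), bin_width > 0)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < ifelse(n_components == 1L, 20L, 40L))
    stop("need at least ", ifelse(n_components == 1L, 20, 40),
         " values for a ", n_components, "-component fit", call. = FALSE)
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- ceiling(max(values) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(values, breaks = breaks, plot = FALSE)
  x <- h$mids; y <- h$counts
  occupied <- sum(y > 0)
  if (occupied < 3L * n_components)
    stop("degenerate histogram: ", occupied, " occupied bin(s), need at least ",
         3L * n_components, call. = FALSE)

  if (n_components == 1L) {
    start <- list(a1 = max(y), m1 = mean(values), s1 = stats::sd(values))
    rng <- range(x)
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)),
      start = start,
      lower = c(a1 = 0, m1 = rng[1], s1 = bin_width / 10),
      upper = c(a1 = 2 * n, m1 = rng[2], s1 = diff(rng) + bin_width),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    cf <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    means <- unname(cf["m1"]); sds <- unname(abs(cf["s1"]))
    amps <- unname(cf["a1"]); sems <- unname(se["m1"])
  } else {
    km <- stats::kmeans(values, centers = stats::quantile(values, c(0.25, 0.75)),
                        iter.max = 50L)
    grp <- order(km$centers)          # slow group first
    g1 <- values[km$cluster == grp[1]]; g2 <- values[km$cluster == grp[2]]
    s1 <- max(stats::sd(g1), bin_width / 2); s2 <- max(stats::sd(g2), bin_width / 2)
    start <- list(a1 = length(g1) * bin_width / (s1 * sqrt(2 * pi)),
                  m1 = mean(g1), s1 = s1,
                  a2 = length(g2) * bin_width / (s2 * sqrt(2 * pi)),
                  m2 = mean(g2), s2 = s2)
    rng <- range(x)
    fit <- minpack.lm::nlsLM(
      y ~ a1 * exp(-(x - m1)^2 / (2 * s1^2)) +
        a2 * exp(-(x - m2)^2 / (2 * s2^2)),
      start = start,
      lower = c(a1 = 0, m1 = rng[1], s1 = bin_width / 10,
                a2 = 0, m2 = rng[1], s2 = bin_width / 10),
      upper = c(a1 = 2 * n, m1 = rng[2], s1 = diff(rng) + bin_width,
                a2 = 2 * n, m2 = rng[2], s2 = diff(rng) + bin_width),
      control = minpack.lm::nls.lm.control(maxiter = 400))
    cf <- stats::coef(fit)
    se <- summary(fit)$coefficients[, "Std. Error"]
    ord <- order(c(cf["m1"], cf["m2"]))
    means <- unname(c(cf["m1"], cf["m2"])[ord])
    sds <- unname(abs(c(cf["s1"], cf["s2"]))[ord])
    amps <- unname(c(cf["a1"], cf["a2"])[ord])
    sems <- unname(c(se["m1"], se["m2"])[ord])
  }
  res <- stats::resid(fit)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  structure(list(n_components = n_components, means = means, sds = sds,
                 amplitudes = amps, sem_of_means = sems, r_squared = r2,
                 n = n, bin_width = bin_width),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> %d component(s), n = %d, r^2 = %.3f\n",
              x$n_components, x$n, x$r_squared))
  for (i in seq_len(x$n_components))
    cat(sprintf("  mean %.1f +/- %.1f nm/s (s.d. %.1f)\n",
                x$means[i], x$sem_of_means[i], x$sds[i]))
  invisible(x)
}

#' Exponential fit to a survival (1 - cumulative frequency) curve
#'
#' Computes the empirical survival function `S(x) = 1 - ecdf(x)` at the
#' sorted unique values and least-squares fits `A * exp(-x / tau)` with the
#' amplitude free. The decay constant `tau` is the reported run length or
#' residency time. A free amplitude absorbs left truncation by the
#' minimum-event-length filter (for an exponential, truncation rescales the
#' survival curve without changing its decay).
#'
#' @param values Positive numeric vector (nm or s), n >= 20.
#' @param ci One of `"bootstrap"` (percentile bootstrap of the refitted decay
#'   constant; the default), `"asymptotic"` (normal interval from the fit
#'   covariance) or `"none"`.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @return An object of class `survival_fit`: `decay_constant`, `amplitude`,
#'   `ci95` (low, high), `r_squared`, `n`.
#' @export
survival_exponential_fit <- function(values, ci = c("bootstrap", "asymptotic", "none"),
                                     n_boot = 1000L, seed = 1L) {
  ci <- match.arg(ci)
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 20L) stop("need at least 20 values", call. = FALSE)
  if (any(values <= 0)) stop("values must be positive", call. = FALSE)

  fit_tau <- function(v) {
    x <- sort(unique(v))
    S <- 1 - stats::ecdf(v)(x)
    fit <- minpack.lm::nlsLM(S ~ A * exp(-x / tau),
                             start = list(A = 1, tau = mean(v)),
                             lower = c(A = 0, tau = .Machine$double.eps),
                             control = minpack.lm::nls.lm.control(maxiter = 200))
    list(fit = fit, x = x, S = S)
  }
  f <- fit_tau(values)
  cf <- stats::coef(f$fit)
  tau <- unname(cf["tau"]); A <- unname(cf["A"])
  res <- stats::resid(f$fit)
  r2 <- 1 - sum(res^2) / sum((f$S - mean(f$S))^2)

  ci95 <- switch(ci,
    none = c(NA_real_, NA_real_),
    asymptotic = {
      se <- summary(f$fit)$coefficients["tau", "Std. Error"]
      tau + c(-1.96, 1.96) * se
    },
    bootstrap = bootstrap_ci95(values,
                               function(v) unname(stats::coef(fit_tau(v)$fit)["tau"]),
                               n_boot = n_boot, seed = seed))
  structure(list(decay_constant = tau, amplitude = A, ci95 = unname(ci95),
                 r_squared = r2, n = n, ci_method = ci),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  cat(sprintf("<survival_fit> decay constant %.2f (CI95 [%.2f, %.2f], %s), n = %d, r^2 = %.3f\n",
              x$decay_constant, x$ci95[1], x$ci95[2], x$ci_method, x$n, x$r_squared))
  invisible(x)
}

#' Percentile bootstrap 95% confidence interval
#'
#' Resamples `values` with replacement `n_boot` times, applies `estimator`
#' and returns the 2.5 and 97.5 percentiles. Deterministic given the seed.
#' Errors if the estimator fails on more than 5% of resamples.
#'
#' @param values Numeric vector.
#' @param estimator Function mapping a numeric vector to a scalar.
#' @param n_boot Number of resamples (>= 200; default 1000).
#' @param seed Integer seed.
#' @return Numeric `(low, high)`.
#' @export
bootstrap_ci95 <- function(values, estimator, n_boot = 1000L, seed = 1L) {
  if (n_boot < 200L) stop("n_boot must be >= 200", call. = FALSE)
  set.seed(seed)
  n <- length(values)
  est <- vapply(seq_len(n_boot), function(b) {
    v <- values[sample.int(n, n, replace = TRUE)]
    tryCatch(estimator(v), error = function(e) NA_real_)
  }, numeric(1))
  fail <- mean(is.na(est))
  if (fail > 0.05)
    stop(sprintf("estimator failed on %.1f%% of bootstrap resamples", 100 * fail),
         call. = FALSE)
  unname(stats::quantile(est, c(0.025, 0.975), na.rm = TRUE))
}
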