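## Per-construct analysis report: filter -> classify -> fits -> rates,
## serialised losslessly to JSON.

fit_or_unavailable <- function(expr, what) {
  tryCatch(expr, error = function(e)
    structure(list(available = FALSE, what = what, reason = conditionMessage(e)),
              class = "unavailable_fit"))
}

is_available <- function(x) !inherits(x, "unavailable_fit")

#' Run the full statistical analysis on an events table
#'
#' Applies the minimum-event-length filter, computes the motile fraction,
#' fits the velocity histogram (1 or 2 Gaussians) and the run-length and
#' residency survival curves on motile events, and, when a field and
#' observation time are supplied, the total and processive landing rates.
#' Fits that cannot be computed (too few events) are reported as unavailable
#' with the reason, not dropped.
#'
#' @param events A `RunEvent` data frame (unfiltered).
#' @param construct Construct label echoed in the report.
#' @param n_velocity_components 1 or 2.
#' @param bin_width Velocity histogram bin width (nm/s).
#' @param min_frames Event-length filter threshold (frames).
#' @param field Optional `mt_field` for landing rates.
#' @param duration_min Optional observation time in minutes.
#' @param bleach Optional photobleach summary (from [bleach_summary()]).
#' @param seed Seed echoed in the report and used for bootstrap CIs.
#' @param config Optional config list echoed in the report.
#' @return An object of class `analysis_report`.
#' @export
analyze_events <- function(events, construct = "", n_velocity_components = 1L,
                           bin_width = 20, min_frames = 5L,
                           field = NULL, duration_min = NULL,
                           bleach = NULL, seed = 1L, config = NULL) {
  filtered <- filter_events(events, min_frames = min_frames)
  motile <- filtered[which(filtered$motile), , drop = FALSE]
  mf <- fit_or_unavailable(motile_fraction(filtered), "motile_fraction")
  vf <- fit_or_unavailable(
    histogram_gaussian_fit(motile$velocity, n_velocity_components, bin_width),
    "velocity_fit")
  rl <- fit_or_unavailable(
    survival_exponential_fit(motile$run_length, ci = "bootstrap", seed = seed),
    "run_length_fit")
  rt <- fit_or_unavailable(
    survival_exponential_fit(motile$residency, ci = "bootstrap", seed = seed + 1L),
    "residency_fit")
  lr_tot <- lr_proc <- NULL
  if (!is.null(field) && !is.null(duration_min)) {
    lr_tot <- fit_or_unavailable(
      landing_rate(filtered, field, duration_min, processive_only = FALSE),
      "landing_rate_total")
    lr_proc <- fit_or_unavailable(
      landing_rate(filtered, field, duration_min, processive_only = TRUE),
      "landing_rate_processive")
  }
  structure(list(construct = construct,
                 n_events = nrow(events),
                 n_filtered = nrow(filtered),
                 n_removed = attr(filtered, "n_removed"),
                 n_motile = nrow(motile),
                 motile_fraction = mf,
                 velocity_fit = vf,
                 run_length_fit = rl,
                 residency_fit = rt,
                 landing_rate_total = lr_tot,
                 landing_rate_processive = lr_proc,
                 photobleach = bleach_report_part(bleach),
                 config = config,
                 seed = seed),
            class = "analysis_report")
}

bleach_report_part <- function(bleach) {
  if (is.null(bleach)) return(NULL)
  list(n_traces = nrow(bleach$summary),
       n_excluded = sum(bleach$summary$excluded),
       step_histogram = as.list(bleach$step_histogram),
       initial_intensity_median = stats::median(bleach$summary$initial_intensity))
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> %s: %d events (%d pass filter, %d motile)\n",
              x$construct, x$n_events, x$n_filtered, x$n_motile))
  for (nm in c("motile_fraction", "velocity_fit", "run_length_fit",
               "residency_fit", "landing_rate_total", "landing_rate_processive")) {
    part <- x[[nm]]
    if (is.null(part)) next
    if (!is_available(part)) {
      cat(sprintf("  %s: unavailable (%s)\n", nm, part$reason))
    } else {
      cat("  "); print(part)
    }
  }
  invisible(x)
}

report_to_list <- function(x) {
  strip <- function(part) {
    if (is.null(part)) return(NULL)
    if (!is_available(part)) return(list(available = FALSE, reason = part$reason))
    c(list(available = TRUE), unclass(part))
  }
  list(construct = x$construct, n_events = x$n_events,
       n_filtered = x$n_filtered, n_removed = x$n_removed,
       n_motile = x$n_motile,
       motile_fraction = strip(x$motile_fraction),
       velocity_fit = strip(x$velocity_fit),
       run_length_fit = strip(x$run_length_fit),
       residency_fit = strip(x$residency_fit),
       landing_rate_total = strip(x$landing_rate_total),
       landing_rate_processive = strip(x$landing_rate_processive),
       photobleach = x$photobleach,
       seed = x$seed)
}

#' Write / read an analysis report as JSON
#'
#' Numbers are written at full precision so reports round-trip losslessly.
#'
#' @param report An `analysis_report`.
#' @param path JSON path.
#' @return `path` invisibly; `read_report()` returns the report as a list.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report_to_list(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write / read a ground-truth frame table as CSV
#'
#' @param truth Frame table from [truth_table()].
#' @param path CSV path.
#' @export
write_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("motor_id", "mt_id", "frame", "t", "position_nm", "state",
            "n_unbleached")
  missing <- setdiff(need, names(tr))
  if (length(missing))
    stop("truth CSV is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  tr
}
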