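## Photobleaching analysis: ROI/background intensity extraction from movies,
## initial intensity, aggregate exclusion, automated step counting by
## penalised change-point segmentation.

new_intensity_trace <- function(roi_mean, background_mean, frame_interval,
                                source_point = NULL, truth = NULL) {
  corrected <- roi_mean - background_mean
  structure(list(roi_mean = roi_mean,
                 background_mean = background_mean,
                 corrected = corrected,
                 initial_intensity = mean(corrected[seq_len(min(5L, length(corrected)))]),
                 frame_interval = frame_interval,
                 source_point = source_point,
                 truth = truth),
            class = "intensity_trace")
}

#' @export
print.intensity_trace <- function(x, ...) {
  cat(sprintf("<intensity_trace> %d frames, initial intensity %.1f counts\n",
              length(x$corrected), x$initial_intensity))
  invisible(x)
}

#' Extract a background-corrected ROI intensity trace from a movie
#'
#' Per frame, the ROI signal is the mean of a 4x4 pixel block around the
#' picked point and the local background is the mean of the surrounding
#' 10x10 block with the 4x4 core excluded (84 pixels); the corrected trace is
#' their difference. Block anchoring: the picked point is the
#' upper-left-of-centre pixel, i.e. the 4x4 block covers rows/columns
#' `p - 1 .. p + 2` and the 10x10 block `p - 4 .. p + 5`.
#'
#' @param movie A `movie` object.
#' @param point Integer `(row, col)` of the picked spot, at least 5 px from
#'   every image edge.
#' @return An `intensity_trace`.
#' @export
extract_trace <- function(movie, point) {
  d <- dim(movie$data)
  r <- as.integer(point[1]); c <- as.integer(point[2])
  if (r - 4L < 1L || c - 4L < 1L || r + 5L > d[1] || c + 5L > d[2])
    stop(sprintf("point (%d, %d) is closer than 5 px to an image edge (%d x %d)",
                 r, c, d[1], d[2]), call. = FALSE)
  roi_rows <- (r - 1L):(r + 2L); roi_cols <- (c - 1L):(c + 2L)
  bg_rows <- (r - 4L):(r + 5L); bg_cols <- (c - 4L):(c + 5L)
  nf <- d[3]
  roi <- numeric(nf); bg <- numeric(nf)
  for (f in seq_len(nf)) {
    img <- movie$data[, , f]
    core <- img[roi_rows, roi_cols]
    block <- img[bg_rows, bg_cols]
    roi[f] <- mean(core)
    bg[f] <- (sum(block) - sum(core)) / (length(block) - length(core))
  }
  new_intensity_trace(roi, bg, movie$optics$frame_interval,
                      source_point = c(row = r, col = c))
}

#' Initial intensity of a trace
#'
#' Mean of the background-corrected intensity over the first five frames of
#' imaging — the single-spot brightness measure used to compare constructs
#' and to flag aggregates.
#'
#' @param trace An `intensity_trace` with at least 5 frames.
#' @return Counts (scalar).
#' @export
initial_intensity <- function(trace) {
  if (length(trace$corrected) < 5L)
    stop("trace has fewer than 5 frames", call. = FALSE)
  mean(trace$corrected[1:5])
}

#' Exclude aggregates by initial intensity
#'
#' Traces whose initial intensity exceeds `median + threshold_multiplier *
#' MAD` of the population are treated as aggregates (multiple motors stuck
#' together) and excluded.
#'
#' @param traces List of `intensity_trace` objects (>= 5).
#' @param threshold_multiplier MAD multiplier (default 5).
#' @return List with elements `kept` and `excluded` (lists of traces), plus
#'   `threshold` (counts) and `initial_intensities`.
#' @export
exclude_aggregates <- function(traces, threshold_multiplier = 5) {
  if (length(traces) < 5L) stop("need at least 5 traces", call. = FALSE)
  ii <- vapply(traces, initial_intensity, numeric(1))
  thr <- stats::median(ii) + threshold_multiplier * stats::mad(ii)
  out <- ii > thr
  list(kept = traces[!out], excluded = traces[out], threshold = thr,
       initial_intensities = ii, excluded_flag = out)
}

## segment cost: within-segment sum of squared deviations, O(1) via cumsums
seg_sse <- function(cs, cs2, i, j) {
  s <- cs[j + 1L] - cs[i]
  s2 <- cs2[j + 1L] - cs2[i]
  len <- j - i + 1L
  max(s2 - s^2 / len, 0)
}

best_split <- function(cs, cs2, i, j) {
  if (j <= i) return(list(gain = -Inf, at = NA_integer_))
  whole <- seg_sse(cs, cs2, i, j)
  cuts <- i:(j - 1L)
  sse <- vapply(cuts, function(t)
    seg_sse(cs, cs2, i, t) + seg_sse(cs, cs2, t + 1L, j), numeric(1))
  k <- which.min(sse)
  list(gain = whole - sse[k], at = cuts[k], sse = sse[k])
}

#' Count photobleaching steps by penalised change-point segmentation
#'
#' Greedy binary segmentation of the corrected trace: at each iteration the
#' split yielding the largest reduction in within-segment squared error is
#' added, while the Schwarz (BIC) criterion
#' `n * log(SSE / n) + 2 * k * log(n)` keeps improving, up to `max_steps`
#' change points. Steps are the downward level transitions of at least
#' `min_step` counts; by default `min_step` is half the robust unit-step
#' estimate (the median of the detected level drops), which is scale-free
#' across laser settings.
#'
#' @param trace An `intensity_trace` (>= 10 frames) or numeric vector.
#' @param min_step Minimum counted downward step in counts, or `NULL` for
#'   the robust default.
#' @param max_steps Maximum number of change points (default 8).
#' @return An object of class `step_count_result`: `n_steps`,
#'   `change_points` (index of the first frame of each new segment),
#'   `level_means`, `penalty_used`, `min_step_used`.
#' @export
count_steps <- function(trace, min_step = NULL, max_steps = 8L) {
  y <- if (inherits(trace, "intensity_trace")) trace$corrected else as.numeric(trace)
  n <- length(y)
  if (n < 10L) stop("need at least 10 frames", call. = FALSE)
  if (!all(is.finite(y))) stop("trace contains non-finite values", call. = FALSE)
  if (!is.null(min_step) && min_step <= 0) stop("min_step must be > 0", call. = FALSE)
  cs <- c(0, cumsum(y)); cs2 <- c(0, cumsum(y^2))
  eps <- max(1e-12, 1e-12 * stats::var(y) * n)
  bounds <- c(0L, n)                 # segment boundaries (end indices)
  sse_tot <- seg_sse(cs, cs2, 1L, n)
  penalty <- 2 * log(n)
  cost <- n * log(max(sse_tot, eps) / n)
  repeat {
    if (length(bounds) - 2L >= max_steps) break
    # best split across all current segments
    best <- list(gain = -Inf)
    for (s in seq_len(length(bounds) - 1L)) {
      i <- bounds[s] + 1L; j <- bounds[s + 1L]
      cand <- best_split(cs, cs2, i, j)
      if (cand$gain > best$gain) best <- cand
    }
    if (!is.finite(best$gain) || is.na(best$at)) break
    sse_new <- max(sse_tot - best$gain, 0)
    cost_new <- n * log(max(sse_new, eps) / n) +
      (length(bounds) - 1L) * penalty
    if (cost_new >= cost - 1e-12 && sse_new > eps) break
    if (cost_new >= cost - 1e-12 && sse_new <= eps && best$gain <= eps) break
    bounds <- sort(c(bounds, best$at))
    sse_tot <- sse_new
    cost <- cost_new
  }
  segs <- cbind(bounds[-length(bounds)] + 1L, bounds[-1L])
  levels <- apply(segs, 1L, function(ij) mean(y[ij[1]:ij[2]]))
  drops <- -diff(levels)
  down <- drops[drops > 0]
  ms <- min_step %||% if (length(down)) 0.5 * stats::median(down) else Inf
  n_steps <- sum(drops >= ms & drops > 0)
  structure(list(n_steps = as.integer(n_steps),
                 change_points = as.integer(segs[-1L, 1L]),
                 level_means = as.numeric(levels),
                 penalty_used = penalty,
                 min_step_used = ms),
            class = "step_count_result")
}

#' @export
print.step_count_result <- function(x, ...) {
  cat(sprintf("<step_count> %d step(s), %d change point(s), levels: %s\n",
              x$n_steps, length(x$change_points),
              paste(sprintf("%.1f", x$level_means), collapse = " -> ")))
  invisible(x)
}

#' Summarise photobleaching over a set of picked points
#'
#' Runs [extract_trace()], [initial_intensity()], optional
#' [exclude_aggregates()] and [count_steps()] over all picked spots of a
#' movie.
#'
#' @param movie A `movie`.
#' @param points Data frame or matrix with columns `row`, `col`.
#' @param exclude Apply aggregate exclusion (default TRUE).
#' @param threshold_multiplier Passed to [exclude_aggregates()].
#' @param ... Passed to [count_steps()].
#' @return List with `traces`, `summary` (data frame: trace id, initial
#'   intensity, n_steps, excluded flag) and `step_histogram` (table over
#'   non-excluded traces).
#' @export
bleach_summary <- function(movie, points, exclude = TRUE,
                           threshold_multiplier = 5, ...) {
  points <- as.data.frame(points)
  traces <- lapply(seq_len(nrow(points)), function(i)
    extract_trace(movie, c(points$row[i], points$col[i])))
  excluded <- rep(FALSE, length(traces))
  if (exclude && length(traces) >= 5L)
    excluded <- exclude_aggregates(traces, threshold_multiplier)$excluded_flag
  steps <- vapply(traces, function(tr) count_steps(tr, ...)$n_steps, integer(1))
  summary <- data.frame(trace_id = seq_along(traces),
                        row = points$row, col = points$col,
                        initial_intensity = vapply(traces, initial_intensity, numeric(1)),
                        n_steps = steps, excluded = excluded)
  list(traces = traces, summary = summary,
       step_histogram = table(steps[!excluded]))
}
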