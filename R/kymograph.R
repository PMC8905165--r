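## Kymograph construction and motility event extraction.
##
## Event measurement definitions: run length is the net (start-to-end)
## displacement; residency is the time between the first and last frame of
## the track; velocity is run length / residency, i.e. an average over the
## whole run *including pauses*.

new_kymograph <- function(intensity, pixel_size, frame_interval, mt_length,
                          mt_id = NA_integer_) {
  structure(list(intensity = intensity, pixel_size = pixel_size,
                 frame_interval = frame_interval, mt_length = mt_length,
                 mt_id = mt_id),
            class = "kymograph")
}

#' @export
print.kymograph <- function(x, ...) {
  cat(sprintf("<kymograph> mt %s: %d px x %d frames (%.0f nm/px, %.2f s)\n",
              x$mt_id, nrow(x$intensity), ncol(x$intensity),
              x$pixel_size, x$frame_interval))
  invisible(x)
}

bilinear <- function(img, x, y) {
  ny <- nrow(img); nx <- ncol(img)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- pmin(floor(x), nx - 1L); y0 <- pmin(floor(y), ny - 1L)
  fx <- x - x0; fy <- y - y0
  img[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    img[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    img[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    img[cbind(y0 + 1, x0 + 1)] * fx * fy
}

#' Build a kymograph along a microtubule segment
#'
#' For each frame, intensity is sampled (bilinear interpolation) at 1-px
#' steps along the minus-to-plus line of the segment, taking the maximum over
#' a perpendicular band. Row 1 is the minus end; one column per frame.
#'
#' @param movie A `movie` object.
#' @param field An `mt_field`.
#' @param mt_id Which microtubule to read out.
#' @param band_width Perpendicular band in px (odd; default 3).
#' @return A `kymograph` object.
#' @export
build_kymograph <- function(movie, field, mt_id, band_width = 3L) {
  if (band_width %% 2L != 1L) stop("band_width must be odd", call. = FALSE)
  seg <- field[field$mt_id == mt_id, , drop = FALSE]
  if (nrow(seg) != 1L) stop("unknown mt_id: ", mt_id, call. = FALSE)
  px <- movie$optics$pixel_size
  len_px <- seg$length_um * 1000 / px
  if (len_px < 1) stop("zero-length segment", call. = FALSE)
  n_pos <- as.integer(floor(len_px)) + 1L
  s <- seq_len(n_pos) - 1L
  p0 <- mt_point(field, mt_id, 0)
  p1 <- mt_point(field, mt_id, seg$length_um * 1000)
  ux <- (p1$x - p0$x) / len_px; uy <- (p1$y - p0$y) / len_px
  # unit normal
  nxv <- -uy; nyv <- ux
  offs <- seq_len(band_width) - (band_width + 1L) / 2
  nf <- dim(movie$data)[3]
  out <- matrix(0, nrow = n_pos, ncol = nf)
  for (f in seq_len(nf)) {
    img <- movie$data[, , f]
    acc <- rep(-Inf, n_pos)
    for (o in offs) {
      xs <- p0$x + ux * s + nxv * o
      ys <- p0$y + uy * s + nyv * o
      acc <- pmax(acc, bilinear(img, xs, ys))
    }
    out[, f] <- acc
  }
  new_kymograph(out, pixel_size = px,
                frame_interval = movie$optics$frame_interval,
                mt_length = seg$length_um, mt_id = mt_id)
}

## spot detection within one kymograph column: contiguous runs above the
## threshold become one spot each, located at their intensity-weighted centroid
detect_spots_column <- function(col, threshold, floor_level) {
  above <- col > threshold
  if (!any(above)) return(numeric(0))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  vapply(keep, function(k) {
    idx <- starts[k]:ends[k]
    w <- pmax(col[idx] - floor_level, .Machine$double.eps)
    sum(idx * w) / sum(w)
  }, numeric(1))
}

#' Extract motility events from a kymograph
#'
#' Spots are detected per time column as contiguous runs above
#' `median + k * MAD` of the whole kymograph, then linked frame-to-frame by
#' nearest neighbour within `max_jump` pixels, closing gaps of up to
#' `max_gap` frames. Each track becomes one `RunEvent` row with the standard
#' measurement definitions; `motile` is set by [classify_motile()].
#'
#' @param kymograph A `kymograph`.
#' @param k MAD multiplier for the detection threshold (default 5).
#' @param max_jump Maximum linking distance per frame, px (default 4).
#' @param max_gap Maximum number of missed frames bridged (default 1).
#' @param min_net_displacement,min_consistency Passed to [classify_motile()].
#' @return A `RunEvent` data frame (possibly 0 rows): `motor_id`, `mt_id`,
#'   `t_start`, `t_end`, `n_frames`, `x_start`, `x_end`, `net_displacement`,
#'   `run_length`, `residency`, `velocity`, `frac_consistent`, `motile`.
#' @export
extract_events <- function(kymograph, k = 5, max_jump = 4, max_gap = 1L,
                           min_net_displacement = 320, min_consistency = 0.8) {
  img <- kymograph$intensity
  if (!all(is.finite(img))) stop("kymograph contains non-finite values", call. = FALSE)
  med <- stats::median(img)
  madv <- stats::mad(img)
  thr <- med + k * max(madv, .Machine$double.eps)
  nf <- ncol(img)
  tracks <- list()      # finished
  active <- list()      # each: list(pos = vec, frames = vec, last_seen)
  for (f in seq_len(nf)) {
    spots <- detect_spots_column(img[, f], thr, med)
    # retire stale tracks
    if (length(active)) {
      stale <- vapply(active, function(a) f - a$last_seen > max_gap + 1L, logical(1))
      tracks <- c(tracks, active[stale])
      active <- active[!stale]
    }
    if (length(spots)) {
      taken <- rep(FALSE, length(spots))
      if (length(active)) {
        # constant-velocity prediction keeps identities through crossings
        pred <- vapply(active, function(a) {
          np <- length(a$pos)
          v <- if (np >= 2L)
            (a$pos[np] - a$pos[np - 1L]) / (a$frames[np] - a$frames[np - 1L])
          else 0
          a$pos[np] + v * (f - a$last_seen)
        }, numeric(1))
        # greedy global assignment: closest (track, spot) pairs first
        d <- abs(outer(pred, spots, "-"))
        gapf <- vapply(active, function(a) f - a$last_seen, numeric(1))
        d[d > max_jump * gapf] <- Inf
        while (any(is.finite(d))) {
          k <- arrayInd(which.min(d), dim(d))
          ai <- k[1]; j <- k[2]
          active[[ai]]$pos <- c(active[[ai]]$pos, spots[j])
          active[[ai]]$frames <- c(active[[ai]]$frames, f)
          active[[ai]]$last_seen <- f
          taken[j] <- TRUE
          d[ai, ] <- Inf; d[, j] <- Inf
        }
      }
      for (j in which(!taken))
        active[[length(active) + 1L]] <- list(pos = spots[j], frames = f,
                                              last_seen = f)
    }
  }
  tracks <- c(tracks, active)
  if (!length(tracks)) return(empty_events())
  px <- kymograph$pixel_size; dt <- kymograph$frame_interval
  ev <- do.call(rbind, lapply(seq_along(tracks), function(i) {
    tr <- tracks[[i]]
    x <- (tr$pos - 1) * px
    dpx <- diff(x)
    net <- x[length(x)] - x[1]
    span <- tr$frames[length(tr$frames)] - tr$frames[1]
    cons <- if (length(dpx)) mean(dpx == 0 | sign(dpx) == sign(net)) else 1
    data.frame(motor_id = i, mt_id = kymograph$mt_id,
               t_start = (tr$frames[1] - 1) * dt,
               t_end = (tr$frames[length(tr$frames)] - 1) * dt,
               n_frames = span + 1L,
               x_start = x[1], x_end = x[length(x)],
               net_displacement = net, run_length = abs(net),
               residency = span * dt,
               velocity = if (span > 0) abs(net) / (span * dt) else NA_real_,
               frac_consistent = cons, stringsAsFactors = FALSE)
  }))
  ev$motile <- classify_motile(ev, min_net_displacement, min_consistency)
  class(ev) <- c("run_events", "data.frame")
  ev
}

empty_events <- function() {
  ev <- data.frame(motor_id = integer(), mt_id = integer(),
                   t_start = numeric(), t_end = numeric(),
                   n_frames = integer(), x_start = numeric(),
                   x_end = numeric(), net_displacement = numeric(),
                   run_length = numeric(), residency = numeric(),
                   velocity = numeric(), frac_consistent = numeric(),
                   motile = logical(), stringsAsFactors = FALSE)
  class(ev) <- c("run_events", "data.frame")
  ev
}

#' Measure events directly from a ground-truth frame table
#'
#' Bypasses imaging and tracking: each motor in the truth table becomes one
#' `RunEvent`, measured from its recorded frames with exactly the same
#' definitions as [extract_events()] (net displacement, first-to-last-frame
#' residency, pause-inclusive velocity). Lets estimators be validated
#' independently of tracking quality.
#'
#' @param truth Frame table from [truth_table()] (or the truth CSV): columns
#'   `motor_id`, `mt_id`, `frame`, `t`, `position_nm`, `state`, `n_unbleached`.
#' @param min_net_displacement,min_consistency Passed to [classify_motile()].
#' @return A `RunEvent` data frame, one row per motor.
#' @export
events_from_truth <- function(truth, min_net_displacement = 320,
                              min_consistency = 0.8) {
  need <- c("motor_id", "mt_id", "frame", "t", "position_nm")
  missing <- setdiff(need, names(truth))
  if (length(missing))
    stop("truth table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (nrow(truth) == 0L) return(empty_events())
  ord <- order(truth$motor_id, truth$frame)
  tr <- truth[ord, ]
  id <- tr$motor_id
  first <- !duplicated(id)
  i0 <- which(first)
  i1 <- c(i0[-1] - 1L, nrow(tr))
  nfr <- i1 - i0 + 1L
  net <- tr$position_nm[i1] - tr$position_nm[i0]
  residency <- tr$t[i1] - tr$t[i0]
  # frame-to-frame direction consistency per motor
  n <- nrow(tr)
  frac <- rep(1, length(i0))
  if (n > 1L) {
    dp <- tr$position_nm[-1] - tr$position_nm[-n]
    same <- id[-1] == id[-n]
    net_row <- rep(net, nfr)
    cons <- (dp == 0) | (sign(dp) == sign(net_row[-1]))
    if (any(same)) {
      g <- match(id[-1][same], id[i0])
      num <- rowsum(as.numeric(cons[same]), g)
      den <- rowsum(rep(1, sum(same)), g)
      frac[as.integer(rownames(num))] <- num / den
    }
  }
  ev <- data.frame(
    motor_id = id[i0], mt_id = tr$mt_id[i0],
    t_start = tr$t[i0], t_end = tr$t[i1],
    n_frames = nfr,
    x_start = tr$position_nm[i0], x_end = tr$position_nm[i1],
    net_displacement = net, run_length = abs(net),
    residency = residency,
    velocity = ifelse(residency > 0, abs(net) / residency, NA_real_),
    frac_consistent = frac, stringsAsFactors = FALSE)
  ev$motile <- classify_motile(ev, min_net_displacement, min_consistency)
  class(ev) <- c("run_events", "data.frame")
  ev
}

#' Apply the minimum-event-length filter
#'
#' Landing events spanning fewer than `min_frames` frames are excluded from
#' analysis (short detections cannot be measured reliably). The number of
#' removed events is attached as attribute `n_removed`.
#'
#' @param events A `RunEvent` data frame.
#' @param min_frames Minimum frame span (default 5).
#' @param verbose Report the removed count.
#' @return The retained events.
#' @export
filter_events <- function(events, min_frames = 5L, verbose = FALSE) {
  keep <- events$n_frames >= min_frames
  out <- events[keep, , drop = FALSE]
  attr(out, "n_removed") <- sum(!keep)
  if (verbose)
    message(sum(!keep), " event(s) shorter than ", min_frames, " frames removed")
  class(out) <- c("run_events", "data.frame")
  out
}

#' Classify events as motile or static
#'
#' An event is motile if its net displacement is at least
#' `min_net_displacement` (default 2 pixels = 320 nm, below which a
#' kymograph line cannot be called moving) *and* its motion is directionally
#' consistent: at least `min_consistency` of frame-to-frame displacements
#' share the sign of the net displacement or are zero.
#'
#' @param events A `RunEvent` data frame (needs `run_length` and
#'   `frac_consistent`).
#' @param min_net_displacement nm (default 320).
#' @param min_consistency Fraction in `[0, 1]` (default 0.8).
#' @return Logical vector, one element per event.
#' @export
classify_motile <- function(events, min_net_displacement = 320,
                            min_consistency = 0.8) {
  fc <- events$frac_consistent %||% rep(1, nrow(events))
  events$run_length >= min_net_displacement & fc >= min_consistency
}

#' Measure gliding velocities from kymographs of translocating microtubules
#'
#' For each kymograph the leading end of the microtubule (largest position
#' above the half-maximum threshold) is located in the first and last frame;
#' the speed is its displacement divided by the elapsed time.
#'
#' @param kymographs A list of `kymograph` objects (or the list returned by
#'   [sample_gliding_kymographs()]).
#' @return Numeric vector of speeds (nm/s, magnitudes).
#' @export
gliding_velocities <- function(kymographs) {
  if (!is.null(kymographs$kymographs)) kymographs <- kymographs$kymographs
  vapply(kymographs, function(ky) {
    img <- ky$intensity
    # background level from per-column minima (robust even when the
    # microtubule covers most of the position axis)
    bg <- stats::median(apply(img, 2, min))
    amp <- max(img) - bg
    thr <- bg + amp / 2
    # sub-pixel leading edge: invert the fractional pixel coverage of the
    # last pixel above half-max (exact for a rigid bar profile)
    edge <- function(col) {
      w <- which(col > thr)
      if (!length(w)) return(NA_real_)
      j <- max(w)
      (j - 0.5) + min((col[j] - bg) / max(amp, .Machine$double.eps), 1)
    }
    e0 <- edge(img[, 1]); e1 <- edge(img[, ncol(img)])
    if (is.na(e0) || is.na(e1)) return(NA_real_)
    abs(e1 - e0) * ky$pixel_size / ((ncol(img) - 1) * ky$frame_interval)
  }, numeric(1))
}

#' Write / read an events table as CSV
#'
#' @param events A `RunEvent` data frame.
#' @param path CSV path.
#' @return `path` invisibly; for `read_events()`, the events data frame.
#' @export
write_events <- function(events, path) {
  utils::write.csv(as.data.frame(events), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(ev) <- c("run_events", "data.frame")
  ev
}
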