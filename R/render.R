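## Rendering of simulated TIRF movies: Gaussian PSF spots on a constant
## background, Poisson shot noise plus Gaussian read noise, 16-bit output.

#' Render a simulated TIRF movie
#'
#' Each motor with at least one unbleached fluorophore contributes, in every
#' frame it is attached, a 2-D Gaussian spot whose *integrated* intensity is
#' `photons_per_fluorophore_per_frame * n_unbleached` (the discrete kernel is
#' normalised to sum to exactly that, so photometry is exact with noise
#' disabled). Pixel values are `Poisson(signal + background) +
#' N(0, read_noise_sd)`, clipped at zero and quantised to 16 bits.
#'
#' @param field An `mt_field` (used to map lattice positions to pixels).
#' @param trajectories List of [sample_trajectory()] objects.
#' @param optics An [optics_model()].
#' @param seed Integer seed for the noise draws.
#' @param noise If `FALSE`, return the noiseless expectation
#'   (`signal + background`, unquantised) — used by photometry checks.
#' @return An object of class `movie`: list with `data` (array
#'   `rows x cols x frames`) and `optics`.
#' @export
render_movie <- function(field, trajectories, optics, seed = 1L, noise = TRUE) {
  ny <- optics$image_shape[1]; nx <- optics$image_shape[2]
  nf <- n_frames(optics)
  sig <- array(0, dim = c(ny, nx, nf))
  s_px <- optics$psf_sigma / optics$pixel_size
  r <- as.integer(ceiling(4 * s_px))
  for (tr in trajectories) {
    fr <- tr$frames
    if (nrow(fr) == 0L) next
    keep <- fr$n_unbleached >= 1L & fr$frame >= 0L & fr$frame < nf
    if (!any(keep)) next
    fr <- fr[keep, , drop = FALSE]
    pt <- mt_point(field, tr$mt_id, fr$position_nm)
    if (any(pt$x < 1 | pt$x > nx | pt$y < 1 | pt$y > ny))
      stop(sprintf("trajectory of motor %s leaves the image bounds", tr$motor_id),
           call. = FALSE)
    for (k in seq_len(nrow(fr))) {
      cx <- pt$x[k]; cy <- pt$y[k]
      ix <- max(1L, as.integer(round(cx)) - r):min(nx, as.integer(round(cx)) + r)
      iy <- max(1L, as.integer(round(cy)) - r):min(ny, as.integer(round(cy)) + r)
      kern <- outer(exp(-(iy - cy)^2 / (2 * s_px^2)),
                    exp(-(ix - cx)^2 / (2 * s_px^2)))
      kern <- kern / sum(kern) *
        optics$photons_per_fluorophore_per_frame * fr$n_unbleached[k]
      sig[iy, ix, fr$frame[k] + 1L] <- sig[iy, ix, fr$frame[k] + 1L] + kern
    }
  }
  lambda <- sig + optics$background_mean
  if (noise) {
    set.seed(seed)
    vals <- stats::rpois(length(lambda), lambda) +
      stats::rnorm(length(lambda), 0, optics$read_noise_sd)
    vals <- pmin(pmax(round(vals), 0), 65535)
    lambda <- array(vals, dim = dim(lambda))
  }
  structure(list(data = lambda, optics = optics), class = "movie")
}

#' @export
print.movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<movie> %d x %d px, %d frames (%.2f s interval, %.0f nm/px)\n",
              d[1], d[2], d[3], x$optics$frame_interval, x$optics$pixel_size))
  invisible(x)
}

#' Write / read a movie as multi-page 16-bit TIFF with a YAML sidecar
#'
#' One TIFF page per frame; pixel size and frame interval are recorded in
#' `<path>.yaml` so the movie round-trips through [read_movie()].
#'
#' @param movie A `movie` object.
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_movie <- function(movie, path) {
  d <- dim(movie$data)
  pages <- lapply(seq_len(d[3]), function(f)
    pmin(pmax(movie$data[, , f], 0), 65535) / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  o <- movie$optics
  yaml::write_yaml(list(pixel_size = o$pixel_size,
                        frame_interval = o$frame_interval,
                        exposure = o$exposure,
                        image_shape = as.integer(o$image_shape),
                        n_frames = d[3]),
                   paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname write_movie
#' @param optics Optional [optics_model()] overriding the sidecar metadata.
#' @export
read_movie <- function(path, optics = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  arr <- array(0, dim = c(dim(pages[[1]])[1:2], length(pages)))
  for (f in seq_along(pages)) {
    pg <- pages[[f]]
    if (length(dim(pg)) == 3L) pg <- pg[, , 1]
    arr[, , f] <- pg * 65535
  }
  if (is.null(optics)) {
    side <- paste0(path, ".yaml")
    meta <- if (file.exists(side)) yaml::read_yaml(side) else list()
    optics <- optics_model(
      pixel_size = meta$pixel_size %||% 160,
      frame_interval = meta$frame_interval %||% 0.12,
      exposure = meta$exposure %||% 0.1,
      duration = (meta$frame_interval %||% 0.12) * dim(arr)[3],
      image_shape = dim(arr)[1:2])
  }
  structure(list(data = arr, optics = optics), class = "movie")
}

#' Simulate a photobleaching intensity trace
#'
#' A surface-adsorbed motor's background-corrected intensity is a
#' piecewise-constant staircase `unit_intensity * n_unbleached(t)` with
#' Gaussian noise; fluorophores bleach as independent exponentials. The true
#' bleach times and visible step count are kept alongside for validation.
#'
#' @param model A [motor_model()] (uses `n_fluorophores`, `bleach_rate`).
#' @param unit_intensity Counts contributed by one unbleached fluorophore.
#' @param noise_sd Gaussian noise s.d. in counts.
#' @param n_frames Number of frames (>= 5).
#' @param seed Integer seed.
#' @param frame_interval Frame interval in s.
#' @param pre_bleach_prob Probability that a fluorophore is already dark at
#'   frame 1 (bleached during search/focus before acquisition).
#' @return An `intensity_trace` with a `truth` element
#'   (`bleach_times`, `n_steps`, `n_active0`).
#' @export
sample_bleach_trace <- function(model, unit_intensity = 200, noise_sd = 0,
                                n_frames = 100L, seed = 1L,
                                frame_interval = 0.12,
                                pre_bleach_prob = 0) {
  stopifnot(n_frames >= 5L)
  set.seed(seed)
  active <- stats::runif(model$n_fluorophores) >= pre_bleach_prob
  bleach <- if (model$bleach_rate > 0)
    stats::rexp(model$n_fluorophores) / model$bleach_rate
  else rep(Inf, model$n_fluorophores)
  bleach[!active] <- 0
  tt <- (seq_len(n_frames) - 1L) * frame_interval
  counts <- colSums(outer(bleach, tt, ">"))
  corrected <- unit_intensity * counts +
    if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
  new_intensity_trace(
    roi_mean = corrected, background_mean = rep(0, n_frames),
    frame_interval = frame_interval, source_point = NULL,
    truth = list(bleach_times = bleach,
                 n_active0 = sum(active),
                 n_steps = sum(bleach > 0 & bleach <= tt[n_frames])))
}

#' Simulate gliding-assay kymographs
#'
#' In a gliding assay surface-anchored motors translocate free microtubules;
#' each kymograph shows one rigid microtubule (a bright bar) translating at a
#' constant speed drawn from a Gaussian. Used to validate
#' [gliding_velocities()].
#'
#' @param n Number of microtubules.
#' @param speed_mean,speed_sd Gliding speed distribution (nm/s).
#' @param optics An [optics_model()].
#' @param mt_length_um Microtubule length in um.
#' @param seed Integer seed.
#' @param noise Add Poisson noise if `TRUE`.
#' @return List with `kymographs` (list of `kymograph` objects) and
#'   `speeds` (the generative draws, nm/s).
#' @export
sample_gliding_kymographs <- function(n, speed_mean, speed_sd,
                                      optics = optics_model(),
                                      mt_length_um = 5, seed = 1L,
                                      noise = FALSE) {
  set.seed(seed)
  speeds <- stats::rnorm(n, speed_mean, speed_sd)
  nf <- n_frames(optics)
  dt <- optics$frame_interval
  px <- optics$pixel_size
  len_px <- mt_length_um * 1000 / px
  amp <- 10 * optics$background_mean
  kymos <- vector("list", n)
  for (i in seq_len(n)) {
    travel_px <- abs(speeds[i]) * (nf - 1) * dt / px
    n_pos <- as.integer(ceiling(len_px + travel_px)) + 6L
    m <- matrix(optics$background_mean, nrow = n_pos, ncol = nf)
    centers <- seq_len(n_pos)
    for (f in seq_len(nf)) {
      tail_px <- 3 + abs(speeds[i]) * (f - 1) * dt / px
      lead_px <- tail_px + len_px
      # fractional pixel coverage of the bar [tail, lead]
      cov <- pmin(lead_px, centers + 0.5) - pmax(tail_px, centers - 0.5)
      m[, f] <- m[, f] + amp * pmin(pmax(cov, 0), 1)
    }
    if (noise) m <- matrix(stats::rpois(length(m), m), nrow = n_pos)
    kymos[[i]] <- new_kymograph(m, pixel_size = px, frame_interval = dt,
                                mt_length = mt_length_um, mt_id = i)
  }
  list(kymographs = kymos, speeds = speeds)
}
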