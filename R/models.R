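#' Generative model of a single motor construct
#'
#' A `motor_model` holds every parameter needed to simulate the behaviour of
#' one motor construct in a single-molecule TIRF assay: how often it lands on
#' a microtubule, what fraction of landings move processively, the
#' (Gaussian-mixture) distribution of instantaneous speeds, the exponential
#' scales of run length and residency time, the pausing kinetics, and the
#' photophysics of its fluorescent tags.
#'
#' @param name Text label for the construct.
#' @param landing_rate_total Landing events per micrometre of microtubule per
#'   minute (total, motile and static combined).
#' @param processive_fraction Probability in `[0, 1]` that a landing event is
#'   processive (moves along the lattice) rather than a static binder.
#' @param velocity_components Data frame (or list coercible to one) with
#'   columns `weight`, `mean`, `sd` describing the Gaussian mixture of
#'   per-motor instantaneous speeds in nm/s. Weights must sum to 1.
#' @param run_length_mean Exponential scale of run length in nm (used when
#'   `detach_mode = "per_distance"`).
#' @param residency_mean Exponential scale of residency time in s (used when
#'   `detach_mode = "per_time"`).
#' @param pause_entry_rate,pause_exit_rate Rates (per s) of the two-state
#'   moving/paused Markov chain. Both default to 0 (pause-free motion).
#' @param static_dwell_mean Mean exponential dwell (s) of non-processive
#'   (static) binders before they detach.
#' @param detach_mode Either `"per_distance"` (detach after an exponential
#'   cumulative moving distance; run lengths are exactly exponential) or
#'   `"per_time"` (detach after an exponential wall-clock residency;
#'   residencies are exactly exponential). The two cannot hold simultaneously
#'   once velocity couples them, so fixtures pick the mode matching the
#'   estimator under test.
#' @param n_fluorophores Number of fluorophores on one motor (1-8).
#' @param bleach_rate Photobleaching rate per s per fluorophore.
#'
#' @return An object of class `motor_model`.
#' @seealso [construct_model()] for the packaged construct parameterisations,
#'   [sample_trajectory()], [sample_landings()].
#' @export
motor_model <- function(name = "motor",
                        landing_rate_total = 0.392,
                        processive_fraction = 0.5,
                        velocity_components = data.frame(weight = 1, mean = 180, sd = 40),
                        run_length_mean = 700,
                        residency_mean = 5,
                        pause_entry_rate = 0,
                        pause_exit_rate = 0,
                        static_dwell_mean = 1,
                        detach_mode = c("per_distance", "per_time"),
                        n_fluorophores = 1L,
                        bleach_rate = 0) {
  detach_mode <- match.arg(detach_mode)
  vc <- as.data.frame(velocity_components)
  m <- structure(list(
    name = as.character(name),
    landing_rate_total = as.numeric(landing_rate_total),
    processive_fraction = as.numeric(processive_fraction),
    velocity_components = vc,
    run_length_mean = as.numeric(run_length_mean),
    residency_mean = as.numeric(residency_mean),
    pause_entry_rate = as.numeric(pause_entry_rate),
    pause_exit_rate = as.numeric(pause_exit_rate),
    static_dwell_mean = as.numeric(static_dwell_mean),
    detach_mode = detach_mode,
    n_fluorophores = as.integer(n_fluorophores),
    bleach_rate = as.numeric(bleach_rate)
  ), class = "motor_model")
  validate_motor_model(m)
}

#' @export
print.motor_model <- function(x, ...) {
  cat("<motor_model> ", x$name, "\n", sep = "")
  cat(sprintf("  landing rate: %.3f events/(um min), processive fraction %.3f\n",
              x$landing_rate_total, x$processive_fraction))
  for (i in seq_len(nrow(x$velocity_components))) {
    v <- x$velocity_components[i, ]
    cat(sprintf("  velocity component %d: weight %.2f, %.1f +/- %.1f nm/s\n",
                i, v$weight, v$mean, v$sd))
  }
  cat(sprintf("  run length %.1f nm | residency %.2f s | detach %s\n",
              x$run_length_mean, x$residency_mean, x$detach_mode))
  cat(sprintf("  %d fluorophore(s), bleach rate %.3f /s\n",
              x$n_fluorophores, x$bleach_rate))
  invisible(x)
}

validate_motor_model <- function(m) {
  stopifnot(inherits(m, "motor_model"))
  vc <- m$velocity_components
  if (!all(c("weight", "mean", "sd") %in% names(vc)))
    stop("velocity_components must have columns weight, mean, sd", call. = FALSE)
  if (abs(sum(vc$weight) - 1) > 1e-9)
    stop("velocity component weights must sum to 1 (got ",
         format(sum(vc$weight)), ")", call. = FALSE)
  if (any(vc$sd < 0)) stop("velocity component sd must be >= 0", call. = FALSE)
  nonneg <- c(landing_rate_total = m$landing_rate_total,
              run_length_mean = m$run_length_mean,
              residency_mean = m$residency_mean,
              pause_entry_rate = m$pause_entry_rate,
              pause_exit_rate = m$pause_exit_rate,
              static_dwell_mean = m$static_dwell_mean,
              bleach_rate = m$bleach_rate)
  bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
  if (length(bad))
    stop("motor_model fields must be finite and >= 0: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (m$processive_fraction < 0 || m$processive_fraction > 1)
    stop("processive_fraction must lie in [0, 1]", call. = FALSE)
  if (m$n_fluorophores < 1L || m$n_fluorophores > 8L)
    stop("n_fluorophores must be an integer in 1..8", call. = FALSE)
  m
}

#' Imaging / optics parameters of the simulated TIRF acquisition
#'
#' Defaults emulate an EMCCD TIRF setup: 160 nm pixels (back-projected),
#' 100 ms exposure at one frame every 0.12 s, and a 130 nm Gaussian PSF sigma.
#'
#' @param pixel_size nm per pixel.
#' @param frame_interval Seconds between frame starts; must be >= `exposure`.
#' @param exposure Exposure time in s.
#' @param psf_sigma Gaussian point-spread-function sigma in nm.
#' @param photons_per_fluorophore_per_frame Expected integrated counts one
#'   unbleached fluorophore contributes to its spot per frame.
#' @param background_mean Mean background counts per pixel per frame.
#' @param read_noise_sd Gaussian read noise s.d. in counts.
#' @param duration Movie duration in s (must cover at least 5 frames).
#' @param image_shape Integer `(rows, cols)` of the field of view in pixels.
#'
#' @return An object of class `optics_model`.
#' @export
optics_model <- function(pixel_size = 160,
                         frame_interval = 0.12,
                         exposure = 0.1,
                         psf_sigma = 130,
                         photons_per_fluorophore_per_frame = 200,
                         background_mean = 100,
                         read_noise_sd = 3,
                         duration = 60,
                         image_shape = c(128L, 128L)) {
  o <- structure(list(
    pixel_size = as.numeric(pixel_size),
    frame_interval = as.numeric(frame_interval),
    exposure = as.numeric(exposure),
    psf_sigma = as.numeric(psf_sigma),
    photons_per_fluorophore_per_frame = as.numeric(photons_per_fluorophore_per_frame),
    background_mean = as.numeric(background_mean),
    read_noise_sd = as.numeric(read_noise_sd),
    duration = as.numeric(duration),
    image_shape = as.integer(image_shape)
  ), class = "optics_model")
  if (!(o$frame_interval >= o$exposure && o$exposure > 0))
    stop("need frame_interval >= exposure > 0", call. = FALSE)
  if (o$psf_sigma <= 0) stop("psf_sigma must be > 0", call. = FALSE)
  if (o$duration / o$frame_interval < 5)
    stop("duration must cover at least 5 frames", call. = FALSE)
  if (length(o$image_shape) != 2L || any(o$image_shape < 8L))
    stop("image_shape must be (rows, cols), each >= 8 px", call. = FALSE)
  o
}

#' @export
print.optics_model <- function(x, ...) {
  cat("<optics_model>\n")
  cat(sprintf("  %d x %d px at %.0f nm/px, %.0f frames of %.2f s (exposure %.2f s)\n",
              x$image_shape[1], x$image_shape[2], x$pixel_size,
              n_frames(x), x$frame_interval, x$exposure))
  cat(sprintf("  PSF sigma %.0f nm, %.0f photons/fluorophore/frame, background %.0f, read noise %.1f\n",
              x$psf_sigma, x$photons_per_fluorophore_per_frame,
              x$background_mean, x$read_noise_sd))
  invisible(x)
}

n_frames <- function(optics) as.integer(floor(optics$duration / optics$frame_interval))

## ---- configuration files -------------------------------------------------

#' Read a simulation config (YAML) into model objects
#'
#' The config has `motor:`, `optics:`, `field:` and `seed:` blocks; see the
#' packaged construct configs under `inst/extdata/configs/` for the schema.
#'
#' @param path Path to a YAML config file.
#' @return A list with elements `motor` (a [motor_model()]), `optics`
#'   (an [optics_model()]), `field` (list: `n_mts`, `length_mean_um`,
#'   `length_sd_um`) and `seed`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  missing <- setdiff(c("motor", "optics", "field", "seed"), names(raw))
  if (length(missing))
    stop("config is missing block(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  mo <- raw$motor
  vc <- do.call(rbind, lapply(mo$velocity_components, function(v)
    data.frame(weight = v$weight, mean = v$mean, sd = v$sd)))
  motor <- motor_model(
    name = mo$name,
    landing_rate_total = mo$landing_rate_total,
    processive_fraction = mo$processive_fraction,
    velocity_components = vc,
    run_length_mean = mo$run_length_mean,
    residency_mean = mo$residency_mean,
    pause_entry_rate = mo$pause_entry_rate %||% 0,
    pause_exit_rate = mo$pause_exit_rate %||% 0,
    static_dwell_mean = mo$static_dwell_mean %||% 1,
    detach_mode = mo$detach_mode %||% "per_distance",
    n_fluorophores = mo$n_fluorophores %||% 1L,
    bleach_rate = mo$bleach_rate %||% 0
  )
  op <- raw$optics
  optics <- optics_model(
    pixel_size = op$pixel_size %||% 160,
    frame_interval = op$frame_interval %||% 0.12,
    exposure = op$exposure %||% 0.1,
    psf_sigma = op$psf_sigma %||% 130,
    photons_per_fluorophore_per_frame = op$photons_per_fluorophore_per_frame %||% 200,
    background_mean = op$background_mean %||% 100,
    read_noise_sd = op$read_noise_sd %||% 3,
    duration = op$duration %||% 60,
    image_shape = unlist(op$image_shape %||% c(128L, 128L))
  )
  list(motor = motor, optics = optics, field = raw$field,
       seed = as.integer(raw$seed))
}

#' Packaged construct parameterisations
#'
#' Returns the generative [motor_model()] for one of the constructs shipped
#' with the package, calibrated so that the downstream estimators should
#' recover the construct's published motility parameters:
#' `"cenpe483"` (weakly dimeric motor truncation), `"cenpe483lz"`
#' (leucine-zipper-stabilised dimer), `"cenpe754"` (stalk-stabilised dimer),
#' `"cenpefl"` (full-length motor, two-component velocity mixture, rare
#' processive events) and `"k560"` (kinesin-1 truncation control, nominal
#' kinetics).
#'
#' @param name One of `"cenpe483"`, `"cenpe483lz"`, `"cenpe754"`,
#'   `"cenpefl"`, `"k560"`.
#' @return A [motor_model()].
#' @export
construct_model <- function(name = c("cenpe483", "cenpe483lz", "cenpe754",
                                     "cenpefl", "k560")) {
  name <- match.arg(name)
  construct_config(name)$motor
}

#' @rdname construct_model
#' @return For `construct_config()`, the full config list as from
#'   [load_config()].
#' @export
construct_config <- function(name = c("cenpe483", "cenpe483lz", "cenpe754",
                                      "cenpefl", "k560")) {
  name <- match.arg(name)
  path <- system.file("extdata", "configs", paste0(name, ".yaml"),
                      package = "tirfkin", mustWork = TRUE)
  load_config(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
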