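## Generative simulator: microtubule fields, Poisson landings, motor
## trajectories (moving/paused two-state kinetics, exponential detachment,
## per-fluorophore exponential photobleaching).

#' Deterministic per-motor child seed
#'
#' One root seed governs a whole simulation; every motor (and every auxiliary
#' sampling stage) gets its own reproducible stream derived from
#' `(root_seed, id)`. The mixing constant is odd so distinct ids below 1e7
#' never collide.
#'
#' @param root_seed Integer root seed.
#' @param id Non-negative integer stream id (motor id, or a reserved id for
#'   field/landing sampling). Must be < 1e7.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
child_seed <- function(root_seed, id) {
  stopifnot(id >= 0, id < 1e7)
  as.integer((as.numeric(root_seed) %% 2147483647 +
                as.numeric(id) * 507086513) %% 2147483647)
}

# data.frame constructor without the validation overhead (hot path)
quick_df <- function(cols) {
  n <- length(cols[[1L]])
  structure(cols, class = "data.frame", row.names = .set_row_names(n))
}

# reserved auxiliary stream ids (outside the motor id range used in practice)
.SEED_FIELD <- 9000001
.SEED_LANDINGS <- 9000002
.SEED_PHASE <- 9000003
.SEED_RENDER <- 9000004

#' Sample a field of immobilized microtubules
#'
#' Places `n_mts` straight microtubule segments uniformly at random (position
#' and orientation) inside the field of view. Lengths are Gaussian, truncated
#' at 1 um. Segments may overlap, as they do on a real coverslip. Each
#' segment carries a polarity: the motor plus-end direction points from the
#' minus-end seed endpoint to the other end.
#'
#' @param n_mts Number of microtubules (>= 1).
#' @param length_mean,length_sd Length distribution in um.
#' @param optics An [optics_model()]; fixes pixel size and image bounds.
#' @param seed Integer seed.
#' @return A data frame of class `mt_field` with one row per segment:
#'   `mt_id`, endpoint pixel coordinates `ax, ay, bx, by` (x = column,
#'   y = row, 1-based), `length_um`, `polarity` (+1: plus end at b).
#' @export
sample_field <- function(n_mts, length_mean, length_sd, optics, seed = 1L) {
  stopifnot(n_mts >= 1)
  set.seed(seed)
  ny <- optics$image_shape[1]; nx <- optics$image_shape[2]
  margin <- 2
  rows <- vector("list", n_mts)
  for (i in seq_len(n_mts)) {
    len_um <- if (length_sd == 0) length_mean else {
      l <- stats::rnorm(1, length_mean, length_sd)
      tries <- 0L
      while (l < 1 && tries < 1000L) { l <- stats::rnorm(1, length_mean, length_sd); tries <- tries + 1L }
      max(l, 1)
    }
    len_px <- len_um * 1000 / optics$pixel_size
    placed <- FALSE
    for (try in seq_len(500L)) {
      theta <- stats::runif(1, 0, 2 * pi)
      ax <- stats::runif(1, 1 + margin, nx - margin)
      ay <- stats::runif(1, 1 + margin, ny - margin)
      bx <- ax + len_px * cos(theta)
      by <- ay + len_px * sin(theta)
      if (bx >= 1 + margin && bx <= nx - margin &&
          by >= 1 + margin && by <= ny - margin) { placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf("could not place microtubule %d (%.1f um = %.0f px) inside a %d x %d px image",
                   i, len_um, len_px, ny, nx), call. = FALSE)
    rows[[i]] <- data.frame(mt_id = i, ax = ax, ay = ay, bx = bx, by = by,
                            length_um = len_um,
                            polarity = sample(c(1L, -1L), 1))
  }
  field <- do.call(rbind, rows)
  attr(field, "pixel_size") <- optics$pixel_size
  class(field) <- c("mt_field", "data.frame")
  field
}

#' Pixel coordinates of a position along a microtubule
#'
#' Positions are measured in nm from the minus-end seed endpoint toward the
#' plus end (the direction processive motors move).
#'
#' @param field An `mt_field`.
#' @param mt_id Microtubule id.
#' @param position_nm Position(s) along the lattice in nm.
#' @return A list with numeric vectors `x` (column) and `y` (row) in pixels.
#' @export
mt_point <- function(field, mt_id, position_nm) {
  seg <- field[field$mt_id == mt_id, , drop = FALSE]
  if (nrow(seg) != 1L) stop("unknown mt_id: ", mt_id, call. = FALSE)
  px <- attr(field, "pixel_size")
  len_px <- seg$length_um * 1000 / px
  if (seg$polarity >= 0) { x0 <- seg$ax; y0 <- seg$ay; x1 <- seg$bx; y1 <- seg$by }
  else { x0 <- seg$bx; y0 <- seg$by; x1 <- seg$ax; y1 <- seg$ay }
  ux <- (x1 - x0) / len_px; uy <- (y1 - y0) / len_px
  s <- position_nm / px
  list(x = x0 + ux * s, y = y0 + uy * s)
}

#' Sample motor landing events on a microtubule field
#'
#' Landing on each microtubule is a homogeneous Poisson process with rate
#' `landing_rate_total * length_um` events per minute; each event is
#' independently processive with probability `processive_fraction`, its time
#' uniform over the observation window and its position uniform along the
#' segment.
#'
#' @param field An `mt_field` from [sample_field()].
#' @param model A [motor_model()].
#' @param duration Observation duration in seconds.
#' @param seed Integer seed.
#' @return Data frame: `event_id`, `mt_id`, `t_land` (s), `position_nm`,
#'   `class` (`"processive"` or `"static"`).
#' @export
sample_landings <- function(field, model, duration, seed = 1L) {
  stopifnot(duration > 0)
  set.seed(seed)
  dur_min <- duration / 60
  counts <- stats::rpois(nrow(field), model$landing_rate_total * field$length_um * dur_min)
  n <- sum(counts)
  if (n == 0L)
    return(data.frame(event_id = integer(), mt_id = integer(),
                      t_land = numeric(), position_nm = numeric(),
                      class = character(), stringsAsFactors = FALSE))
  mt_id <- rep(field$mt_id, counts)
  len_nm <- rep(field$length_um, counts) * 1000
  data.frame(
    event_id = seq_len(n),
    mt_id = mt_id,
    t_land = stats::runif(n, 0, duration),
    position_nm = stats::runif(n, 0, len_nm),
    class = ifelse(stats::runif(n) < model$processive_fraction,
                   "processive", "static"),
    stringsAsFactors = FALSE
  )
}

#' Draw instantaneous speeds from a motor's velocity mixture
#'
#' Raw Gaussian-mixture draws (no truncation): this is the generative model
#' behind velocity histograms. Trajectory simulation truncates its own speed
#' draw at > 0 since a track needs a physical speed.
#'
#' @param model A [motor_model()].
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return Numeric vector of speeds (nm/s).
#' @export
sample_velocities <- function(model, n, seed = 1L) {
  set.seed(seed)
  vc <- model$velocity_components
  comp <- if (nrow(vc) > 1L)
    sample.int(nrow(vc), n, replace = TRUE, prob = vc$weight)
  else rep(1L, n)
  stats::rnorm(n, vc$mean[comp], vc$sd[comp])
}

draw_speed <- function(model) {
  vc <- model$velocity_components
  comp <- if (nrow(vc) > 1L)
    sample.int(nrow(vc), 1L, prob = vc$weight) else 1L
  v <- stats::rnorm(1, vc$mean[comp], vc$sd[comp])
  tries <- 0L
  while (v <= 0 && tries < 1000L) {
    v <- stats::rnorm(1, vc$mean[comp], vc$sd[comp]); tries <- tries + 1L
  }
  if (v <= 0) v <- abs(stats::rnorm(1, vc$mean[comp], vc$sd[comp])) + 1e-6
  list(speed = v, component = comp)
}

#' Simulate one motor's ground-truth trajectory
#'
#' Static binders dwell at a fixed position for an exponential time. A
#' processive motor draws one instantaneous speed from the velocity mixture
#' and alternates moving/paused states (exponential holding times). Under
#' `detach_mode = "per_distance"` it detaches once its cumulative moving
#' distance reaches an exponential draw of scale `run_length_mean`; under
#' `"per_time"` it detaches after an exponential residency of scale
#' `residency_mean`. Fluorophores bleach as independent exponentials starting
#' at landing. Positions are recorded on the acquisition frame grid.
#'
#' The first random number consumed is the unit-exponential detachment draw,
#' so simulations of different constructs sharing a root seed share their
#' detachment quantiles motor-for-motor (useful for paired comparisons).
#'
#' @param model A [motor_model()].
#' @param landing One landing record: list or one-row data frame with
#'   `event_id` (or `motor_id`), `mt_id`, `t_land`, `position_nm`, `class`.
#' @param optics An [optics_model()] (fixes the frame grid).
#' @param seed Integer seed (typically [child_seed()] of the root and motor id).
#' @param censor_at Stop recording frames at this time (s); defaults to `Inf`
#'   (no movie-end censoring). Rendering pipelines pass the movie duration.
#' @return An object of class `trajectory`: `motor_id`, `mt_id`, `class`,
#'   `t_land`, `t_detach`, `velocity_draw` (nm/s; NA for static),
#'   `bleach_times` (absolute s), `censored`, and `frames` (data frame:
#'   `frame`, `t`, `position_nm`, `state`, `n_unbleached`).
#' @export
sample_trajectory <- function(model, landing, optics, seed = 1L,
                              censor_at = Inf) {
  landing <- as.list(landing)
  motor_id <- landing$event_id %||% landing$motor_id %||% 1L
  if (is.null(landing$class)) stop("landing record has no class", call. = FALSE)
  set.seed(seed)
  u_detach <- stats::rexp(1)   # unit exponential, scaled below
  t_land <- landing$t_land
  x0 <- landing$position_nm

  if (landing$class == "static") {
    t_detach <- t_land + u_detach * model$static_dwell_mean
    knots_t <- c(t_land, t_detach)
    knots_x <- c(x0, x0)
    seg_state <- "paused"
    v <- NA_real_
  } else {
    if (model$detach_mode == "per_distance" && model$run_length_mean <= 0)
      stop("degenerate model: per_distance detachment with run_length_mean = 0",
           call. = FALSE)
    v <- draw_speed(model)$speed
    if (model$detach_mode == "per_distance") {
      moving_budget <- u_detach * model$run_length_mean / v  # total moving time
      time_budget <- Inf
    } else {
      moving_budget <- Inf
      time_budget <- u_detach * model$residency_mean
    }
    if (model$detach_mode == "per_distance" &&
        model$pause_entry_rate > 0 && model$pause_exit_rate <= 0)
      stop("degenerate model: motors pause but never resume under per_distance detachment",
           call. = FALSE)
    # alternate moving/paused exponential holds until a budget is exhausted
    durs <- numeric(0); states <- character(0)
    state <- "moving"; t_rel <- 0; moved <- 0
    repeat {
      rate <- if (state == "moving") model$pause_entry_rate else model$pause_exit_rate
      hold <- if (rate > 0) stats::rexp(1, rate) else Inf
      cap <- min(if (state == "moving") moving_budget - moved else Inf,
                 time_budget - t_rel)
      if (hold >= cap) { durs <- c(durs, cap); states <- c(states, state); break }
      durs <- c(durs, hold); states <- c(states, state)
      t_rel <- t_rel + hold
      if (state == "moving") moved <- moved + hold
      state <- if (state == "moving") "paused" else "moving"
    }
    knots_t <- t_land + c(0, cumsum(durs))
    step_x <- ifelse(states == "moving", durs * v, 0)
    knots_x <- x0 + c(0, cumsum(step_x))
    t_detach <- knots_t[length(knots_t)]
    seg_state <- states
  }

  bleach_times <- if (model$bleach_rate > 0)
    t_land + stats::rexp(model$n_fluorophores) / model$bleach_rate
  else rep(Inf, model$n_fluorophores)

  dt <- optics$frame_interval
  t_stop <- min(t_detach, censor_at)
  f0 <- ceiling(t_land / dt - 1e-9)
  f1 <- floor(t_stop / dt + 1e-9)
  if (f1 >= f0) {
    f <- seq.int(f0, f1)
    tt <- f * dt
    pos <- if (length(knots_t) > 2L)
      stats::approx(knots_t, knots_x, xout = tt, rule = 2)$y
    else knots_x[1] + (knots_x[2] - knots_x[1]) *
      (tt - knots_t[1]) / max(knots_t[2] - knots_t[1], .Machine$double.eps)
    si <- pmin(pmax(findInterval(tt, knots_t, rightmost.closed = TRUE), 1L),
               length(seg_state))
    st <- seg_state[si]
    nb <- if (all(is.infinite(bleach_times))) rep(length(bleach_times), length(tt))
    else colSums(outer(bleach_times, tt, ">"))
    frames <- quick_df(list(frame = as.integer(f), t = tt, position_nm = pos,
                            state = st, n_unbleached = as.integer(nb)))
  } else {
    frames <- quick_df(list(frame = integer(), t = numeric(),
                            position_nm = numeric(), state = character(),
                            n_unbleached = integer()))
  }

  structure(list(motor_id = motor_id, mt_id = landing$mt_id %||% NA_integer_,
                 class = landing$class, t_land = t_land, t_detach = t_detach,
                 velocity_draw = v, bleach_times = bleach_times,
                 censored = is.finite(censor_at) && t_detach > censor_at,
                 frames = frames),
            class = "trajectory")
}

#' Bind trajectories into a ground-truth frame table
#'
#' @param trajectories List of [sample_trajectory()] objects.
#' @return Data frame with one row per motor-frame: `motor_id`, `mt_id`,
#'   `frame`, `t`, `position_nm`, `state`, `n_unbleached`.
#' @export
truth_table <- function(trajectories) {
  if (!length(trajectories))
    return(quick_df(list(motor_id = integer(), mt_id = integer(),
                         frame = integer(), t = numeric(),
                         position_nm = numeric(), state = character(),
                         n_unbleached = integer())))
  nfr <- vapply(trajectories, function(tr) nrow(tr$frames), integer(1))
  pull <- function(col) unlist(lapply(trajectories, function(tr) tr$frames[[col]]),
                               use.names = FALSE)
  data.frame(
    motor_id = rep(vapply(trajectories, function(tr) as.integer(tr$motor_id), integer(1)), nfr),
    mt_id = rep(vapply(trajectories, function(tr) as.integer(tr$mt_id), integer(1)), nfr),
    frame = pull("frame"),
    t = pull("t"),
    position_nm = pull("position_nm"),
    state = pull("state"),
    n_unbleached = pull("n_unbleached"),
    stringsAsFactors = FALSE
  )
}

#' Per-motor ground-truth summary
#'
#' @param trajectories List of trajectories.
#' @return Data frame: one row per motor with landing/detach times, class,
#'   speed draw, frame count and censoring flag.
#' @export
motor_summary <- function(trajectories) {
  data.frame(
    motor_id = vapply(trajectories, function(tr) as.integer(tr$motor_id), integer(1)),
    mt_id = vapply(trajectories, function(tr) as.integer(tr$mt_id), integer(1)),
    class = vapply(trajectories, function(tr) tr$class, character(1)),
    t_land = vapply(trajectories, function(tr) tr$t_land, numeric(1)),
    t_detach = vapply(trajectories, function(tr) tr$t_detach, numeric(1)),
    velocity_draw = vapply(trajectories, function(tr) tr$velocity_draw, numeric(1)),
    n_frames = vapply(trajectories, function(tr) nrow(tr$frames), integer(1)),
    censored = vapply(trajectories, function(tr) isTRUE(tr$censored), logical(1)),
    stringsAsFactors = FALSE
  )
}

#' Run a full simulated experiment from a config
#'
#' Samples a microtubule field, Poisson landings and one trajectory per
#' landing, all from deterministic child streams of the root seed.
#'
#' @param config A config list from [load_config()] / [construct_config()].
#' @param seed Root seed; defaults to the config's seed.
#' @param censor_at Frame-recording cutoff passed to [sample_trajectory()];
#'   defaults to the optics duration (motors still attached at movie end are
#'   flagged censored).
#' @return List: `field`, `landings`, `trajectories`, `truth` (frame table),
#'   `summary` (per-motor), plus the `motor`, `optics` and `seed` used.
#' @export
simulate_experiment <- function(config, seed = NULL,
                                censor_at = config$optics$duration) {
  seed <- seed %||% config$seed
  optics <- config$optics
  field <- sample_field(config$field$n_mts, config$field$length_mean_um,
                        config$field$length_sd_um, optics,
                        seed = child_seed(seed, .SEED_FIELD))
  landings <- sample_landings(field, config$motor, optics$duration,
                              seed = child_seed(seed, .SEED_LANDINGS))
  trajectories <- lapply(seq_len(nrow(landings)), function(i)
    sample_trajectory(config$motor, landings[i, ], optics,
                      seed = child_seed(seed, landings$event_id[i]),
                      censor_at = censor_at))
  list(field = field, landings = landings, trajectories = trajectories,
       truth = truth_table(trajectories), summary = motor_summary(trajectories),
       motor = config$motor, optics = optics, seed = seed)
}

#' Simulate a batch of processive runs and measure them
#'
#' Convenience fixture generator for estimator validation: `n` processive
#' motors land (each at a uniformly random phase within one frame interval,
#' so the frame grid is unbiased), their trajectories are sampled with
#' per-motor child streams, and events are measured from the ground truth
#' with the standard kymograph definitions ([events_from_truth()]).
#'
#' @param model A [motor_model()].
#' @param n Number of motors.
#' @param optics An [optics_model()].
#' @param seed Root seed.
#' @param mode Override of the model's `detach_mode`.
#' @return A `RunEvent` data frame (see [events_from_truth()]), unfiltered.
#' @export
sample_run_events <- function(model, n, optics = optics_model(), seed = 1L,
                              mode = model$detach_mode) {
  model$detach_mode <- mode
  set.seed(child_seed(seed, .SEED_PHASE))
  phase <- stats::runif(n, 0, optics$frame_interval)
  trajs <- lapply(seq_len(n), function(i) {
    landing <- list(event_id = i, mt_id = 1L, t_land = phase[i],
                    position_nm = 0, class = "processive")
    sample_trajectory(model, landing, optics, seed = child_seed(seed, i))
  })
  events_from_truth(truth_table(trajs))
}
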