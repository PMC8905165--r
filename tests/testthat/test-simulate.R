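optics <- optics_model()

test_that("sample_field: zero-variance lengths are exact; sample mean obeys the LLN", {
  f1 <- sample_field(1, 10, 0, optics, seed = 1)
  expect_equal(f1$length_um, 10)
  # endpoint distance consistent with the recorded length
  d_px <- sqrt((f1$bx - f1$ax)^2 + (f1$by - f1$ay)^2)
  expect_equal(d_px * optics$pixel_size / 1000, 10, tolerance = 1e-6)

  f <- sample_field(100, 10, 2, optics, seed = 7)
  se <- 2 / sqrt(100)
  expect_lt(abs(mean(f$length_um) - 10), 3 * se)
  expect_true(all(f$length_um >= 1))
})

test_that("sample_field errors when a microtubule cannot fit", {
  small <- optics_model(image_shape = c(16, 16))
  expect_error(sample_field(1, 50, 0, small, seed = 1), "could not place")
})

test_that("landing counts are Poisson with rate x length x minutes", {
  model <- motor_model(landing_rate_total = 0)
  f <- sample_field(3, 10, 0, optics, seed = 1)
  expect_equal(nrow(sample_landings(f, model, 600, seed = 1)), 0L)

  # 0.392 ev/(um min) on 10 um for 10 min -> mean 39.2 per microtubule;
  # a field of 2000 microtubules is 2000 iid replicates
  model <- motor_model(landing_rate_total = 0.392)
  big <- optics_model(image_shape = c(1024, 1024))
  f <- sample_field(2000, 10, 0, big, seed = 2)
  l <- sample_landings(f, model, 600, seed = 3)
  counts <- as.numeric(table(factor(l$mt_id, levels = f$mt_id)))
  se <- sqrt(39.2 / 2000)
  expect_lt(abs(mean(counts) - 39.2), 3 * se)
  # positions uniform along the lattice
  expect_gt(min(l$position_nm), 0)
  expect_lt(max(l$position_nm), 10 * 1000 + 1)
})

test_that("processive thinning reproduces the full-length processive landing rate", {
  # total 0.147 with processive probability 0.061 -> 0.009 ev/(um min)
  model <- motor_model(landing_rate_total = 0.147, processive_fraction = 0.061)
  big <- optics_model(image_shape = c(1024, 1024))
  f <- sample_field(1500, 10, 0, big, seed = 4)
  l <- sample_landings(f, model, 600, seed = 5)
  n_proc <- sum(l$class == "processive")
  rate_proc <- n_proc / (1500 * 10 * 10)
  se <- sqrt(0.147 * 0.061 / (1500 * 10 * 10))
  expect_lt(abs(rate_proc - 0.147 * 0.061), 3 * se)
})

test_that("pause-free per_distance trajectories satisfy residency = run/speed exactly", {
  model <- motor_model(pause_entry_rate = 0, detach_mode = "per_distance",
                       run_length_mean = 700)
  landing <- list(event_id = 1L, mt_id = 1L, t_land = 0.03, position_nm = 0,
                  class = "processive")
  tr <- sample_trajectory(model, landing, optics, seed = 11)
  v <- tr$velocity_draw
  run_true <- (tr$t_detach - tr$t_land) * v
  expect_equal(tr$t_detach - tr$t_land, run_true / v, tolerance = 1e-12)
  # frame positions advance at exactly v
  d <- diff(tr$frames$position_nm) / diff(tr$frames$t)
  expect_equal(d, rep(v, length(d)), tolerance = 1e-9)
})

test_that("per_time residencies are exponential with the configured mean", {
  model <- motor_model(detach_mode = "per_time", residency_mean = 37.1)
  res <- vapply(1:4000, function(i) {
    landing <- list(event_id = i, mt_id = 1L, t_land = 0, position_nm = 0,
                    class = "processive")
    tr <- sample_trajectory(model, landing, optics, seed = child_seed(5, i))
    tr$t_detach - tr$t_land
  }, numeric(1))
  se <- 37.1 / sqrt(4000)
  expect_lt(abs(mean(res) - 37.1), 3 * se)
})

test_that("per_distance run lengths converge to the configured scale", {
  model <- motor_model(detach_mode = "per_distance", run_length_mean = 703.3)
  runs <- vapply(1:4000, function(i) {
    landing <- list(event_id = i, mt_id = 1L, t_land = 0, position_nm = 0,
                    class = "processive")
    tr <- sample_trajectory(model, landing, optics, seed = child_seed(6, i))
    (tr$t_detach - tr$t_land) * tr$velocity_draw
  }, numeric(1))
  se <- 703.3 / sqrt(4000)
  expect_lt(abs(mean(runs) - 703.3), 3 * se)
})

test_that("whole-run velocity <= instantaneous speed, equal iff pause-free", {
  pausy <- motor_model(detach_mode = "per_time", residency_mean = 20,
                       pause_entry_rate = 0.5, pause_exit_rate = 0.5)
  n_with_pause <- 0L
  for (i in 1:50) {
    landing <- list(event_id = i, mt_id = 1L, t_land = 0, position_nm = 0,
                    class = "processive")
    tr <- sample_trajectory(pausy, landing, optics, seed = child_seed(9, i))
    if (nrow(tr$frames) < 2L) next
    net <- diff(range(tr$frames$position_nm))
    span <- diff(range(tr$frames$t))
    v_run <- net / span
    expect_lte(v_run, tr$velocity_draw + 1e-9)
    if (any(tr$frames$state == "paused")) {
      n_with_pause <- n_with_pause + 1L
      expect_lt(v_run, tr$velocity_draw)
    }
  }
  expect_gt(n_with_pause, 5L)  # the pause process is actually exercised
})

test_that("static binders dwell exponentially at a fixed position", {
  model <- motor_model(static_dwell_mean = 1)
  landing <- list(event_id = 1L, mt_id = 1L, t_land = 0.5, position_nm = 420,
                  class = "static")
  tr <- sample_trajectory(model, landing, optics, seed = 3)
  expect_true(all(tr$frames$position_nm == 420))
  expect_true(all(tr$frames$state == "paused"))
  dwells <- vapply(1:2000, function(i)
    with(sample_trajectory(model, landing, optics, seed = child_seed(7, i)),
         t_detach - t_land), numeric(1))
  expect_lt(abs(mean(dwells) - 1), 3 / sqrt(2000))
})

test_that("degenerate models are rejected", {
  m <- motor_model(detach_mode = "per_distance", run_length_mean = 0)
  landing <- list(event_id = 1L, mt_id = 1L, t_land = 0, position_nm = 0,
                  class = "processive")
  expect_error(sample_trajectory(m, landing, optics, seed = 1), "degenerate")
})

test_that("first-bleach times follow the order-statistic exponential", {
  # min of k iid Exp(rate) is Exp(k * rate)
  model <- motor_model(n_fluorophores = 4L, bleach_rate = 0.05)
  landing <- list(event_id = 1L, mt_id = 1L, t_land = 0, position_nm = 0,
                  class = "static")
  first <- vapply(1:3000, function(i)
    min(sample_trajectory(model, landing, optics,
                          seed = child_seed(8, i))$bleach_times),
    numeric(1))
  expected <- 1 / (4 * 0.05)
  expect_lt(abs(mean(first) - expected), 3 * expected / sqrt(3000))
})

test_that("sampling is reproducible bit-for-bit given (config, seed)", {
  cfg <- construct_config("cenpe754")
  cfg$optics <- optics_model(duration = 12)
  cfg$field$n_mts <- 5
  s1 <- simulate_experiment(cfg, seed = 99)
  s2 <- simulate_experiment(cfg, seed = 99)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$field, s2$field)
  s3 <- simulate_experiment(cfg, seed = 100)
  expect_false(identical(s1$truth, s3$truth))
})

test_that("landing counts conserve: expected events = rate x total length x minutes", {
  cfg <- construct_config("cenpe754")
  cfg$optics <- optics_model(duration = 60, image_shape = c(512, 512))
  cfg$field$n_mts <- 300
  sims <- simulate_experiment(cfg, seed = 17)
  expected <- cfg$motor$landing_rate_total * sum(sims$field$length_um) * 1
  n <- nrow(sims$landings)
  expect_lt(abs(n - expected), 3 * sqrt(expected))
})
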