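optics <- optics_model(duration = 6, image_shape = c(48, 48))

flat_movie <- function(value, nf = 20, shape = c(32, 32)) {
  structure(list(data = array(value, dim = c(shape, nf)),
                 optics = optics_model(duration = nf * 0.12,
                                       image_shape = shape)),
            class = "movie")
}

test_that("extract_trace: flat field cancels to zero; edges are rejected", {
  mv <- flat_movie(137)
  tr <- extract_trace(mv, c(16, 16))
  expect_equal(tr$corrected, rep(0, 20))
  expect_equal(tr$roi_mean, rep(137, 20))
  expect_error(extract_trace(mv, c(4, 16)), "edge")
  expect_error(extract_trace(mv, c(16, 29)), "edge")
})

test_that("extract_trace geometry: 4x4 ROI, 84-pixel background annulus", {
  mv <- flat_movie(10, nf = 6)
  # paint the exact 4x4 block around (16,16): rows/cols 15..18
  mv$data[15:18, 15:18, ] <- 10 + 32
  tr <- extract_trace(mv, c(16, 16))
  # corrected = spot mean, independent of the flat background level
  expect_equal(tr$corrected, rep(32, 6))
  mv2 <- mv; mv2$data <- mv2$data + 500   # add a constant to the whole movie
  tr2 <- extract_trace(mv2, c(16, 16))
  expect_equal(tr2$corrected, tr$corrected)
})

test_that("corrected trace of a rendered bleaching spot matches the truth staircase", {
  field <- sample_field(1, 5, 0, optics, seed = 2)
  model <- motor_model(n_fluorophores = 2L, bleach_rate = 0.3)
  landing <- list(event_id = 1L, mt_id = 1L, t_land = 0, position_nm = 2500,
                  class = "static")
  tr <- sample_trajectory(model, landing, optics, seed = 6, censor_at = 6)
  mv <- render_movie(field, list(tr), optics, noise = FALSE)
  pt <- mt_point(field, 1L, 2500)
  trace <- extract_trace(mv, c(round(pt$y), round(pt$x)))
  staircase_truth <- tr$frames$n_unbleached[
    match(seq_len(dim(mv$data)[3]) - 1L, tr$frames$frame)]
  staircase_truth[is.na(staircase_truth)] <- 0
  # ROI holds most of the PSF; corrected trace is proportional to the staircase
  expect_gt(cor(trace$corrected, staircase_truth), 0.999)
})

test_that("initial intensity is the mean of the first five corrected frames", {
  tr <- sample_bleach_trace(motor_model(n_fluorophores = 1L, bleach_rate = 1e-9),
                            unit_intensity = 10, noise_sd = 0, n_frames = 10,
                            seed = 1)
  tr$corrected <- c(10, 10, 10, 10, 10, 0, 0, 0, 0, 0)
  expect_equal(initial_intensity(tr), 10)
  short <- tr; short$corrected <- c(1, 2, 3)
  expect_error(initial_intensity(short), "fewer than 5")
})

test_that("a motor bleaching once within the first five frames averages between levels", {
  model <- motor_model(n_fluorophores = 2L, bleach_rate = 2)
  found <- FALSE
  for (s in 1:100) {
    tr <- sample_bleach_trace(model, unit_intensity = 100, noise_sd = 0,
                              n_frames = 20, seed = s)
    bt <- sort(tr$truth$bleach_times)
    if (bt[1] > 0.12 && bt[1] < 0.48 && bt[2] > 0.6) { found <- TRUE; break }
  }
  expect_true(found)
  ii <- initial_intensity(tr)
  expect_gt(ii, 100); expect_lt(ii, 200)
})

test_that("similar constructs give similar initial intensities (same tag count)", {
  # both the stalk dimer and the kinesin-1 control carry 4 fluorophores
  ii <- function(name, seeds) vapply(seeds, function(s)
    initial_intensity(sample_bleach_trace(construct_model(name), 200, 20, 60,
                                          seed = s)), numeric(1))
  a <- ii("cenpe754", 1:80)
  b <- ii("k560", 101:180)
  expect_lt(abs(median(a) - median(b)) / median(a), 0.1)
})

test_that("aggregate exclusion removes bright outliers and never dim traces", {
  model <- motor_model(n_fluorophores = 2L, bleach_rate = 0.05)
  traces <- lapply(1:100, function(s)
    sample_bleach_trace(model, 200, 10, 50, seed = s))
  hom <- exclude_aggregates(traces)
  expect_equal(length(hom$excluded), 0L)   # homogeneous population kept

  big <- sample_bleach_trace(motor_model(n_fluorophores = 2L, bleach_rate = 0.05),
                             2000, 10, 50, seed = 999)  # 10x unit intensity
  mix <- exclude_aggregates(c(traces, list(big)))
  expect_equal(length(mix$excluded), 1L)
  expect_equal(mix$excluded[[1]]$initial_intensity, big$initial_intensity)
  # nothing below the median is ever excluded
  med <- median(mix$initial_intensities)
  expect_true(all(mix$initial_intensities[mix$excluded_flag] > med))
  expect_error(exclude_aggregates(traces[1:3]), "at least 5")
})

test_that("a 2-mer / 20-mer mixture is fully separated at the default threshold", {
  dim2 <- lapply(1:60, function(s)
    sample_bleach_trace(motor_model(n_fluorophores = 2L, bleach_rate = 0.02),
                        200, 15, 50, seed = s))
  # aggregates: 10 tandem dimers stuck together = ~10x initial intensity
  agg <- lapply(61:70, function(s) {
    tr <- sample_bleach_trace(motor_model(n_fluorophores = 2L, bleach_rate = 0.02),
                              2000, 15, 50, seed = s)
    tr
  })
  res <- exclude_aggregates(c(dim2, agg))
  expect_equal(length(res$excluded), 10L)
  expect_equal(length(res$kept), 60L)
})

test_that("noiseless staircases of 1-8 steps are counted exactly", {
  for (k in 1:8) {
    y <- staircase(seq(k, 0), len = 6L)
    sc <- count_steps(y)
    expect_equal(sc$n_steps, k)
    expect_equal(length(sc$change_points), k)
    # accepted levels strictly decreasing
    expect_true(all(diff(sc$level_means) < 0))
  }
  expect_equal(count_steps(rep(7, 30))$n_steps, 0L)
})

test_that("greedy segmentation equals the exhaustive DP oracle on short traces", {
  # noiseless: always identical
  for (k in 1:5) {
    y <- staircase(seq(k, 0), len = ceiling(32 / (k + 1)))[1:32]
    expect_equal(count_steps(y)$n_steps, dp_count_steps(y))
  }
  # noisy 32-frame traces: agreement on >= 95%
  set.seed(201)
  agree <- vapply(1:200, function(i) {
    k <- sample(1:4, 1)
    lens <- as.vector(stats::rmultinom(1, 32 - (k + 1), rep(1, k + 1))) + 1L
    y <- rep(seq(k, 0) * 200, times = lens) + rnorm(32, 0, 25)
    count_steps(y)$n_steps == dp_count_steps(y)
  }, logical(1))
  expect_gte(mean(agree), 0.95)
})

test_that("step counts from a pre-bleached 4-mer follow Binomial(4, 1 - q)", {
  # bleach fast enough that every active fluorophore bleaches in-trace
  model <- motor_model(n_fluorophores = 4L, bleach_rate = 0.2)
  q <- 0.2
  steps <- vapply(1:500, function(s)
    count_steps(sample_bleach_trace(model, 200, 20, 400, seed = s,
                                    pre_bleach_prob = q))$n_steps,
    integer(1))
  obs <- tabulate(steps + 1L, nbins = 5L)
  expected <- dbinom(0:4, 4, 1 - q) * 500
  keep <- expected > 1
  chi2 <- sum((obs[keep] - expected[keep])^2 / expected[keep])
  expect_lt(chi2, qchisq(0.999, df = sum(keep) - 1))
})

test_that("min_step rejects sub-threshold dips and max_steps caps the count", {
  y <- c(rep(400, 10), rep(395, 10), rep(200, 10), rep(0, 10))
  sc <- count_steps(y, min_step = 50)
  expect_equal(sc$n_steps, 2L)   # the 5-count dip is not a step
  y8 <- staircase(seq(8, 0), len = 5L)
  sc8 <- count_steps(y8, max_steps = 3L)
  expect_lte(length(sc8$change_points), 3L)
  expect_error(count_steps(y, min_step = -1), "min_step")
  expect_error(count_steps(rep(1, 5)), "at least 10")
})
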