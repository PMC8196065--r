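test_that("renders are seeded, quantized, and unsaturated", {
  pop <- sample_droplet_population(4, c(256, 256), c(5, 12), seed = 4,
                                   assembled_fraction = 0.4)
  im <- imaging_params(rng_seed = 4)
  a <- render_frame(pop, im)
  b <- render_frame(pop, im)
  expect_identical(a$image, b$image)
  expect_true(is.integer(a$image))
  expect_lt(max(a$image), 0.9 * (2^16 - 1))
  expect_gte(min(a$image), 0)
  c <- render_frame(pop, imaging_params(rng_seed = 5))
  expect_false(identical(a$image, c$image))
  # gross overexposure is refused with actionable advice
  expect_error(render_frame(pop, imaging_params(exposure_gain = 50,
                                                rng_seed = 4)),
               "exposure_gain")
})

test_that("an empty population renders to background noise only", {
  pop <- sample_droplet_population(0, c(128, 128), c(1, 10), seed = 1)
  fr <- render_frame(pop, imaging_params(rng_seed = 1))
  expect_equal(nrow(fr$truth), 0L)
  expect_lt(abs(mean(fr$image) - 200), 5)
  expect_equal(nrow(detect_droplets(fr$image)), 0L)
})

test_that("total droplet signal is conserved across assembled fractions", {
  im <- imaging_params(rng_seed = 6)
  budget <- sig <- numeric(0)
  for (f in c(0, 0.3, 0.8)) {
    pop <- sample_droplet_population(1, c(160, 160), c(10, 10), seed = 6,
                                     assembled_fraction = f,
                                     partition_sdlog = 0)
    fr <- render_frame(pop, im, return_noiseless = TRUE)
    budget <- c(budget, fr$truth$signal_total)
    nl <- attr(fr, "noiseless")
    sig <- c(sig, sum(nl - im$background_level) / im$exposure_gain)
  }
  # the analytic per-droplet budget is independent of assembled fraction
  expect_equal(budget, rep(budget[1], 3))
  # condensation redistributes signal but does not create or destroy it
  expect_lt(max(abs(sig - sig[1])) / sig[1], 0.02)
  # and the budget scales with the tile load
  pop2 <- sample_droplet_population(1, c(160, 160), c(10, 10), seed = 6,
                                    partition_sdlog = 0, tile_total = 250)
  fr2 <- render_frame(pop2, im, return_noiseless = TRUE)
  s2 <- sum(attr(fr2, "noiseless") - im$background_level) /
    im$exposure_gain
  expect_lt(abs(s2 - sig[1] / 2) / (sig[1] / 2), 0.02)
})

test_that("a dispersed-tile droplet interior is nearly symmetric", {
  pop <- sample_droplet_population(1, c(140, 140), c(10, 10), seed = 8,
                                   assembled_fraction = 0,
                                   partition_sdlog = 0)
  fr <- render_frame(pop, imaging_params(rng_seed = 8))
  px <- extract_droplet_pixels(fr$image,
                               c(pop$center_row, pop$center_col),
                               pop$radius_px, 0.1)
  expect_lt(abs(sample_skewness(px)), 0.15)
})

test_that("time series follow the trajectory and validate inputs", {
  pop <- sample_droplet_population(5, c(256, 256), c(6, 12), seed = 10)
  im <- imaging_params(rng_seed = 10)
  traj <- data.frame(time = c(0, 100), f = c(0, 0.6))
  frames <- render_timeseries(traj, pop, im, c(0, 50, 100),
                              fraction_jitter_sdlog = 0)
  expect_length(frames, 3L)
  expect_equal(frames[[2]]$truth$assembled_fraction, rep(0.3, 5))
  expect_equal(vapply(frames, `[[`, numeric(1), "time_min"),
               c(0, 50, 100))
  expect_error(render_timeseries(traj, pop, im, numeric(0)),
               "non-empty")
  expect_error(render_timeseries(traj, pop, im, c(0, 150)),
               "time range")
  # constant-zero trajectory: frames are fraction-0 renders
  z <- render_timeseries(data.frame(time = c(0, 10), f = 0), pop, im,
                         c(0, 10))
  expect_true(all(z[[1]]$truth$assembled_fraction == 0))
})
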