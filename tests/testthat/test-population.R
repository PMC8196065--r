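test_that("population sampling handles degenerate sizes", {
  p0 <- sample_droplet_population(0, c(256, 256), c(1, 20), seed = 1)
  expect_equal(nrow(p0), 0L)
  p1 <- sample_droplet_population(1, c(256, 256), c(5, 5), seed = 1,
                                  partition_sdlog = 0)
  expect_equal(p1$radius_px, 5)
  expect_equal(p1$radius_um, 5)
  m <- 4 # default border margin
  expect_true(p1$center_row - 5 > m && p1$center_row + 5 <= 256 - m)
  expect_true(p1$center_col - 5 > m && p1$center_col + 5 <= 256 - m)
})

test_that("droplets never overlap and never touch the border", {
  pop <- sample_droplet_population(50, c(768, 768), c(1, 20), seed = 9)
  expect_equal(nrow(pop), 50L)
  # exhaustive pairwise check
  for (i in 1:49) for (j in (i + 1):50) {
    d <- sqrt((pop$center_row[i] - pop$center_row[j])^2 +
                (pop$center_col[i] - pop$center_col[j])^2)
    expect_gt(d, pop$radius_px[i] + pop$radius_px[j])
  }
  expect_true(all(pop$center_row - pop$radius_px > 4))
  expect_true(all(pop$center_col + pop$radius_px <= 768 - 4))
  expect_true(all(pop$radius_um >= 1 & pop$radius_um <= 20))
})

test_that("impossible packings fail with an informative error", {
  expect_error(
    sample_droplet_population(80, c(128, 128), c(15, 20), seed = 2,
                              max_attempts = 50),
    "placed \\d+ of 80")
  expect_error(
    sample_droplet_population(1, c(30, 30), c(20, 20), seed = 1),
    "frame too small")
})

test_that("populations are reproducible and partitioning noise works", {
  a <- sample_droplet_population(20, c(512, 512), c(2, 15), seed = 7)
  b <- sample_droplet_population(20, c(512, 512), c(2, 15), seed = 7)
  expect_identical(a, b)
  c <- sample_droplet_population(20, c(512, 512), c(2, 15), seed = 8)
  expect_false(identical(a$center_row, c$center_row))
  # lognormal partitioning jitter has roughly unit mean
  big <- sample_droplet_population(300, c(4096, 4096), c(2, 10),
                                   seed = 3, partition_sdlog = 0.2)
  expect_gt(mean(big$tile_total), 450)
  expect_lt(mean(big$tile_total), 550)
  expect_gt(sd(big$tile_total / 500), 0.1)
  none <- sample_droplet_population(5, c(512, 512), c(2, 15), seed = 3,
                                    partition_sdlog = 0)
  expect_true(all(none$tile_total == 500))
})

test_that("radii are spread across the log range", {
  pop <- sample_droplet_population(400, c(4096, 4096), c(1, 16),
                                   seed = 13)
  lr <- log(pop$radius_um)
  # log-uniform: quartiles of log radius are evenly spaced
  q <- quantile(lr, c(0.25, 0.5, 0.75))
  expect_lt(abs((q[2] - q[1]) - (q[3] - q[2])), 0.35)
})
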