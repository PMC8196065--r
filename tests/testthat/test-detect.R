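test_that("degenerate images yield empty detection tables, not errors", {
  expect_equal(nrow(detect_droplets(matrix(100, 64, 64))), 0L)
  set.seed(1)
  noise <- matrix(rnorm(64^2, 200, 10), 64, 64)
  expect_equal(nrow(detect_droplets(noise)), 0L)
  expect_error(detect_droplets(array(1, c(4, 4, 2))), "2D")
  expect_error(detect_droplets(1:10), "2D")
})

test_that("an isolated droplet is localized precisely", {
  pop <- sample_droplet_population(1, c(200, 200), c(15, 15), seed = 31,
                                   assembled_fraction = 0,
                                   partition_sdlog = 0)
  fr <- render_frame(pop, imaging_params(rng_seed = 31,
                                         read_noise_sd = 2))
  det <- detect_droplets(fr$image)
  expect_equal(nrow(det), 1L)
  err <- sqrt((det$center_row - pop$center_row)^2 +
                (det$center_col - pop$center_col)^2)
  expect_lt(err, 2)
  expect_lt(abs(det$radius_px - pop$radius_px) / pop$radius_px, 0.1)
  expect_gte(det$n_pixels, 50)
})

test_that("detections respect the non-overlap property after suppression", {
  fr <- small_scene()
  det <- detect_droplets(fr$image)
  expect_gt(nrow(det), 1L)
  for (i in seq_len(nrow(det) - 1L)) {
    for (j in (i + 1L):nrow(det)) {
      d <- sqrt((det$center_row[i] - det$center_row[j])^2 +
                  (det$center_col[i] - det$center_col[j])^2)
      expect_gte(d, 0.5 * (det$radius_px[i] + det$radius_px[j]))
    }
  }
})

test_that("detection is invariant under positive affine rescaling", {
  fr <- small_scene()
  det1 <- detect_droplets(fr$image)
  det2 <- detect_droplets(3.7 * fr$image + 450)
  expect_equal(nrow(det1), nrow(det2))
  o1 <- order(det1$center_row); o2 <- order(det2$center_row)
  expect_equal(det1$center_row[o1], det2$center_row[o2], tolerance = 1e-6)
  expect_equal(det1$radius_px[o1], det2$radius_px[o2], tolerance = 1e-6)
})

test_that("border-touching droplets are excluded", {
  fr <- small_scene()
  det <- detect_droplets(fr$image, detection_config(border_margin_px = 4))
  expect_true(all(det$center_row - det$radius_px > 4))
  expect_true(all(det$center_row + det$radius_px <= nrow(fr$image) - 4))
})

test_that("the threshold fallback finds clean droplets", {
  pop <- sample_droplet_population(3, c(256, 256), c(10, 16), seed = 33,
                                   assembled_fraction = 0,
                                   partition_sdlog = 0)
  fr <- render_frame(pop, imaging_params(rng_seed = 33))
  det <- detect_droplets(fr$image, method = "threshold")
  m <- match_droplets(fr$truth, det)
  expect_gte(m$recall, 2 / 3)
})

test_that("pixel extraction matches brute-force disk enumeration", {
  img <- matrix(seq_len(40 * 40), 40, 40)
  ctr <- c(20.3, 19.6); r <- 10
  px <- extract_droplet_pixels(img, ctr, r, 0.1)
  brute <- c()
  for (i in 1:40) for (j in 1:40) {
    if (sqrt((i - ctr[1])^2 + (j - ctr[2])^2) < 0.9 * r) {
      brute <- c(brute, img[i, j])
    }
  }
  expect_setequal(px, brute)
  expect_length(px, length(brute))
  # single-pixel disk
  one <- extract_droplet_pixels(img, c(20, 20), 0.9, 0)
  expect_equal(one, img[20, 20])
  expect_error(extract_droplet_pixels(img, c(2, 2), 10, 0.1), "outside")
})

test_that("greedy truth matching scores recall and precision sensibly", {
  truth <- data.frame(center_row = c(50, 120), center_col = c(50, 120),
                      radius_px = c(10, 12))
  det <- data.frame(center_row = c(51, 200), center_col = c(50, 200),
                    radius_px = c(10.5, 8))
  m <- match_droplets(truth, det)
  expect_equal(nrow(m$matches), 1L)
  expect_equal(m$recall, 0.5)
  expect_equal(m$precision, 0.5)
  expect_equal(m$mean_center_error, 1)
})
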