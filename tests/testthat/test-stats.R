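test_that("droplet summaries report moments or an exclusion reason", {
  s <- summarize_droplet(c(10, 10, 11, 12, 40, 10, 11), mode = "pixels")
  expect_equal(s$skewness, oracle_g1(c(10, 10, 11, 12, 40, 10, 11)))
  expect_true(is.na(s$excluded_reason))
  const <- summarize_droplet(rep(7, 100), mode = "pixels")
  expect_equal(const$excluded_reason, "zero variance")
  expect_true(is.na(const$skewness))
  tiny <- summarize_droplet(c(1, 2), mode = "pixels")
  expect_equal(tiny$excluded_reason, "too few values")
  # unique mode collapses a constant droplet to a single bin -> excluded
  u <- summarize_droplet(c(7, 7, 7, 7.2, 7.4), mode = "unique")
  expect_equal(u$excluded_reason, "too few values")
})

test_that("unique and pixels modes genuinely differ on skewed occupancy", {
  # many pixels at one level, few at others: occupancy weights matter
  x <- c(rep(100, 500), 150, 200, 250, 300)
  su <- summarize_droplet(x, mode = "unique")
  sp <- summarize_droplet(x, mode = "pixels")
  expect_equal(su$n_values, 5L)
  expect_gt(abs(su$skewness - sp$skewness), 0.5)
  # the unique list is the uniform set of levels -> near-zero skewness
  expect_lt(abs(su$skewness), 1)
  expect_gt(sp$skewness, 5)
})

test_that("population aggregation reports mean and sample SD", {
  s <- data.frame(skewness = c(0.5, 1.5), excess_kurtosis = c(0, 1),
                  excluded_reason = NA_character_)
  tp <- aggregate_population(s, 30)
  expect_equal(tp$mean_skewness, 1)
  expect_equal(tp$sd_skewness, sd(c(0.5, 1.5)))
  expect_equal(round(tp$sd_skewness, 4), 0.7071)
  one <- aggregate_population(
    data.frame(skewness = 0.7, excess_kurtosis = 0.2,
               excluded_reason = NA_character_), 5)
  expect_equal(one$sd_skewness, 0)
  expect_true(one$single_droplet)
  set.seed(22)
  big <- data.frame(skewness = rnorm(100), excess_kurtosis = rnorm(100),
                    excluded_reason = NA_character_)
  tp2 <- aggregate_population(big, 1)
  expect_equal(tp2$mean_skewness, sum(big$skewness) / 100)
  expect_equal(tp2$sd_skewness,
               sqrt(sum((big$skewness - mean(big$skewness))^2) / 99))
  excl <- rbind(big, data.frame(skewness = NA, excess_kurtosis = NA,
                                excluded_reason = "zero variance"))
  expect_equal(aggregate_population(excl, 1)$n_excluded, 1L)
  all_bad <- data.frame(skewness = NA_real_, excess_kurtosis = NA_real_,
                        excluded_reason = "zero variance")
  expect_error(aggregate_population(all_bad, 99), "99")
})

test_that("timecourses are sorted and reject duplicate timestamps", {
  tps <- lapply(c(30, 10, 20), function(t) {
    aggregate_population(
      data.frame(skewness = t / 10, excess_kurtosis = 0,
                 excluded_reason = NA_character_), t)
  })
  tc <- build_timecourse(tps)
  expect_equal(tc$time_min, c(10, 20, 30))
  expect_equal(tc$mean_skewness, c(1, 2, 3))
  dup <- c(tps, tps[2])
  expect_error(build_timecourse(dup), "duplicate")
  single <- build_timecourse(tps[1])
  expect_equal(nrow(single), 1L)
})

test_that("per-droplet summaries are exposure-invariant through the stack", {
  fr <- small_scene()
  det <- detect_droplets(fr$image)
  s1 <- summarize_frame(det, mode = "pixels")
  det2 <- det
  det2$pixel_values <- lapply(det$pixel_values, function(v) 2.5 * v + 30)
  s2 <- summarize_frame(det2, mode = "pixels")
  expect_equal(s1$skewness, s2$skewness, tolerance = 1e-9)
  expect_equal(s1$excess_kurtosis, s2$excess_kurtosis, tolerance = 1e-9)
})
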