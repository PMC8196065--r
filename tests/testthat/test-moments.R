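test_that("skewness and kurtosis match hand-computable cases", {
  expect_equal(sample_skewness(c(1, 2, 3, 4, 5)), 0)
  expect_equal(sample_skewness(c(0, 0, 0, 1)), oracle_g1(c(0, 0, 0, 1)))
  expect_equal(sample_excess_kurtosis(c(0, 0, 1, 1, 5)),
               oracle_g2(c(0, 0, 1, 1, 5)))
})

test_that("estimators agree with the direct-formula oracle on random lists", {
  set.seed(101)
  for (i in 1:200) {
    n <- sample(5:200, 1)
    x <- switch(1 + i %% 3,
                rnorm(n, 100, 25),
                rexp(n, 0.05),
                sample.int(50, n, replace = TRUE))
    if (max(x) == min(x)) next
    expect_equal(sample_skewness(x), oracle_g1(x), tolerance = 1e-12)
    expect_equal(sample_excess_kurtosis(x), oracle_g2(x),
                 tolerance = 1e-12)
  }
})

test_that("bias-corrected estimators match e1071's type-2 convention", {
  skip_if_not_installed("e1071")
  set.seed(7)
  x <- rexp(500)
  expect_equal(sample_skewness(x), e1071::skewness(x, type = 2),
               tolerance = 1e-12)
  expect_equal(sample_excess_kurtosis(x), e1071::kurtosis(x, type = 2),
               tolerance = 1e-12)
})

test_that("analytic distribution limits are recovered", {
  set.seed(11)
  x <- rexp(1e5)
  expect_lt(abs(sample_skewness(x) - 2),
            2 * block_se(x, sample_skewness) + 0.02)
  z <- rnorm(1e5)
  expect_lt(abs(sample_skewness(z)), 0.03)
  expect_lt(abs(sample_excess_kurtosis(z)), 0.06)
  u <- runif(1e5)
  expect_lt(abs(sample_excess_kurtosis(u) + 1.2), 0.04)
})

test_that("moments are invariant under positive affine rescaling", {
  set.seed(3)
  for (i in 1:20) {
    x <- rexp(500, 0.01)
    a <- runif(1, 0.1, 50); b <- runif(1, -100, 100)
    expect_equal(sample_skewness(a * x + b), sample_skewness(x),
                 tolerance = 1e-9)
    expect_equal(sample_excess_kurtosis(a * x + b),
                 sample_excess_kurtosis(x), tolerance = 1e-9)
  }
})

test_that("plain (uncorrected) estimators are available", {
  x <- c(1, 1, 2, 8)
  d <- x - mean(x)
  expect_equal(sample_skewness(x, bias_correct = FALSE),
               mean(d^3) / mean(d^2)^1.5)
  expect_equal(sample_excess_kurtosis(x, bias_correct = FALSE),
               mean(d^4) / mean(d^2)^2 - 3)
})

test_that("degenerate samples are rejected", {
  expect_error(sample_skewness(c(1, 2)), "at least 3")
  expect_error(sample_excess_kurtosis(c(1, 2, 3)), "at least 4")
  expect_error(sample_skewness(rep(5, 10)), "zero variance")
  expect_error(sample_skewness(c(1, 2, NA, 4)), "NA")
})

test_that("unique-value reduction follows the histogram procedure", {
  expect_equal(unique_value_reduction(c(5, 5, 5, 7)), c(5, 7))
  expect_equal(unique_value_reduction(rep(3, 10)), 3)
  expect_equal(unique_value_reduction(c(0.2, 0.9, 1.4), bin_width = 0.5),
               c(0, 0.5, 1))
  set.seed(19)
  for (i in 1:50) {
    x <- runif(200, 0, 300)
    w <- sample(c(0.5, 1, 2, 5), 1)
    expect_equal(unique_value_reduction(x, w), oracle_unique_bins(x, w))
  }
  expect_error(unique_value_reduction(numeric(0)), "empty")
  expect_error(unique_value_reduction(1:5, bin_width = 0))
})
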