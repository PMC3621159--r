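test_that("bland_altman returns mean difference and twice the sample SD", {
  expect_equal(bland_altman(c(10, 20, 30), c(12, 22, 32)),
               list(bias = 2, precision = 0))
  x <- rnorm(10)
  expect_equal(bland_altman(x, x), list(bias = 0, precision = 0))
  # hand computation with the n-1 standard deviation
  expect_equal(bland_altman(c(0, 0), c(-1, 1)),
               list(bias = 0, precision = 2 * sqrt(2)))
  expect_error(bland_altman(1:3, 1:4), "length")
})

test_that("r_squared is the squared Pearson correlation", {
  x <- c(1, 2, 4, 8)
  expect_equal(r_squared(x, 2 * x + 1), 1)
  expect_error(r_squared(x, rep(3, 4)), "variance")
  # brute-force formula on a worked four-point set
  y <- c(2.3, 1.9, 5.2, 7.8)
  num <- sum((x - mean(x)) * (y - mean(y)))
  r2 <- (num / sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2)))^2
  expect_equal(r_squared(x, y), r2, tolerance = 1e-12)
})

test_that("percentage errors summarise with interpolated percentiles", {
  expect_equal(percentage_error_stats(c(50, 80), c(50, 80)),
               list(median = 0, p5 = 0, p95 = 0))
  expect_equal(percentage_error_stats(100, 110),
               list(median = 10, p5 = 10, p95 = 10))
  set.seed(3)
  m <- runif(20, 50, 150)
  f <- m * (1 + rnorm(20, 0, 0.1))
  e <- sort(100 * abs(f - m) / m)
  got <- percentage_error_stats(m, f)
  expect_equal(got$median, unname(quantile(e, 0.5)))
  expect_equal(got$p5, unname(quantile(e, 0.05)))
  expect_equal(got$p95, unname(quantile(e, 0.95)))
  expect_true(got$p5 <= got$median && got$median <= got$p95)
  expect_error(percentage_error_stats(c(0, 1), c(1, 1)), "nonzero")
})

test_that("metrics are invariant to the order of paired observations", {
  set.seed(11)
  m <- runif(15, 10, 90)
  f <- m + rnorm(15)
  o <- sample(15)
  expect_equal(bland_altman(m, f), bland_altman(m[o], f[o]))
  expect_equal(r_squared(m, f), r_squared(m[o], f[o]))
  expect_equal(percentage_error_stats(m, f),
               percentage_error_stats(m[o], f[o]))
})

test_that("coupling and afterload ratios follow their definitions", {
  expect_equal(rvac(1.3, 1.3), 1)
  # standard initial pulmonary values at a 0.5 s beat
  expect_equal(afterload_metric(0.03, 0.4, 0.5), 0.86)
  expect_equal(rvac(0.8, 0.86), 0.8 / 0.86, tolerance = 1e-12)
  expect_equal(rvac(2 * 0.8, 2 * 0.86), 0.8 / 0.86, tolerance = 1e-12)
  expect_equal(afterload_metric(0.03, 0.4, 1), 0.43)
  expect_error(afterload_metric(0.03, 0.4, 0), "positive")
  expect_error(rvac(1, 0), "positive")
})

test_that("agreement_report aggregates per quantity", {
  d <- tibble::tibble(
    quantity = rep(c("LVEDV", "RVEDV"), each = 4),
    measured = c(100, 110, 90, 105, 80, 85, 95, 90),
    modelled = c(102, 108, 93, 104, 84, 83, 98, 95))
  rep <- agreement_report(d)
  expect_equal(nrow(rep), 2)
  lv <- rep[rep$quantity == "LVEDV", ]
  ba <- bland_altman(d$measured[1:4], d$modelled[1:4])
  expect_equal(lv$bias, ba$bias)
  expect_equal(lv$precision, ba$precision)
  expect_equal(lv$n, 4)
})
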