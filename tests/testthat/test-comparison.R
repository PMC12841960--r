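test_that("Passing-Bablok recovers exact lines", {
  pb <- passing_bablok(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_identical(pb$slope, 1)
  expect_identical(pb$intercept, 0)
  pb <- passing_bablok(c(1, 2, 3, 4, 5), c(3, 5, 7, 9, 11))
  expect_identical(pb$slope, 2)
  expect_identical(pb$intercept, 1)
})

test_that("Passing-Bablok equals the exhaustive enumeration oracle", {
  set.seed(31)
  for (k in 1:30) {
    n <- sample(4:10, 1)
    x <- round(runif(n, 0, 100), 1)
    y <- round(0.9 * x + rnorm(n, sd = 8), 1)  # rounding induces ties
    pb <- passing_bablok(x, y)
    or <- pb_oracle(x, y)
    expect_identical(pb$slope, or$slope)
    expect_identical(pb$intercept, or$intercept)
  }
})

test_that("Passing-Bablok is scale-equivariant and symmetric", {
  # strict equivariance requires no pairwise slope to cross -1 under
  # rescaling (the K offset counts slopes below -1), so use co-monotone
  # data where every pairwise slope is positive
  set.seed(17)
  x <- seq(10, 100, length.out = 15)
  y <- 1.4 * x + runif(15, -0.4, 0.4)
  pb <- passing_bablok(x, y)
  for (cc in c(0.5, 2, 10)) {
    pbc <- passing_bablok(x, cc * y)
    expect_equal(pbc$slope, cc * pb$slope, tolerance = 1e-12)
    expect_equal(pbc$intercept, cc * pb$intercept, tolerance = 1e-12)
  }
  # slope(x->y) * slope(y->x) = 1 on tie-free data with an odd slope count
  x7 <- x[1:7]; y7 <- y[1:7]
  expect_equal(passing_bablok(x7, y7)$slope * passing_bablok(y7, x7)$slope,
               1, tolerance = 1e-12)
})

test_that("Passing-Bablok confidence bounds are ordered and cover the estimate", {
  set.seed(23)
  x <- exp(rnorm(61, log(261), 1))
  y <- x - 91 + rnorm(61, sd = 15)
  pb <- passing_bablok(x, y)
  expect_lt(pb$slope_ci[1], pb$slope_ci[2])
  expect_true(pb$slope_ci[1] <= pb$slope && pb$slope <= pb$slope_ci[2])
  expect_lt(pb$intercept_ci[1], pb$intercept_ci[2])
  expect_true(pb$intercept_ci[1] <= pb$intercept &&
                pb$intercept <= pb$intercept_ci[2])
  # below n = 10, point estimates only
  expect_true(all(is.na(passing_bablok(x[1:8], y[1:8])$slope_ci)))
})

test_that("Passing-Bablok rejects degenerate inputs", {
  expect_error(passing_bablok(c(1, 1, 1), c(1, 2, 3)),
               class = "freehb_estimation_error")
  expect_error(passing_bablok(c(1, 2), c(1, 2)),
               class = "freehb_estimation_error")
  # all pairs identical or on slope -1
  expect_error(passing_bablok(c(1, 2, 3), c(4, 3, 2)),
               class = "freehb_estimation_error")
})

test_that("Bland-Altman reproduces hand-computed quantities", {
  ba0 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ba0$bias, 0)
  expect_identical(ba0$loa_low, 0)
  expect_identical(ba0$loa_high, 0)
  # d = (1, 2, 3): bias 2, sd 1
  ba <- bland_altman(c(2, 4, 6), c(1, 2, 3))
  expect_identical(ba$bias, 2)
  expect_identical(ba$sd_diff, 1)
  expect_equal(ba$loa_low, 2 - 1.96, tolerance = 1e-12)
  expect_equal(ba$loa_high, 2 + 1.96, tolerance = 1e-12)
  half <- qt(0.975, df = 2) / sqrt(3)
  expect_equal(ba$bias_ci, c(2 - half, 2 + half), tolerance = 1e-12)
  expect_error(bland_altman(1, 2), class = "freehb_estimation_error")
})

test_that("limits of agreement contain ~95% of normal differences", {
  set.seed(404)
  d <- rnorm(10000)
  ba <- bland_altman(d, rep(0, 10000))
  inside <- mean(d >= ba$loa_low & d <= ba$loa_high)
  expect_gt(inside, 0.94)
  expect_lt(inside, 0.96)
  # width identity: 2 * multiplier * sd
  expect_equal(ba$loa_high - ba$loa_low, 2 * 1.96 * sd(d), tolerance = 1e-12)
})

test_that("Spearman rho handles monotone data and ties", {
  expect_identical(spearman_rank(1:10, (1:10)^3)$rho, 1)
  expect_identical(spearman_rank(1:10, -(1:10))$rho, -1)
  expect_identical(spearman_rank(1:10, (1:10)^3)$p_value, 0)
  # frozen mid-rank arithmetic: ranks y = (1.5, 1.5, 3, 5, 4, 6)
  x <- 1:6
  y <- c(2, 2, 3, 5, 4, 7)
  sp <- spearman_rank(x, y)
  expect_equal(sp$rho, 16 / sqrt(297.5), tolerance = 1e-12)
  # cross-check against the standard routine
  expect_equal(sp$rho, suppressWarnings(cor.test(x, y, method = "spearman"))$estimate[[1]],
               tolerance = 1e-12)
  expect_error(spearman_rank(rep(1, 5), 1:5), class = "freehb_estimation_error")
})

test_that("Spearman CI and p behave sensibly on noisy data", {
  set.seed(9)
  x <- rnorm(61)
  y <- x + rnorm(61)
  sp <- spearman_rank(x, y)
  expect_true(sp$rho_ci[1] < sp$rho && sp$rho < sp$rho_ci[2])
  expect_lt(sp$p_value, 0.001)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(sp$rho, ref$estimate[[1]], tolerance = 1e-12)
})

test_that("compare_methods assembles the full panel with tidy/glance views", {
  co <- simulate_cohort(n = 61, seed = 3)
  cmp <- compare_methods(co, fhb, efhb)
  td <- tidy(cmp)
  expect_setequal(td$term, c("pb_intercept", "pb_slope", "spearman_rho",
                             "ba_bias", "ba_loa_low", "ba_loa_high"))
  gl <- glance(cmp)
  expect_equal(nrow(gl), 1)
  expect_identical(gl$n, 61L)
  # agreement ordering invariant
  expect_true(gl$ba_loa_low <= gl$ba_bias && gl$ba_bias <= gl$ba_loa_high)
  # difference direction is reference minus comparator
  expect_identical(gl$ba_bias, mean(co$fhb - co$efhb))
  expect_s3_class(autoplot(cmp), "ggplot")
  expect_s3_class(autoplot(cmp, type = "bland_altman"), "ggplot")
  expect_output(print(cmp), "Passing-Bablok")
})
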