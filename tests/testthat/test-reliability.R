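test_that("ICC(2,1) matches the ANOVA oracle and known values", {
  # the classic 6-target x 4-judge single-score dataset
  x <- matrix(c(9, 2, 5, 8,
                6, 1, 3, 2,
                8, 4, 6, 8,
                7, 1, 2, 6,
                10, 5, 6, 9,
                6, 2, 4, 7), nrow = 6, byrow = TRUE)
  r <- icc_2_1(x)
  expect_equal(r$icc, aov_icc21(x), tolerance = 1e-12)
  expect_equal(r$icc, 0.2897638, tolerance = 1e-6)
  # stored mean squares reproduce the ICC exactly
  expect_equal(r$icc, (r$MSR - r$MSE) /
                 (r$MSR + (r$k - 1) * r$MSE + r$k * (r$MSC - r$MSE) / r$n))
  # perfect agreement
  y <- matrix(rep(c(1, 2, 3), 3), ncol = 3)
  expect_identical(icc_2_1(y)$icc, 1)
  # degenerate variance raises, never a sentinel
  expect_error(icc_2_1(matrix(5, 4, 3)), "undefined|constant")
  expect_error(icc_2_1(matrix(1:3, 1, 3)), "at least 2")
})

test_that("ICC is invariant to shift and positive scaling", {
  set.seed(21)
  for (i in 1:20) {
    x <- matrix(rnorm(15, 5, 2), 5, 3)
    base <- icc_2_1(x)$icc
    expect_equal(icc_2_1(x + 7.3)$icc, base, tolerance = 1e-12)
    expect_equal(icc_2_1(x * 2.6)$icc, base, tolerance = 1e-12)
    expect_equal(icc_2_1(x)$icc, aov_icc21(x), tolerance = 1e-10)
  }
})

test_that("missing targets are dropped listwise with a message", {
  x <- matrix(rnorm(15, 5, 2), 5, 3)
  x[2, 3] <- NA
  expect_message(r <- icc_2_1(x), "1 targets dropped")
  expect_identical(r$n, 4L)
  expect_equal(r$icc, icc_2_1(x[-2, ])$icc)
})

test_that("Bland-Altman summaries match hand calculations", {
  ba <- bland_altman(c(2, 3, 4), c(2, 5, 4))
  expect_equal(ba$mean_difference, -2 / 3)
  expect_equal(ba$sd_difference, 1.1547005, tolerance = 1e-6)
  expect_equal(ba$upper_limit, -2 / 3 + 2 * ba$sd_difference)
  expect_equal(ba$lower_limit, -2 / 3 - 2 * ba$sd_difference)
  expect_equal(ba$points$mean, c(2, 4, 4))
  expect_equal(ba$points$difference, c(0, -2, 0))
  # identical pairs: zero difference and spread
  ba2 <- bland_altman(c(1, 2, 3), c(1, 2, 3))
  expect_identical(ba2$mean_difference, 0)
  expect_identical(ba2$sd_difference, 0)
  # zero measurements (no contact stress) are omitted and counted
  ba3 <- bland_altman(c(0, 2, 3, 4), c(3, 2, 5, 4))
  expect_identical(ba3$n_omitted_zeros, 1L)
  expect_identical(nrow(ba3$points), 3L)
  expect_error(bland_altman(c(0, 2), c(1, 2)), "fewer than 2")
})

test_that("Bland-Altman limits cover ~95% of normal differences", {
  set.seed(33)
  a <- rnorm(1000, 5, 1)
  b <- a + rnorm(1000, 0.2, 0.5)
  ba <- bland_altman(a, b)
  inside <- mean(ba$points$difference >= ba$lower_limit &
                   ba$points$difference <= ba$upper_limit)
  expect_gt(inside, 0.90)
  expect_lt(inside, 0.99)
})

test_that("simulated ratings recover the population ICC", {
  r <- simulate_ratings(100, 3, 2, c(9, 0.5, 0.5), seed = 8)
  expect_equal(attr(r, "population_icc"), 0.9)
  expect_identical(r, simulate_ratings(100, 3, 2, c(9, 0.5, 0.5), seed = 8))
  r2 <- simulate_ratings(100, 3, 2, c(9, 0.5, 0.5), seed = 9)
  expect_false(identical(r$value_mpa, r2$value_mpa))
  # day-1 interrater slice estimates the population value
  w <- stats::reshape(r[r$day == 1, c("knee_id", "rater_id", "value_mpa")],
                      idvar = "knee_id", timevar = "rater_id",
                      direction = "wide")
  expect_equal(icc_2_1(as.matrix(w[, -1]))$icc, 0.9, tolerance = 0.05)
  # no rater or error variance: perfect reliability
  r0 <- simulate_ratings(10, 3, 2, c(4, 0, 0), seed = 2)
  w0 <- stats::reshape(r0[r0$day == 1, c("knee_id", "rater_id", "value_mpa")],
                       idvar = "knee_id", timevar = "rater_id",
                       direction = "wide")
  expect_equal(icc_2_1(as.matrix(w0[, -1]))$icc, 1, tolerance = 1e-9)
})

test_that("reliability report has the study's table shape", {
  st <- simulate_ratings_study(10, seed = 5)
  rep_ <- reliability_report(st)
  expect_identical(nrow(rep_$table), 4L)
  expect_identical(names(rep_$table),
                   c("reliability", "compartment", "peak", "mean"))
  expect_setequal(rep_$table$reliability,
                  c("day-to-day", "interrater"))
  expect_true(all(is.finite(unlist(rep_$table[, c("peak", "mean")]))))
  # a noiseless study gives ICC = 1 in every cell
  st0 <- simulate_ratings_study(10, variance_components = c(4, 0, 0),
                                seed = 6)
  rep0 <- reliability_report(st0)
  expect_equal(unlist(rep0$table[, c("peak", "mean")]),
               rep(1, 8), tolerance = 1e-9, ignore_attr = TRUE)
  # a missing design arm yields NA cells, not an error
  part <- st[st$compartment == "medial", ]
  repp <- reliability_report(part)
  expect_true(all(is.na(
    repp$table[repp$table$compartment == "lateral", c("peak", "mean")])))
})
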