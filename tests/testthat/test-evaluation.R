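test_that("a perfect estimator zeroes every error index", {
  a <- c(100, 110, 125, 140)
  m <- regression_metrics(a, a)
  expect_identical(m$mae, 0)
  expect_identical(m$mse, 0)
  expect_identical(m$rmse, 0)
  expect_identical(m$me, 0)
  expect_identical(m$std, 0)
  expect_equal(m$r2, 1)
})

test_that("the two-pair worked example evaluates by hand", {
  m <- regression_metrics(c(100, 120), c(110, 110))
  expect_equal(m$me, 0)
  expect_equal(m$mae, 10)
  expect_equal(m$mse, 100)
  expect_equal(m$rmse, 10)
  expect_equal(m$std, sqrt(200), tolerance = 1e-9)  # 14.1421
  expect_equal(m$bp_bar, 110)
})

test_that("all six indices match a straight-from-formula oracle", {
  set.seed(42)
  a <- rnorm(1000, 120, 15)
  e <- a + rnorm(1000, 1, 6)
  m <- regression_metrics(a, e)
  err <- a - e
  expect_equal(m$r2, 1 - sum(err^2) / sum((a - mean(a))^2), tolerance = 1e-9)
  expect_equal(m$mae, sum(abs(err)) / 1000, tolerance = 1e-9)
  expect_equal(m$mse, sum(err^2) / 1000, tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(sum(err^2) / 1000), tolerance = 1e-9)
  expect_equal(m$me, sum(err) / 1000, tolerance = 1e-9)
  expect_equal(m$std, sqrt(sum((err - mean(err))^2) / 999), tolerance = 1e-9)
  expect_equal(m$rmse, sqrt(m$mse), tolerance = 1e-12)
  expect_lte(m$mae, m$rmse)
})

test_that("degenerate metric inputs are handled explicitly", {
  expect_error(regression_metrics(1:3, 1:4), "same length")
  m <- regression_metrics(rep(100, 5), c(99, 101, 100, 98, 102))
  expect_true(is.na(m$r2))
  expect_match(m$r2_note, "undefined")
})

test_that("the published AAMI rows pass and boundaries behave", {
  expect_true(aami_check(0.533, 4.175, 125)$pass)
  expect_true(aami_check(-0.299, 2.441, 125)$pass)
  expect_true(aami_check(-0.049, 2.188, 125)$pass)
  v <- aami_check(0, 0, 84)
  expect_false(v$pass)
  expect_length(v$reasons, 1)
  expect_match(v$reasons, "subjects")
  # inclusive limits: exactly 5 / 8 / 85 still passes
  expect_true(aami_check(5, 8, 85)$pass)
  expect_false(aami_check(5.001, 8, 85)$pass)
  expect_false(aami_check(-5.001, 8, 85)$pass)
  expect_false(aami_check(0, 8.001, 85)$pass)
})

test_that("BHS grading reproduces the published percentages and boundaries", {
  # error vector engineered to 91 / 95 / 99 % within 5 / 10 / 15 mmHg
  abs_err <- c(rep(4, 91), rep(9, 4), rep(14, 4), rep(20, 1))
  g <- bhs_grade(rep(120, 100), 120 - abs_err)
  expect_equal(unname(g$cumulative), c(91, 95, 99))
  expect_identical(g$grade, "A")
  g2 <- bhs_grade(rep(120, 10), rep(124, 10))  # all |err| = 4
  expect_equal(unname(g2$cumulative), c(100, 100, 100))
  expect_identical(g2$grade, "A")
  # failing only the first Grade-A threshold drops to B
  abs_err3 <- c(rep(4, 599), rep(9, 391), rep(14, 0), rep(20, 10))
  g3 <- bhs_grade(rep(120, 1000), 120 - abs_err3)
  expect_equal(unname(g3$cumulative), c(59.9, 99, 99))
  expect_identical(g3$grade, "B")
  g4 <- bhs_grade(rep(120, 10), rep(150, 10))
  expect_identical(g4$grade, "D")
})

test_that("improving one error never lowers a cumulative percentage or grade", {
  set.seed(5)
  a <- rnorm(60, 120, 10)
  e <- a + rnorm(60, 0, 7)
  g0 <- bhs_grade(a, e)
  worst <- which.max(abs(a - e))
  e2 <- e; e2[worst] <- a[worst]
  g1 <- bhs_grade(a, e2)
  expect_true(all(g1$cumulative >= g0$cumulative))
  expect_lte(match(g1$grade, c("A", "B", "C", "D")),
             match(g0$grade, c("A", "B", "C", "D")))
})

test_that("standards boundaries are recovered by bisection", {
  # minimum 5-mmHg percentage yielding Grade A (10/15-mmHg criteria held)
  grade_at <- function(p5) {
    n <- 1000
    n_in <- round(p5 * n)
    abs_err <- c(rep(1, n_in), rep(8, n - n_in))  # rest within 10 and 15
    bhs_grade(rep(100, n), 100 - abs_err)$grade
  }
  lo <- 0.3; hi <- 0.9
  for (i in 1:12) {
    mid <- round(1000 * (lo + hi) / 2) / 1000
    if (grade_at(mid) == "A") hi <- mid else lo <- mid
  }
  expect_equal(hi * 100, 60, tolerance = 0.2)
  # AAMI |ME| limit by bisection over constructed error vectors
  pass_at_me <- function(me) aami_check(me, 4, 100)$pass
  lo <- 0; hi <- 10
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (pass_at_me(mid)) lo <- mid else hi <- mid
  }
  expect_equal(lo, 5, tolerance = 1e-6)
  # AAMI STD limit
  pass_at_std <- function(s) aami_check(0, s, 100)$pass
  lo <- 0; hi <- 20
  for (i in 1:30) {
    mid <- (lo + hi) / 2
    if (pass_at_std(mid)) lo <- mid else hi <- mid
  }
  expect_equal(lo, 8, tolerance = 1e-6)
  # minimum subject count
  n_min <- Position(function(n) aami_check(0, 0, n)$pass, 1:200)
  expect_identical(n_min, 85L)
})

test_that("Bland-Altman limits follow md +/- 1.96 sd with the stated sign", {
  # constant bias: estimated = actual + 3 -> differences are all -3
  a <- c(100, 110, 120)
  ba <- bland_altman(a, a + 3)
  expect_equal(ba$md, -3)
  expect_equal(ba$sd, 0)
  expect_equal(ba$lower, -3)
  expect_equal(ba$upper, -3)
  # two-pair hand example: differences {0, 2}
  ba2 <- bland_altman(c(100, 102), c(100, 100))
  expect_equal(ba2$md, 1)
  expect_equal(ba2$sd, sqrt(2), tolerance = 1e-9)  # 1.4142
  expect_equal(ba2$lower, 1 - 1.96 * sqrt(2), tolerance = 1e-9)
  expect_equal(ba2$upper, 1 + 1.96 * sqrt(2), tolerance = 1e-9)
  # Gaussian errors: ~95% of points inside the limits
  set.seed(77)
  a <- rnorm(10000, 120, 12)
  ba3 <- bland_altman(a, a + rnorm(10000, 0, 5))
  expect_gte(ba3$fraction_inside, 0.94)
  expect_lte(ba3$fraction_inside, 0.96)
})

test_that("eval_report bundles all four analyses coherently", {
  set.seed(9)
  a <- rnorm(120, 120, 15)
  e <- a + rnorm(120, 0.5, 3)
  r <- eval_report(a, e, n_subjects = 100, target = "SBP")
  expect_identical(r$target, "SBP")
  expect_equal(r$metrics$rmse, sqrt(r$metrics$mse), tolerance = 1e-12)
  expect_identical(r$aami$pass,
                   abs(r$metrics$me) <= 5 && r$metrics$std <= 8)
  expect_true(all(diff(r$bhs$cumulative) >= 0))
  row <- report_row(r)
  expect_identical(nrow(row), 1L)
  expect_identical(row$target, "SBP")
})
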