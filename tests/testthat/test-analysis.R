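test_that("change-of-mind classification follows the motor read-out", {
  tm <- seq(0, 1000, by = 0.5)
  # monotone movement to the target: no change-of-mind
  r <- fake_record(tm, seq(0, 750, length.out = length(tm)),
                   final_choice = 1, correct_side = 1)
  expect_false(classify_change_of_mind(r)$com)
  # initial excursion to -120 then crossing to +750, correct side Right:
  # an error-to-correct change of mind (choice 1 maps to positive x)
  x <- c(seq(0, -120, length.out = 400), seq(-120, 750, length.out = 1601))
  r <- fake_record(tm, x, final_choice = 1, correct_side = 1)
  cls <- classify_change_of_mind(r)
  expect_true(cls$com)
  expect_equal(cls$direction, "error-to-correct")
  # same movement with the other side correct: correct-to-error
  r <- fake_record(tm, x, final_choice = 1, correct_side = 2)
  expect_equal(classify_change_of_mind(r)$direction, "correct-to-error")
  # a sign change without a target reached (indecision) never counts
  r <- fake_record(tm, c(seq(0, -120, length.out = 1000),
                         seq(-120, 60, length.out = 1001)),
                   final_choice = 0, indecision = TRUE, correct_side = 1)
  expect_false(classify_change_of_mind(r)$com)
  r <- fake_record(tm, rep(0, length(tm)), final_choice = 1,
                   correct_side = 1)
  r$x <- NULL
  expect_error(classify_change_of_mind(r), "trace")
})

test_that("uncertainty measures are the peak and the trapezoidal area", {
  tm <- seq(0, 100, by = 0.5)
  r <- fake_record(tm, rep(0, length(tm)), 1, 1, y_U = rep(0, length(tm)))
  m <- uncertainty_measures(r)
  expect_equal(m$peak, 0)
  expect_equal(m$area, 0)
  # triangle of height h over base T: area h*T/2, exactly (trapezoid rule
  # is exact for piecewise-linear traces)
  h <- 4.2
  tri <- c(seq(0, h, length.out = 101), seq(h, 0, length.out = 101)[-1])
  r <- fake_record(seq(0, 200, by = 1), c(tri, rep(0, 0)), 1, 1, y_U = tri)
  m <- uncertainty_measures(r)
  expect_equal(m$peak, h)
  expect_equal(m$area, h * 200 / 2)
  # a zero tail changes neither measure
  tm2 <- seq(0, 400, by = 1)
  r2 <- fake_record(tm2, rep(0, length(tm2)), 1, 1,
                    y_U = c(tri, rep(0, 200)))
  m2 <- uncertainty_measures(r2)
  expect_equal(m2$peak, m$peak)
  expect_equal(m2$area, m$area)
})

test_that("feature scaling maps onto the unit interval", {
  expect_equal(normalize_feature(c(2, 4, 6)), c(0, 0.5, 1))
  v <- rnorm(50)
  nv <- normalize_feature(v)
  expect_equal(nv[which.min(v)], 0)
  expect_equal(nv[which.max(v)], 1)
  # invariance under affine transformation
  expect_equal(normalize_feature(3 * v - 7), nv)
  expect_error(normalize_feature(rep(1, 5)), "distinct")
})

test_that("Weibull fit recovers noiseless psychometric parameters", {
  eps <- c(0, 3.2, 6.4, 12.8, 25.6, 51.2)
  p <- 1 - 0.5 * exp(-(eps / 7.32)^1.32)
  d <- data.frame(epsilon = eps, n_correct = p * 1e6, n_total = 1e6)
  fit <- fit_weibull(d)
  expect_equal(fit$alpha, 7.32, tolerance = 1e-6)
  expect_equal(fit$beta, 1.32, tolerance = 1e-6)
  fit_ls <- fit_weibull(d, method = "ls")
  expect_equal(fit_ls$alpha, 7.32, tolerance = 1e-6)
  # at the threshold the fitted form gives 1 - 0.5/e, not 85%
  expect_equal(1 - 0.5 * exp(-(7.32 / fit$alpha)^fit$beta),
               1 - 0.5 * exp(-1), tolerance = 1e-6)
  expect_error(fit_weibull(d[1:2, ]), "non-zero")
})

test_that("chronometric summary handles sparse cells", {
  s <- data.frame(epsilon = c(3.2, 3.2, 6.4), rt_ms = c(500, 700, 650),
                  correct = c(TRUE, FALSE, TRUE), indecision = FALSE)
  tab <- chronometric_summary(s)
  one <- tab[tab$epsilon == 3.2 & tab$outcome == "error", ]
  expect_equal(one$mean_rt, 700)
  expect_true(is.na(one$sem_rt))
  expect_equal(tab$mean_rt[tab$epsilon == 3.2 & tab$outcome == "correct"],
               500)
})

test_that("change-of-mind curve is an exact partition", {
  s <- data.frame(
    epsilon = rep(c(3.2, 6.4), each = 10),
    com = c(rep(TRUE, 3), rep(FALSE, 7), rep(FALSE, 10)),
    com_direction = c("error-to-correct", "error-to-correct",
                      "correct-to-error", rep("none", 17)),
    indecision = FALSE)
  cc <- com_probability_curve(s)
  expect_equal(cc$p_any, cc$p_to_correct + cc$p_to_error)
  expect_equal(cc$p_any, c(0.3, 0))
  expect_equal(cc$p_to_correct[1], 0.2)
})

test_that("regression on collinear synthetic pairs is perfect", {
  s <- data.frame(epsilon = rep(c(0, 3.2, 6.4), each = 10),
                  rt_ms = 1:30, uncertainty_peak = (1:30) * 2 + 5,
                  indecision = FALSE, correct = TRUE)
  reg <- rt_uncertainty_regression(s)
  expect_equal(reg$trial$pearson_r, 1)
  expect_equal(reg$trial$r_squared, 1)
  expect_equal(reg$trial$slope, 0.5)
  expect_equal(reg$condition$r_squared, 1)
  expect_error(rt_uncertainty_regression(s[1, ]), "3 trials")
})
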