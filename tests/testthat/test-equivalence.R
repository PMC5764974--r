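test_that("calibration fitting recovers exact and noisy lines", {
  x <- c(1, 2, 4, 8, 16)
  cc <- suppressWarnings(fit_calibration(x, 2 * x + 1)) # lm flags exact fit
  expect_equal(cc$slope, 2)
  expect_equal(cc$intercept, 1)
  expect_equal(cc$r2, 1)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")

  # LOD/LOQ follow 3.3 sigma / S and 10 sigma / S
  set.seed(2)
  y <- 5 * x + 3 + rnorm(5, sd = 0.5)
  cn <- fit_calibration(x, y)
  sig <- stats::sigma(lm(y ~ x))
  expect_equal(cn$lod, 3.3 * sig / cn$slope)
  expect_equal(cn$loq, 10 * sig / cn$slope)
})

test_that("the packaged marker calibrations carry the printed parameters", {
  cal <- dbt_calibration()
  expect_named(cal, c("DIOB", "EEA"))
  expect_equal(cal$DIOB$slope, 10185812.57)
  expect_equal(cal$DIOB$intercept, 367287.09)
  expect_equal(cal$DIOB$r2, 0.9993)
  expect_equal(cal$EEA$range, c(20.55, 657.60))
  expect_equal(unname(attr(cal$DIOB, "contents")["S22"]), 0.066)
})

test_that("quantification inverts the calibration line with flags", {
  cc <- calibration_curve(slope = 2, intercept = 100, range = c(5, 200),
                          lod = 1, loq = 3)
  expect_equal(quantify(100, cc)$conc_ugml, 0)
  expect_true(quantify(100, cc)$below_lod)
  expect_equal(quantify(2 * 100 + 100, cc)$conc_ugml, 100)
  # round trip over the packaged DIOB range
  diob <- dbt_calibration()$DIOB
  x <- seq(diob$range[1], diob$range[2], length.out = 25)
  resp <- diob$slope * x + diob$intercept
  expect_equal(quantify(resp, diob)$conc_ugml, x, tolerance = 1e-9)
})

test_that("marker dose is content times extract dose", {
  expect_equal(hecm_dose(0, 2000), 0)
  expect_equal(hecm_dose(0.066, 2000), 132)
  expect_equal(hecm_dose(1, 123), 123)
  expect_error(hecm_dose(1.2, 100))
})

test_that("equivalence CI matches the hand-computed example", {
  # zero within-group variance: CI collapses to the exact ratio
  eq0 <- equivalence_test(rep(100, 5), rep(100, 5))
  expect_equal(eq0$ratio_ci, c(1, 1))
  expect_true(eq0$equivalent)

  # n1 = n2 = 5, log-mean difference 0.1, sigma_w = 0.2:
  # half-width = qt(.95, 8) * 0.2 * sqrt(0.5 * (1/5 + 1/5)) = 0.166325
  # so CI = exp(0.1 -/+ 0.166325) = (0.93583, 1.30516)
  # construct groups with exact log-means and exact sigma_w = 0.2
  base <- c(-2, -1, 0, 1, 2)
  base <- base / sqrt(sum(base^2) / 4)       # sample sd 1, mean 0
  lg1 <- 0.1 + base * 0.2
  lg2 <- 0 + base * 0.2
  eq <- equivalence_test(exp(lg1), exp(lg2))
  expect_equal(eq$sigma_w, 0.2)
  expect_equal(eq$t_quantile, qt(0.95, 8))
  expect_equal(round(eq$ratio_ci, 4), c(0.9358, 1.3052))
  expect_true(eq$equivalent)

  # textbook SE drops the 1/2: wider interval
  eqt <- equivalence_test(exp(lg1), exp(lg2), se = "textbook")
  expect_gt(eqt$ratio_ci[2] - eqt$ratio_ci[1],
            eq$ratio_ci[2] - eq$ratio_ci[1])

  # a 2-fold ratio with small variance is not equivalent
  g <- generate_equivalence_groups(2.0, cv = 0.05, n = 8, seed = 3)
  eq2 <- equivalence_test(g$candidate, g$original)
  expect_gt(eq2$ratio_ci[1], 1.43)
  expect_false(eq2$equivalent)

  expect_error(equivalence_test(c(-1, 2, 3), c(1, 2, 3)))
})

test_that("equivalence decision is strict containment in (0.70, 1.43)", {
  expect_true(equivalence_decision(c(0.999, 1.256))$equivalent)
  expect_equal(equivalence_decision(c(0.999, 1.256))$report, "99.9-125.6%")
  expect_false(equivalence_decision(c(0.65, 1.20))$equivalent)
  expect_false(equivalence_decision(c(0.70, 1.43))$equivalent)
})

test_that("CI structure follows the geometric means and group swap", {
  set.seed(9)
  for (i in 1:10) {
    a <- rlnorm(7, 8, 0.3); b <- rlnorm(9, 8.2, 0.25)
    eq <- equivalence_test(a, b)
    gm <- exp(mean(log(a)) - mean(log(b)))
    expect_equal(sqrt(prod(eq$ratio_ci)), gm, tolerance = 1e-10)
    swapped <- equivalence_test(b, a)
    expect_equal(swapped$ratio_ci, rev(1 / eq$ratio_ci), tolerance = 1e-10)
  }
})

test_that("CI width grows with sigma_w and shrinks with n", {
  base <- scale(rnorm(20))[, 1]
  widths_sigma <- sapply(c(0.1, 0.2, 0.4), function(s) {
    eq <- equivalence_test(exp(base[1:10] * s), exp(base[11:20] * s))
    diff(log(eq$ratio_ci))
  })
  expect_true(all(diff(widths_sigma) > 0))
  widths_n <- sapply(c(4, 8, 16), function(n) {
    z <- scale(rnorm(n))[, 1] * 0.3
    eq <- equivalence_test(exp(z), exp(z + 0.01))
    diff(log(eq$ratio_ci))
  })
  expect_true(all(diff(widths_n) < 0))
})
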