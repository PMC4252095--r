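# dose-response curves: GT pieces, ML fitting, classical curves,
# prediction SEs, bands, goodness of fit

cal <- load_calibration()

test_that("Gompertz rate curve has the right limits", {
  p <- printed_gt
  expect_equal(gt_lambda(1e6, p), p[["beta0"]], tolerance = 1e-10)
  expect_equal(gt_lambda(0, p), p[["beta0"]] * exp(-p[["beta1"]]),
               tolerance = 1e-12)
  expect_equal(round(gt_lambda(0, p), 4), 0.0090)
  expect_equal(gt_lambda(25, p), 8.30, tolerance = 0.01)
})

test_that("weight parameter grows linearly with no intercept", {
  p <- printed_gt
  expect_equal(gt_b(0, p), 0)
  expect_equal(gt_b(10, p), 10.623, tolerance = 1e-10)
  expect_true(all(diff(gt_b(seq(0, 30, 0.5), p)) >= 0))
})

test_that("GT yield is sigmoid: at or above the rate, monotone, bounded", {
  p <- printed_gt
  expect_equal(gt_yield(0, p), gt_lambda(0, p), tolerance = 1e-12)
  dd <- seq(0, 100, by = 0.5)
  y <- gt_yield(dd, p)
  expect_true(all(y[-1] >= gt_lambda(dd[-1], p)))
  expect_true(all(diff(y) >= -1e-10))
  expect_lt(max(y), 2 * p[["beta0"]])
})

test_that("ML fit recovers simulated GT truth within 3 SE", {
  truth <- unname(printed_gt)
  sim <- simulate_whole_body(truth,
                             doses = c(0, 0.1, 0.5, 1, 3, 5, 7, 10, 15, 20, 25),
                             cells = c(2000, 2000, 2000, 1000, 500, 150,
                                       150, 150, 100, 100, 100),
                             seed = 2024)
  f <- gt_fit(sim)
  se <- sqrt(diag(vcov(f)))
  expect_true(all(abs(coef(f) - truth) <= 3 * se))
})

test_that("the kept optimum is at least as good as every start", {
  f <- gt_fit(cal)
  expect_true(all(-f$loglik <= f$starts$nll_start + 1e-6))
  expect_true(all(-f$loglik <= f$starts$nll_end + 1e-6, na.rm = TRUE))
})

test_that("underdetermined designs are refused", {
  expect_error(gt_fit(calibration_data(list(cal[[6]]))), "at least 4")
})

test_that("linear no-intercept ML equals its closed-form score solution", {
  f <- classical_fit(cal, "linear", intercept = FALSE)
  expect_equal(unname(coef(f)[["alpha"]]), 5360 / 13000, tolerance = 2e-4)
  expect_lt(abs(sqrt(vcov(f)[1, 1]) - 0.0056), 5e-5)
})

test_that("negative fitted intercept triggers the no-intercept refit", {
  expect_message(f <- classical_fit(cal, "linear", intercept = TRUE),
                 "refitting without intercept")
  expect_true(f$refit_without_intercept)
  expect_false("C" %in% names(coef(f)))
  expect_message(flq <- classical_fit(cal, "linear-quadratic",
                                      intercept = TRUE),
                 "refitting without intercept")
  expect_true(all(coef(flq) >= 0))
})

test_that("classical recovery: Poisson data from Y = 0.4 d", {
  set.seed(11)
  doses <- c(0, 0.1, 0.5, 1, 3, 5, 7, 10, 15, 20, 25)
  cells <- c(2000, 2000, 2000, 1000, 500, 150, 150, 150, 100, 100, 100)
  dists <- mapply(function(d, n)
    dicentric_dist(tabulate(rpois(n, 0.4 * d) + 1L, 26), dose = d),
    doses, cells, SIMPLIFY = FALSE)
  f <- classical_fit(calibration_data(dists), "linear", intercept = FALSE)
  expect_lt(abs(coef(f)[["alpha"]] - 0.4), 3 * sqrt(vcov(f)[1, 1]))
})

test_that("degenerate all-zero data are refused", {
  dists <- lapply(c(1, 2, 5), function(d)
    dicentric_dist(c(50), dose = d))
  expect_error(classical_fit(calibration_data(dists), "linear",
                             intercept = FALSE), "degenerate")
})

test_that("delta-method prediction SE has its closed forms", {
  # zero covariance -> zero prediction SE
  lin0 <- classical_curve("linear", alpha = 0.4034)
  pr <- predict(lin0, dose = c(1, 5), se.fit = TRUE)
  expect_equal(pr$se.fit, c(0, 0))
  # linear no-intercept: s(d) = d * SE(alpha) exactly
  lin <- classical_curve("linear", alpha = 0.4034, se = c(alpha = 0.0056))
  pr <- predict(lin, dose = c(1, 5, 10), se.fit = TRUE)
  expect_equal(pr$se.fit, c(1, 5, 10) * 0.0056, tolerance = 1e-6)
})

test_that("band constants follow the fitted parameter count", {
  expect_equal(band_constant(4), sqrt(qchisq(0.95, 4)), tolerance = 1e-12)
  expect_equal(round(band_constant(4), 4), 3.0802)
  expect_equal(round(band_constant(1), 4), 1.9600)
  lin <- classical_curve("linear", alpha = 0.4)
  expect_equal(band_constant(lin), band_constant(1))
  lq <- classical_curve("linear-quadratic", alpha = 0.24, beta = 0.013)
  expect_equal(band_constant(lq), sqrt(qchisq(0.95, 2)))
})

test_that("prediction bands contain the fitted curve", {
  f <- gt_fit(cal)
  pr <- predict(f, dose = c(0.5, 2, 8, 20), interval = "band")
  expect_true(all(pr$lower <= pr$fit & pr$fit <= pr$upper))
})

test_that("a curve through the observed yields gives zero chi-square", {
  df <- as.data.frame(calibration_data(cal[4]))       # the 1 Gy row
  lin <- classical_curve("linear", alpha = df$Y / df$dose)
  g <- chi2_goodness(calibration_data(cal[4]), lin)
  expect_equal(g$chisq[1], 0, tolerance = 1e-18)
})

test_that("chi-square excludes structurally-zero expectations", {
  lin <- classical_curve("linear", alpha = 0.4034)
  g <- chi2_goodness(cal, lin)
  expect_true(is.na(g$chisq[g$dose == 0]))
  expect_equal(attr(g, "total"), sum(g$chisq, na.rm = TRUE))
})
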