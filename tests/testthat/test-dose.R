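# dose inference: inverse regression, Merkle limits, zero-truncated fits,
# Dolphin method

cal <- load_calibration()
gt <- gt_fit(cal)
samples <- load_samples()
names(samples) <- vapply(samples, `[[`, character(1), "label")

test_that("curve inversion round-trips the dose to 1e-6 Gy", {
  for (d_true in c(0.5, 2, 7.3, 12, 20)) {
    est <- dose_from_yield(gt, gt_yield(d_true, gt), yield_se = 0)
    expect_equal(est$dose, d_true, tolerance = 1e-6)
  }
})

test_that("confidence limits bracket the point estimate and tighten as the
           yield SE vanishes", {
  y <- gt_yield(6, gt)
  wide <- dose_from_yield(gt, y, yield_se = 0.2)
  narrow <- dose_from_yield(gt, y, yield_se = 0.02)
  band_only <- dose_from_yield(gt, y, yield_se = 0)
  for (e in list(wide, narrow, band_only)) {
    expect_lt(e$conf_int[["lower"]], e$dose)
    expect_gt(e$conf_int[["upper"]], e$dose)
  }
  expect_lt(diff(narrow$conf_int), diff(wide$conf_int))
  # SE -> 0 shrinks toward the curve-band-only interval
  expect_equal(unname(dose_from_yield(gt, y, yield_se = 1e-12)$conf_int),
               unname(band_only$conf_int), tolerance = 1e-4)
})

test_that("saturating yields are refused with a clear message", {
  expect_error(dose_from_yield(gt, 50), "saturation")
  expect_error(whole_body_dose(dicentric_dist(c(rep(0, 15), 100)), gt),
               "exceeds")
})

test_that("a zero-yield sample gives dose 0 with an upper limit only", {
  est <- whole_body_dose(dicentric_dist(c(100)), gt)
  expect_equal(est$dose, 0)
  expect_equal(est$conf_int[["lower"]], 0)
  expect_gt(est$conf_int[["upper"]], 0)
})

test_that("whole-body estimates reproduce published values from printed
           classical coefficients", {
  lin <- classical_curve("linear", alpha = 0.4034)
  lq <- classical_curve("linear-quadratic", alpha = 0.2431, beta = 0.0133)
  expect_equal(whole_body_dose(samples[["2Gy-100"]], lin)$dose, 0.77,
               tolerance = 0.01)
  expect_equal(whole_body_dose(samples[["6Gy-100"]], lq)$dose, 8.08,
               tolerance = 0.01)
})

test_that("zero-truncated fit needs enough informative cells", {
  expect_error(ztwp_fit(dicentric_dist(c(120, 1))), "at least 2")
})

test_that("zero-truncated fit recovers known parameters within 3 SE", {
  lam <- 3; b <- 2
  set.seed(5)
  k <- rwpois(5000, lam, b)
  k <- k[k >= 1]
  zf <- ztwp_fit(dicentric_dist(tabulate(k + 1L, nbins = max(k) + 1L)))
  se <- sqrt(diag(zf$vcov))
  expect_lt(abs(zf$lambda - lam), 3 * se[["lambda"]])
  expect_lt(abs(zf$b - b), 3 * se[["b"]])
  expect_equal(zf$yield, wpois_mean(lam, b), tolerance = 0.1)
})

test_that("a whole-body sample analysed as partial-body stays consistent", {
  est_w <- whole_body_dose(samples[["6Gy-100"]], gt)
  est_p <- suppressWarnings(partial_body_dose(samples[["6Gy-100"]], gt))
  # consistent: the two confidence intervals overlap
  expect_lt(max(est_w$conf_int[1], est_p$conf_int[1]),
            min(est_w$conf_int[2], est_p$conf_int[2]))
})

test_that("partial-body analysis warns when overdispersion is absent", {
  expect_warning(partial_body_dose(samples[["6Gy-100"]], gt),
                 "not indicate overdispersion")
})

test_that("Dolphin solver agrees with a bisection oracle to 1e-10", {
  x <- samples[["6Gy-70"]]
  lin <- classical_curve("linear", alpha = 0.4034)
  est <- dolphin_dose(x, lin)
  # independent bisection on Y/(1 - exp(-Y)) = 295/99
  lo <- 1e-8; hi <- 50
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid / (1 - exp(-mid)) < 295 / 99) lo <- mid else hi <- mid
  }
  expect_equal(est$yield, (lo + hi) / 2, tolerance = 1e-10)
  expect_equal(est$dose, est$yield / 0.4034, tolerance = 1e-9)
  expect_equal(est$fraction, (295 / est$yield) / 300, tolerance = 1e-9)
})

test_that("Dolphin method is refused without a zero-class excess", {
  lin <- classical_curve("linear", alpha = 0.4034)
  expect_error(dolphin_dose(dicentric_dist(c(0, 50)), lin), "inapplicable")
  expect_error(dolphin_dose(dicentric_dist(c(50)), lin), "at least one")
})

test_that("Merkle combination options are honoured", {
  y <- gt_yield(6, gt)
  m <- dose_from_yield(gt, y, 0.1, combine = "merkle")
  b <- dose_from_yield(gt, y, 0.1, combine = "band")
  yy <- dose_from_yield(gt, y, 0.1, combine = "yield")
  expect_lt(m$conf_int[1], b$conf_int[1])
  expect_lt(m$conf_int[1], yy$conf_int[1])
  expect_gt(m$conf_int[2], b$conf_int[2])
  expect_gt(m$conf_int[2], yy$conf_int[2])
})

test_that("simulated partial-body mixtures recover the true dose with
           nominal coverage", {
  set.seed(31)
  hits <- 0; total <- 0
  for (f in c(0.3, 0.7)) {
    for (d_true in c(6, 12)) {
      for (r in 1:5) {
        pb <- simulate_partial_body(gt, d_true, cells = 400, fraction = f,
                                    seed = sample.int(1e6, 1))
        est <- tryCatch(
          suppressWarnings(partial_body_dose(pb, gt)),
          error = function(e) NULL)
        if (is.null(est)) next
        total <- total + 1
        hits <- hits + (est$conf_int[1] <= d_true &&
                          d_true <= est$conf_int[2])
      }
    }
  }
  expect_gte(total, 18)
  expect_gte(hits / total, 0.9)
})
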