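# the weighted Poisson count model: normalization, moments, truncation,
# sampling

grid <- expand.grid(lambda = c(0.001, 0.05, 0.5, 2, 6.1, 12),
                    b = c(0, 0.1, 1, 10.6, 30))

test_that("closed-form normalizer equals the brute-force series", {
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; b <- grid$b[i]
    expect_equal(wpois_norm(lam, b), oracle_norm(lam, b),
                 tolerance = 1e-12)
    expect_equal(wpois_norm(lam, b, method = "series", tol = 1e-14),
                 oracle_norm(lam, b), tolerance = 1e-12)
  }
})

test_that("pmf is a probability distribution on the whole grid", {
  for (i in seq_len(nrow(grid))) {
    p <- dwpois(0:500, grid$lambda[i], grid$b[i])
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-10)
  }
})

test_that("b = 0 reduces exactly to the Poisson distribution", {
  for (lam in c(0.01, 1, 6.1)) {
    expect_equal(dwpois(0:60, lam, 0), dpois(0:60, lam), tolerance = 1e-12)
    expect_equal(wpois_mean(lam, 0), lam, tolerance = 1e-12)
    expect_equal(wpois_var(lam, 0), lam, tolerance = 1e-12)
  }
  expect_equal(dwpois(0, 1, 0), exp(-1), tolerance = 1e-12)
})

test_that("closed-form moments match the series oracle", {
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; b <- grid$b[i]
    mo <- oracle_moments(lam, b)
    expect_equal(wpois_mean(lam, b), mo[["mean"]], tolerance = 1e-8)
    expect_equal(wpois_var(lam, b), mo[["var"]], tolerance = 1e-8)
  }
})

test_that("the family reaches underdispersion and mild overdispersion", {
  di <- function(lam, b) wpois_var(lam, b) / wpois_mean(lam, b)
  sweep <- expand.grid(lambda = seq(0.1, 12, by = 0.3),
                       b = c(0.05, 0.1, 0.2, 0.5, 1, 2, 5, 10, 30))
  dis <- mapply(di, sweep$lambda, sweep$b)
  expect_lt(min(dis), 0.75)        # clear underdispersion attained
  expect_gt(max(dis), 1.05)        # and values slightly above 1
  expect_lt(max(dis), 1.15)        # ... but only slightly (around 1.1)
})

test_that("increasing weight: pmf/Poisson ratio is nondecreasing in k", {
  for (i in seq_len(nrow(grid))) {
    k <- 0:40
    r <- dwpois(k, grid$lambda[i], grid$b[i]) / dpois(k, grid$lambda[i])
    expect_true(all(diff(r) >= -1e-12))
  }
})

test_that("small-lambda limit concentrates all mass at zero", {
  expect_equal(dwpois(0, 1e-9, 10), 1, tolerance = 1e-6)
})

test_that("zero-truncated variant sums to one and shifts the mean up", {
  for (i in seq_len(nrow(grid))) {
    lam <- grid$lambda[i]; b <- grid$b[i]
    pz <- dztwpois(1:500, lam, b)
    expect_equal(sum(pz), 1, tolerance = 1e-10)
    expect_gte(sum((1:500) * pz), wpois_mean(lam, b) - 1e-10)
  }
  # zero-truncated Poisson closed form at the Poisson limit
  expect_equal(dztwpois(1, 1, 0), exp(-1) / (1 - exp(-1)), tolerance = 1e-12)
})

test_that("parameter and support domains are enforced", {
  expect_error(dwpois(-1, 1, 1), "non-negative")
  expect_error(dwpois(1, -1, 1), "lambda")
  expect_error(dwpois(1, 1, -0.5), "'b'")
  expect_error(dztwpois(0, 1, 1), ">= 1")
  expect_error(wpois_norm(1, 1, method = "series", tol = 1), "tol")
  expect_error(rwpois(0, 1, 1), "positive")
})

test_that("sampling is seeded, reproducible and matches the moments", {
  x1 <- rwpois(1000, 2, 5, seed = 42)
  x2 <- rwpois(1000, 2, 5, seed = 42)
  expect_identical(x1, x2)

  # Poisson limit
  x <- rwpois(1e5, 6.1, 0, seed = 1)
  expect_lt(abs(mean(x) - 6.1), 3 * sqrt(6.1 / 1e5))

  # 10 Gy-like parameters: mean and variance within Monte-Carlo error
  lam <- 4.32; b <- 10.6
  y <- rwpois(1e5, lam, b, seed = 7)
  expect_lt(abs(mean(y) - wpois_mean(lam, b)),
            4 * sqrt(wpois_var(lam, b) / 1e5))
  expect_lt(abs(var(y) / wpois_var(lam, b) - 1), 0.05)
})
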