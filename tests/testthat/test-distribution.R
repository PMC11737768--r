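test_that("cdf and quantile are inverse to high precision across parameters", {
  set.seed(11)
  p <- runif(1000)
  for (par in param_grid) {
    q <- qhleird(p, par$sigma, par$alpha, par$lambda)
    expect_true(all(q > 0))
    expect_equal(phleird(q, par$sigma, par$alpha, par$lambda), p,
                 tolerance = 1e-9)
    # strictly increasing in p
    o <- order(p)
    expect_true(all(diff(q[o]) > 0))
  }
})

test_that("density integrates to one and matches the cdf derivative", {
  for (par in param_grid) {
    total <- integrate(dhleird, 0, Inf, sigma = par$sigma, alpha = par$alpha,
                       lambda = par$lambda, rel.tol = 1e-10)$value
    expect_equal(total, 1, tolerance = 1e-7)
  }
  h <- 1e-5
  fd <- (phleird(2 + h) - phleird(2 - h)) / (2 * h)
  expect_equal(dhleird(2), fd, tolerance = 1e-6)
})

test_that("density at unit point matches its closed form", {
  # direct evaluation: 4 e^{-1} (1-e^{-1})^0 / (1 + (1-e^{-1}))^2
  direct <- 4 * exp(-1) / (1 + (1 - exp(-1)))^2
  expect_equal(dhleird(1, 1, 1, 1), direct, tolerance = 1e-12)
  expect_equal(dhleird(1, 1, 1, 1, log = TRUE), log(direct), tolerance = 1e-12)
})

test_that("survival and hazard are consistent with cdf and density", {
  x <- c(0.3, 0.8, 1.5, 3, 10)
  for (par in param_grid) {
    s <- shleird(x, par$sigma, par$alpha, par$lambda)
    expect_equal(s + phleird(x, par$sigma, par$alpha, par$lambda),
                 rep(1, length(x)), tolerance = 1e-12)
    h <- hhleird(x, par$sigma, par$alpha, par$lambda)
    expect_equal(h * s, dhleird(x, par$sigma, par$alpha, par$lambda),
                 tolerance = 1e-10)
  }
})

test_that("median agrees with the closed form and a bisection oracle", {
  par <- hleird_params(2, 2, 2)
  med <- qhleird(0.5, 2, 2, 2)
  closed <- 2 / sqrt(-log(1 - (1 / 3)^(1 / 4)))
  expect_equal(med, closed, tolerance = 1e-12)
  expect_equal(med, quantile_bisect(0.5, par), tolerance = 1e-8)
  expect_equal(med, 1.674574, tolerance = 1e-6)  # frozen from the oracle
})

test_that("support boundaries behave by convention", {
  expect_equal(phleird(c(-1, 0)), c(0, 0))
  expect_equal(phleird(Inf), 1)
  expect_equal(dhleird(c(-1, 0, Inf)), c(0, 0, 0))
  expect_error(qhleird(0), "inside")
  expect_error(qhleird(1.2), "inside")
  expect_error(dhleird(1, sigma = -1), "positive")
})

test_that("the law depends on the shapes only through their product", {
  x <- c(0.4, 1, 2.7, 8)
  for (c_exact in c(0.5, 2, 8)) {
    expect_identical(phleird(x, 1.3, 0.8, 1.9),
                     phleird(x, 1.3, c_exact * 0.8, 1.9 / c_exact))
    expect_identical(dhleird(x, 1.3, 0.8, 1.9),
                     dhleird(x, 1.3, c_exact * 0.8, 1.9 / c_exact))
  }
  expect_equal(phleird(x, 1.3, 10 * 0.8, 1.9 / 10),
               phleird(x, 1.3, 0.8, 1.9), tolerance = 1e-14)
})

test_that("sigma is a scale parameter", {
  p <- c(0.1, 0.4, 0.9)
  for (cc in c(0.25, 3, 11)) {
    expect_equal(qhleird(p, cc * 1.2, 0.7, 2.1),
                 cc * qhleird(p, 1.2, 0.7, 2.1), tolerance = 1e-13)
  }
})

test_that("cdf is increasing in each shape and decreasing in the scale", {
  x <- c(0.5, 1, 2, 5)
  base <- phleird(x, 1, 1, 1)
  expect_true(all(phleird(x, 1, 1.5, 1) > base))
  expect_true(all(phleird(x, 1, 1, 1.5) > base))
  expect_true(all(phleird(x, 1.5, 1, 1) < base))
})

test_that("random generation is seed-deterministic and matches the model", {
  a <- rhleird(100, 1, 1, 1, seed = 42)
  b <- rhleird(100, 1, 1, 1, seed = 42)
  expect_identical(a, b)
  expect_true(all(a > 0))
  x <- rhleird(1e5, 1, 1, 1, seed = 7)
  d <- ks_statistic(x, function(q) phleird(q, 1, 1, 1))
  expect_lt(d, 0.01)  # 1.36/sqrt(n) ~ 0.0043; loose bound
  y <- rhleird(1e5, 2, 2, 2, seed = 8)
  expect_equal(median(y), qhleird(0.5, 2, 2, 2), tolerance = 0.02)
  expect_error(rhleird(0), "positive")
})

test_that("parameter constructor validates and derives theta", {
  p <- hleird_params(2, 3, 4)
  expect_equal(p$theta, 12)
  expect_error(hleird_params(-1, 1, 1), "sigma")
  expect_error(hleird_params(1, 0, 1), "alpha")
  expect_error(hleird_params(1, 1, Inf), "lambda")
})
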