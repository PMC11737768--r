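crit_funs <- list(
  mle = hleird_neg_loglik,
  lse = hleird_lse_criterion,
  wlse = hleird_wlse_criterion,
  cvme = hleird_cvm_criterion,
  mps = hleird_mps_criterion
)

test_that("every criterion is invariant along the identifiability ridge", {
  x <- rhleird(40, 1, 1, 1, seed = 21)
  for (nm in names(crit_funs)) {
    f <- crit_funs[[nm]]
    base <- f(hleird_params(1.2, 0.8, 1.9), x)
    for (cc in c(0.5, 2, 8)) {
      expect_identical(f(hleird_params(1.2, cc * 0.8, 1.9 / cc), x), base,
                       label = paste(nm, "ridge c =", cc))
    }
    expect_equal(f(hleird_params(1.2, 10 * 0.8, 1.9 / 10), x), base,
                 tolerance = 1e-12)
  }
})

test_that("spacings always sum to one and ties fall back to the density", {
  x <- rhleird(30, 1, 1, 2, seed = 22)
  for (par in param_grid) {
    expect_equal(sum(hleird_spacings(par, x)), 1, tolerance = 1e-12)
  }
  x_tied <- c(0.8, 1.1, 1.1, 1.9, 2.4)   # exact tie
  h <- hleird_mps_criterion(hleird_params(1, 1, 1), x_tied)
  expect_true(is.finite(h))
})

test_that("criteria vanish (to their floors) on perfectly placed samples", {
  n <- 25
  par <- hleird_params(1.4, 1, 2)
  x <- qhleird(seq_len(n) / (n + 1), par$sigma, par$alpha, par$lambda)
  expect_lt(hleird_lse_criterion(par, x), 1e-20)
  expect_lt(hleird_wlse_criterion(par, x), 1e-16)
  f <- fit_hleird(x, "lse")
  expect_lt(f$objective, 1e-10)
  # the CvM criterion can never undercut its 1/(12n) floor
  expect_gte(hleird_cvm_criterion(par, x), 1 / (12 * n))
})

test_that("maximum likelihood reproduces the carbon-fiber headline fit", {
  x1 <- carbon_fibers("20mm")
  f <- fit_hleird(x1, "mle")
  expect_equal(f$loglik, -50.50187, tolerance = 1e-4)
  expect_true(f$converged)
  expect_equal(f$objective, f$loglik)
  # free mode reaches the same identifiable optimum from another split
  f3 <- fit_hleird(x1, "mle", mode = "free",
                   start = hleird_params(3.6, 0.77, 12.55))
  expect_equal(f3$theta, f$theta, tolerance = 5e-3)
  expect_equal(f3$loglik, f$loglik, tolerance = 1e-5)
  # the caller's split is preserved in profile mode
  fs <- fit_hleird(x1, "mle", start = hleird_params(3.6, 2, 5))
  expect_equal(fs$alpha / fs$lambda, 2 / 5, tolerance = 1e-9)
  expect_equal(fs$theta, f$theta, tolerance = 1e-6)
})

test_that("Wald machinery behaves: intervals cover the estimates", {
  x <- rhleird(200, 1, 1, 2, seed = 23)
  f <- fit_hleird(x, "mle")
  expect_true(all(f$se >= 0))
  expect_true(f$ci["theta", 1] < f$theta && f$theta < f$ci["theta", 2])
  expect_true(f$ci["sigma", 1] < f$sigma && f$sigma < f$ci["sigma", 2])
  f3 <- fit_hleird(x, "mle", mode = "free", start = hleird_params(1, 1, 2))
  expect_match(f3$se_basis, "pseudo-inverse")
  expect_true(all(f3$se >= 0))
})

test_that("the maximum likelihood estimator recovers (theta, sigma)", {
  true <- hleird_params(1, 2, 1)   # theta = 2
  x <- rhleird(5000, true$sigma, true$alpha, true$lambda, seed = 24)
  f <- fit_hleird(x, "mle")
  expect_lt(abs(f$theta - true$theta), 3 * f$se["theta"])
  expect_lt(abs(f$sigma - true$sigma), 3 * f$se["sigma"])
})

test_that("minimum-distance and spacings estimators are consistent", {
  true <- hleird_params(1, 1, 1)
  x <- rhleird(5000, 1, 1, 1, seed = 25)
  fl <- fit_hleird(x, "lse")
  fc <- fit_hleird(x, "cvme")
  # CvM and LSE optima coincide asymptotically
  expect_lt(abs(fl$theta - fc$theta), 0.02 * max(1, fl$theta))
  expect_lt(abs(fl$sigma - fc$sigma), 0.02)
  fm <- fit_hleird(x, "mps")
  expect_lt(abs(fm$theta - 1), 0.15)
  expect_lt(abs(fm$sigma - 1), 0.05)
  fw <- fit_hleird(x, "wlse")
  expect_lt(abs(fw$sigma - 1), 0.05)
})

test_that("fit plumbing validates input", {
  expect_error(fit_hleird(c(1, 2)), "at least 3")
  expect_error(fit_hleird(c(1, -1, 2)), "positive")
  expect_error(fit_hleird(c(1, 2, 3), level = 1.5), "level")
  expect_error(fit_hleird(c(1, 2, 3), method = "pmle"))
})
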