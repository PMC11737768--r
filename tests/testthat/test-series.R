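test_that("series moments match adaptive quadrature", {
  for (theta in c(1, 2, 4)) for (r in c(0.5, 1, 1.5)) {
    par <- hleird_params(1.3, 1, theta)
    expect_equal(hleird_moment(r, par),
                 moment_quad_oracle(r, par), tolerance = 1e-8,
                 label = sprintf("series moment (theta=%g, r=%g)", theta, r))
  }
  # the two methods are distinct code paths of the same operation
  par <- hleird_params(0.8, 2, 1.1)
  expect_equal(hleird_moment(1, par),
               hleird_moment(1, par, method = "quadrature"), tolerance = 1e-8)
})

test_that("the mean is scale-equivariant", {
  m1 <- hleird_mean(hleird_params(1, 1, 1))
  for (cc in c(0.5, 2, 7)) {
    expect_equal(hleird_mean(hleird_params(cc, 1, 1)), cc * m1,
                 tolerance = 1e-9)
  }
})

test_that("moments exist exactly below min(2, 2 theta)", {
  par <- hleird_params(1, 1, 1)
  expect_error(hleird_moment(2, par), "does not exist")
  expect_error(hleird_moment(2.5, par), "does not exist")
  expect_error(hleird_moment(-1, par), "positive")
  # small theta: the heavy x^{-(1+2 theta)} tail kills even the mean
  small <- hleird_params(1, 0.5, 0.5)     # theta = 0.25
  expect_error(hleird_moment(1, small), "does not exist")
  expect_error(hleird_mean(small), "does not exist")
  m <- hleird_moment(0.4, small)          # r < 2 theta still exists
  expect_equal(m, moment_quad_oracle(0.4, small), tolerance = 1e-7)
})

test_that("Renyi entropy series agrees with the quadrature definition", {
  for (theta in c(1, 2, 4)) for (delta in c(0.75, 2, 3)) {
    par <- hleird_params(1, 1, theta)
    direct <- log(density_power_quad_oracle(delta, par)) / (1 - delta)
    expect_equal(hleird_entropy_renyi(delta, par), direct, tolerance = 1e-6,
                 label = sprintf("Renyi (theta=%g, delta=%g)", theta, delta))
  }
  par <- hleird_params(2, 1.5, 2)
  expect_equal(hleird_entropy_renyi(2, par),
               log(density_power_quad_oracle(2, par)) / (1 - 2),
               tolerance = 1e-6)
})

test_that("Renyi series signals its validity limits", {
  expect_error(hleird_entropy_renyi(0.3, hleird_params(1, 1, 2)), "1/3")
  expect_error(hleird_entropy_renyi(2, hleird_params(1, 0.5, 0.5)), "invalid")
  # quadrature method still defined there
  v <- hleird_entropy_renyi(2, hleird_params(1, 0.5, 0.5),
                            method = "quadrature")
  expect_true(is.finite(v))
})

test_that("q-entropy and Renyi entropy satisfy their algebraic identity", {
  par <- hleird_params(1, 1, 2)
  for (q in c(0.75, 2, 3)) {
    i_d <- hleird_entropy_renyi(q, par)
    h_q <- hleird_entropy_q(q, par)
    expect_equal(h_q, (1 - exp((1 - q) * i_d)) / (1 - q), tolerance = 1e-10)
  }
})

test_that("Renyi entropies bracket the Shannon entropy near delta = 1", {
  par <- hleird_params(1, 1, 2)
  sh <- hleird_entropy_shannon(par)
  lo <- hleird_entropy_renyi(1.01, par)
  hi <- hleird_entropy_renyi(0.99, par)
  expect_lt(lo, sh)
  expect_gt(hi, sh)
  expect_equal((lo + hi) / 2, sh, tolerance = 1e-3)
})

test_that("linear representation reconstructs density powers pointwise", {
  ctl <- series_control(max_terms_j = 5000, max_terms_k = 500,
                        abs_tol = 1e-12)
  par <- hleird_params(1, 1, 1)
  x <- c(0.5, 1, 2)
  expect_equal(hleird_power_series(x, 1, par, ctl),
               dhleird(x, 1, 1, 1), tolerance = 1e-8)
  expect_equal(hleird_power_series(c(1, 2), 2, par, ctl),
               dhleird(c(1, 2), 1, 1, 1)^2, tolerance = 1e-8)
  par2 <- hleird_params(1.5, 2, 1)
  expect_equal(hleird_power_series(c(1, 2, 4), 1, par2, ctl),
               dhleird(c(1, 2, 4), 1.5, 2, 1), tolerance = 1e-8)
})

test_that("leading representation coefficients take their closed values", {
  tab <- hleird_power_coef(1, hleird_params(1, 1, 1), j_max = 5, k_max = 2)
  expect_equal(tab$coef[tab$j == 0 & tab$k == 0], 4)
  # C(-2, j) = (-1)^j (j+1): coefficient (j, k=0) is 4 * that for theta = 1
  got <- tab$coef[tab$k == 0][order(tab$j[tab$k == 0])]
  expect_equal(got, 4 * (-1)^(0:5) * (0:5 + 1))
})

test_that("mgf exists only on the nonpositive half-line", {
  par <- hleird_params(1, 1, 1)
  expect_equal(hleird_mgf(0, par), 1)
  m <- hleird_mgf(c(-0.5, -1, -2), par)
  expect_true(all(diff(m) < 0))        # decreasing in |t|
  expect_true(all(m > 0 & m < 1))
  expect_error(hleird_mgf(0.1, par), "diverges")
  expect_equal(hleird_mgf_coef(1, par), hleird_mean(par), tolerance = 1e-9)
  expect_identical(hleird_mgf_coef(2, par), Inf)
})
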