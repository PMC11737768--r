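test_that("information criteria follow their printed formulas", {
  ic <- information_criteria(-50.502, 3, 69)
  expect_equal(unname(ic["AIC"]), 107.004, tolerance = 1e-6)
  expect_equal(unname(ic["BIC"]), 101.004 + 3 * log(69), tolerance = 1e-12)
  expect_equal(unname(ic["HQIC"]), 101.004 + 6 * log(log(69)), tolerance = 1e-12)
  expect_equal(unname(ic["CAIC"]), 101.004 + 3 * (log(69) + 1), tolerance = 1e-12)
  ic2 <- information_criteria(-52.0685, 2, 69)
  expect_equal(unname(ic2["AIC"]), 108.137, tolerance = 1e-6)
  # degenerate q = 0: all criteria collapse to -2 loglik
  ic0 <- information_criteria(-10, 0, 50)
  expect_true(all(ic0 == 20))
})

test_that("K-S distance follows its construction on engineered samples", {
  n <- 40
  par <- hleird_params(1, 1, 2)
  x <- qhleird((seq_len(n) - 0.5) / n, par$sigma, par$alpha, par$lambda)
  cdf <- function(q) phleird(q, par$sigma, par$alpha, par$lambda)
  expect_equal(ks_statistic(x, cdf), 0.5 / n, tolerance = 1e-10)
})

test_that("the W statistic attains its floor on the midpoint grid and equals the CvM criterion", {
  n <- 30
  par <- hleird_params(1.3, 2, 1)
  x <- qhleird((2 * seq_len(n) - 1) / (2 * n), par$sigma, par$alpha, par$lambda)
  cdf <- function(q) phleird(q, par$sigma, par$alpha, par$lambda)
  aw <- ad_cvm_statistics(x, cdf)
  expect_equal(unname(aw["W"]), 1 / (12 * n), tolerance = 1e-12)
  # identity with the estimation criterion at arbitrary parameters
  y <- rhleird(25, 1, 1, 1, seed = 41)
  par2 <- hleird_params(0.9, 1.2, 0.8)
  aw2 <- ad_cvm_statistics(y, function(q)
    phleird(q, par2$sigma, par2$alpha, par2$lambda))
  expect_equal(unname(aw2["W"]), hleird_cvm_criterion(par2, y),
               tolerance = 1e-14)
})

test_that("asymptotic p-values are proper and decreasing in their statistics", {
  ds <- seq(0.03, 0.3, by = 0.03)
  pk <- vapply(ds, ks_pvalue, numeric(1), n = 69)
  expect_true(all(diff(pk) < 0))
  expect_true(all(pk >= 0 & pk <= 1))
  as <- seq(0.2, 5, by = 0.4)
  pa <- vapply(as, ad_pvalue, numeric(1))
  expect_true(all(diff(pa) < 0))
  ws <- seq(0.02, 1, by = 0.08)
  pw <- vapply(ws, cvm_pvalue, numeric(1))
  expect_true(all(diff(pw) < 0))
  # classical 5% critical points of the limiting laws
  expect_equal(ks_pvalue(1.358 / sqrt(1e6), 1e6), 0.05, tolerance = 0.01)
  expect_equal(ad_pvalue(2.492), 0.05, tolerance = 0.005)
  expect_equal(cvm_pvalue(0.461), 0.05, tolerance = 0.005)
})

test_that("gof_report wires statistics and p-values together", {
  x <- carbon_fibers("20mm")
  f <- fit_hleird(x, "mle")
  g <- gof_report(f)
  expect_equal(g$ks_stat, ks_statistic(x, function(q)
    phleird(q, f$sigma, f$alpha, f$lambda)), tolerance = 1e-12)
  expect_true(all(c(g$ks_pvalue, g$ad_pvalue, g$cvm_pvalue) >= 0))
  expect_true(all(c(g$ks_pvalue, g$ad_pvalue, g$cvm_pvalue) <= 1))
  # the half-logistic model fits these data well
  expect_gt(g$ks_pvalue, 0.9)
})

test_that("bootstrap p-values run and stay in range", {
  x <- rhleird(40, 1, 1, 2, seed = 43)
  f <- fit_hleird(x, "mle")
  g <- gof_report(f, pvalue = "bootstrap", B = 20, seed = 5)
  expect_true(all(c(g$ks_pvalue, g$ad_pvalue, g$cvm_pvalue) >= 0))
  expect_true(all(c(g$ks_pvalue, g$ad_pvalue, g$cvm_pvalue) <= 1))
})

test_that("the comparison table ranks the half-logistic model first on both data sets", {
  for (gauge in c("20mm", "10mm")) {
    tab <- compare_models(carbon_fibers(gauge))
    expect_setequal(unique(tab$model), c("hleird", "eird", "ird", "rd", "iwd"))
    expect_equal(unique(tab$rank[tab$model == "hleird"]), 1)
    # ranks are a permutation of 1..5 per model
    per_model <- tapply(tab$rank, tab$model, function(v) v[1])
    expect_setequal(unname(per_model), 1:5)
    if (gauge == "20mm") {
      expect_equal(unique(tab$rank[tab$model == "eird"]), 2)
      expect_equal(unique(tab$AIC[tab$model == "eird"]), 108.137,
                   tolerance = 1e-4)
    }
  }
})

test_that("a single-model comparison trivially ranks first", {
  tab <- compare_models(carbon_fibers("20mm"), models = "eird")
  expect_true(all(tab$rank == 1))
})
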