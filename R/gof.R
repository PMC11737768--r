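# Goodness of fit and model selection.

#' Information criteria for model selection
#'
#' The four criteria used in the model-comparison tables, all on natural
#' logs: \eqn{AIC = -2\ell + 2q}, \eqn{CAIC = -2\ell + q(\log n + 1)},
#' \eqn{BIC = -2\ell + q \log n}, \eqn{HQIC = -2\ell + 2q\log\log n},
#' where \eqn{\ell} is the maximized log-likelihood and `q` the number of
#' parameters.
#'
#' @param loglik maximized log-likelihood.
#' @param q number of estimated parameters.
#' @param n sample size.
#' @return Named numeric vector `(AIC, CAIC, BIC, HQIC)`.
#' @examples
#' information_criteria(-50.502, q = 3, n = 69)["AIC"]  # 107.004
#' @export
information_criteria <- function(loglik, q, n) {
  stopifnot(n >= 3, q >= 0)
  m2l <- -2 * loglik
  c(AIC = m2l + 2 * q,
    CAIC = m2l + q * (base::log(n) + 1),
    BIC = m2l + q * base::log(n),
    HQIC = m2l + 2 * q * base::log(base::log(n)))
}

#' Goodness-of-fit statistics against a fitted continuous cdf
#'
#' `ks_statistic` is the two-sided Kolmogorov-Smirnov sup-distance
#' \eqn{D_n = \max_i \max\{i/n - u_i,\ u_i - (i-1)/n\}} with
#' \eqn{u_i = F(x_{(i)})}; `ad_cvm_statistics` the Anderson-Darling
#' \eqn{A^2 = -n - n^{-1}\sum (2i-1)[\log u_i + \log(1-u_{n+1-i})]} and
#' Cramér-von Mises \eqn{W = 1/(12n) + \sum\{u_i - (2i-1)/(2n)\}^2}
#' statistics.  `W` is algebraically identical to the Cramér-von Mises
#' estimation criterion evaluated at the same parameters.
#'
#' The p-value helpers use the classical simple-hypothesis asymptotic
#' distributions (parameters treated as known): the Kolmogorov series for
#' D, Marsaglia's ADinf approximation for \eqn{A^2}, and the Bessel-K
#' series of the limiting \eqn{W} law.  When the parameters were
#' estimated from the same data these p-values are conservative
#' (anti-conservative statistics); a parametric-bootstrap alternative is
#' available through [gof_report()].
#'
#' @param x observed sample.
#' @param cdf a vectorized cdf function (e.g. from a fit).
#' @param stat statistic value.
#' @param n sample size.
#' @return `ks_statistic`: the sup-distance; `ad_cvm_statistics`: a named
#'   vector `(A2, W)`; the `*_pvalue` helpers: upper-tail probabilities.
#' @export
ks_statistic <- function(x, cdf) {
  xs <- sort(x); n <- length(xs); i <- seq_len(n)
  u <- cdf(xs)
  max(i / n - u, u - (i - 1) / n)
}

#' @rdname ks_statistic
#' @export
ks_pvalue <- function(stat, n) {
  t <- sqrt(n) * stat
  if (t < 0.2) return(1)
  k <- 1:100
  min(1, max(0, 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * t^2))))
}

#' @rdname ks_statistic
#' @export
ad_cvm_statistics <- function(x, cdf) {
  xs <- sort(x); n <- length(xs); i <- seq_len(n)
  u <- cdf(xs)
  if (any(u <= 0) || any(u >= 1)) {
    a2 <- Inf
  } else {
    a2 <- -n - mean((2 * i - 1) * (base::log(u) + base::log(1 - rev(u))))
  }
  w <- 1 / (12 * n) + sum((u - (2 * i - 1) / (2 * n))^2)
  c(A2 = a2, W = w)
}

#' @rdname ks_statistic
#' @export
ad_pvalue <- function(stat) {
  if (!is.finite(stat)) return(0)
  z <- stat
  cdf <- if (z < 2) {
    exp(-1.2337141 / z) / sqrt(z) *
      (2.00012 + (0.247105 - (0.0649821 - (0.0347962 -
        (0.011672 - 0.00168691 * z) * z) * z) * z) * z)
  } else {
    exp(-exp(1.0776 - (2.30695 - (0.43424 - (0.082433 -
      (0.008056 - 0.0003146 * z) * z) * z) * z) * z))
  }
  min(1, max(0, 1 - cdf))
}

#' @rdname ks_statistic
#' @export
cvm_pvalue <- function(stat) {
  if (!is.finite(stat)) return(0)
  if (stat < 0.00235) return(1)   # below the support of the series' accuracy
  j <- 0:12
  a <- (4 * j + 1)^2 / (16 * stat)
  cdf <- sum((-1)^j * gbinom(-0.5, j) * sqrt(4 * j + 1) * exp(-a) *
               besselK(a, 0.25)) / (pi * sqrt(stat))
  min(1, max(0, 1 - cdf))
}

#' Goodness-of-fit report for a fitted lifetime model
#'
#' Computes the Kolmogorov-Smirnov, Anderson-Darling and Cramér-von Mises
#' statistics of a fitted model (an `hleird_fit` or `competitor_fit`)
#' with either asymptotic simple-hypothesis p-values (default; the
#' convention behind the comparison tables) or parametric-bootstrap
#' p-values that account for parameter estimation.
#'
#' @param x the observed sample (defaults to the fit's data when the fit
#'   carries it).
#' @param fit a fitted model object.
#' @param pvalue `"asymptotic"` or `"bootstrap"`.
#' @param B bootstrap replicates.
#' @param seed optional integer seed for the bootstrap.
#' @return A list of class `"gof_report"` with the three statistics and
#'   their p-values.
#' @export
gof_report <- function(fit, x = NULL, pvalue = c("asymptotic", "bootstrap"),
                       B = 200, seed = NULL) {
  pvalue <- match.arg(pvalue)
  if (is.null(x)) {
    if (is.null(fit$data)) stop("supply 'x' (fit carries no data)")
    x <- fit$data
  }
  n <- length(x)
  cdf <- fit_cdf_fun(fit)
  ks <- ks_statistic(x, cdf)
  aw <- ad_cvm_statistics(x, cdf)
  if (pvalue == "asymptotic") {
    pk <- ks_pvalue(ks, n)
    pa <- ad_pvalue(aw["A2"])
    pw <- cvm_pvalue(aw["W"])
  } else {
    refit_stats <- function(xb) {
      fb <- if (inherits(fit, "hleird_fit")) {
        fit_hleird(xb, method = fit$method, mode = "profile")
      } else {
        fit_competitor(xb, fit$model)
      }
      cb <- fit_cdf_fun(fb)
      c(ks_statistic(xb, cb), ad_cvm_statistics(xb, cb))
    }
    qfun <- if (inherits(fit, "hleird_fit")) {
      function(u) qhleird(u, fit$sigma, fit$alpha, fit$lambda)
    } else {
      par <- unname(fit$estimate)
      switch(fit$model,
             eird = function(u) qeird(u, par[1], par[2]),
             ird = function(u) qird(u, par[1]),
             rd = function(u) qrayleigh(u, par[1]),
             iwd = function(u) qinvweibull(u, par[1], par[2]))
    }
    sim <- function() {
      t(replicate(B, refit_stats(qfun(stats::runif(n)))))
    }
    bs <- if (is.null(seed)) sim() else with_local_seed(seed, sim())
    pk <- mean(bs[, 1] >= ks)
    pa <- mean(bs[, 2] >= aw["A2"])
    pw <- mean(bs[, 3] >= aw["W"])
  }
  structure(list(ks_stat = ks, ks_pvalue = pk,
                 ad_stat = unname(aw["A2"]), ad_pvalue = unname(pa),
                 cvm_stat = unname(aw["W"]), cvm_pvalue = unname(pw),
                 pvalue_type = pvalue, n = n),
            class = "gof_report")
}

#' @export
print.gof_report <- function(x, ...) {
  cat(sprintf("Goodness of fit (n = %d, %s p-values)\n", x$n, x$pvalue_type))
  cat(sprintf("  A2 = %.4g (p = %.3g)   W = %.4g (p = %.3g)   K-S = %.4g (p = %.3g)\n",
              x$ad_stat, x$ad_pvalue, x$cvm_stat, x$cvm_pvalue,
              x$ks_stat, x$ks_pvalue))
  invisible(x)
}

#' Multi-model comparison table
#'
#' Fits the HLEIRD (by maximum likelihood) and the requested competitors
#' to a sample and tabulates estimates, standard errors, log-likelihoods,
#' the four information criteria and the AIC rank (average ranks on
#' ties).  A model whose fit fails is kept as a flagged row rather than
#' dropped.
#'
#' @param x vector of strictly positive observations.
#' @param models character vector from
#'   `c("hleird", "eird", "ird", "rd", "iwd")`.
#' @return A data frame with one row per model parameter, columns
#'   `model`, `parameter`, `estimate`, `se`, `loglik`, `AIC`, `CAIC`,
#'   `BIC`, `HQIC`, `rank`, `converged`.
#' @export
compare_models <- function(x, models = c("hleird", "eird", "ird", "rd", "iwd")) {
  models <- match.arg(models, several.ok = TRUE)
  n <- length(x)
  rows <- lapply(models, function(m) {
    res <- tryCatch({
      if (m == "hleird") {
        f <- fit_hleird(x, method = "mle", mode = "free")
        list(est = c(sigma = f$sigma, alpha = f$alpha, lambda = f$lambda),
             se = f$se, ll = f$loglik, q = 3L, conv = f$converged)
      } else {
        f <- fit_competitor(x, m)
        list(est = f$estimate, se = f$se, ll = f$loglik,
             q = competitor_npar(m), conv = f$converged)
      }
    }, error = function(e) NULL)
    if (is.null(res)) {
      return(data.frame(model = m, parameter = NA_character_,
                        estimate = NA_real_, se = NA_real_,
                        loglik = NA_real_, AIC = NA_real_, CAIC = NA_real_,
                        BIC = NA_real_, HQIC = NA_real_, converged = FALSE))
    }
    ic <- information_criteria(res$ll, res$q, n)
    data.frame(model = m, parameter = names(res$est),
               estimate = unname(res$est),
               se = if (is.null(res$se)) NA_real_ else unname(res$se[names(res$est)]),
               loglik = res$ll, AIC = ic["AIC"], CAIC = ic["CAIC"],
               BIC = ic["BIC"], HQIC = ic["HQIC"], converged = res$conv,
               row.names = NULL)
  })
  out <- do.call(rbind, rows)
  model_aic <- vapply(split(out$AIC, out$model), function(v) v[1], numeric(1))
  rk <- rank(model_aic, ties.method = "average", na.last = "keep")
  out$rank <- rk[out$model]
  out[order(out$rank, out$model), , drop = FALSE]
}
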