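# Shared fixtures and independent oracles.

# parameter triples exercised by the property tests (theta from 0.25 to 9)
param_grid <- list(
  hleird_params(0.5, 0.5, 1),
  hleird_params(1, 1, 1),
  hleird_params(1, 0.5, 0.5),
  hleird_params(2, 2, 2),
  hleird_params(3.6, 0.77, 12.55),
  hleird_params(1.5, 3, 3)
)

# bisection root of F(x) = p; independent of qhleird's closed form
quantile_bisect <- function(p, params, lo = 1e-8, hi = 1e8, tol = 1e-12) {
  f <- function(x) phleird(x, params$sigma, params$alpha, params$lambda) - p
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol * mid) break
  }
  (lo + hi) / 2
}

# adaptive-quadrature oracle for E[X^r], integrating in y = 1/x
moment_quad_oracle <- function(r, params) {
  f <- function(y) {
    v <- exp(dhleird(1 / y, params$sigma, params$alpha, params$lambda,
                     log = TRUE) - (r + 2) * log(y))
    ifelse(is.finite(v), v, 0)
  }
  integrate(f, 0, 1 / params$sigma, rel.tol = 1e-10)$value +
    integrate(f, 1 / params$sigma, Inf, rel.tol = 1e-10)$value
}

density_power_quad_oracle <- function(delta, params) {
  f <- function(x) {
    v <- exp(delta * dhleird(x, params$sigma, params$alpha, params$lambda,
                             log = TRUE))
    ifelse(is.finite(v), v, 0)
  }
  integrate(f, 0, params$sigma, rel.tol = 1e-10)$value +
    integrate(f, params$sigma, Inf, rel.tol = 1e-10)$value
}
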