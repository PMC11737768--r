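#' The half-logistic exponentiated inverse Rayleigh distribution
#'
#' Density, distribution function, survival function, hazard rate, quantile
#' function and random generation for the HLEIRD with scale `sigma` and
#' shapes `alpha`, `lambda`.  Writing \eqn{z = (\sigma/x)^2} and
#' \eqn{u = (1 - e^{-z})^{\alpha\lambda}}, the distribution function is
#' \deqn{F(x) = \frac{1 - u}{1 + u}, \qquad x > 0,}
#' the type-I half-logistic transform of the exponentiated inverse Rayleigh
#' baseline \eqn{G(x) = 1 - (1 - e^{-z})^{\alpha}}.  The density is
#' \deqn{f(x) = \frac{4\alpha\lambda\sigma^2\, e^{-z} (1-e^{-z})^{\alpha\lambda-1}}
#'  {x^3 (1+u)^2}.}
#' The law depends on \eqn{(\alpha, \lambda)} only through the product
#' \eqn{\theta = \alpha\lambda}.  Only the first moment exists.
#'
#' Computations are carried out on the log scale: \eqn{\log(1 - e^{-z})} is
#' evaluated as `log(-expm1(-z))`, so both tails are stable.
#'
#' @param x,q vector of quantiles (support is the positive half-line;
#'   values at or below zero have density 0 and distribution function 0).
#' @param p vector of probabilities in (0, 1).
#' @param n number of observations to generate.
#' @param sigma positive scale parameter.
#' @param alpha,lambda positive shape parameters.
#' @param log,log.p logical; if TRUE, probabilities/densities are returned
#'   on the log scale.
#' @param lower.tail logical; if TRUE (default), probabilities are
#'   \eqn{P(X \le x)}, otherwise \eqn{P(X > x)}.
#' @param seed optional integer; when supplied, `rhleird` draws from a
#'   private RNG stream seeded with it and leaves the caller's RNG state
#'   untouched.
#' @return `dhleird` the density, `phleird` the distribution function,
#'   `shleird` the survival function, `hhleird` the hazard rate,
#'   `qhleird` the quantile function, `rhleird` a vector of random draws.
#' @examples
#' phleird(qhleird(0.5, 2, 2, 2), 2, 2, 2)   # 0.5
#' integrate(dhleird, 0, Inf, sigma = 1)$value  # 1
#' @name hleird-distribution
NULL

check_shape_scale <- function(sigma, alpha, lambda) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) stop("'sigma' must be positive")
  if (any(!is.finite(alpha)) || any(alpha <= 0)) stop("'alpha' must be positive")
  if (any(!is.finite(lambda)) || any(lambda <= 0)) stop("'lambda' must be positive")
}

# log(1 - exp(-z)) and u = (1-e^{-z})^theta, stable at both ends
hleird_lb <- function(x, sigma) {
  z <- (sigma / x)^2
  log(-expm1(-z))
}

#' @rdname hleird-distribution
#' @export
dhleird <- function(x, sigma = 1, alpha = 1, lambda = 1, log = FALSE) {
  check_shape_scale(sigma, alpha, lambda)
  theta <- alpha * lambda
  ld <- rep(-Inf, length(x))
  ok <- is.finite(x) & x > 0
  if (any(ok)) {
    xs <- x[ok]
    z <- (sigma / xs)^2
    lb <- log(-expm1(-z))
    lu <- theta * lb
    ld[ok] <- base::log(4 * theta * sigma^2) - z + (theta - 1) * lb -
      3 * base::log(xs) - 2 * log1p(exp(lu))
  }
  ld[is.na(x)] <- NA_real_
  if (log) ld else exp(ld)
}

#' @rdname hleird-distribution
#' @export
phleird <- function(q, sigma = 1, alpha = 1, lambda = 1,
                    lower.tail = TRUE, log.p = FALSE) {
  check_shape_scale(sigma, alpha, lambda)
  theta <- alpha * lambda
  lsf <- rep(0, length(q))            # log survival; S(0) = 1
  ok <- is.finite(q) & q > 0
  if (any(ok)) {
    lu <- theta * hleird_lb(q[ok], sigma)
    # S = 2u/(1+u)
    lsf[ok] <- base::log(2) + lu - log1p(exp(lu))
  }
  lsf[is.infinite(q) & q > 0] <- -Inf
  lsf[is.na(q)] <- NA_real_
  if (lower.tail) {
    p <- -expm1(lsf)
    if (log.p) base::log(p) else p
  } else {
    if (log.p) lsf else exp(lsf)
  }
}

#' @rdname hleird-distribution
#' @export
shleird <- function(q, sigma = 1, alpha = 1, lambda = 1) {
  phleird(q, sigma, alpha, lambda, lower.tail = FALSE)
}

#' @rdname hleird-distribution
#' @export
hhleird <- function(x, sigma = 1, alpha = 1, lambda = 1) {
  # closed form 2*theta*sigma^2 e^{-z} (1-e^{-z})^{-1} / (x^3 (1+u))
  check_shape_scale(sigma, alpha, lambda)
  theta <- alpha * lambda
  h <- rep(0, length(x))
  ok <- is.finite(x) & x > 0
  if (any(ok)) {
    xs <- x[ok]
    z <- (sigma / xs)^2
    lb <- log(-expm1(-z))
    lu <- theta * lb
    h[ok] <- exp(base::log(2 * theta * sigma^2) - z - lb - 3 * base::log(xs) -
                   log1p(exp(lu)))
  }
  h[is.na(x)] <- NA_real_
  h
}

#' @rdname hleird-distribution
#' @export
qhleird <- function(p, sigma = 1, alpha = 1, lambda = 1,
                    lower.tail = TRUE, log.p = FALSE) {
  check_shape_scale(sigma, alpha, lambda)
  theta <- alpha * lambda
  if (log.p) p <- exp(p)
  if (!lower.tail) p <- 1 - p
  if (any(!is.na(p) & (p <= 0 | p >= 1)))
    stop("probabilities must lie strictly inside (0, 1)")
  # Q(p) = sigma * (-log(1 - ((1-p)/(1+p))^{1/theta}))^{-1/2}
  g <- log1p(-p) - log1p(p)           # log((1-p)/(1+p))
  one_minus_a <- -expm1(g / theta)    # 1 - ((1-p)/(1+p))^{1/theta}
  sigma / sqrt(-base::log(one_minus_a))
}

#' @rdname hleird-distribution
#' @export
rhleird <- function(n, sigma = 1, alpha = 1, lambda = 1, seed = NULL) {
  if (length(n) != 1 || !is.finite(n) || n < 1) stop("'n' must be a positive integer")
  draw <- function() qhleird(stats::runif(n), sigma, alpha, lambda)
  if (is.null(seed)) draw() else with_local_seed(seed, draw())
}
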