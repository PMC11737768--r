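#' Log-likelihood, score and observed information of the HLEIRD
#'
#' `hleird_loglik` evaluates the log-likelihood
#' \deqn{\ell = n\log(4\alpha\lambda\sigma^2) - 3\sum\log x_i
#'  - \sigma^2 \sum x_i^{-2} + (\theta-1)\sum \log b_i
#'  - 2 \sum \log(1 + b_i^{\theta}),}
#' with \eqn{b_i = 1 - e^{-(\sigma/x_i)^2}} and \eqn{\theta=\alpha\lambda};
#' `hleird_neg_loglik` its negative.  `hleird_score` returns the analytic
#' gradient in \eqn{(\sigma, \alpha, \lambda)} and `hleird_information`
#' the observed information (negative Hessian).  Because the likelihood
#' depends on \eqn{(\alpha, \lambda)} only through \eqn{\theta}, the
#' direction \eqn{(0, \alpha, -\lambda)} is a null direction of the score
#' and the 3x3 information is singular along the ridge; use
#' [pinv-based][fit_hleird] standard errors or the identifiable
#' \eqn{(\theta, \sigma)} parameterization.
#'
#' @param params an [hleird_params()] object or numeric triple
#'   `(sigma, alpha, lambda)`.
#' @param x vector of strictly positive observations.
#' @return `hleird_loglik`/`hleird_neg_loglik`: a scalar;
#'   `hleird_score`: the gradient 3-vector named (sigma, alpha, lambda);
#'   `hleird_information`: the symmetric 3x3 observed information matrix.
#' @export
hleird_loglik <- function(params, x) {
  params <- as_hleird_params(params)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("all observations must be strictly positive and finite")
  sum(dhleird(x, params$sigma, params$alpha, params$lambda, log = TRUE))
}

#' @rdname hleird_loglik
#' @export
hleird_neg_loglik <- function(params, x) -hleird_loglik(params, x)

# shared per-observation pieces for score/information
hleird_lik_parts <- function(params, x) {
  sigma <- params$sigma; theta <- params$theta
  z <- (sigma / x)^2
  e <- exp(-z)
  b <- -expm1(-z)
  L <- base::log(b)
  u <- exp(theta * L)
  A <- 1 / x^2
  list(z = z, e = e, b = b, L = L, u = u, A = A,
       w = u / (1 + u),            # u/(1+u)
       v = u / (1 + u)^2,
       db = 2 * sigma * e * A,     # db/dsigma
       d2b = 2 * e * A * (1 - 2 * sigma^2 * A))
}

#' @rdname hleird_loglik
#' @export
hleird_score <- function(params, x) {
  params <- as_hleird_params(params)
  p <- hleird_lik_parts(params, x)
  n <- length(x)
  sigma <- params$sigma; alpha <- params$alpha; lambda <- params$lambda
  theta <- params$theta
  s_shape <- sum(p$L * (1 - 2 * p$w))
  g_sigma <- 2 * n / sigma - 2 * sigma * sum(p$A) +
    sum(p$db * ((theta - 1) / p$b - 2 * theta * p$u / (p$b * (1 + p$u))))
  c(sigma = g_sigma,
    alpha = n / alpha + lambda * s_shape,
    lambda = n / lambda + alpha * s_shape)
}

#' @rdname hleird_loglik
#' @export
hleird_information <- function(params, x) {
  params <- as_hleird_params(params)
  p <- hleird_lik_parts(params, x)
  n <- length(x)
  sigma <- params$sigma; alpha <- params$alpha; lambda <- params$lambda
  theta <- params$theta
  L2v <- sum(p$L^2 * p$v)
  s_shape <- sum(p$L * (1 - 2 * p$w))
  # d(b^{theta-1} db-terms)/dsigma pieces; u/b = b^{theta-1}
  ub <- p$u / p$b
  H_aa <- -n / alpha^2 - 2 * lambda^2 * L2v
  H_ll <- -n / lambda^2 - 2 * alpha^2 * L2v
  H_al <- s_shape - 2 * alpha * lambda * L2v
  mix <- sum((p$db / p$b) * (1 - 2 * p$w) -
               2 * theta * p$L * ub * p$db / (1 + p$u)^2)
  H_sa <- lambda * mix
  H_sl <- alpha * mix
  H_ss <- -2 * n / sigma^2 - 2 * sum(p$A) +
    (theta - 1) * sum(p$d2b / p$b - (p$db / p$b)^2) -
    2 * theta * sum(((theta - 1) * ub / p$b * p$db^2 + ub * p$d2b) / (1 + p$u)) +
    2 * theta^2 * sum(ub^2 * p$db^2 / (1 + p$u)^2)
  H <- matrix(c(H_ss, H_sa, H_sl,
                H_sa, H_aa, H_al,
                H_sl, H_al, H_ll), 3, 3,
              dimnames = list(c("sigma", "alpha", "lambda"),
                              c("sigma", "alpha", "lambda")))
  -H
}

#' Parameter gradient of the HLEIRD cdf
#'
#' The derivatives \eqn{(\partial F/\partial\sigma,
#' \partial F/\partial\alpha, \partial F/\partial\lambda)} used by the
#' estimating equations of the least-squares, weighted least-squares,
#' Cramér-von Mises and spacings estimators.  With
#' \eqn{u = b^{\theta}}, \eqn{b = 1-e^{-(\sigma/x)^2}}:
#' \eqn{\partial F/\partial u = -2/(1+u)^2} and the chain rule gives
#' \eqn{\partial F/\partial\sigma < 0} (F decreases in the scale) while
#' \eqn{\partial F/\partial\alpha = \lambda \log(b)\, u\,
#' (-2/(1+u)^2) > 0} and symmetrically for \eqn{\lambda}; note
#' \eqn{\alpha\,\partial F/\partial\alpha =
#' \lambda\,\partial F/\partial\lambda} (the ridge identity).
#'
#' @param x vector of positive points.
#' @inheritParams hleird_loglik
#' @return A matrix with `length(x)` rows and columns
#'   `(sigma, alpha, lambda)`.
#' @export
hleird_cdf_grad <- function(x, params) {
  params <- as_hleird_params(params)
  p <- hleird_lik_parts(params, x)
  theta <- params$theta
  dFdu <- -2 / (1 + p$u)^2
  cbind(sigma = dFdu * theta * (p$u / p$b) * p$db,
        alpha = dFdu * params$lambda * p$L * p$u,
        lambda = dFdu * params$alpha * p$L * p$u)
}
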