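# Series representations of the HLEIRD.
#
# The density admits the linear representation (power nu > 0)
#   f(x)^nu = sum_{j,k} c_{j,k} g_k(x),
#   c_{j,k} = 4^nu (alpha lambda)^nu sigma^{2nu} (-1)^k C(-2nu, j)
#             C(theta j + (theta-1) nu, k),
#   g_k(x)  = x^{-3nu} exp(-(k + nu)(sigma/x)^2),
# from expanding (1+u)^{-2nu} (|u| < 1) and the inner binomial.  Direct
# truncation of the resulting moment/entropy double sums is numerically
# catastrophic: the inner alternating binomial k-sum is tiny relative to its
# largest term, and the outer j-sum alternates with only logarithmic decay.
# We therefore evaluate the inner k-sum in its exact integral form
# (a Hausdorff-moment resummation) and accelerate the outer alternating
# j-sum with Euler's transformation, which converges geometrically here.
# See the methods vignette for the derivation and validity conditions.

# inner k-sum of the moment series:
#   sum_k (-1)^k C(m, k) (k+1)^{r/2-1}
#     = (1/Gamma(1-r/2)) Int_0^1 s^m (-log(1-s))^{-r/2} ds,  m = theta(j+1)-1
moment_inner <- function(j, r, theta) {
  m <- theta * (j + 1) - 1
  f <- function(s) exp(m * base::log(s) - (r / 2) * base::log(-log1p(-s)))
  stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value
}

#' Raw moments of the HLEIRD
#'
#' The r-th raw moment \eqn{\mu'_r = E[X^r]}, which exists only for
#' \eqn{0 < r < \min(2, 2\theta)}: the upper tail of the density decays
#' like \eqn{x^{-(1+2\theta)}} with \eqn{\theta = \alpha\lambda} (and like
#' \eqn{x^{-3}} once \eqn{\theta \ge 1}), so there is never a variance, and
#' a mean only when \eqn{\theta > 1/2}.  The default method sums
#' the series representation
#' \deqn{\mu'_r = 2\theta \sum_{j,k} (-1)^{j+k} (j+1)
#'   \binom{\theta(j+1)-1}{k} \frac{(\sigma^2(k+1))^{r/2}\,
#'   \Gamma(1-r/2)}{k+1}, \qquad \theta = \alpha\lambda,}
#' with the inner sum resummed in closed integral form and the outer
#' alternating sum Euler-accelerated; `method = "quadrature"` integrates
#' \eqn{x^r f(x)} directly instead.
#'
#' @param r moment order, a real in (0, 2).
#' @param params an [hleird_params()] object (or numeric triple).
#' @param control a [series_control()] object.
#' @param method `"series"` (the representation above) or `"quadrature"`.
#' @return The raw moment, a positive number.
#' @examples
#' hleird_moment(1, hleird_params(1, 1, 1))
#' @export
hleird_moment <- function(r, params, control = series_control(),
                          method = c("series", "quadrature")) {
  params <- as_hleird_params(params)
  method <- match.arg(method)
  if (!is.finite(r) || r <= 0) stop("'r' must be a positive real below 2")
  theta <- params$theta; sigma <- params$sigma
  # upper tail f ~ x^{-(1+2*theta)}: E[X^r] exists iff r < min(2, 2*theta)
  if (r >= 2 || r >= 2 * theta)
    stop("moment of order ", r, " does not exist for the HLEIRD ",
         "(requires r < min(2, 2*alpha*lambda))")
  if (method == "quadrature") {
    # substitute y = 1/x for a Gaussian-decaying integrand
    f <- function(y) {
      v <- exp(dhleird(1 / y, sigma, params$alpha, params$lambda, log = TRUE) -
                 (r + 2) * base::log(y))
      ifelse(is.finite(v), v, 0)
    }
    return(quad_0inf(f, split = 1 / sigma))
  }
  J <- min(control$max_terms_j, 60L)
  b <- vapply(0:J, function(j) (j + 1) * moment_inner(j, r, theta), numeric(1))
  val <- 2 * theta * sigma^r * euler_alt_sum(b)
  tail_est <- 2 * theta * sigma^r * b[length(b)] / 2^length(b)
  if (abs(tail_est) > control$abs_tol)
    warning("series truncation tail estimate ", format(tail_est),
            " exceeds abs_tol; increase max_terms_j")
  val
}

#' @rdname hleird_moment
#' @export
hleird_mean <- function(params, control = series_control()) {
  hleird_moment(1, params, control)
}

# inner integral of the entropy series, in the variable t = e^{-w}:
#   sum_k (-1)^k C(ex_j + ..., k) (k+delta)^{-beta}  resummed as
#   (1/Gamma(beta)) Int_0^inf e^{-delta w} (1-e^{-w})^{ex} w^{beta-1} dw
entropy_inner <- function(ex, delta, beta) {
  f <- function(w) exp(-delta * w + ex * base::log(-expm1(-w)) +
                         (beta - 1) * base::log(w))
  stats::integrate(f, 0, 1, rel.tol = 1e-12, abs.tol = 0)$value +
    stats::integrate(f, 1, Inf, rel.tol = 1e-12, abs.tol = 0)$value
}

# Int f^delta dx by the series representation (shared by both entropies)
hleird_density_power_integral <- function(delta, params, control,
                                          method = c("series", "quadrature")) {
  params <- as_hleird_params(params)
  method <- match.arg(method)
  theta <- params$theta; sigma <- params$sigma
  if (method == "quadrature") {
    f <- function(x) {
      v <- exp(delta * dhleird(x, sigma, params$alpha, params$lambda, log = TRUE))
      ifelse(is.finite(v), v, 0)
    }
    return(quad_0inf(f, split = sigma))
  }
  beta <- (3 * delta - 1) / 2
  if (beta <= 0)
    stop("series representation requires delta > 1/3")
  if ((theta - 1) * delta + beta <= 0 || (theta - 1) * delta <= -1)
    stop("series representation invalid here (j = 0 term diverges); ",
         "use method = \"quadrature\"")
  J <- min(control$max_terms_j, 60L)
  b <- vapply(0:J, function(j) {
    abs(gbinom(-2 * delta, j)) *
      entropy_inner(theta * j + (theta - 1) * delta, delta, beta)
  }, numeric(1))
  4^delta * theta^delta * sigma^(1 - delta) / 2 * euler_alt_sum(b)
}

#' Entropy measures of the HLEIRD
#'
#' Rényi entropy \eqn{I_\delta = (1-\delta)^{-1}\log \int f^\delta dx}
#' (`hleird_entropy_renyi`), the q-entropy
#' \eqn{H_q = (1-q)^{-1}(1 - \int f^q dx)} (`hleird_entropy_q`) and the
#' Shannon entropy \eqn{-\int f \log f\, dx} by quadrature
#' (`hleird_entropy_shannon`, the \eqn{\delta \to 1} limit of both).
#' The series method evaluates \eqn{\int f^\delta} through the linear
#' representation of \eqn{f^\delta}; it requires \eqn{\delta > 1/3} and
#' \eqn{(\theta-1)\delta + (3\delta-1)/2 > 0}.
#'
#' @param delta,q entropy order, positive and different from 1.
#' @inheritParams hleird_moment
#' @return The entropy value (a real number).
#' @export
hleird_entropy_renyi <- function(delta, params, control = series_control(),
                                 method = c("series", "quadrature")) {
  if (!is.finite(delta) || delta <= 0 || delta == 1)
    stop("'delta' must be positive and different from 1")
  base::log(hleird_density_power_integral(delta, params, control, method)) /
    (1 - delta)
}

#' @rdname hleird_entropy_renyi
#' @export
hleird_entropy_q <- function(q, params, control = series_control(),
                             method = c("series", "quadrature")) {
  if (!is.finite(q) || q <= 0 || q == 1)
    stop("'q' must be positive and different from 1")
  (1 - hleird_density_power_integral(q, params, control, method)) / (1 - q)
}

#' @rdname hleird_entropy_renyi
#' @export
hleird_entropy_shannon <- function(params) {
  params <- as_hleird_params(params)
  f <- function(x) {
    l <- dhleird(x, params$sigma, params$alpha, params$lambda, log = TRUE)
    v <- -exp(l) * l
    ifelse(is.finite(v), v, 0)
  }
  quad_0inf(f, split = params$sigma)
}

#' Linear representation of powers of the HLEIRD density
#'
#' `hleird_power_coef` returns the coefficient table \eqn{c_{j,k}(\nu)} of
#' the series expansion of \eqn{f(x)^\nu} in the kernels
#' \eqn{g_k(x) = x^{-3\nu} e^{-(k+\nu)(\sigma/x)^2}};
#' `hleird_power_series` evaluates the truncated double sum pointwise,
#' stopping each sum adaptively when the next block falls below
#' `control$abs_tol` (both sums converge geometrically pointwise, with
#' ratios \eqn{(1-e^{-z})^\theta} and \eqn{e^{-z}}).
#'
#' @param nu positive power of the density.
#' @param x vector of positive evaluation points.
#' @param j_max,k_max extents of the returned coefficient table.
#' @inheritParams hleird_moment
#' @return `hleird_power_coef`: a data frame with columns `j`, `k`,
#'   `coef`.  `hleird_power_series`: the values of \eqn{f(x)^\nu}.
#' @export
hleird_power_coef <- function(nu, params, j_max = 10L, k_max = 10L) {
  params <- as_hleird_params(params)
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be positive")
  theta <- params$theta
  grid <- expand.grid(j = 0:j_max, k = 0:k_max)
  pref <- 4^nu * theta^nu * params$sigma^(2 * nu)
  grid$coef <- pref * (-1)^grid$k * gbinom(-2 * nu, grid$j) *
    mapply(function(j, k) gbinom(theta * j + (theta - 1) * nu, k),
           grid$j, grid$k)
  grid
}

#' @rdname hleird_power_coef
#' @export
hleird_power_series <- function(x, nu, params, control = series_control()) {
  params <- as_hleird_params(params)
  if (!is.finite(nu) || nu <= 0) stop("'nu' must be positive")
  theta <- params$theta; sigma <- params$sigma
  vapply(x, function(xx) {
    if (!is.finite(xx) || xx <= 0) return(0)
    z <- (sigma / xx)^2
    emz <- exp(-z)
    pref <- 4^nu * theta^nu * sigma^(2 * nu) * xx^(-3 * nu) * exp(-nu * z)
    total <- 0
    for (j in 0:control$max_terms_j) {
      cj <- gbinom(-2 * nu, j)
      m <- theta * j + (theta - 1) * nu
      # inner sum_k (-1)^k C(m,k) e^{-kz} = (1 - e^{-z})^m; the explicit
      # alternating sum cancels catastrophically once m*e^{-z} is large
      # (its largest term dwarfs the total), so it is summed literally only
      # while well-conditioned and by its binomial closed form beyond that
      if (m * emz < 1 && m < 200) {
        inner <- 0
        term <- 1
        for (k in 0:control$max_terms_k) {
          inner <- inner + term
          term <- term * (-(m - k) / (k + 1)) * emz
          if (abs(term) < control$abs_tol * 1e-3 && k > m) break
        }
      } else {
        inner <- exp(m * base::log(-expm1(-z)))
      }
      block <- cj * inner
      total <- total + block
      # outer geometric ratio (1-e^{-z})^theta < 1
      if (abs(block) < control$abs_tol && j > 2) break
    }
    pref * total
  }, numeric(1))
}

#' Moment generating function of the HLEIRD
#'
#' \eqn{E[e^{tX}]} exists only for \eqn{t \le 0}: the density's upper tail
#' decays like \eqn{x^{-3}}, so the mgf diverges for every \eqn{t > 0}.
#' `hleird_mgf` computes the transform by quadrature on the valid half-line.
#' `hleird_mgf_coef` returns the formal series coefficient \eqn{\mu'_r / r!}
#' of \eqn{t^r}: finite only for \eqn{r \in (0, 2)} (in particular the
#' coefficient of \eqn{t^1} is the mean); `Inf` for \eqn{r \ge 2}.
#'
#' @param t transform argument, \eqn{t \le 0}.
#' @inheritParams hleird_moment
#' @export
hleird_mgf <- function(t, params) {
  params <- as_hleird_params(params)
  vapply(t, function(tt) {
    if (!is.finite(tt)) return(NA_real_)
    if (tt > 0) stop("the HLEIRD mgf diverges for t > 0")
    if (tt == 0) return(1)
    f <- function(x) {
      v <- exp(tt * x + dhleird(x, params$sigma, params$alpha, params$lambda,
                                log = TRUE))
      ifelse(is.finite(v), v, 0)
    }
    quad_0inf(f, split = params$sigma)
  }, numeric(1))
}

#' @rdname hleird_mgf
#' @export
hleird_mgf_coef <- function(r, params, control = series_control()) {
  params <- as_hleird_params(params)
  vapply(r, function(rr) {
    if (rr == 0) return(1)
    if (rr >= 2 || rr >= 2 * params$theta) return(Inf)
    hleird_moment(rr, params, control) / gamma(rr + 1)
  }, numeric(1))
}
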