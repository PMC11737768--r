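# Internal numerical utilities.

# Generalized binomial coefficient choose(a, k) for real a, integer k >= 0,
# via the falling-factorial product (base choose() already does this for
# real a, but warns and rounds in some versions; keep an explicit version).
gbinom <- function(a, k) {
  vapply(k, function(kk) {
    if (kk < 0) return(0)
    if (kk == 0) return(1)
    prod((a - seq_len(kk) + 1) / seq_len(kk))
  }, numeric(1))
}

# Euler transformation of the alternating series sum_{j>=0} (-1)^j b[j+1].
# Converges geometrically for (essentially) totally monotone b, and is the
# Abel sum where the raw series converges only conditionally.
euler_alt_sum <- function(b) {
  s <- 0
  d <- b
  for (m in seq_along(b) - 1L) {
    s <- s + d[1L] * (-1)^m / 2^(m + 1)
    d <- diff(d)
  }
  s
}

# Moore-Penrose pseudo-inverse via SVD (for the ridge-singular 3x3
# information matrix).
pinv <- function(m, tol = sqrt(.Machine$double.eps)) {
  s <- svd(m)
  pos <- s$d > tol * max(s$d)
  if (!any(pos)) return(matrix(0, ncol(m), nrow(m)))
  s$v[, pos, drop = FALSE] %*% (t(s$u[, pos, drop = FALSE]) / s$d[pos])
}

# Run expr with a private RNG stream; the caller's .Random.seed is untouched.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Central-difference gradient and Hessian (test oracles and profile-mode
# standard errors; kept dependency-free).
num_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-6
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h[i]
    (f(x + e) - f(x - e)) / (2 * h[i])
  }, numeric(1))
}

num_hessian <- function(f, x, h = NULL) {
  p <- length(x)
  if (is.null(h)) h <- pmax(abs(x), 1) * 1e-4
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  for (i in seq_len(p)) {
    ei <- numeric(p); ei[i] <- h[i]
    H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / h[i]^2
    for (j in seq_len(p)) {
      if (j <= i) next
      ej <- numeric(p); ej[j] <- h[j]
      H[i, j] <- H[j, i] <-
        (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
        (4 * h[i] * h[j])
    }
  }
  (H + t(H)) / 2
}

# Robust 1d quadrature on (0, Inf) with a tolerance ladder.
quad_0inf <- function(f, rel.tol = 1e-10, split = NULL) {
  for (tol in c(rel.tol, 1e-8, 1e-6)) {
    v <- tryCatch({
      if (is.null(split)) {
        stats::integrate(f, 0, Inf, rel.tol = tol, abs.tol = 0)$value
      } else {
        stats::integrate(f, 0, split, rel.tol = tol, abs.tol = 0)$value +
          stats::integrate(f, split, Inf, rel.tol = tol, abs.tol = 0)$value
      }
    }, error = function(e) NULL)
    if (!is.null(v)) return(v)
  }
  stop("quadrature failed on (0, Inf)")
}
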