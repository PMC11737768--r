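#' Parameter set of the half-logistic exponentiated inverse Rayleigh law
#'
#' Bundles the scale parameter `sigma` and the two shape parameters `alpha`
#' and `lambda` of the HLEIRD, together with the identified product
#' `theta = alpha * lambda`.  The distribution depends on `alpha` and
#' `lambda` only through `theta`: the parameter triples `(sigma, alpha,
#' lambda)` and `(sigma, c*alpha, lambda/c)` describe the same law for any
#' `c > 0` (the "identifiability ridge").  `theta` is always recomputed
#' from `alpha` and `lambda`, never stored independently.
#'
#' @param sigma positive scale parameter, in the units of the data.
#' @param alpha positive shape parameter.
#' @param lambda positive shape parameter (the half-logistic transform
#'   exponent).
#' @return An object of class `"hleird_params"`: a list with elements
#'   `sigma`, `alpha`, `lambda` and `theta`.
#' @examples
#' p <- hleird_params(2, 2, 2)
#' p$theta  # 4
#' @export
hleird_params <- function(sigma, alpha = 1, lambda = 1) {
  stopifnot(length(sigma) == 1, length(alpha) == 1, length(lambda) == 1)
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be a positive real")
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be a positive real")
  if (!is.finite(lambda) || lambda <= 0) stop("'lambda' must be a positive real")
  structure(list(sigma = sigma, alpha = alpha, lambda = lambda,
                 theta = alpha * lambda),
            class = "hleird_params")
}

#' @export
print.hleird_params <- function(x, ...) {
  cat(sprintf("HLEIRD parameters: sigma = %g, alpha = %g, lambda = %g (theta = alpha*lambda = %g)\n",
              x$sigma, x$alpha, x$lambda, x$theta))
  invisible(x)
}

as_hleird_params <- function(p) {
  if (inherits(p, "hleird_params")) return(p)
  if (is.numeric(p) && length(p) == 3)
    return(hleird_params(p[[1]], p[[2]], p[[3]]))
  stop("expected an 'hleird_params' object or a numeric triple (sigma, alpha, lambda)")
}

#' Truncation control for the series representations
#'
#' Controls the double-sum truncation used by the series forms of the raw
#' moments, the Rényi and q-entropies and the power-of-density linear
#' representation.
#'
#' @param max_terms_j maximum number of outer-series terms.
#' @param max_terms_k maximum number of inner-series terms (pointwise
#'   reconstruction only; the moment/entropy inner sums are evaluated in
#'   closed integral form).
#' @param abs_tol absolute truncation tail target.
#' @return An object of class `"series_control"`.
#' @export
series_control <- function(max_terms_j = 200L, max_terms_k = 200L,
                           abs_tol = 1e-10) {
  stopifnot(max_terms_j >= 1, max_terms_k >= 1, abs_tol > 0)
  structure(list(max_terms_j = as.integer(max_terms_j),
                 max_terms_k = as.integer(max_terms_k),
                 abs_tol = abs_tol),
            class = "series_control")
}
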