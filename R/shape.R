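#' Quantile-based shape measures of the HLEIRD
#'
#' Because only the first moment of the HLEIRD exists, skewness and
#' kurtosis are measured from quantiles: Galton's skewness
#' \deqn{S = \frac{(Q_3 - Q_2) - (Q_2 - Q_1)}{Q_3 - Q_1} \in (-1, 1)}
#' from the quartiles \eqn{Q_i = Q(i/4)}, and Moors' kurtosis
#' \deqn{K = \frac{(E_7 - E_5) + (E_3 - E_1)}{E_6 - E_2} > 0}
#' from the octiles \eqn{E_i = Q(i/8)} (about 1.23 for a normal law).
#' Both are scale-free (invariant to `sigma`) and depend on the shapes
#' only through \eqn{\theta = \alpha\lambda}.
#'
#' @inheritParams hleird_moment
#' @return A list of class `"hleird_shape"` with elements
#'   `galton_skewness` and `moors_kurtosis`.
#' @examples
#' hleird_shape(hleird_params(2, 2, 2))
#' @export
hleird_shape <- function(params) {
  params <- as_hleird_params(params)
  q <- qhleird(c(1, 2, 3) / 4, params$sigma, params$alpha, params$lambda)
  e <- qhleird((1:7) / 8, params$sigma, params$alpha, params$lambda)
  structure(list(
    galton_skewness = ((q[3] - q[2]) - (q[2] - q[1])) / (q[3] - q[1]),
    moors_kurtosis = ((e[7] - e[5]) + (e[3] - e[1])) / (e[6] - e[2])
  ), class = "hleird_shape")
}

#' @export
print.hleird_shape <- function(x, ...) {
  cat(sprintf("Galton skewness: %.6f   Moors kurtosis: %.5f\n",
              x$galton_skewness, x$moors_kurtosis))
  invisible(x)
}
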