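#' Carbon-fiber tensile strength data
#'
#' Tensile strength (GPa) of single carbon fibers, n = 69 in each set:
#' fibers tested under tension at a gauge length of 20 mm
#' (`"20mm"`, Badar and Priest's classical data) and at a gauge length of
#' 10 mm (`"10mm"`).  Values are embedded exactly as printed in the
#' source tables; both sets contain exact ties, which matters for the
#' spacings estimator.
#'
#' @param gauge `"20mm"` (data set one) or `"10mm"` (data set two).
#' @return A numeric vector of 69 strictly positive strengths with a
#'   `"label"` attribute.
#' @examples
#' summarize_sample(carbon_fibers("20mm"))
#' @export
carbon_fibers <- function(gauge = c("20mm", "10mm")) {
  gauge <- match.arg(gauge)
  x <- if (gauge == "20mm") {
    c(1.312, 1.314, 1.479, 1.552, 1.700, 1.803, 1.861, 1.865, 1.944, 1.958,
      1.966, 1.997, 2.006, 2.021, 2.027, 2.055, 2.063, 2.098, 2.14, 2.179,
      2.224, 2.240, 2.253, 2.270, 2.272, 2.274, 2.301, 2.301, 2.359, 2.382,
      2.382, 2.426, 2.434, 2.435, 2.478, 2.490, 2.511, 2.514, 2.535, 2.554,
      2.566, 2.57, 2.586, 2.629, 2.633, 2.642, 2.648, 2.684, 2.697, 2.726,
      2.770, 2.773, 2.800, 2.809, 2.818, 2.821, 2.848, 2.88, 2.954, 3.012,
      3.067, 3.084, 3.090, 3.096, 3.128, 3.233, 3.433, 3.585, 3.585)
  } else {
    c(0.562, 0.564, 0.729, 0.802, 0.950, 1.053, 1.111, 1.115, 1.194, 1.208,
      1.216, 1.247, 1.256, 1.271, 1.277, 1.305, 1.313, 1.348, 1.390, 1.429,
      1.474, 1.490, 1.503, 1.520, 1.522, 1.524, 1.551, 1.551, 1.609, 1.632,
      1.632, 1.676, 1.684, 1.685, 1.728, 1.740, 1.761, 1.764, 1.785, 1.804,
      1.816, 1.824, 1.836, 1.879, 1.883, 1.892, 1.898, 1.934, 1.947, 1.976,
      2.020, 2.023, 2.050, 2.059, 2.068, 2.071, 2.098, 2.130, 2.204, 2.262,
      2.317, 2.334, 2.340, 2.346, 2.378, 2.483, 2.683, 2.835, 2.835)
  }
  attr(x, "label") <- paste0("carbon fibers, ", gauge, " gauge")
  x
}

#' Descriptive summary of a positive sample
#'
#' Sample size, extremes, quartiles (linear-interpolation convention,
#' the default of [stats::quantile()]), mean, unbiased variance, and the
#' moment coefficients of skewness \eqn{g_1 = m_3 / m_2^{3/2}} and
#' kurtosis \eqn{b_2 = m_4 / m_2^2} (central moments with n
#' denominators; `b_2`, not excess).  A constant sample gets variance 0
#' and `NA` shape coefficients.
#'
#' @param x numeric sample, `length(x) >= 2`.
#' @return A list of class `"sample_summary"`.
#' @export
summarize_sample <- function(x) {
  if (length(x) < 2) stop("need at least two observations")
  qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  m2 <- mean((x - mean(x))^2)
  if (m2 > 0) {
    sk <- mean((x - mean(x))^3) / m2^1.5
    ku <- mean((x - mean(x))^4) / m2^2
  } else {
    sk <- NA_real_
    ku <- NA_real_
  }
  structure(list(n = length(x), min = min(x), q1 = qs[1], median = qs[2],
                 mean = mean(x), q3 = qs[3], max = max(x),
                 variance = stats::var(x), skewness = sk, kurtosis = ku),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  v <- unlist(x)
  print(round(v, 4))
  invisible(x)
}

#' Read a positive sample from a text or CSV file
#'
#' Accepts a single column of numbers (header optional), values
#' separated by whitespace, commas or newlines; blank lines are skipped.
#'
#' @param path file path.
#' @return Numeric vector of strictly positive values.
#' @export
read_lifetime_sample <- function(path) {
  raw <- readLines(path, warn = FALSE)
  raw <- trimws(unlist(strsplit(raw, "[,[:space:]]+")))
  raw <- raw[nzchar(raw)]
  x <- suppressWarnings(as.numeric(raw))
  if (length(x) && is.na(x[1]) && !is.na(suppressWarnings(as.numeric(raw[2])))) {
    x <- x[-1]  # tolerate a single header token
  }
  if (any(is.na(x))) stop("non-numeric values in ", path)
  if (!length(x)) stop("no data in ", path)
  if (any(x <= 0)) stop("sample must be strictly positive")
  x
}
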