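Package: hleird
Title: The Half-Logistic Exponentiated Inverse Rayleigh Distribution
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Density, distribution function, quantile function, random
    generation, hazard and survival functions for the half-logistic
    exponentiated inverse Rayleigh distribution (HLEIRD), a three-parameter
    lifetime model obtained by applying the type-I half-logistic transform
    to the exponentiated inverse Rayleigh baseline.  Series-based raw
    moments, Renyi and q-entropies, order-statistic densities and
    quantile-based shape measures (Galton skewness, Moors kurtosis).  Five
    estimation methods (maximum likelihood, ordinary and weighted least
    squares on the order-statistic cdf, Cramer-von Mises minimum distance,
    maximum product of spacings) with Wald intervals, goodness-of-fit
    statistics (Kolmogorov-Smirnov, Anderson-Darling, Cramer-von Mises)
    and information-criterion model comparison against inverse Rayleigh
    type competitors, a Monte Carlo harness for estimator comparison, and
    the two embedded carbon-fiber strength data sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, optparse, fitdistrplus
Config/testthat/edition: 3
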