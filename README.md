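# hleird

Lifetime data in reliability engineering and survival analysis — fiber
strengths, failure times, survival durations — often show skewness and
hazard shapes that classical two-parameter families cannot track. The
**half-logistic exponentiated inverse Rayleigh distribution (HLEIRD)** is a
three-parameter family built for such data: it applies the type-I
half-logistic transform to the exponentiated inverse Rayleigh baseline and
can produce decreasing, increasing and upside-down-bathtub hazard rates.
This package is a complete, tested implementation of the family and of the
estimation/model-comparison workflow around it, for statisticians and
reliability analysts who want to fit it, simulate from it, or benchmark
estimators on it.

## The model

With scale `σ > 0` and shapes `α, λ > 0`, write `z = (σ/x)²` and
`u = (1 − e^{−z})^{αλ}`. Then

    F(x) = (1 − u) / (1 + u),   x > 0
    f(x) = 4αλσ² e^{−z} (1 − e^{−z})^{αλ−1} / [x³ (1 + u)²]
    Q(p) = σ [ −log(1 − ((1−p)/(1+p))^{1/(αλ)}) ]^{−1/2}

The two shapes enter only through their product `θ = αλ` (the
*identifiability ridge*): `(σ, α, λ)` and `(σ, cα, λ/c)` describe the same
law for every `c > 0`, so only `(θ, σ)` is estimable. The upper tail decays
like `x^{−(1+2θ)}`, hence `E[X^r]` exists only for `r < min(2, 2θ)` — there
is never a variance, and skewness/kurtosis are measured from quantiles
(Galton skewness, Moors kurtosis).

The package provides:

* `dhleird` / `phleird` / `qhleird` / `rhleird` (plus survival `shleird`,
  hazard `hhleird`), numerically stable in both tails;
* series-based raw moments and Rényi/q-entropies with quadrature
  cross-check methods, order-statistic densities, quantile shape measures;
* five estimators behind one interface, `fit_hleird(x, method = ...)`:
  maximum likelihood (`mle`), ordinary and weighted least squares on the
  order-statistic cdf (`lse`, `wlse`), Cramér–von Mises minimum distance
  (`cvme`) and maximum product of spacings (`mps`, with the Cheng–Amin tie
  correction), with Wald standard errors on the identifiable pair;
* goodness of fit (`gof_report`: K–S, Anderson–Darling, Cramér–von Mises,
  asymptotic or bootstrap p-values), information criteria and multi-model
  comparison (`compare_models`) against the exponentiated inverse
  Rayleigh, inverse Rayleigh, Rayleigh and inverse Weibull models;
* a Monte Carlo estimator-comparison harness (`hleird_mc_study`,
  `hleird_mc_rank`);
* the two classical carbon-fiber strength datasets (`carbon_fibers`,
  n = 69 each) and a small command line front end
  (`inst/cli/hleird.R`: `summarize | fit | gof | compare | simulate`).

## Worked example

Fitting the 20 mm gauge carbon-fiber strengths:

```r
library(hleird)
x <- carbon_fibers("20mm")
f <- fit_hleird(x, method = "mle")
print(f)
#> HLEIRD fit (MLE, profile mode), n = 69
#>   sigma = 3.65389  alpha = 1  lambda = 10.2773  (theta = 10.2773)
#>   maximized log-likelihood: -50.5019
#>   std. errors (observed information, (theta, sigma)):
#>   theta   sigma
#> 2.55873 0.21977

information_criteria(f$loglik, q = 3, n = f$n)
#>      AIC     CAIC      BIC     HQIC
#> 107.0037 116.7061 113.7061 109.6628

gof_report(f)
#> Goodness of fit (n = 69, asymptotic p-values)
#>   A2 = 0.3723 (p = 0.876)   W = 0.04564 (p = 0.902)   K-S = 0.05965 (p = 0.967)

hleird_shape(hleird_params(2, 2, 2))
#> Galton skewness: 0.106396   Moors kurtosis: 1.27979
```

The fitted maximum log-likelihood is −50.502 (AIC 107.00), the estimated
identifiable pair is `θ̂ ≈ 10.28`, `σ̂ ≈ 3.654`, and the large K–S p-value
(0.97) says the model tracks the empirical cdf closely — and better, by
AIC, than its four competitors (`compare_models(x)` ranks HLEIRD first on
both gauges).

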