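# Monte Carlo estimator-comparison harness.

#' Default parameter grid of the estimator-comparison study
#'
#' The eight `(sigma, alpha, lambda)` triples of the simulation design:
#' all combinations of sigma in {0.5, 1}, alpha in {0.5, 1} and lambda in
#' {1, 2}.
#'
#' @return A list of [hleird_params()] objects.
#' @export
hleird_mc_grid <- function() {
  out <- list()
  for (lambda in c(1, 2)) for (alpha in c(0.5, 1)) for (sigma in c(0.5, 1))
    out[[length(out) + 1]] <- hleird_params(sigma, alpha, lambda)
  out
}

#' Monte Carlo bias/MSE study of the five estimators
#'
#' Draws `replicates` HLEIRD samples for each sample size and parameter
#' configuration, applies the requested estimators and tabulates the
#' average bias and mean squared error of each parameter estimate.
#' Following the study's convention, each replicate's optimizer is the
#' free 3-parameter simplex started at the true parameter values (on the
#' likelihood ridge the individual `alpha`/`lambda` columns are
#' meaningful only under a fixed start convention; the `sigma` and
#' `theta` columns are start-independent).  Replicates whose fit throws
#' are counted and excluded; a cell whose failure rate exceeds 1% is
#' flagged.
#'
#' @param params a single [hleird_params()] object or a list of them
#'   (e.g. [hleird_mc_grid()]).
#' @param n vector of sample sizes.
#' @param replicates Monte Carlo replicates per cell.
#' @param methods subset of `c("mle", "lse", "wlse", "cvme", "mps")`.
#' @param seed integer seed; the study is bit-reproducible given it.
#' @return A data frame of class `"hleird_mc"` with one row per
#'   (configuration, n, method) cell: true parameters, bias and MSE per
#'   parameter (including `theta`), failure count and flag.
#' @examples
#' \donttest{
#' rep <- hleird_mc_study(hleird_params(0.5, 0.5, 1), n = c(20, 50),
#'                        replicates = 100, methods = "mle", seed = 1)
#' }
#' @export
hleird_mc_study <- function(params, n = c(20, 40, 70, 100, 150),
                            replicates = 1000,
                            methods = c("mle", "lse", "wlse", "cvme", "mps"),
                            seed = NULL) {
  if (inherits(params, "hleird_params")) params <- list(params)
  params <- lapply(params, as_hleird_params)
  methods <- match.arg(methods, several.ok = TRUE)
  stopifnot(replicates >= 1, all(n >= 5))
  run <- function() {
    rows <- list()
    for (cfg in params) {
      for (nn in n) {
        est <- array(NA_real_,
                     c(replicates, length(methods), 4),
                     dimnames = list(NULL, methods,
                                     c("sigma", "alpha", "lambda", "theta")))
        fails <- stats::setNames(integer(length(methods)), methods)
        for (r in seq_len(replicates)) {
          xx <- qhleird(stats::runif(nn), cfg$sigma, cfg$alpha, cfg$lambda)
          for (m in methods) {
            f <- tryCatch(fit_hleird(xx, method = m, mode = "free",
                                     start = cfg),
                          error = function(e) NULL)
            if (is.null(f)) fails[m] <- fails[m] + 1L
            else est[r, m, ] <- c(f$sigma, f$alpha, f$lambda, f$theta)
          }
        }
        for (m in methods) {
          e <- est[, m, , drop = FALSE]
          dim(e) <- c(replicates, 4)
          truth <- c(cfg$sigma, cfg$alpha, cfg$lambda, cfg$theta)
          dev <- sweep(e, 2, truth)
          bias <- colMeans(dev, na.rm = TRUE)
          mse <- colMeans(dev^2, na.rm = TRUE)
          rows[[length(rows) + 1]] <- data.frame(
            sigma = cfg$sigma, alpha = cfg$alpha, lambda = cfg$lambda,
            n = nn, method = m,
            bias_sigma = bias[1], bias_alpha = bias[2],
            bias_lambda = bias[3], bias_theta = bias[4],
            mse_sigma = mse[1], mse_alpha = mse[2],
            mse_lambda = mse[3], mse_theta = mse[4],
            n_fail = fails[m],
            flagged = fails[m] > 0.01 * replicates,
            row.names = NULL)
        }
      }
    }
    do.call(rbind, rows)
  }
  out <- if (is.null(seed)) run() else with_local_seed(seed, run())
  class(out) <- c("hleird_mc", class(out))
  out
}

#' Rank estimation methods by Monte Carlo MSE
#'
#' For each (configuration, n) cell of an [hleird_mc_study()] report,
#' ranks the methods by the sum of the three parameter MSEs (average
#' ranks on ties), then totals the ranks per method.
#'
#' @param report a data frame from [hleird_mc_study()].
#' @return A list with `cell_ranks` (long data frame of per-cell ranks),
#'   `rank_sum` (named vector) and `overall_rank` (named vector; 1 =
#'   best).
#' @export
hleird_mc_rank <- function(report) {
  stopifnot(is.data.frame(report))
  key <- interaction(report$sigma, report$alpha, report$lambda, report$n,
                     drop = TRUE)
  pieces <- lapply(split(report, key), function(cell) {
    total <- cell$mse_sigma + cell$mse_alpha + cell$mse_lambda
    cell$rank <- rank(total, ties.method = "average")
    cell[, c("sigma", "alpha", "lambda", "n", "method", "rank")]
  })
  cr <- do.call(rbind, pieces)
  rownames(cr) <- NULL
  rs <- tapply(cr$rank, cr$method, sum)
  list(cell_ranks = cr,
       rank_sum = rs[order(names(rs))],
       overall_rank = rank(rs, ties.method = "average")[order(names(rs))])
}
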