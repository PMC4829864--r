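#' Small-sample Akaike information criterion
#'
#' \eqn{AICc = -2\log L + 2k + 2k(k+1)/(n-k-1)}.
#'
#' @param logL maximised log-likelihood.
#' @param k number of free parameters.
#' @param n number of species.
#' @return the AICc value.
#' @examples
#' aicc(-10, 2, 48)
#' @export
aicc <- function(logL, k, n) {
  if (n - k - 1 <= 0)
    stop("AICc undefined: need n > k + 1 (n = ", n, ", k = ", k, ")")
  -2 * logL + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

# NA when the small-sample correction is undefined (n <= k + 1), so
# tiny worked examples can still be fitted.
aicc_or_na <- function(logL, k, n)
  if (n - k - 1 > 0) aicc(logL, k, n) else NA_real_

#' Rank fitted models by AICc
#'
#' @param fits a (optionally named) list of `model_fit` objects, e.g.
#'   from [fit_bm1()], [fit_bms()], [fit_ou1()].
#' @return a data.frame with one row per model, ascending in AICc, with
#'   columns `model`, `logL`, `k`, `aicc`, `delta_aicc`.
#' @export
compare_models <- function(fits) {
  stopifnot(length(fits) >= 1)
  tab <- data.frame(
    model = vapply(fits, function(f) f$model, character(1)),
    logL = vapply(fits, function(f) f$logL, numeric(1)),
    k = vapply(fits, function(f) f$k, integer(1)),
    aicc = vapply(fits, function(f) f$aicc, numeric(1)))
  tab <- tab[order(tab$aicc), , drop = FALSE]
  tab$delta_aicc <- tab$aicc - tab$aicc[1]
  rownames(tab) <- NULL
  tab
}
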