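# OU trait covariance on an ultrametric tree with the root at the
# optimum: V_ij = (sigma2/(2 alpha)) exp(-alpha d_ij) (1 - exp(-2 alpha t_ij)),
# d_ij = patristic distance, t_ij = shared time. Returned without the
# sigma2 factor (it is profiled out in the fit).
ou_correlation <- function(tree, alpha) {
  Ct <- vcv_tree(tree)
  depth <- max(diag(Ct))
  d <- 2 * (depth - Ct)  # patristic distance on an ultrametric tree
  exp(-alpha * d) * (1 - exp(-2 * alpha * Ct)) / (2 * alpha)
}

#' Ornstein-Uhlenbeck log-likelihood (single optimum)
#'
#' @param tree an ultrametric \code{phylo} object.
#' @param x named trait vector.
#' @param alpha adaptation rate (1/time), > 0.
#' @param sigma2 Brownian intensity, > 0.
#' @param theta phenotypic optimum (and root state).
#' @return the log-likelihood.
#' @export
ou_loglik <- function(tree, x, alpha, sigma2, theta) {
  stopifnot(alpha > 0, sigma2 > 0)
  if (!is_ultrametric(tree))
    stop("OU1 requires an ultrametric tree")
  X <- align_traits(tree, x)[, 1]
  V <- sigma2 * ou_correlation(tree, alpha)
  L <- chol_safe(V)
  r <- forwardsolve(t(L), X - theta)
  -0.5 * (length(X) * log(2 * pi) + 2 * sum(log(diag(L))) + sum(r^2))
}

#' Fit a single-optimum Ornstein-Uhlenbeck model (OU1)
#'
#' Maximum-likelihood fit of the OU model with a global optimum
#' \eqn{\theta} and adaptation rate \eqn{\alpha}, on an ultrametric tree
#' with the root placed at the optimum. \eqn{\theta} (GLS mean) and
#' \eqn{\sigma^2} are profiled in closed form; \eqn{\alpha} is maximised
#' by golden-section search of the profile likelihood over
#' \eqn{[10^{-8}, 50/T]} (T = tree depth). As \eqn{\alpha \to 0} the
#' model collapses to BM1 with the root as optimum.
#'
#' @param tree an ultrametric \code{phylo} object.
#' @param x named trait vector.
#' @param alpha_bounds optional length-2 vector overriding the search
#'   interval for \eqn{\alpha}.
#' @return an object of class `ou_fit` with fields `model`, `alpha`,
#'   `theta`, `sigma2`, `logL`, `k` (= 3), `n`, `aicc`, `at_bound`.
#' @export
fit_ou1 <- function(tree, x, alpha_bounds = NULL) {
  if (!is_ultrametric(tree))
    stop("OU1 requires an ultrametric tree")
  X <- align_traits(tree, x)[, 1]
  n <- length(X)
  depth <- max(node_heights(tree))
  if (is.null(alpha_bounds)) alpha_bounds <- c(1e-8, 50 / depth)

  profile <- function(log_alpha) {
    a <- exp(log_alpha)
    V0 <- ou_correlation(tree, a)
    L <- tryCatch(chol_safe(V0), error = function(e) NULL)
    if (is.null(L)) return(list(logL = -Inf))
    ones_w <- forwardsolve(t(L), rep(1, n))
    Xw <- forwardsolve(t(L), X)
    theta <- sum(ones_w * Xw) / sum(ones_w^2)
    q <- sum((Xw - theta * ones_w)^2)
    s <- q / n
    if (!is.finite(s) || s <= 0) return(list(logL = -Inf))
    logL <- -0.5 * (n * log(2 * pi * s) + 2 * sum(log(diag(L))) + n)
    list(logL = logL, alpha = a, theta = theta, sigma2 = s)
  }

  opt <- optimize(function(la) -profile(la)$logL,
                  interval = log(alpha_bounds), tol = 1e-10)
  best <- profile(opt$minimum)
  at_bound <- abs(opt$minimum - log(alpha_bounds[2])) < 1e-4
  if (at_bound)
    warning("OU1: alpha estimate is at its upper bound; ",
            "the optimum is effectively unidentifiable")
  logL <- best$logL
  structure(list(model = "OU1", alpha = best$alpha, theta = best$theta,
                 sigma2 = best$sigma2, logL = logL, k = 3L, n = n,
                 aicc = aicc_or_na(logL, 3L, n), at_bound = at_bound),
            class = c("ou_fit", "model_fit"))
}
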