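# Shared pruning front-end ---------------------------------------------

# Decompose tip data into independent contrasts + GLS root via the C++
# pruning pass. X may be a vector or a matrix of datasets (columns).
# Returns contrasts, pooled variances V_k, node ids, root value(s) and
# v_root = 1/(1'C^-1 1).
bm_prune <- function(tree, x) {
  X <- align_traits(tree, x)
  post <- reorder(tree, "postorder")
  bm_pruning_cpp(post$edge, post$edge.length, ape::Ntip(tree), X)
}

# log-likelihood from a pruning decomposition at given (sigma2, mu),
# for a single dataset (column j).
bm_loglik_from_prune <- function(pr, sigma2, root_state, j = 1) {
  n <- length(pr$contrast_var) + 1L
  css <- sum(pr$contrasts[, j]^2 / pr$contrast_var)
  -0.5 * ((n - 1) * log(2 * pi * sigma2) + sum(log(pr$contrast_var)) +
            css / sigma2 +
            log(2 * pi * sigma2 * pr$root_var) +
            (pr$root_value[j] - root_state)^2 / (sigma2 * pr$root_var))
}

#' Brownian-motion log-likelihood
#'
#' Log density of tip values under single-rate Brownian motion: a
#' multivariate normal with mean `root_state` and covariance
#' `sigma2 * vcv_tree(tree)`, evaluated in O(n) by Felsenstein pruning.
#'
#' @param tree a \code{phylo} object.
#' @param x named trait vector aligned to the tips.
#' @param sigma2 Brownian rate (squared trait units per unit time), > 0.
#' @param root_state trait value at the root.
#' @return the log-likelihood (scalar).
#' @examples
#' bm_loglik(read_newick("(A:1,B:1);"), c(A = 0, B = 2), 1, 1)
#' @export
bm_loglik <- function(tree, x, sigma2, root_state) {
  stopifnot(sigma2 > 0)
  bm_loglik_from_prune(bm_prune(tree, x), sigma2, root_state)
}

#' Fit single-rate Brownian motion (BM1)
#'
#' Maximum-likelihood fit of the single-rate Brownian model. The root
#' state is the GLS mean \eqn{(1'C^{-1}x)/(1'C^{-1}1)} and the ML rate is
#' the phylogenetically-corrected mean square with denominator `n`
#' (`rate_denominator = "n-1"` gives the REML/contrasts estimate).
#'
#' @param tree a \code{phylo} object.
#' @param x named trait vector.
#' @param rate_denominator `"n"` (ML, default) or `"n-1"` (REML).
#' @return an object of class `bm_fit` with fields `model`, `sigma2`,
#'   `root_state`, `logL`, `k`, `n`, `aicc`.
#' @export
fit_bm1 <- function(tree, x, rate_denominator = c("n", "n-1")) {
  rate_denominator <- match.arg(rate_denominator)
  n <- ape::Ntip(tree)
  if (n < 2) stop("at least two species are required")
  pr <- bm_prune(tree, x)
  css <- sum(pr$contrasts[, 1]^2 / pr$contrast_var)
  denom <- if (rate_denominator == "n") n else n - 1
  sigma2 <- css / denom
  if (sigma2 <= 0) stop("trait is constant: Brownian rate is zero")
  root <- pr$root_value[1]
  logL <- bm_loglik_from_prune(pr, css / n, root)  # logL at the ML rate
  structure(list(model = "BM1", sigma2 = sigma2, root_state = root,
                 logL = logL, k = 2L, n = n, aicc = aicc_or_na(logL, 2L, n)),
            class = c("bm_fit", "model_fit"))
}

#' @export
print.model_fit <- function(x, ...) {
  cat(x$model, "fit:", "logL =", format(x$logL, digits = 6),
      " k =", x$k, " AICc =", format(x$aicc, digits = 6), "\n")
  pars <- setdiff(names(x), c("model", "logL", "k", "n", "aicc", "convergence",
                              "at_bound"))
  for (p in pars)
    cat("  ", p, " = ", paste(format(x[[p]], digits = 6), collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Phylogenetically independent contrasts
#'
#' Standardized contrasts by Felsenstein's pruning recursion: at each
#' internal node the contrast is the difference between daughter values
#' divided by the square root of the pooled, branch-augmented variance;
#' the parent receives the weighted average and an augmented branch
#' length. Zero pooled variance (two daughters on zero-length branches)
#' raises an error rather than being regularised.
#'
#' @param tree a binary \code{phylo} object.
#' @param x named trait vector.
#' @return a data.frame with columns `node` (ape node id), `height`
#'   (time from root), and `contrast` (standardized, signed); `n - 1`
#'   rows for `n` tips.
#' @examples
#' pic_contrasts(read_newick("((A:1,B:1):1,C:2);"), c(A = 0, B = 2, C = 4))
#' @export
pic_contrasts <- function(tree, x) {
  pr <- bm_prune(tree, x)
  h <- node_heights(tree)
  data.frame(node = pr$contrast_node,
             height = h[pr$contrast_node],
             contrast = pr$contrasts[, 1] / sqrt(pr$contrast_var))
}

#' Ancestral state reconstruction under Brownian motion
#'
#' GLS/ML ancestral values: each internal node's state is the conditional
#' expectation given the tips under the fitted BM model,
#' \eqn{\hat a_u = \hat\mu + C_{u,tips} C^{-1} (x - \hat\mu 1)}. The root
#' value equals the [fit_bm1()] root state.
#'
#' @param tree a \code{phylo} object.
#' @param x named trait vector.
#' @return numeric vector of ancestral values, named by ape node id
#'   (`Ntip+1` .. `Ntip+Nnode`).
#' @export
asr_bm <- function(tree, x) {
  X <- align_traits(tree, x)
  n <- ape::Ntip(tree)
  mu <- fit_bm1(tree, X[, 1])$root_state
  h <- node_heights(tree)
  M <- ape::mrca(tree, full = TRUE)
  nodes <- n + seq_len(tree$Nnode)
  # shared time between internal node u and tip i = height of their MRCA
  Cui <- matrix(h[M[nodes, seq_len(n), drop = FALSE]],
                length(nodes), n)
  C <- vcv_tree(tree)
  L <- chol_safe(C)
  Cinv_r <- backsolve(L, forwardsolve(t(L), X[, 1] - mu))
  anc <- mu + as.numeric(Cui %*% Cinv_r)
  setNames(anc, nodes)
}

#' Phylogenetic regression residuals
#'
#' Residuals of a generalised-least-squares regression of `y` on `x`
#' (with intercept) that accounts for the expected phylogenetic
#' covariances among species: \eqn{\beta = (X'C^{-1}X)^{-1}X'C^{-1}y}.
#' The returned residuals are raw response residuals \eqn{y - X\beta}
#' (not re-whitened), ready for use as species-level size-corrected
#' trait values.
#'
#' @param tree a \code{phylo} object.
#' @param y named response vector (e.g. a log head dimension).
#' @param x named covariate vector (e.g. log body size).
#' @return named residual vector in tip-label order.
#' @export
pgls_residuals <- function(tree, y, x) {
  Y <- align_traits(tree, y)[, 1]
  Xc <- align_traits(tree, x)[, 1]
  D <- cbind(1, Xc)
  C <- vcv_tree(tree)
  L <- chol_safe(C)
  Dw <- forwardsolve(t(L), D)
  Yw <- forwardsolve(t(L), Y)
  qrD <- qr(Dw)
  if (qrD$rank < ncol(D)) stop("collinear design: covariate is constant")
  beta <- qr.coef(qrD, Yw)
  setNames(Y - as.numeric(D %*% beta), names(Y))
}

#' ML evolutionary rate matrix for multivariate Brownian motion
#'
#' \eqn{\hat R = (X - 1\hat\mu')' C^{-1} (X - 1\hat\mu') / n} with
#' per-trait GLS means; the multivariate analogue of the BM1 rate.
#'
#' @param tree a \code{phylo} object.
#' @param X species-by-trait matrix (rownames = tip labels), >= 2 traits.
#' @param denominator `"n"` (ML, default) or `"n-1"` (REML).
#' @return a symmetric positive semi-definite rate matrix.
#' @export
evol_vcv <- function(tree, X, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  X <- align_traits(tree, X)
  n <- nrow(X)
  if (ncol(X) < 1) stop("at least one trait is required")
  if (ncol(X) > n) stop("more traits than species")
  C <- vcv_tree(tree)
  L <- chol_safe(C)
  ones_w <- forwardsolve(t(L), rep(1, n))
  Xw <- forwardsolve(t(L), X)
  mu <- colSums(ones_w * Xw) / sum(ones_w^2)
  Ew <- Xw - outer(ones_w, mu)
  R <- crossprod(Ew) / if (denominator == "n") n else n - 1
  dimnames(R) <- list(colnames(X), colnames(X))
  R
}
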