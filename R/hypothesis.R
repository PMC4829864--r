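# Monte-Carlo p-value with the add-one correction: never 0, floor
# 1/(n_sims + 1) -- at 10,000 simulations the smallest reportable p is
# 1e-4.
mc_pvalue <- function(null, observed, tail = c("upper", "lower")) {
  tail <- match.arg(tail)
  k <- if (tail == "upper") sum(null >= observed) else sum(null <= observed)
  (1 + k) / (1 + length(null))
}

new_mc_test <- function(statistic, observed, null, tail, n_sims, seed) {
  structure(list(statistic = statistic, observed = observed,
                 null = null, tail = tail,
                 p_value = mc_pvalue(null, observed, tail),
                 n_sims = n_sims, seed = seed),
            class = "mc_test")
}

#' @export
print.mc_test <- function(x, ...) {
  cat("Monte-Carlo test of", x$statistic, "\n",
      " observed =", format(x$observed, digits = 5),
      "  p =", format(x$p_value, digits = 4),
      " (", x$tail, "tail,", x$n_sims, "simulations, seed", x$seed, ")\n")
  invisible(x)
}

#' One-way ANOVA F statistic
#'
#' Classical between/within mean-square ratio,
#' \eqn{F = (SSB/df_B)/(SSW/df_W)}. Vectorised over columns when `x` is
#' a matrix of datasets, which is what the simulation nulls exploit.
#'
#' @param x numeric vector, or matrix with one dataset per column.
#' @param groups group labels (same length as observations).
#' @return a scalar F (or one F per column).
#' @export
anova_f <- function(x, groups) {
  X <- if (is.null(dim(x))) matrix(x, ncol = 1) else as.matrix(x)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (any(table(g) == 0)) stop("every group must be non-empty")
  n <- nrow(X); G <- nlevels(g)
  cnt <- as.numeric(table(g))
  gm <- rowsum(X, g) / cnt
  grand <- colMeans(X)
  ssb <- colSums(cnt * (gm - rep(grand, each = G))^2)
  sst <- colSums(X^2) - n * grand^2
  ssw <- sst - ssb
  if (any(ssw <= 0))
    stop("zero within-group variance: F statistic undefined")
  out <- (ssb / (G - 1)) / (ssw / (n - G))
  if (is.null(dim(x))) out[[1]] else out
}

#' Wilks' lambda for one-way MANOVA
#'
#' \eqn{\Lambda = \det(W)/\det(W + B)} with within- and between-group
#' scatter matrices W and B; small values are extreme.
#'
#' @param X observations x traits matrix.
#' @param groups group labels.
#' @return the Wilks' lambda statistic.
#' @export
wilks_lambda <- function(X, groups) {
  X <- as.matrix(X)
  g <- factor(groups)
  if (nlevels(g) < 2) stop("at least two groups are required")
  if (any(table(g) == 0)) stop("every group must be non-empty")
  cnt <- as.numeric(table(g))
  gm <- rowsum(X, g) / cnt
  Xc <- X - gm[g, , drop = FALSE]
  W <- crossprod(Xc)
  grand <- colMeans(X)
  B <- crossprod(sweep(gm, 2, grand) * sqrt(cnt))
  evW <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(evW) <= 1e-12 * max(evW))
    stop("singular within-group scatter: Wilks' lambda undefined")
  dW <- determinant(W, logarithm = TRUE)
  dT <- determinant(W + B, logarithm = TRUE)
  if (dW$sign <= 0 || dT$sign <= 0)
    stop("singular within-group scatter: Wilks' lambda undefined")
  exp(as.numeric(dW$modulus - dT$modulus))
}

#' Phylogenetic ANOVA by Brownian simulation
#'
#' Tests for group differences in a trait against a null distribution of
#' F statistics from Brownian-motion simulations on the tree, with the
#' rate set to the ML estimate from the observed data and group labels
#' held fixed across simulations.
#'
#' @param tree a \code{phylo} object.
#' @param x named trait vector.
#' @param groups named group labels over the tips.
#' @param n_sims number of null simulations (>= 99).
#' @param seed integer seed (mandatory).
#' @return an object of class `mc_test` (upper tail).
#' @export
phylo_anova <- function(tree, x, groups, n_sims, seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_sims < 99) stop("use at least 99 simulations")
  X <- align_traits(tree, x)[, 1]
  g <- align_groups(tree, groups)
  fit <- fit_bm1(tree, X)
  obs <- anova_f(X, g)
  sims <- sim_bm(tree, fit$sigma2, fit$root_state, n_sims, seed = seed)
  null <- anova_f(sims, g)
  new_mc_test("F", obs, null, "upper", n_sims, seed)
}

#' Phylogenetic MANOVA by multivariate Brownian simulation
#'
#' As [phylo_anova()] but multivariate: the statistic is Wilks' lambda
#' (lower tail) and the null datasets are simulated under multivariate
#' Brownian motion with the ML evolutionary rate matrix ([evol_vcv()])
#' estimated from the observed traits.
#'
#' @param tree a \code{phylo} object.
#' @param X species x traits matrix (>= 2 traits).
#' @param groups named group labels over the tips.
#' @param n_sims number of null simulations (>= 99).
#' @param seed integer seed (mandatory).
#' @return an object of class `mc_test` (lower tail).
#' @export
phylo_manova <- function(tree, X, groups, n_sims, seed) {
  if (missing(seed)) stop("a seed is required")
  if (n_sims < 99) stop("use at least 99 simulations")
  X <- align_traits(tree, X)
  g <- align_groups(tree, groups)
  R <- evol_vcv(tree, X)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <=
      1e-12 * max(diag(R)))
    stop("singular evolutionary rate matrix: MANOVA null cannot be simulated")
  mu <- gls_means(tree, X)
  obs <- wilks_lambda(X, g)
  sims <- sim_mvbm(tree, R, mu, n_sims, seed = seed)
  null <- vapply(sims, wilks_lambda, numeric(1), groups = g)
  new_mc_test("WilksLambda", obs, null, "lower", n_sims, seed)
}

# GLS (phylogenetic) mean of each trait column.
gls_means <- function(tree, X) {
  X <- align_traits(tree, X)
  L <- chol_safe(vcv_tree(tree))
  ones_w <- forwardsolve(t(L), rep(1, nrow(X)))
  Xw <- forwardsolve(t(L), X)
  colSums(ones_w * Xw) / sum(ones_w^2)
}

align_groups <- function(tree, groups) {
  if (is.null(names(groups))) {
    if (length(groups) != ape::Ntip(tree))
      stop("unnamed group vector must have one label per tip")
    names(groups) <- tree$tip.label
  }
  g <- groups[tree$tip.label]
  if (anyNA(g)) stop("missing group label for some tips")
  factor(as.character(g))
}

#' Parametric bootstrap test of the multi-rate Brownian model
#'
#' Tests BMS (regime-specific rates) against BM1 (one rate) with the
#' log-likelihood difference as the statistic. The null distribution is
#' obtained by refitting both models to datasets simulated under the
#' fitted BM1; the p-value is upper-tail with the add-one correction.
#' Statistical power at 95% confidence is the fraction of datasets
#' simulated under the fitted BMS whose statistic exceeds the empirical
#' 95th percentile of the null sample.
#'
#' Replicates on which either fit fails are dropped and counted; more
#' than 5% failures aborts the test.
#'
#' @param tree a \code{phylo} object.
#' @param painting a \code{regime_painting} covering the tree.
#' @param x named trait vector.
#' @param n_boot number of bootstrap replicates (>= 99).
#' @param seed integer seed (mandatory).
#' @param n_power number of BMS-simulated datasets for the power
#'   estimate; `0` skips the power computation (default `n_boot`).
#' @return an object of class `bootstrap_result`: `observed_lr`,
#'   `null_lr`, `p_value`, `power`, `n_boot`, `n_failed`, `seed`, and
#'   the two observed fits.
#' @export
parametric_bootstrap_bms <- function(tree, painting, x, n_boot, seed,
                                     n_power = n_boot) {
  if (missing(seed)) stop("a seed is required")
  if (n_boot < 99) stop("use at least 99 bootstrap replicates")
  X <- align_traits(tree, x)[, 1]
  fit1 <- fit_bm1(tree, X)
  fitS <- fit_bms(tree, painting, x)
  obs_lr <- max(fitS$logL - fit1$logL, 0)

  lr_for <- function(y) {
    tryCatch({
      f1 <- fit_bm1(tree, y)
      fS <- fit_bms(tree, painting, y)
      max(fS$logL - f1$logL, 0)
    }, error = function(e) NA_real_)
  }

  null_sims <- sim_bm(tree, fit1$sigma2, fit1$root_state, n_boot,
                      seed = seed)
  null_lr <- vapply(seq_len(n_boot), function(b) lr_for(null_sims[, b]),
                    numeric(1))
  n_failed <- sum(is.na(null_lr))
  null_lr <- null_lr[!is.na(null_lr)]

  power <- NA_real_
  if (n_power > 0) {
    alt_sims <- sim_bm(tree, root_state = fitS$root_state, n_reps = n_power,
                       seed = seed + 1L, painting = painting,
                       rates = fitS$sigma2_by_regime)
    alt_lr <- vapply(seq_len(n_power), function(b) lr_for(alt_sims[, b]),
                     numeric(1))
    n_failed <- n_failed + sum(is.na(alt_lr))
    alt_lr <- alt_lr[!is.na(alt_lr)]
    thresh <- sort(null_lr)[ceiling(0.95 * length(null_lr))]
    power <- mean(alt_lr > thresh)
  }
  if (n_failed > 0.05 * (n_boot + max(n_power, 0)))
    stop("more than 5% of bootstrap replicates failed to fit (",
         n_failed, " failures)")

  structure(list(observed_lr = obs_lr, null_lr = null_lr,
                 p_value = mc_pvalue(null_lr, obs_lr, "upper"),
                 power = power, n_boot = n_boot, n_failed = n_failed,
                 seed = seed, fit_bm1 = fit1, fit_bms = fitS),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat("Parametric bootstrap, BMS vs BM1\n",
      " observed logL difference =", format(x$observed_lr, digits = 5),
      "\n  p =", format(x$p_value, digits = 4),
      "  power(95%) =", format(x$power, digits = 3),
      " (", x$n_boot, "replicates,", x$n_failed, "failed, seed",
      x$seed, ")\n")
  invisible(x)
}
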