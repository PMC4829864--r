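#' Fit multi-rate Brownian motion (BMS)
#'
#' Brownian motion in which each regime of a branch painting has its own
#' rate \eqn{\sigma^2_r}, so the trait covariance is
#' \eqn{\sum_r \sigma^2_r C_r} with \eqn{C_r} the per-regime shared-time
#' matrices of [regime_vcv()]. Equivalently, BMS is single-rate Brownian
#' motion on a tree whose branch segments are rescaled by their regime's
#' rate, which is how the likelihood is evaluated (pruning in O(n)).
#'
#' The overall rate scale and the root state are profiled out in closed
#' form; the remaining relative log-rates are maximised numerically with
#' three deterministic starts (all-equal, and the non-reference regimes
#' shrunk/inflated tenfold), so the fit can never fall below the nested
#' BM1 fit.
#'
#' @param tree a \code{phylo} object.
#' @param painting a \code{regime_painting} covering every branch; every
#'   regime in its alphabet must have positive total time.
#' @param x named trait vector.
#' @return an object of class `bms_fit` with fields `model`,
#'   `sigma2_by_regime`, `root_state`, `logL`, `k` (= 1 + #regimes), `n`,
#'   `aicc`, `convergence`.
#' @export
fit_bms <- function(tree, painting, x) {
  durmat <- painting_durations(tree, painting)
  tot <- colSums(durmat)
  if (any(tot <= 0))
    stop("regime(s) absent from the painting: ",
         paste(names(tot)[tot <= 0], collapse = ", "))
  n <- ape::Ntip(tree)
  R <- ncol(durmat)
  X <- align_traits(tree, x)
  post <- reorder(tree, "postorder")
  perm <- match(paste(post$edge[, 1], post$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  dpost <- durmat[perm, , drop = FALSE]

  # profiled log-likelihood at relative rates w (w[1] fixed at 1):
  # lengths = dpost %*% w, then the scale s-hat = (sum c^2/V)/n and the
  # root are closed-form.
  profile <- function(logw) {
    lens <- as.numeric(dpost %*% c(1, exp(logw)))
    pr <- bm_pruning_cpp(post$edge, lens, n, X)
    css <- sum(pr$contrasts[, 1]^2 / pr$contrast_var)
    s <- css / n
    if (!is.finite(s) || s <= 0) return(list(logL = -Inf))
    logL <- -0.5 * (n * log(2 * pi * s) + sum(log(pr$contrast_var)) +
                      log(pr$root_var) + n)
    list(logL = logL, s = s, root = pr$root_value[1])
  }

  if (R == 1) {
    best_par <- numeric(0)
    best <- profile(best_par)
    conv <- 0L
  } else if (R == 2) {
    o <- optimize(function(lw) -profile(lw)$logL, interval = c(-25, 25),
                  tol = 1e-10)
    best_par <- o$minimum
    best <- profile(best_par)
    # keep the equal-rates point if the line search did not beat it, so
    # the BM1 nesting inequality can never be violated
    if (profile(0)$logL > best$logL) {
      best_par <- 0
      best <- profile(0)
    }
    conv <- 0L
  } else {
    obj <- function(logw) -profile(logw)$logL
    starts <- list(rep(0, R - 1), rep(log(0.1), R - 1), rep(log(10), R - 1))
    best_opt <- NULL
    for (st in starts) {
      o <- optim(st, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-10))
      if (is.null(best_opt) || o$value < best_opt$value) best_opt <- o
    }
    best_par <- best_opt$par
    best <- profile(best_par)
    conv <- best_opt$convergence
  }
  rates <- best$s * c(1, exp(best_par))
  names(rates) <- colnames(durmat)
  k <- 1L + R
  logL <- best$logL
  structure(list(model = "BMS", sigma2_by_regime = rates,
                 root_state = best$root, logL = logL, k = k, n = n,
                 aicc = aicc_or_na(logL, k, n), convergence = conv),
            class = c("bms_fit", "model_fit"))
}
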