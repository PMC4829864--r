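# Mk (continuous-time Markov) machinery for discrete regimes -----------

# Validate a rate matrix: square, named, non-negative off-diagonals,
# rows summing to zero.
validate_q <- function(Q) {
  Q <- as.matrix(Q)
  if (nrow(Q) != ncol(Q) || is.null(rownames(Q)))
    stop("Q must be a square matrix with state names as dimnames")
  off <- Q; diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be >= 0")
  if (any(abs(rowSums(Q)) > 1e-12 * max(1, max(abs(Q)))))
    stop("rows of Q must sum to zero")
  Q
}

# Stationary distribution of Q (left null vector, normalised).
stationary_distribution <- function(Q) {
  Q <- validate_q(Q)
  s <- svd(t(Q))
  pi <- abs(s$u[, ncol(Q)])
  pi <- pi / sum(pi)
  setNames(pi, rownames(Q))
}

# Tip likelihood matrix: one row per tip (in tip-id order), one column
# per state; "?" gives a row of ones.
tip_likelihoods <- function(tree, tip_states, states) {
  ts <- tip_states[tree$tip.label]
  if (anyNA(ts)) stop("missing tip state for: ",
                      paste(tree$tip.label[is.na(ts)], collapse = ", "))
  L <- matrix(0, length(ts), length(states),
              dimnames = list(tree$tip.label, states))
  for (i in seq_along(ts)) {
    if (ts[i] == "?") L[i, ] <- 1
    else if (ts[i] %in% states) L[i, ts[i]] <- 1
    else stop("unknown state label '", ts[i], "' at tip ", tree$tip.label[i])
  }
  L
}

# Postorder pruning pass. Returns per-node partial likelihoods (rows =
# ape node ids), per-node log scaling factors, and the postorder tree.
mk_prune <- function(tree, tip_states, Q) {
  states <- rownames(Q)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  L <- matrix(1, n_node, length(states))
  L[seq_len(n_tip), ] <- tip_likelihoods(tree, tip_states, states)
  logscale <- numeric(n_node)
  post <- reorder(tree, "postorder")
  P <- lapply(seq_len(nrow(post$edge)), function(e)
    ape::matexpo(Q * post$edge.length[e]))
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    # rescale the (complete) child row before it is consumed, so partial
    # likelihoods cannot underflow on large trees
    mx <- max(L[ch, ])
    if (mx > 0 && mx < 1e-100) {
      L[ch, ] <- L[ch, ] / mx
      logscale[ch] <- logscale[ch] + log(mx)
    }
    msg <- as.numeric(P[[e]] %*% L[ch, ])
    L[p, ] <- L[p, ] * msg
    logscale[p] <- logscale[p] + logscale[ch]
  }
  list(L = L, logscale = logscale, post = post, P = P, states = states)
}

#' Mk model log-likelihood
#'
#' Felsenstein pruning likelihood of discrete tip states under a
#' continuous-time Markov model with rate matrix `Q`, using
#' \eqn{P(t) = e^{Qt}} per branch.
#'
#' @param tree a \code{phylo} object.
#' @param tip_states named character vector of tip states (`"?"` =
#'   missing, treated as a uniform likelihood vector).
#' @param Q rate matrix with state names as dimnames; rows sum to zero.
#' @param root_prior `"stationary"` (default), `"uniform"`, or a
#'   probability vector over states.
#' @return the log-likelihood.
#' @export
mk_loglik <- function(tree, tip_states, Q, root_prior = "stationary") {
  Q <- validate_q(Q)
  pr <- mk_prune(tree, tip_states, Q)
  pi <- resolve_root_prior(root_prior, Q)
  root <- ape::Ntip(tree) + 1L
  lik <- sum(pi * pr$L[root, ])
  if (lik <= 0) return(-Inf)
  log(lik) + pr$logscale[root]
}

resolve_root_prior <- function(root_prior, Q) {
  S <- nrow(Q)
  if (is.numeric(root_prior)) {
    stopifnot(length(root_prior) == S, abs(sum(root_prior) - 1) < 1e-8)
    pi <- root_prior
  } else if (identical(root_prior, "uniform")) {
    pi <- rep(1 / S, S)
  } else if (identical(root_prior, "stationary")) {
    pi <- stationary_distribution(Q)
  } else stop("unknown root prior")
  setNames(as.numeric(pi), rownames(Q))
}

# Build a Q matrix from free parameters under a given model structure.
build_q <- function(rates, states, model) {
  S <- length(states)
  Q <- matrix(0, S, S, dimnames = list(states, states))
  idx <- which(row(Q) != col(Q))
  if (model == "ARD") {
    Q[idx] <- rates
  } else if (model == "SYM") {
    k <- 0
    for (i in seq_len(S - 1)) for (j in (i + 1):S) {
      k <- k + 1
      Q[i, j] <- Q[j, i] <- rates[k]
    }
  } else if (model == "ER") {
    Q[idx] <- rates[1]
  } else stop("unknown model")
  diag(Q) <- -rowSums(Q)
  Q
}

n_rates <- function(S, model)
  switch(model, ARD = S * (S - 1), SYM = S * (S - 1) / 2, ER = 1L)

#' Fit an Mk model of discrete character evolution
#'
#' Maximum-likelihood transition rates under the all-rates-different
#' (`"ARD"`, default), symmetric (`"SYM"`) or equal-rates (`"ER"`)
#' model, by bounded optimisation on the log-rate scale with
#' deterministic multi-start. Rates that end up at the search bounds are
#' flagged.
#'
#' @param tree a \code{phylo} object.
#' @param tip_states named character vector of tip states; at least two
#'   distinct observed states are required.
#' @param model `"ARD"`, `"SYM"` or `"ER"`.
#' @param root_prior as in [mk_loglik()].
#' @return an object of class `mk_fit`: `Q`, `states`, `logL`, `k`,
#'   `aicc`, `root_prior`, `at_bound`.
#' @export
fit_mk <- function(tree, tip_states, model = c("ARD", "SYM", "ER"),
                   root_prior = "stationary") {
  model <- match.arg(model)
  obs <- setdiff(unique(tip_states[tree$tip.label]), "?")
  if (length(obs) < 2)
    stop("all tips share one state: transition rates are unidentifiable")
  states <- sort(obs)
  S <- length(states)
  np <- n_rates(S, model)
  TL <- sum(tree$edge.length)
  r0 <- max(S / TL, 1e-6)
  lb <- log(1e-9); ub <- log(1e4 / max(node_heights(tree)))

  negll <- function(logr) {
    Q <- build_q(exp(pmin(pmax(logr, lb), ub)), states, model)
    ll <- mk_loglik(tree, tip_states, Q, root_prior)
    if (!is.finite(ll)) 1e10 else -ll
  }
  best <- NULL
  for (mult in c(1, 0.1, 10)) {
    st <- rep(log(r0 * mult), np)
    o <- if (np == 1)
      stats::optim(st, negll, method = "Brent", lower = lb, upper = ub)
    else
      stats::optim(st, negll, method = "L-BFGS-B", lower = lb, upper = ub,
                   control = list(maxit = 500))
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (!is.finite(best$value) || best$value >= 1e10)
    stop("Mk likelihood is not finite at the optimum")
  logr <- pmin(pmax(best$par, lb), ub)
  at_bound <- any(abs(logr - lb) < 1e-6) || any(abs(logr - ub) < 1e-6)
  Q <- build_q(exp(logr), states, model)
  ll <- -best$value
  n <- ape::Ntip(tree)
  structure(list(Q = Q, states = states, logL = ll, k = np,
                 aicc = if (n - np - 1 > 0) aicc(ll, np, n) else NA_real_,
                 root_prior = root_prior, model = model,
                 at_bound = at_bound),
            class = "mk_fit")
}

#' @export
print.mk_fit <- function(x, ...) {
  cat("Mk", x$model, "fit: logL =", format(x$logL, digits = 6), "\n")
  print(round(x$Q, 6))
  if (x$at_bound) cat("  (one or more rates at the search bounds)\n")
  invisible(x)
}

#' Marginal ancestral state posteriors under an Mk model
#'
#' Per-node marginal posterior probabilities of each state, by the
#' standard up-down (inside-outside) pruning algorithm.
#'
#' @inheritParams mk_loglik
#' @return a matrix, nodes x states, rows indexed by ape node id
#'   (tips included).
#' @export
mk_marginals <- function(tree, tip_states, Q, root_prior = "stationary") {
  Q <- validate_q(Q)
  prn <- mk_prune(tree, tip_states, Q)
  pi <- resolve_root_prior(root_prior, Q)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  S <- nrow(Q)
  # down[u, ] = likelihood of everything outside u's subtree, given the
  # state at u (includes the root prior)
  down <- matrix(0, n_node, S)
  down[n_tip + 1L, ] <- pi
  post <- prn$post
  for (e in rev(seq_len(nrow(post$edge)))) {  # preorder
    p <- post$edge[e, 1]; ch <- post$edge[e, 2]
    # sibling contributions at p: partials of p divided by this child's
    # upward message
    msg <- as.numeric(prn$P[[e]] %*% prn$L[ch, ])
    sib <- prn$L[p, ] / ifelse(msg > 0, msg, 1)
    down[ch, ] <- as.numeric((down[p, ] * sib) %*% prn$P[[e]])
  }
  m <- prn$L * down
  sw <- rowSums(m)
  m <- m / ifelse(sw > 0, sw, 1)
  dimnames(m) <- list(seq_len(n_node), rownames(Q))
  m
}
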