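# Stochastic character mapping ----------------------------------------

# Endpoint-conditioned CTMC path sampling by uniformization: dominating
# rate Omega = max |diag(Q)|, jump chain R = I + Q/Omega. The number of
# (possibly virtual) jumps is drawn from its exact conditional
# distribution, intermediate states by a forward-backward bridge, and
# virtual self-jumps are merged away.
make_unif_cache <- function(Q) {
  Omega <- max(-diag(Q))
  S <- nrow(Q)
  env <- new.env(parent = emptyenv())
  env$Omega <- Omega
  env$R <- if (Omega > 0) diag(S) + Q / Omega else diag(S)
  dimnames(env$R) <- dimnames(Q)
  env$pows <- list(diag(S))  # pows[[k]] = R^(k-1)
  env$power <- function(k) {   # R^k
    while (length(env$pows) < k + 1)
      env$pows[[length(env$pows) + 1]] <-
        env$pows[[length(env$pows)]] %*% env$R
    env$pows[[k + 1]]
  }
  env
}

sample_path <- function(a, b, t, P_ab, cache, max_jumps = 10000L) {
  states <- rownames(cache$R)
  if (t <= 0 || cache$Omega == 0) {
    if (a != b) stop("impossible endpoint combination on a zero-rate branch")
    return(setNames(t, states[a]))
  }
  # number of jumps N: P(N = n | a,b) = dpois(n, Omega t) [R^n]_ab / P_ab(t)
  u <- runif(1) * P_ab
  n <- -1L
  acc <- 0
  repeat {
    n <- n + 1L
    if (n > max_jumps)
      stop("endpoint-conditioned path sampling exceeded ", max_jumps,
           " jumps")
    acc <- acc + stats::dpois(n, cache$Omega * t) * cache$power(n)[a, b]
    if (acc >= u) break
  }
  if (n == 0L) return(setNames(t, states[a]))
  seq_states <- integer(n + 1)
  seq_states[1] <- a
  seq_states[n + 1] <- b
  if (n > 1) for (k in 2:n) {
    back <- cache$power(n + 1 - k)[, b]
    p <- cache$R[seq_states[k - 1], ] * back
    seq_states[k] <- sample.int(length(p), 1, prob = p)
  }
  times <- c(0, sort(runif(n)) * t, t)
  durs <- diff(times)
  merge_segments(setNames(durs, states[seq_states]))
}

#' Stochastic character mapping
#'
#' Samples complete discrete-character histories (regime paintings) on
#' the tree, conditional on the observed tip states, under the Mk model
#' `Q`. Node states are drawn from their joint conditional distribution
#' (backward pruning, forward sampling); within-branch histories are
#' drawn exactly, conditional on the branch endpoints, by
#' uniformization. Every sampled painting agrees with the observed tip
#' states at the tips.
#'
#' @param tree a \code{phylo} object.
#' @param tip_states named character vector of tip states.
#' @param Q rate matrix (e.g. from [fit_mk()]).
#' @param n_maps number of sampled histories.
#' @param seed integer seed (mandatory).
#' @param root_prior as in [mk_loglik()].
#' @return a list of `n_maps` \code{regime_painting} objects (edge order
#'   = `tree$edge`), each with a `node_states` attribute (sampled state
#'   per ape node id).
#' @export
stochastic_map <- function(tree, tip_states, Q, n_maps, seed,
                           root_prior = "stationary") {
  if (missing(seed)) stop("a seed is required")
  Q <- validate_q(Q)
  set.seed(seed)
  prn <- mk_prune(tree, tip_states, Q)
  pi <- resolve_root_prior(root_prior, Q)
  states <- rownames(Q)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  post <- prn$post
  cache <- make_unif_cache(Q)
  perm <- match(paste(tree$edge[, 1], tree$edge[, 2]),
                paste(post$edge[, 1], post$edge[, 2]))
  pre_seq <- rev(seq_len(nrow(post$edge)))  # parent edges first

  root_w <- pi * prn$L[root, ]
  if (sum(root_w) <= 0) stop("data have zero likelihood under Q")

  lapply(seq_len(n_maps), function(m) {
    node_state <- integer(n_tip + tree$Nnode)
    node_state[root] <- sample.int(length(states), 1, prob = root_w)
    maps_post <- vector("list", nrow(post$edge))
    for (e in pre_seq) {
      p <- post$edge[e, 1]; ch <- post$edge[e, 2]
      w <- prn$P[[e]][node_state[p], ] * prn$L[ch, ]
      node_state[ch] <- sample.int(length(states), 1, prob = w)
      maps_post[[e]] <- sample_path(node_state[p], node_state[ch],
                                    post$edge.length[e],
                                    prn$P[[e]][node_state[p], node_state[ch]],
                                    cache)
    }
    painting <- regime_painting(maps_post[perm], states)
    attr(painting, "node_states") <- setNames(states[node_state],
                                              seq_along(node_state))
    painting
  })
}

#' Summarise sampled character histories
#'
#' @param paintings a list of \code{regime_painting} objects over the
#'   same tree (e.g. from [stochastic_map()]).
#' @return a list with `transitions` (states x states matrix of mean
#'   within-branch transition counts per map) and `dwell` (named vector
#'   of mean total dwell time per state).
#' @export
transition_summary <- function(paintings) {
  stopifnot(length(paintings) >= 1)
  states <- paintings[[1]]$alphabet
  S <- length(states)
  counts <- matrix(0, S, S, dimnames = list(states, states))
  dwell <- setNames(numeric(S), states)
  for (pt in paintings) {
    for (m in pt$maps) {
      for (s in unique(names(m))) dwell[s] <- dwell[s] + sum(m[names(m) == s])
      if (length(m) > 1) {
        from <- names(m)[-length(m)]
        to <- names(m)[-1]
        for (k in seq_along(from))
          counts[from[k], to[k]] <- counts[from[k], to[k]] + 1
      }
    }
  }
  list(transitions = counts / length(paintings),
       dwell = dwell / length(paintings))
}
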