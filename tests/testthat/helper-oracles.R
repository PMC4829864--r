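# Independent oracles used across the suite. These deliberately avoid
# the package's own pruning/GLS code paths: dense matrix algebra and
# explicit enumeration only.

# Dense multivariate-normal BM log-likelihood (O(n^3)).
dense_bm_loglik <- function(tree, x, sigma2, root_state) {
  C <- sigma2 * ape::vcv.phylo(tree)
  x <- x[rownames(C)]
  r <- x - root_state
  n <- length(x)
  -0.5 * (n * log(2 * pi) + determinant(C)$modulus[1] +
            sum(r * solve(C, r)))
}

# Brute-force shared-time matrix: enumerate root-to-node paths and take
# the height of the deepest common node of each tip pair.
brute_vcv <- function(tree) {
  n <- ape::Ntip(tree)
  root <- n + 1L
  parent <- integer(n + tree$Nnode)
  elen <- numeric(n + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    parent[tree$edge[e, 2]] <- tree$edge[e, 1]
    elen[tree$edge[e, 2]] <- tree$edge.length[e]
  }
  height <- function(nd) {
    h <- 0
    while (nd != root) { h <- h + elen[nd]; nd <- parent[nd] }
    h
  }
  path_to_root <- function(nd) {
    p <- nd
    while (nd != root) { nd <- parent[nd]; p <- c(p, nd) }
    p
  }
  V <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(n)) for (j in i:n) {
    common <- intersect(path_to_root(i), path_to_root(j))
    V[i, j] <- V[j, i] <- max(vapply(common, height, numeric(1)))
  }
  V
}

# Exhaustive Mk likelihood: sum over every assignment of states to
# internal nodes.
enum_mk_loglik <- function(tree, tip_states, Q, prior) {
  states <- rownames(Q)
  S <- length(states)
  n <- ape::Ntip(tree)
  internals <- n + seq_len(tree$Nnode)
  P <- lapply(seq_len(nrow(tree$edge)),
              function(e) ape::matexpo(Q * tree$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(seq_len(S)), length(internals))))
  tip_idx <- match(tip_states[tree$tip.label], states)
  total <- 0
  for (g in seq_len(nrow(grid))) {
    st <- integer(n + tree$Nnode)
    st[seq_len(n)] <- tip_idx
    st[internals] <- grid[g, ]
    lik <- as.numeric(prior[st[n + 1L]])
    for (e in seq_len(nrow(tree$edge)))
      lik <- lik * P[[e]][st[tree$edge[e, 1]], st[tree$edge[e, 2]]]
    total <- total + lik
  }
  log(total)
}

# A reproducible unit-depth Yule tree for ad-hoc cases.
rand_tree <- function(n, seed) yule_tree(n, seed = seed)

# Named trait vector simulated under BM1, for quick datasets.
rand_traits <- function(tree, seed, sigma2 = 1, root = 0) {
  sim_bm(tree, sigma2, root, 1, seed = seed)[, 1]
}

fixture_svl <- function(fx) setNames(fx$traits$svl, fx$traits$species)

fixture_heads <- function(fx) {
  m <- as.matrix(fx$traits[, c("hl", "hw", "hd")])
  rownames(m) <- fx$traits$species
  m
}

fixture_groups <- function(fx) setNames(fx$groups$group, fx$groups$species)
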