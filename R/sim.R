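# Edges in root-down order plus the permutation back to tree$edge rows.
preorder_edges <- function(tree) {
  pre <- reorder(tree, "cladewise")
  perm <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  list(edge = pre$edge, perm = perm)
}

#' Simulate Brownian motion on a tree
#'
#' Recursive edge-wise Gaussian increments with variance = rate x
#' duration. With a `painting` and per-regime `rates`, each branch
#' segment contributes its own regime's rate, which simulates the
#' multi-rate (BMS) process.
#'
#' @param tree a \code{phylo} object.
#' @param sigma2 single Brownian rate (ignored when `painting` given);
#'   may be 0, in which case all tips equal the root state.
#' @param root_state trait value at the root.
#' @param n_reps number of replicate datasets.
#' @param seed integer seed (mandatory, for reproducibility).
#' @param painting optional \code{regime_painting}.
#' @param rates named per-regime rates (required with `painting`);
#'   non-negative, named by the painting alphabet.
#' @return a numeric matrix, tips x replicates, rownames = tip labels.
#' @export
sim_bm <- function(tree, sigma2 = 1, root_state = 0, n_reps = 1, seed,
                   painting = NULL, rates = NULL) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  sim_bm_(tree, sigma2, root_state, n_reps, painting, rates)
}

# Internal: same as sim_bm but draws from the current RNG stream, so
# callers that manage their own seed can chain simulations.
sim_bm_ <- function(tree, sigma2 = 1, root_state = 0, n_reps = 1,
                    painting = NULL, rates = NULL) {
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  if (!is.null(painting)) {
    durmat <- painting_durations(tree, painting)
    if (is.null(rates) || !all(colnames(durmat) %in% names(rates)))
      stop("per-regime `rates` (named by the painting alphabet) are required")
    if (any(rates < 0)) stop("rates must be non-negative")
    edge_var <- as.numeric(durmat %*% rates[colnames(durmat)])
  } else {
    if (sigma2 < 0) stop("sigma2 must be non-negative")
    edge_var <- sigma2 * tree$edge.length
  }
  pe <- preorder_edges(tree)
  inc <- matrix(rnorm(nrow(tree$edge) * n_reps), nrow(tree$edge), n_reps) *
    sqrt(edge_var)
  val <- matrix(0, n_node, n_reps)
  val[n_tip + 1L, ] <- root_state
  for (k in seq_len(nrow(pe$edge))) {
    e <- pe$perm[k]
    val[tree$edge[e, 2], ] <- val[tree$edge[e, 1], ] + inc[e, ]
  }
  out <- val[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}

#' Simulate correlated multivariate Brownian motion
#'
#' @param tree a \code{phylo} object.
#' @param R trait rate (evolutionary variance-covariance) matrix;
#'   must be positive definite.
#' @param roots root state per trait (recycled).
#' @param n_reps number of replicate datasets.
#' @param seed integer seed (mandatory).
#' @return a list of `n_reps` matrices, each tips x traits.
#' @export
sim_mvbm <- function(tree, R, roots = 0, n_reps = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  set.seed(seed)
  sim_mvbm_(tree, R, roots, n_reps)
}

sim_mvbm_ <- function(tree, R, roots = 0, n_reps = 1) {
  R <- as.matrix(R)
  p <- ncol(R)
  U <- tryCatch(chol(R), error = function(e)
    stop("trait rate matrix R is not positive definite"))
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  roots <- rep_len(roots, p)
  pe <- preorder_edges(tree)
  sdlen <- sqrt(tree$edge.length)
  lapply(seq_len(n_reps), function(rep) {
    inc <- (matrix(rnorm(nrow(tree$edge) * p), ncol = p) %*% U) * sdlen
    val <- matrix(0, n_node, p)
    val[n_tip + 1L, ] <- roots
    for (k in seq_len(nrow(pe$edge))) {
      e <- pe$perm[k]
      val[tree$edge[e, 2], ] <- val[tree$edge[e, 1], ] + inc[e, ]
    }
    out <- val[seq_len(n_tip), , drop = FALSE]
    dimnames(out) <- list(tree$tip.label, colnames(R))
    out
  })
}

#' Simulate a single-optimum Ornstein-Uhlenbeck process
#'
#' Exact edge-wise transition sampling with the root at the optimum:
#' along a branch of length t, the child is normal with mean
#' \eqn{\theta + (x_{parent}-\theta)e^{-\alpha t}} and variance
#' \eqn{\sigma^2 (1 - e^{-2\alpha t}) / (2\alpha)}.
#'
#' @param tree a \code{phylo} object.
#' @param alpha adaptation rate, > 0.
#' @param sigma2 Brownian intensity, >= 0.
#' @param theta optimum (and root state).
#' @param n_reps number of replicate datasets.
#' @param seed integer seed (mandatory).
#' @return a numeric matrix, tips x replicates.
#' @export
sim_ou <- function(tree, alpha, sigma2, theta = 0, n_reps = 1, seed) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(alpha > 0, sigma2 >= 0)
  set.seed(seed)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  pe <- preorder_edges(tree)
  shrink <- exp(-alpha * tree$edge.length)
  evar <- sigma2 * (1 - shrink^2) / (2 * alpha)
  inc <- matrix(rnorm(nrow(tree$edge) * n_reps), nrow(tree$edge), n_reps) *
    sqrt(evar)
  val <- matrix(0, n_node, n_reps)
  val[n_tip + 1L, ] <- theta
  for (k in seq_len(nrow(pe$edge))) {
    e <- pe$perm[k]
    val[tree$edge[e, 2], ] <- theta + (val[tree$edge[e, 1], ] - theta) *
      shrink[e] + inc[e, ]
  }
  out <- val[seq_len(n_tip), , drop = FALSE]
  rownames(out) <- tree$tip.label
  out
}
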