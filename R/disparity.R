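#' Group disparity
#'
#' Average squared Euclidean distance between the trait values of all
#' unordered pairs of species in a group -- the disparity of a species
#' assemblage.
#'
#' @param X trait values: a numeric vector, or a species x traits matrix.
#' @param members optional species names (or indices) selecting the
#'   group; default uses all rows of `X`.
#' @return the mean pairwise squared distance (scalar).
#' @examples
#' group_disparity(c(a = 0, b = 1, c = 2))  # 2
#' @export
group_disparity <- function(X, members = NULL) {
  M <- if (is.null(dim(X))) matrix(X, ncol = 1, dimnames = list(names(X)))
       else as.matrix(X)
  if (!is.null(members)) M <- M[members, , drop = FALSE]
  n <- nrow(M)
  if (n < 2) stop("disparity needs at least two group members")
  d2 <- as.numeric(stats::dist(M))^2
  mean(d2)
}

#' Disparity-ratio test against a Brownian null
#'
#' Compares the island/continent disparity ratio
#' \eqn{r = D_{island}/D_{continent}} with a null distribution of ratios
#' from trait datasets simulated under Brownian motion on the same tree
#' with the same group memberships: univariate simulations use the ML
#' BM1 rate, multivariate ones the ML evolutionary rate matrix. Large
#' ratios are extreme (upper tail, add-one correction).
#'
#' @param tree a \code{phylo} object.
#' @param X named trait vector (univariate) or species x traits matrix
#'   (multivariate mode).
#' @param island_members,continent_members disjoint tip-label sets, each
#'   with >= 2 species.
#' @param n_sims number of null simulations (>= 99).
#' @param seed integer seed (mandatory).
#' @param mode `"univariate"` or `"multivariate"`; defaults to whatever
#'   matches the shape of `X`.
#' @return an object of class `disparity_test` (an `mc_test` with the
#'   per-group disparities attached).
#' @export
disparity_ratio_test <- function(tree, X, island_members, continent_members,
                                 n_sims, seed,
                                 mode = c("auto", "univariate",
                                          "multivariate")) {
  if (missing(seed)) stop("a seed is required")
  if (n_sims < 99) stop("use at least 99 simulations")
  mode <- match.arg(mode)
  if (mode == "auto")
    mode <- if (is.null(dim(X)) || ncol(as.matrix(X)) == 1)
      "univariate" else "multivariate"
  if (length(intersect(island_members, continent_members)))
    stop("island and continent groups must be disjoint")
  if (length(island_members) < 2 || length(continent_members) < 2)
    stop("each group needs at least two species")
  M <- align_traits(tree, X)
  ratio <- function(mat) {
    dc <- group_disparity(mat, continent_members)
    if (dc == 0) stop("continental disparity is zero: ratio undefined")
    group_disparity(mat, island_members) / dc
  }
  obs <- ratio(M)
  if (mode == "univariate") {
    fit <- fit_bm1(tree, M[, 1])
    sims <- sim_bm(tree, fit$sigma2, fit$root_state, n_sims, seed = seed)
    null <- vapply(seq_len(n_sims),
                   function(b) ratio(sims[, b, drop = FALSE]), numeric(1))
  } else {
    R <- evol_vcv(tree, M)
    mu <- gls_means(tree, M)
    sims <- sim_mvbm(tree, R, mu, n_sims, seed = seed)
    null <- vapply(sims, ratio, numeric(1))
  }
  out <- new_mc_test("disparity_ratio", obs, null, "upper", n_sims, seed)
  out$disparity_island <- group_disparity(M, island_members)
  out$disparity_continent <- group_disparity(M, continent_members)
  class(out) <- c("disparity_test", class(out))
  out
}

#' Pseudo-community range test
#'
#' Asks whether any assemblage of `k` continental species reproduces the
#' trait range (max - min) observed in an island assemblage of the same
#' size. Pseudo-communities are drawn from the continental pool without
#' replacement; when the number of possible communities does not exceed
#' `n_resamples` they are enumerated exhaustively and the p-value is the
#' exact proportion of communities whose range reaches the island range
#' (ties count as reached). In Monte-Carlo mode the add-one correction
#' is applied.
#'
#' @param continental_values numeric vector (one trait) or matrix
#'   (traits in columns) of continental species values.
#' @param island_values values of the island species; one row/entry per
#'   island species, `k` in total.
#' @param k pseudo-community size (= island community size).
#' @param n_resamples Monte-Carlo sample size (also the exhaustive
#'   threshold).
#' @param seed integer seed (mandatory; unused in exhaustive mode).
#' @return an object of class `range_test`: per-trait observed ranges,
#'   p-values, mode, `k`, `n_resamples`, seed.
#' @examples
#' pseudo_community_test(c(1, 2, 3), c(0, 2), k = 2, n_resamples = 100,
#'                       seed = 1)
#' @export
pseudo_community_test <- function(continental_values, island_values, k,
                                  n_resamples, seed) {
  if (missing(seed)) stop("a seed is required")
  Mc <- if (is.null(dim(continental_values)))
    matrix(continental_values, ncol = 1) else as.matrix(continental_values)
  Mi <- if (is.null(dim(island_values)))
    matrix(island_values, ncol = 1) else as.matrix(island_values)
  if (ncol(Mc) != ncol(Mi)) stop("trait columns do not match")
  if (nrow(Mi) != k)
    stop("island community size (", nrow(Mi), ") must equal k (", k, ")")
  n_cont <- nrow(Mc)
  if (k > n_cont) stop("k exceeds the continental species pool")
  rng <- function(M) apply(M, 2, function(v) max(v) - min(v))
  obs <- rng(Mi)
  exhaustive <- choose(n_cont, k) <= n_resamples
  if (exhaustive) {
    combos <- combn(n_cont, k)
    ranges <- apply(combos, 2, function(idx) rng(Mc[idx, , drop = FALSE]))
    ranges <- matrix(ranges, nrow = ncol(Mc))
    p <- rowMeans(ranges >= obs)
    n_used <- ncol(combos)
  } else {
    set.seed(seed)
    ranges <- vapply(seq_len(n_resamples), function(b)
      rng(Mc[sample.int(n_cont, k), , drop = FALSE]), numeric(ncol(Mc)))
    ranges <- matrix(ranges, nrow = ncol(Mc))
    p <- (1 + rowSums(ranges >= obs)) / (1 + n_resamples)
    n_used <- n_resamples
  }
  traits <- colnames(Mc)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(Mc)))
  structure(list(observed_range = setNames(obs, traits),
                 p_value = setNames(p, traits),
                 null_ranges = ranges,
                 mode = if (exhaustive) "exhaustive" else "monte-carlo",
                 k = k, n_resamples = n_used, seed = seed),
            class = "range_test")
}

#' @export
print.range_test <- function(x, ...) {
  cat("Pseudo-community range test (k =", x$k, ",", x$mode, ",",
      x$n_resamples, "communities)\n")
  print(data.frame(range = x$observed_range, p = x$p_value))
  invisible(x)
}

#' Independent contrasts through time with a simulation envelope
#'
#' Computes the absolute standardized contrasts of a trait at every
#' internal node, together with a per-node null envelope from Brownian
#' simulations at the empirically estimated rate. A node is flagged when
#' its observed |contrast| exceeds the per-node `level` quantile of the
#' simulated |contrasts|, so under single-rate Brownian evolution about
#' `1 - level` of nodes are flagged.
#'
#' @param tree a \code{phylo} object (>= 3 tips).
#' @param x named trait vector.
#' @param n_sims number of Brownian simulations.
#' @param level envelope level (default 0.95).
#' @param seed integer seed (mandatory).
#' @param envelope `"pointwise"` (per node, default) or `"pooled"`
#'   (one bound shared across nodes).
#' @return a data.frame of class `ctt` with one row per internal node:
#'   `node`, `height`, `contrast_abs`, `bound`, `flagged`; attributes
#'   `level`, `n_sims`, `seed`, `sigma2`.
#' @export
contrasts_through_time <- function(tree, x, n_sims, level = 0.95, seed,
                                   envelope = c("pointwise", "pooled")) {
  if (missing(seed)) stop("a seed is required")
  envelope <- match.arg(envelope)
  if (ape::Ntip(tree) < 3) stop("need at least 3 tips")
  X <- align_traits(tree, x)[, 1]
  fit <- fit_bm1(tree, X)
  obs <- pic_contrasts(tree, X)
  sims <- sim_bm(tree, fit$sigma2, fit$root_state, n_sims, seed = seed)
  pr <- bm_prune(tree, sims)
  simc <- abs(pr$contrasts / sqrt(pr$contrast_var))
  # rows of simc follow pr$contrast_node; align to obs$node
  simc <- simc[match(obs$node, pr$contrast_node), , drop = FALSE]
  bound <- if (envelope == "pointwise")
    apply(simc, 1, quantile, probs = level, names = FALSE)
  else rep(quantile(simc, probs = level, names = FALSE), nrow(obs))
  out <- data.frame(node = obs$node, height = obs$height,
                    contrast_abs = abs(obs$contrast), bound = bound,
                    flagged = abs(obs$contrast) > bound)
  attr(out, "level") <- level
  attr(out, "n_sims") <- n_sims
  attr(out, "seed") <- seed
  attr(out, "sigma2") <- fit$sigma2
  class(out) <- c("ctt", class(out))
  out
}
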