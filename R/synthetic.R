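# Synthetic data generator --------------------------------------------

#' Simulate a pure-birth (Yule) tree scaled to unit depth
#'
#' @param n_tips number of tips (>= 2).
#' @param seed integer seed (mandatory).
#' @param birth speciation rate of the pure-birth process.
#' @return an ultrametric binary \code{phylo} with all tip heights 1.
#' @export
yule_tree <- function(n_tips, seed, birth = 1) {
  if (missing(seed)) stop("a seed is required")
  stopifnot(n_tips >= 2)
  set.seed(seed)
  tr <- ape::rphylo(n_tips, birth = birth, death = 0)
  depth <- max(node_heights(tr))
  tr$edge.length <- tr$edge.length / depth
  tr
}

#' Paint island clades onto a tree
#'
#' Builds a regime painting in which each clade spec's crown branches
#' are painted with its island regime; the stem branch switches from the
#' background regime to the island regime at a fixed fraction of its
#' length (mid-stem by default); everything else is background.
#'
#' @param tree a \code{phylo} object.
#' @param clade_specs list of specs, each `list(tips = <tip labels>,
#'   regime = <label>)`; every tip set must be monophyletic.
#' @param background background regime label.
#' @param stem_fraction position of the switch along the stem branch,
#'   from the parent end (0.5 = mid-stem).
#' @return a \code{regime_painting} (edge order = `tree$edge`).
#' @export
paint_clades <- function(tree, clade_specs, background = "continent",
                         stem_fraction = 0.5) {
  alphabet <- c(background,
                vapply(clade_specs, function(s) s$regime, character(1)))
  alphabet <- unique(alphabet)
  maps <- lapply(tree$edge.length, function(l) setNames(l, background))
  n_tip <- ape::Ntip(tree)
  for (spec in clade_specs) {
    idx <- match(spec$tips, tree$tip.label)
    if (anyNA(idx)) stop("unknown tip(s): ",
                         paste(spec$tips[is.na(idx)], collapse = ", "))
    mrca <- if (length(idx) == 1) idx else ape::getMRCA(tree, idx)
    desc <- clade_tips(tree, mrca)
    if (!setequal(desc, idx))
      stop("tip set for regime '", spec$regime, "' is not monophyletic")
    crown <- which(tree$edge[, 1] %in% clade_nodes(tree, mrca))
    for (e in crown)
      maps[[e]] <- setNames(tree$edge.length[e], spec$regime)
    stem <- which(tree$edge[, 2] == mrca)
    if (length(stem) == 1) {
      l <- tree$edge.length[stem]
      maps[[stem]] <- if (l > 0)
        setNames(c(l * stem_fraction, l * (1 - stem_fraction)),
                 c(background, spec$regime))
      else setNames(numeric(0), character(0))
    }
  }
  regime_painting(maps, alphabet)
}

# tip ids below node `nd` (inclusive if nd is a tip)
clade_tips <- function(tree, nd) {
  n_tip <- ape::Ntip(tree)
  if (nd <= n_tip) return(nd)
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  unlist(lapply(kids, clade_tips, tree = tree))
}

# all node ids in the clade rooted at `nd` (including nd)
clade_nodes <- function(tree, nd) {
  kids <- tree$edge[tree$edge[, 1] == nd, 2]
  c(nd, unlist(lapply(kids, clade_nodes, tree = tree)))
}

#' The synthetic study fixture: a mainland-island radiation
#'
#' A deterministic stand-in for an empirical mainland-island dataset:
#' a 48-tip unit-depth Yule tree containing a 2-tip island clade
#' ("AbdAlKuri") and a disjoint 5-tip island clade ("Socotra"); log
#' body size (`svl`) evolving under regime-specific Brownian rates
#' (continent 1, Socotra 2, AbdAlKuri 20 by default -- the ~2x and ~20x
#' island accelerations the analyses are designed to detect); and three
#' head dimensions (`hl`, `hw`, `hd`) evolving as single-rate
#' multivariate Brownian motion correlated 0.8 with the neutral
#' component of body size. All traits are generated directly on the
#' log10 scale; the absolute scale is arbitrary.
#'
#' Island clades are the first clades of the required sizes in node-id
#' order; if a drawn tree has no two disjoint clades of sizes 2 and 5,
#' the tree is redrawn from a deterministically derived seed.
#'
#' @param seed integer seed (mandatory).
#' @param n_tips number of tips.
#' @param rates named per-regime rates for body size.
#' @param cor_size_head correlation between size and each head trait.
#' @return a list: `tree`, `painting`, `traits` (data.frame with
#'   `species`, `svl`, `hl`, `hw`, `hd`; attribute `scale = "log10"`),
#'   `groups` (data.frame `species`, `group`), `clades`, `seed`.
#' @export
study_fixture <- function(seed, n_tips = 48,
                          rates = c(continent = 1, Socotra = 2,
                                    AbdAlKuri = 20),
                          cor_size_head = 0.8) {
  if (missing(seed)) stop("a seed is required")
  found <- NULL
  for (attempt in 0:99) {
    tree_seed <- derive_seed(seed, paste0("fixture-tree-", attempt))
    tr <- yule_tree(n_tips, seed = tree_seed)
    cl <- find_island_clades(tr, sizes = c(AbdAlKuri = 2, Socotra = 5))
    if (!is.null(cl)) { found <- list(tree = tr, clades = cl); break }
  }
  if (is.null(found)) stop("no tree with the required clades in 100 draws")
  tree <- found$tree
  specs <- lapply(names(found$clades), function(reg)
    list(tips = tree$tip.label[found$clades[[reg]]], regime = reg))
  painting <- paint_clades(tree, specs, background = "continent")

  # Head traits and the neutral size component share one 4-variate BM;
  # the island rate excess enters size as an independent added BM, so
  # total size rates per regime are exactly `rates` while heads stay
  # single-rate.
  rho <- cor_size_head
  Rbase <- rbind(c(1, rho, rho, rho),
                 c(rho, 1, rho^2, rho^2),
                 c(rho, rho^2, 1, rho^2),
                 c(rho, rho^2, rho^2, 1))
  dimnames(Rbase) <- list(c("svl", "hl", "hw", "hd"),
                          c("svl", "hl", "hw", "hd"))
  roots <- c(svl = 1.8, hl = 1.2, hw = 1.0, hd = 0.85)
  base <- sim_mvbm(tree, Rbase, roots, 1,
                   seed = derive_seed(seed, "fixture-base"))[[1]]
  excess_rates <- rates - rates["continent"]
  excess <- sim_bm(tree, root_state = 0, n_reps = 1,
                   seed = derive_seed(seed, "fixture-excess"),
                   painting = painting, rates = excess_rates)
  X <- base
  X[, "svl"] <- X[, "svl"] * sqrt(rates[["continent"]]) + excess[, 1]

  group <- rep("continent", n_tips)
  for (reg in names(found$clades)) group[found$clades[[reg]]] <- reg
  traits <- data.frame(species = tree$tip.label,
                       svl = X[, "svl"], hl = X[, "hl"],
                       hw = X[, "hw"], hd = X[, "hd"],
                       row.names = NULL)
  attr(traits, "scale") <- "log10"
  list(tree = tree, painting = painting, traits = traits,
       groups = data.frame(species = tree$tip.label, group = group),
       clades = found$clades, seed = seed)
}

# First disjoint clades of the requested sizes, in node-id order;
# NULL when impossible on this tree.
find_island_clades <- function(tree, sizes) {
  counts <- ape::node.depth(tree)  # number of tips below each node
  ord <- names(sort(sizes))        # place the larger clade first
  ord <- names(sizes)[order(-sizes)]
  taken <- integer(0)
  out <- list()
  for (reg in ord) {
    k <- sizes[[reg]]
    cands <- which(counts == k)
    cands <- cands[cands > ape::Ntip(tree)]
    ok <- NA
    for (nd in sort(cands)) {
      tips <- clade_tips(tree, nd)
      if (!length(intersect(tips, taken))) { ok <- nd; break }
    }
    if (is.na(ok)) return(NULL)
    out[[reg]] <- clade_tips(tree, ok)
    taken <- c(taken, out[[reg]])
  }
  out[names(sizes)]
}

#' Simulate replicate datasets from a configuration
#'
#' General-purpose generator for calibration studies: each replicate
#' bundle holds a tree, an optional regime painting, and traits
#' simulated under the configured model.
#'
#' @param config a list with fields: `n_tips` (>= 2), `seed`
#'   (mandatory), `n_reps` (default 1), `model` (`"bm1"`, `"bms"`,
#'   `"ou"` or `"mvbm"`), `new_tree_per_rep` (default FALSE), plus
#'   model parameters: `sigma2`/`root_state` (bm1), `clades` +
#'   `rates` (bms; clades as in [paint_clades()]), `alpha`/`sigma2`/
#'   `theta` (ou), `R`/`roots` (mvbm).
#' @return a list of `n_reps` bundles `list(tree, painting, traits)`.
#' @export
simulate_dataset <- function(config) {
  problems <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  need(is.list(config), "config must be a list")
  need(!is.null(config$n_tips) && config$n_tips >= 2, "n_tips must be >= 2")
  need(!is.null(config$seed), "seed is mandatory")
  model <- if (is.null(config$model)) "bm1" else config$model
  need(model %in% c("bm1", "bms", "ou", "mvbm"),
       "model must be one of bm1, bms, ou, mvbm")
  if (model == "bms") {
    need(!is.null(config$clades), "bms model needs `clades`")
    need(!is.null(config$rates) && all(config$rates >= 0),
         "bms model needs non-negative `rates`")
  }
  if (model == "ou")
    need(!is.null(config$alpha) && config$alpha > 0, "ou needs alpha > 0")
  if (model == "mvbm") need(!is.null(config$R), "mvbm needs rate matrix R")
  if (length(problems))
    stop("invalid config: ", paste(problems, collapse = "; "))

  n_reps <- if (is.null(config$n_reps)) 1L else config$n_reps
  fresh <- isTRUE(config$new_tree_per_rep)
  base_tree <- if (!fresh)
    yule_tree(config$n_tips, seed = derive_seed(config$seed, "tree"))
  lapply(seq_len(n_reps), function(r) {
    tree <- if (fresh)
      yule_tree(config$n_tips, seed = derive_seed(config$seed,
                                                  paste0("tree-", r)))
    else base_tree
    painting <- NULL
    sd_r <- derive_seed(config$seed, paste0("traits-", r))
    traits <- switch(model,
      bm1 = sim_bm(tree, sigma2 = config$sigma2 %||% 1,
                   root_state = config$root_state %||% 0, 1, seed = sd_r),
      bms = {
        painting <- paint_clades(tree, config$clades)
        sim_bm(tree, root_state = config$root_state %||% 0, n_reps = 1,
               seed = sd_r, painting = painting, rates = config$rates)
      },
      ou = sim_ou(tree, alpha = config$alpha,
                  sigma2 = config$sigma2 %||% 1,
                  theta = config$theta %||% 0, 1, seed = sd_r),
      mvbm = sim_mvbm(tree, config$R, config$roots %||% 0, 1,
                      seed = sd_r)[[1]])
    list(tree = tree, painting = painting, traits = traits)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
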