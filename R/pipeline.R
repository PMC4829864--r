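# Pipeline orchestration ------------------------------------------------

#' Derive a stage-specific sub-seed
#'
#' Deterministic splitting of a master seed so that each analysis stage
#' gets an independent, reproducible RNG stream and adding a stage never
#' shifts another stage's stream. The rule is a 31-bit polynomial
#' rolling hash of the stage name folded into the master seed.
#'
#' @param seed master integer seed.
#' @param stage character stage tag.
#' @return an integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  mod <- 2147483647
  h <- as.numeric(seed) %% mod
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 31 + ch) %% mod
  as.integer(max(h, 1))
}

#' Run the island-effect analysis pipeline
#'
#' Orchestrates the full workflow on one tree or on a set of trees:
#' stochastic mapping of regimes (when tip states are supplied instead
#' of a painting), size-correction residuals for head traits,
#' model fitting and AICc comparison for body size, phylogenetic
#' ANOVA/MANOVA, disparity-ratio tests, parametric bootstrap, and the
#' contrasts-through-time envelope. With a tree set, every stage is
#' repeated per tree (residuals included) and scalar results are
#' aggregated as distributions.
#'
#' @param config a list with fields:
#'   \describe{
#'     \item{tree}{a \code{phylo}, a list of them, or a Newick path
#'       (multi-line = tree set).}
#'     \item{traits}{trait data.frame (as [read_trait_table()]) or path;
#'       must contain `species` and the `size_trait` column.}
#'     \item{groups}{named group vector, data.frame, or path; the label
#'       `continent` is the mainland, all others are island regimes.}
#'     \item{painting}{optional \code{regime_painting} (single tree
#'       only); when absent and `analyses` needs one, a stochastic map
#'       is drawn from a fitted Mk model of the group labels.}
#'     \item{analyses}{subset of `c("fit", "anova", "manova",
#'       "disparity", "pseudocom", "bootstrap", "ctt")` (default all).}
#'     \item{n_sims, n_boot, n_maps}{simulation sizes (defaults 999,
#'       199, 100).}
#'     \item{seed}{mandatory master seed.}
#'     \item{size_trait, head_traits}{trait column names (defaults
#'       `"svl"` and `c("hl", "hw", "hd")`).}
#'     \item{out}{optional path for a JSON report.}
#'   }
#' @return an object of class `run_report`: per-tree results, config
#'   echo, package version, and (for tree sets) aggregated summaries.
#'   Re-running with the same config reproduces it bit-for-bit.
#' @export
run_pipeline <- function(config) {
  if (is.null(config$seed)) stop("config$seed is mandatory")
  analyses <- config$analyses %||%
    c("fit", "anova", "manova", "disparity", "pseudocom", "bootstrap",
      "ctt")
  n_sims <- config$n_sims %||% 999L
  n_boot <- config$n_boot %||% 199L
  if (length(analyses) &&
      any(analyses %in% c("anova", "manova", "disparity")) && n_sims < 99)
    stop("n_sims must be >= 99")
  size_trait <- config$size_trait %||% "svl"
  head_traits <- config$head_traits %||% c("hl", "hw", "hd")

  trees <- config$tree
  if (is.character(trees)) trees <- read_tree_set(trees)
  if (inherits(trees, "phylo")) trees <- list(trees)
  if (inherits(trees, "multiPhylo")) trees <- unclass(trees)
  traits <- config$traits
  if (is.character(traits)) traits <- read_trait_table(traits)
  groups <- config$groups
  if (is.character(groups) && length(groups) == 1 && file.exists(groups))
    groups <- read_groups(groups)
  if (is.data.frame(groups))
    groups <- setNames(as.character(groups$group), groups$species)

  per_tree <- lapply(seq_along(trees), function(ti) {
    run_one_tree(trees[[ti]], traits, groups,
                 painting = if (length(trees) == 1) config$painting,
                 analyses = analyses, n_sims = n_sims, n_boot = n_boot,
                 size_trait = size_trait, head_traits = head_traits,
                 seed = derive_seed(config$seed, paste0("tree-", ti)))
  })
  report <- list(
    package = "islandpcm",
    version = as.character(utils::packageVersion("islandpcm")),
    config = list(analyses = analyses, n_sims = n_sims, n_boot = n_boot,
                  seed = config$seed, n_trees = length(trees),
                  size_trait = size_trait, head_traits = head_traits),
    trees = per_tree)
  if (length(trees) > 1) {
    stats <- lapply(per_tree, function(x) x$summary_stats)
    report$aggregate <- aggregate_over_trees(stats)
  }
  class(report) <- "run_report"
  if (!is.null(config$out)) {
    json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE,
                             digits = NA, pretty = TRUE, null = "null")
    writeLines(json, config$out)
  }
  report
}

run_one_tree <- function(tree, traits, groups, painting, analyses,
                         n_sims, n_boot, size_trait, head_traits, seed) {
  res <- list()
  stats <- c()
  failed <- FALSE
  run_stage <- function(name, fun) {
    if (failed || !(name %in% c(analyses, "prepare"))) return(invisible())
    out <- tryCatch(fun(), error = function(e) {
      message("stage ", name, " failed: ", conditionMessage(e))
      failed <<- TRUE
      list(error = conditionMessage(e))
    })
    if (!is.null(out)) res[[name]] <<- out
  }

  g <- align_groups(tree, groups)
  islands <- setdiff(levels(g), "continent")
  sp <- tree$tip.label
  size <- setNames(traits[[size_trait]][match(sp, traits$species)], sp)
  keep <- !is.na(size)
  if (!all(keep)) {
    message(sum(!keep), " species dropped for missing ", size_trait)
    tree <- ape::drop.tip(tree, sp[!keep])
    sp <- tree$tip.label
    size <- size[sp]
    g <- droplevels(g[match(sp, names(g))])
  }
  have_heads <- all(head_traits %in% names(traits))

  # size-corrected head residuals, recomputed on this tree
  heads <- NULL
  if (have_heads && length(head_traits)) {
    hmat <- sapply(head_traits, function(h)
      setNames(traits[[h]][match(sp, traits$species)], sp))
    ok <- complete.cases(hmat)
    if (all(ok)) {
      heads <- sapply(head_traits, function(h)
        pgls_residuals(tree, hmat[, h], size))
      rownames(heads) <- sp
    }
  }
  island_grouping <- setNames(ifelse(as.character(g) == "continent",
                                     "continent", "island"), sp)

  if (is.null(painting) &&
      any(c("fit", "bootstrap") %in% analyses)) {
    tip_states <- setNames(as.character(g), sp)
    mk <- fit_mk(tree, tip_states, model = "ARD")
    painting <- stochastic_map(tree, tip_states, mk$Q, 1,
                               seed = derive_seed(seed, "simmap"))[[1]]
    res$simmap <- list(Q = mk$Q, logL = mk$logL)
  }

  run_stage("fit", function() {
    fits <- list(bm1 = fit_bm1(tree, size),
                 bms = fit_bms(tree, painting, size),
                 ou1 = fit_ou1(tree, size))
    tab <- compare_models(fits)
    for (r in names(fits$bms$sigma2_by_regime))
      stats[[paste0("rate_", r)]] <<- fits$bms$sigma2_by_regime[[r]]
    stats[["best_model_is_bms"]] <<- as.numeric(tab$model[1] == "BMS")
    stats[["delta_aicc_second"]] <<- tab$delta_aicc[2]
    list(table = tab, fits = lapply(fits, fit_to_record))
  })
  run_stage("anova", function() {
    t <- phylo_anova(tree, size, island_grouping, n_sims,
                     seed = derive_seed(seed, "anova"))
    stats[["anova_p"]] <<- t$p_value
    list(statistic = t$statistic, observed = t$observed,
         p_value = t$p_value, n_sims = t$n_sims)
  })
  run_stage("manova", function() {
    if (is.null(heads)) stop("head traits unavailable")
    t <- phylo_manova(tree, heads, island_grouping, n_sims,
                      seed = derive_seed(seed, "manova"))
    stats[["manova_p"]] <<- t$p_value
    list(statistic = t$statistic, observed = t$observed,
         p_value = t$p_value, n_sims = t$n_sims)
  })
  run_stage("disparity", function() {
    out <- lapply(islands, function(isl) {
      members <- sp[as.character(g) == isl]
      cont <- sp[as.character(g) == "continent"]
      t <- disparity_ratio_test(tree, size, members, cont, n_sims,
                                seed = derive_seed(seed,
                                                   paste0("disparity-", isl)))
      stats[[paste0("disparity_ratio_", isl)]] <<- t$observed
      stats[[paste0("disparity_p_", isl)]] <<- t$p_value
      list(island = isl, ratio = t$observed, p_value = t$p_value,
           disparity_island = t$disparity_island,
           disparity_continent = t$disparity_continent)
    })
    setNames(out, islands)
  })
  run_stage("pseudocom", function() {
    cont <- sp[as.character(g) == "continent"]
    out <- lapply(islands, function(isl) {
      members <- sp[as.character(g) == isl]
      t <- pseudo_community_test(size[cont], size[members],
                                 k = length(members), n_resamples = 10000,
                                 seed = derive_seed(seed,
                                                    paste0("pseudocom-", isl)))
      stats[[paste0("pseudocom_p_", isl)]] <<- unname(t$p_value[1])
      list(island = isl, k = t$k, mode = t$mode,
           observed_range = unname(t$observed_range),
           p_value = unname(t$p_value))
    })
    setNames(out, islands)
  })
  run_stage("bootstrap", function() {
    t <- parametric_bootstrap_bms(tree, painting, size, n_boot,
                                  seed = derive_seed(seed, "bootstrap"))
    stats[["bootstrap_p"]] <<- t$p_value
    stats[["bootstrap_power"]] <<- t$power
    list(observed_lr = t$observed_lr, p_value = t$p_value,
         power = t$power, n_boot = t$n_boot, n_failed = t$n_failed)
  })
  run_stage("ctt", function() {
    t <- contrasts_through_time(tree, size, n_sims,
                                seed = derive_seed(seed, "ctt"))
    stats[["ctt_n_flagged"]] <<- sum(t$flagged)
    list(n_nodes = nrow(t), n_flagged = sum(t$flagged),
         flagged_nodes = t$node[t$flagged])
  })
  res$summary_stats <- stats
  res$seed <- seed
  res$failed <- failed
  res
}

#' Aggregate per-tree results into distribution summaries
#'
#' @param stats a list (one element per tree) of named numeric vectors,
#'   e.g. the `summary_stats` entries of a [run_pipeline()] report.
#' @return a data.frame with one row per statistic: `min`, `median`,
#'   `mean`, `max`, `n_trees`. Order of trees is irrelevant.
#' @export
aggregate_over_trees <- function(stats) {
  stopifnot(length(stats) >= 1)
  nm <- names(stats[[1]])
  for (s in stats)
    if (!identical(sort(names(s)), sort(nm)))
      stop("heterogeneous result schemas across trees")
  out <- do.call(rbind, lapply(nm, function(k) {
    v <- vapply(stats, function(s) as.numeric(s[[k]]), numeric(1))
    data.frame(statistic = k, min = min(v), median = median(v),
               mean = mean(v), max = max(v), n_trees = length(v))
  }))
  rownames(out) <- NULL
  out
}

#' @export
print.run_report <- function(x, ...) {
  cat("islandpcm run:", x$config$n_trees, "tree(s), seed",
      x$config$seed, "\n analyses:",
      paste(x$config$analyses, collapse = ", "), "\n")
  if (!is.null(x$aggregate)) print(x$aggregate)
  else if (length(x$trees)) {
    s <- x$trees[[1]]$summary_stats
    if (length(s)) print(data.frame(statistic = names(s),
                                    value = as.numeric(s)))
  }
  invisible(x)
}
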