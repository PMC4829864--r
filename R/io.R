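# Tabular I/O -----------------------------------------------------------

#' Read a species trait table
#'
#' CSV with header `species,svl,hl,hw,hd` (any subset of the trait
#' columns). Trait values are log10-transformed at ingestion unless
#' `log10 = FALSE` (for data already on the log scale); empty cells are
#' missing values, and species missing a trait are dropped per-analysis
#' downstream with a message.
#'
#' @param path CSV file path.
#' @param log10 transform values with log10 on ingestion (default TRUE).
#' @return a data.frame with a `species` column and numeric trait
#'   columns; attribute `scale` records `"log10"` or `"raw"`.
#' @export
read_trait_table <- function(path, log10 = TRUE) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(tab)) stop("trait CSV needs a `species` column")
  traits <- setdiff(names(tab), "species")
  if (!length(traits)) stop("trait CSV has no trait columns")
  for (tr in traits) {
    tab[[tr]] <- as.numeric(tab[[tr]])
    if (log10) {
      if (any(tab[[tr]] <= 0, na.rm = TRUE))
        stop("trait '", tr, "' has non-positive values; cannot log10")
      tab[[tr]] <- log10(tab[[tr]])
    }
  }
  if (anyDuplicated(tab$species)) stop("duplicate species in trait table")
  attr(tab, "scale") <- if (log10) "log10" else "raw"
  tab
}

#' Read a species group table
#'
#' @param path CSV with header `species,group`.
#' @return named character vector of group labels.
#' @export
read_groups <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "group") %in% names(tab)))
    stop("groups CSV needs `species` and `group` columns")
  setNames(as.character(tab$group), tab$species)
}

#' Read discrete tip states
#'
#' @param path CSV with header `species,state` (`?` allowed for
#'   missing states).
#' @return named character vector of states.
#' @export
read_tip_states <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("species", "state") %in% names(tab)))
    stop("tip-states CSV needs `species` and `state` columns")
  setNames(as.character(tab$state), tab$species)
}

#' Read a set of trees
#'
#' One Newick tree per line; each tree is validated as in
#' [read_newick()].
#'
#' @param path file path.
#' @return a list of \code{phylo} objects.
#' @export
read_tree_set <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lapply(lines, read_newick)
}

# Serialise a model fit to a plain list for JSON output.
fit_to_record <- function(fit) {
  pars <- fit[setdiff(names(fit), c("model", "logL", "k", "n", "aicc",
                                    "convergence", "at_bound"))]
  list(model = fit$model, params = pars, logL = fit$logL,
       k = fit$k, n = fit$n, aicc = fit$aicc)
}
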