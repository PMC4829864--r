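#' Read a Newick tree
#'
#' Parses a standard Newick string into an `ape` \code{phylo} object and
#' validates it for downstream comparative analyses: the tree must be
#' rooted, all non-root branches must carry a (non-negative) length, and
#' tip labels must be unique and non-empty. Polytomies are resolved
#' deterministically into zero-length binary branches, because contrasts
#' and pruning require binary trees.
#'
#' @param text a Newick string (single tree, terminated by `;`).
#' @return an object of class \code{phylo}.
#' @examples
#' tr <- read_newick("((A:1,B:1):1,C:2);")
#' node_heights(tr)
#' @export
read_newick <- function(text) {
  tr <- tryCatch(ape::read.tree(text = text),
                 error = function(e) NULL, warning = function(w) NULL)
  if (is.null(tr) || !inherits(tr, "phylo"))
    stop("malformed Newick: could not parse '", substr(text, 1, 60), "'")
  validate_tree(tr)
}

#' Write a tree as Newick
#'
#' @param tree a \code{phylo} object.
#' @param digits significant digits for branch lengths.
#' @return a Newick string.
#' @export
write_newick <- function(tree, digits = 12) {
  ape::write.tree(tree, digits = digits)
}

# Ingestion checks shared by all readers. Returns the (possibly
# binarised) tree or stops with an informative message.
validate_tree <- function(tree) {
  if (is.null(tree$edge.length) || anyNA(tree$edge.length))
    stop("missing branch length on at least one edge")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (any(!nzchar(tree$tip.label))) stop("empty tip label")
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    tree <- ape::multi2di(tree, random = FALSE)
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  tree
}

#' Node heights (time from the root)
#'
#' @param tree a \code{phylo} object.
#' @return numeric vector of length `Ntip + Nnode`, indexed by ape node
#'   id, giving each node's distance from the root.
#' @export
node_heights <- function(tree) {
  ape::node.depth.edgelength(tree)
}

#' Test whether a tree is ultrametric
#'
#' Tip heights are compared to the tree depth; the tree is declared
#' ultrametric when their spread is below `rel_tol` times the depth.
#'
#' @param tree a \code{phylo} object.
#' @param rel_tol relative tolerance (default `1e-6`).
#' @return logical flag.
#' @export
is_ultrametric <- function(tree, rel_tol = 1e-6) {
  h <- node_heights(tree)[seq_len(ape::Ntip(tree))]
  depth <- max(h)
  if (depth == 0) return(TRUE)
  (max(h) - min(h)) <= rel_tol * depth
}

#' Phylogenetic variance-covariance matrix
#'
#' Entry (i, j) is the shared path length from the root to the most
#' recent common ancestor of tips i and j; the diagonal holds tip depths.
#' Under Brownian motion with rate \eqn{\sigma^2} the trait covariance
#' among tips is \eqn{\sigma^2} times this matrix.
#'
#' @param tree a \code{phylo} object.
#' @return a symmetric matrix with tip labels as dimnames.
#' @export
vcv_tree <- function(tree) {
  ape::vcv.phylo(tree)
}

# Cholesky with a single-jitter fallback: if the factorisation fails,
# 1e-10 * max(diag) is added to the diagonal once, then we give up.
chol_safe <- function(C) {
  L <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(L)) {
    jitter <- 1e-10 * max(diag(C))
    L <- tryCatch(chol(C + diag(jitter, nrow(C))), error = function(e) NULL)
    if (is.null(L)) stop("covariance matrix is not positive definite")
  }
  L
}

# Align a named trait vector or matrix to the tip order of `tree`.
# Returns a matrix with Ntip rows in tip-id order.
align_traits <- function(tree, x) {
  labs <- tree$tip.label
  if (is.null(dim(x))) {
    if (is.null(names(x))) {
      if (length(x) != length(labs))
        stop("unnamed trait vector must have one value per tip")
      names(x) <- labs
    }
    x <- matrix(x[labs], ncol = 1, dimnames = list(labs, NULL))
  } else {
    x <- as.matrix(x)
    if (is.null(rownames(x))) {
      if (nrow(x) != length(labs))
        stop("unnamed trait matrix must have one row per tip")
      rownames(x) <- labs
    }
    x <- x[labs, , drop = FALSE]
  }
  if (anyNA(x)) stop("missing trait values for some tips")
  x
}
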