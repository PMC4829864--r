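#' Regime paintings
#'
#' A regime painting assigns every instant along every branch of a tree
#' to one discrete regime (for example `continent`, `Socotra`,
#' `AbdAlKuri`), the way a stochastic character map does. It is stored as
#' one named numeric vector per edge -- segment durations named by regime,
#' ordered from the parent end to the child end -- parallel to the rows of
#' `tree$edge`.
#'
#' @param maps list of named numeric vectors, one per edge of the tree,
#'   in `tree$edge` row order.
#' @param alphabet character vector of allowed regime labels.
#' @return an object of class \code{regime_painting}.
#' @export
regime_painting <- function(maps, alphabet) {
  stopifnot(is.list(maps), is.character(alphabet), length(alphabet) >= 1)
  maps <- lapply(maps, merge_segments)
  bad <- setdiff(unique(unlist(lapply(maps, names))), alphabet)
  if (length(bad))
    stop("regime label(s) outside the declared alphabet: ",
         paste(bad, collapse = ", "))
  if (any(vapply(maps, function(m) any(m <= 0), logical(1))))
    stop("segment durations must be strictly positive")
  structure(list(maps = maps, alphabet = alphabet),
            class = "regime_painting")
}

# Collapse adjacent segments with the same regime label.
merge_segments <- function(m) {
  if (length(m) <= 1) return(m)
  keep <- c(TRUE, names(m)[-1] != names(m)[-length(m)])
  grp <- cumsum(keep)
  out <- as.numeric(rowsum(as.numeric(m), grp))
  names(out) <- names(m)[keep]
  out
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting over", length(x$maps), "edges; alphabet: {",
      paste(x$alphabet, collapse = ", "), "}\n")
  dwell <- rowsum(unlist(x$maps, use.names = FALSE),
                  unlist(lapply(x$maps, names)))
  for (s in rownames(dwell))
    cat("  ", s, ": total dwell time ", format(dwell[s, 1]), "\n", sep = "")
  invisible(x)
}

# Check a painting against its tree: one map per edge, durations summing
# to the branch length within a relative tolerance.
validate_painting <- function(tree, painting, rel_tol = 1e-9) {
  stopifnot(inherits(painting, "regime_painting"))
  if (length(painting$maps) != nrow(tree$edge))
    stop("painting does not cover every branch: ", length(painting$maps),
         " maps for ", nrow(tree$edge), " edges")
  lens <- tree$edge.length
  sums <- vapply(painting$maps, sum, numeric(1))
  off <- abs(sums - lens) > rel_tol * pmax(lens, 1e-300)
  if (any(off))
    stop("segment durations do not sum to branch length on edge(s) ",
         paste(which(off), collapse = ", "))
  invisible(painting)
}

#' Per-edge regime durations
#'
#' @param tree a \code{phylo} object.
#' @param painting a \code{regime_painting} for `tree`.
#' @return a matrix with one row per edge (in `tree$edge` order) and one
#'   column per regime, holding the time each edge spends in each regime.
#' @export
painting_durations <- function(tree, painting) {
  validate_painting(tree, painting)
  R <- length(painting$alphabet)
  out <- matrix(0, nrow(tree$edge), R,
                dimnames = list(NULL, painting$alphabet))
  for (e in seq_along(painting$maps)) {
    m <- painting$maps[[e]]
    for (s in unique(names(m))) out[e, s] <- sum(m[names(m) == s])
  }
  out
}

#' Read a painted Newick string
#'
#' Parses the painted-Newick dialect in which every non-root branch is
#' annotated, after its length, with `[&regimes=s1:d1|s2:d2|...]` giving
#' regime segments ordered from the parent end to the child end. The
#' annotation survives standard Newick parsers as a comment. Adjacent
#' segments with the same label are merged; per branch, durations must
#' sum to the branch length within a relative tolerance of 1e-9.
#'
#' @param text a painted-Newick string.
#' @param alphabet character vector of allowed regime labels.
#' @return a list with components `tree` (a \code{phylo}) and `painting`
#'   (a \code{regime_painting}).
#' @examples
#' pt <- read_painting("(A:1.0[&regimes=c:1.0],B:1.0[&regimes=c:0.4|i:0.6]);",
#'                     alphabet = c("c", "i"))
#' pt$painting
#' @export
read_painting <- function(text, alphabet) {
  text <- gsub("[[:space:]]", "", text)
  env <- new.env(parent = emptyenv())
  env$pos <- 1L
  env$text <- text
  env$n <- nchar(text)

  peek <- function() if (env$pos > env$n) "" else substr(env$text, env$pos, env$pos)
  advance <- function() env$pos <- env$pos + 1L
  fail <- function(what)
    stop("painted-Newick parse error at position ", env$pos, " ('",
         substr(env$text, env$pos, min(env$n, env$pos + 12)), "'): ", what)

  read_label <- function() {
    m <- regexpr("^[^(),:;\\[\\]]+", substr(env$text, env$pos, env$n), perl = TRUE)
    if (m == -1L || attr(m, "match.length") == 0L) fail("expected a label")
    lab <- substr(env$text, env$pos, env$pos + attr(m, "match.length") - 1L)
    env$pos <- env$pos + attr(m, "match.length")
    lab
  }
  read_number <- function() {
    m <- regexpr("^[-+]?[0-9]*\\.?[0-9]+([eE][-+]?[0-9]+)?",
                 substr(env$text, env$pos, env$n))
    if (m == -1L || attr(m, "match.length") == 0L) fail("expected a number")
    num <- substr(env$text, env$pos, env$pos + attr(m, "match.length") - 1L)
    env$pos <- env$pos + attr(m, "match.length")
    as.numeric(num)
  }
  read_annotation <- function() {
    start <- env$pos
    m <- regexpr("^\\[&regimes=[^\\]]*\\]", substr(env$text, env$pos, env$n),
                 perl = TRUE)
    if (m == -1L) fail("expected a [&regimes=...] annotation")
    ann <- substr(env$text, env$pos, env$pos + attr(m, "match.length") - 1L)
    env$pos <- env$pos + attr(m, "match.length")
    body <- sub("^\\[&regimes=", "", sub("\\]$", "", ann))
    segs <- strsplit(body, "|", fixed = TRUE)[[1]]
    if (!length(segs)) fail("empty regime annotation")
    states <- sub(":.*$", "", segs)
    durs <- suppressWarnings(as.numeric(sub("^[^:]*:", "", segs)))
    if (anyNA(durs)) stop("bad regime segment in '", ann, "'")
    bad <- setdiff(states, alphabet)
    if (length(bad))
      stop("regime label(s) outside the declared alphabet: ",
           paste(bad, collapse = ", "), " (position ", start, ")")
    if (any(durs <= 0)) stop("segment durations must be strictly positive")
    setNames(durs, states)
  }
  # Recursive descent; returns list(label|children, len, segs).
  parse_clade <- function(is_root) {
    node <- list()
    if (peek() == "(") {
      advance()
      children <- list(parse_clade(FALSE))
      while (peek() == ",") {
        advance()
        children[[length(children) + 1L]] <- parse_clade(FALSE)
      }
      if (peek() != ")") fail("expected ')' or ','")
      advance()
      node$children <- children
      if (!peek() %in% c(":", ",", ")", ";", "[")) node$label <- read_label()
    } else {
      node$label <- read_label()
    }
    if (peek() == ":") {
      advance()
      node$len <- read_number()
      if (peek() == "[") node$segs <- read_annotation()
    }
    if (!is_root) {
      if (is.null(node$len)) fail("missing branch length")
      if (is.null(node$segs)) fail("missing [&regimes=...] annotation")
    }
    node
  }

  root <- parse_clade(TRUE)
  if (peek() != ";") fail("expected ';'")

  # Flatten to an ape phylo: tips numbered in order of appearance,
  # internal nodes in preorder (root = n_tip + 1), edges cladewise.
  count_tips <- function(nd)
    if (is.null(nd$children)) 1L else
      sum(vapply(nd$children, count_tips, integer(1)))
  n_tip <- count_tips(root)
  if (n_tip < 2) stop("painted-Newick tree must have at least 2 tips")

  st <- new.env(parent = emptyenv())
  st$tip <- 0L
  st$int <- n_tip + 1L
  st$parent <- integer(0)
  st$child <- integer(0)
  st$len <- numeric(0)
  st$maps <- list()
  st$labels <- character(0)

  # Two passes keep the bookkeeping simple: first number nodes, then emit
  # edges in preorder.
  number_node <- function(nd) {
    if (is.null(nd$children)) {
      st$tip <- st$tip + 1L
      st$labels[st$tip] <- nd$label
      nd$id <- st$tip
    } else {
      nd$id <- st$int
      st$int <- st$int + 1L
      nd$children <- lapply(nd$children, number_node)
    }
    nd
  }
  emit_edges <- function(nd) {
    if (is.null(nd$children)) return(invisible())
    for (ch in nd$children) {
      k <- length(st$parent) + 1L
      st$parent[k] <- nd$id
      st$child[k] <- ch$id
      st$len[k] <- ch$len
      st$maps[[k]] <- ch$segs
      emit_edges(ch)
    }
  }
  root <- number_node(root)
  emit_edges(root)

  tree <- structure(list(edge = cbind(st$parent, st$child),
                         edge.length = st$len,
                         tip.label = st$labels,
                         Nnode = st$int - n_tip - 1L),
                    class = "phylo", order = "cladewise")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate tip label: ",
         tree$tip.label[duplicated(tree$tip.label)][1])
  if (!ape::is.binary(tree))
    stop("painted trees must be binary (paintings cannot be carried through polytomy resolution)")
  painting <- regime_painting(st$maps, alphabet)
  validate_painting(tree, painting)
  list(tree = tree, painting = painting)
}

#' Write a painted Newick string
#'
#' Inverse of [read_painting()]: serialises a tree and painting in the
#' `[&regimes=...]` dialect, losslessly to 12 significant digits.
#'
#' @param tree a \code{phylo} object.
#' @param painting a \code{regime_painting} for `tree`.
#' @param digits significant digits for lengths and durations.
#' @return a painted-Newick string.
#' @export
write_painting <- function(tree, painting, digits = 12) {
  validate_painting(tree, painting)
  fmt <- function(x) sprintf(paste0("%.", digits, "g"), x)
  n_tip <- ape::Ntip(tree)
  children <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  build <- function(node) {
    kids <- children[[as.character(node)]]
    inner <- if (is.null(kids)) tree$tip.label[node] else
      paste0("(", paste(vapply(kids, function(e) {
        m <- painting$maps[[e]]
        ann <- paste(names(m), fmt(m), sep = ":", collapse = "|")
        paste0(build(tree$edge[e, 2]), ":", fmt(tree$edge.length[e]),
               "[&regimes=", ann, "]")
      }, character(1)), collapse = ","), ")")
    inner
  }
  paste0(build(n_tip + 1L), ";")
}

#' Per-regime shared-time matrices
#'
#' Decomposes the phylogenetic covariance matrix by regime: for regime
#' *r*, entry (i, j) is the time painted *r* along the shared root-to-MRCA
#' path of tips i and j. The matrices sum elementwise to [vcv_tree()],
#' and are exactly the per-regime shared-time components the multi-rate
#' Brownian likelihood needs.
#'
#' @param tree a \code{phylo} object.
#' @param painting a \code{regime_painting} covering every branch.
#' @return a named list of symmetric matrices, one per regime.
#' @export
regime_vcv <- function(tree, painting) {
  durmat <- painting_durations(tree, painting)
  n_tip <- ape::Ntip(tree)
  n_node <- n_tip + tree$Nnode
  R <- ncol(durmat)
  # cumulative per-regime depth of each node, root-down
  acc <- matrix(0, n_node, R, dimnames = list(NULL, colnames(durmat)))
  pre <- reorder(tree, "cladewise")
  perm <- match(paste(pre$edge[, 1], pre$edge[, 2]),
                paste(tree$edge[, 1], tree$edge[, 2]))
  for (k in seq_len(nrow(pre$edge))) {
    e <- perm[k]
    acc[tree$edge[e, 2], ] <- acc[tree$edge[e, 1], ] + durmat[e, ]
  }
  M <- ape::mrca(tree)
  labs <- tree$tip.label
  out <- lapply(colnames(durmat), function(s) {
    V <- matrix(acc[M, s], n_tip, n_tip, dimnames = list(labs, labs))
    diag(V) <- acc[seq_len(n_tip), s]
    V
  })
  names(out) <- colnames(durmat)
  out
}
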