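#' Rooted multifurcating trees
#'
#' `mftree` is the package's internal representation of a rooted tree in
#' which no node has out-degree 1 (every internal node has at least two
#' children).  It is a flat parent-vector encoding: nodes are numbered
#' `1..N` with the root at 1 and every non-root node has a parent with a
#' strictly smaller number, so a single forward (or backward) loop over the
#' node vector visits parents before children (or children before parents).
#' All index computations are linear in the number of nodes.
#'
#' A tree may carry leaf labels (a *phylogenetic* tree) or not (a tree
#' *shape*, i.e. an isomorphism class).  Labels, when present, are stored as
#' a character vector over all nodes with `NA` at internal nodes.
#'
#' @param parent integer vector of parent indices; `parent[1]` must be 0 and
#'   `parent[v] < v` for `v > 1`.
#' @param labels optional character vector of node labels (`NA` for internal
#'   nodes), or `NULL` for an unlabeled shape.
#' @return An object of class `mftree`.
#' @examples
#' cherry <- mftree(c(0L, 1L, 1L))
#' n_leaves(cherry)
#' @export
mftree <- function(parent, labels = NULL) {
  parent <- as.integer(parent)
  t <- structure(list(parent = parent, labels = labels), class = "mftree")
  validate_mftree(t)
}

validate_mftree <- function(t) {
  p <- t$parent
  n <- length(p)
  if (n < 1L) stop("tree must have at least one node")
  if (p[1L] != 0L) stop("node 1 must be the root (parent 0)")
  if (n > 1L && !all(p[-1L] >= 1L & p[-1L] < seq_len(n)[-1L]))
    stop("every non-root node must have a parent with a smaller index")
  deg <- out_degrees(t)
  if (any(deg == 1L))
    stop("out-degree-1 nodes are not allowed: rooted trees here have every ",
         "internal node with at least two children")
  if (!is.null(t$labels)) {
    if (length(t$labels) != n) stop("labels must have one entry per node")
    lab <- t$labels[deg == 0L]
    if (anyNA(lab) || any(lab == ""))
      stop("all leaves must be labelled (or drop labels entirely)")
    if (anyDuplicated(lab)) stop("duplicate leaf labels")
  }
  t
}

#' @export
print.mftree <- function(x, ...) {
  kind <- if (is.null(x$labels)) "tree shape" else "phylogenetic tree"
  cat(sprintf("<mftree> %s with %d leaves, %d internal nodes, depth %d\n",
              kind, n_leaves(x), sum(out_degrees(x) > 0L), tree_depth(x)))
  cat(" ", write_newick(x), "\n", sep = "")
  invisible(x)
}

#' Tree accessors
#'
#' Basic structural queries on an [mftree]: number of leaves, out-degree of
#' every node, node depths, number of descendant leaves under every node,
#' and the depth of the tree.
#'
#' @param tree an [mftree] (or anything [as_mftree] accepts).
#' @return `out_degrees` and `node_depths` return an integer vector over all
#'   nodes; `n_leaves` and `tree_depth` a single integer; `kappa_values` the
#'   number of descendant leaves of every node.
#' @export
n_leaves <- function(tree) {
  tree <- as_mftree(tree)
  sum(out_degrees(tree) == 0L)
}

#' @rdname n_leaves
#' @export
out_degrees <- function(tree) {
  if (inherits(tree, "mftree"))
    tabulate(tree$parent[-1L], nbins = length(tree$parent))
  else out_degrees(as_mftree(tree))
}

#' @rdname n_leaves
#' @export
node_depths <- function(tree) {
  tree <- as_mftree(tree)
  p <- tree$parent
  d <- integer(length(p))
  for (v in seq_along(p)[-1L]) d[v] <- d[p[v]] + 1L
  d
}

#' @rdname n_leaves
#' @export
tree_depth <- function(tree) max(node_depths(tree))

#' @rdname n_leaves
#' @export
kappa_values <- function(tree) {
  tree <- as_mftree(tree)
  p <- tree$parent
  n <- length(p)
  deg <- out_degrees(tree)
  k <- as.integer(deg == 0L)
  for (v in n:2) if (v >= 2L) k[p[v]] <- k[p[v]] + k[v]
  if (n == 1L) k <- 1L
  k
}

#' Leaf labels of a tree
#'
#' @param tree an [mftree].
#' @return Character vector of leaf labels in node order, or `NULL` for an
#'   unlabeled shape.
#' @export
leaf_labels <- function(tree) {
  tree <- as_mftree(tree)
  if (is.null(tree$labels)) return(NULL)
  tree$labels[out_degrees(tree) == 0L]
}

#' Forget leaf labels
#'
#' Drops the leaf labelling of a phylogenetic tree, returning its shape
#' (isomorphism class representative).
#'
#' @param tree an [mftree].
#' @return An unlabeled [mftree].
#' @export
tree_shape_of <- function(tree) {
  tree <- as_mftree(tree)
  tree$labels <- NULL
  tree
}

# children of every node as a list indexed by node (leaves: integer(0))
children_list <- function(tree) {
  p <- tree$parent
  n <- length(p)
  if (n == 1L) return(list(integer(0)))
  split(2:n, factor(p[-1L], levels = seq_len(n)))
}

#' Coerce to an mftree
#'
#' Converts supported tree representations to [mftree]: `ape::phylo`
#' objects (nodes are renumbered so parents precede children; branch
#' lengths, if any, are ignored) and Newick strings (via [read_newick]).
#' Trees with out-degree-1 nodes are rejected.
#'
#' @param x a tree-like object.
#' @param ... passed on to methods.
#' @return An [mftree].
#' @export
as_mftree <- function(x, ...) UseMethod("as_mftree")

#' @export
as_mftree.mftree <- function(x, ...) x

#' @export
as_mftree.character <- function(x, ...) read_newick(text = x, ...)

#' @export
as_mftree.phylo <- function(x, ...) {
  ntip <- length(x$tip.label)
  nnode <- x$Nnode
  n <- ntip + nnode
  kids <- vector("list", n)
  for (i in seq_len(nrow(x$edge))) {
    a <- x$edge[i, 1L]; b <- x$edge[i, 2L]
    kids[[a]] <- c(kids[[a]], b)
  }
  root <- ntip + 1L
  # BFS renumbering: parents get smaller indices than their children
  newid <- integer(n)
  order_old <- integer(n)
  queue <- root
  nxt <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nxt <- nxt + 1L
    newid[v] <- nxt
    order_old[nxt] <- v
    queue <- c(queue, kids[[v]])
  }
  parent <- integer(n)
  for (i in seq_len(nrow(x$edge)))
    parent[newid[x$edge[i, 2L]]] <- newid[x$edge[i, 1L]]
  tips_old <- seq_len(ntip)
  lab <- x$tip.label
  labels <- rep(NA_character_, n)
  labels[newid[tips_old]] <- lab
  if (all(is.na(lab) | lab == "")) labels <- NULL
  mftree(parent, labels)
}

#' @importFrom ape as.phylo
#' @export
ape::as.phylo

#' Convert an mftree to an ape phylo object
#'
#' Tips are numbered in node order; unlabeled shapes get empty tip labels.
#' Single-leaf trees cannot be represented as `phylo` and raise an error.
#'
#' @param x an [mftree].
#' @param ... unused.
#' @return An object of class `phylo`.
#' @export
as.phylo.mftree <- function(x, ...) {
  deg <- out_degrees(x)
  n <- length(x$parent)
  ntip <- sum(deg == 0L)
  if (n == 1L) stop("a single-leaf tree cannot be represented as a 'phylo' object")
  map <- integer(n)
  map[deg == 0L] <- seq_len(ntip)
  map[deg > 0L] <- ntip + seq_len(n - ntip)  # root (index 1) becomes ntip+1
  edge <- cbind(map[x$parent[-1L]], map[-1L])
  tip.label <- if (is.null(x$labels)) rep("", ntip) else x$labels[deg == 0L]
  structure(list(edge = edge, Nnode = n - ntip, tip.label = tip.label),
            class = "phylo", order = "cladewise")
}

#' Tree constructors: combs, stars, fully symmetric trees and joins
#'
#' `comb_tree(n)` builds the comb (caterpillar) shape with `n` leaves: the
#' bifurcating tree in which every internal node has a leaf child.
#' `star_tree(n)` builds the depth-1 star with `n` leaves.  `fs_tree(ns)`
#' builds the fully symmetric tree determined by an ordered factorization
#' `ns = c(n1, ..., nk)` (each `ni >= 2`): the root has `n1` children, each
#' carrying a copy of `fs_tree(ns[-1])`; `fs_tree(integer(0))` is the
#' single-leaf tree.  `join_trees(...)` joins two or more trees under a new
#' common root.
#'
#' @param n number of leaves (`n >= 1`).
#' @param ns integer vector of factors, each `>= 2` (possibly empty).
#' @param ... trees to join (at least two), or a single list of trees.
#' @return An [mftree] shape (`join_trees` keeps labels if all inputs are
#'   labelled with pairwise disjoint label sets, otherwise returns a shape).
#' @examples
#' sackin(fs_tree(c(2, 3)))
#' colless(comb_tree(5))
#' @export
comb_tree <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(leaf_tree())
  nint <- n - 1L
  parent <- integer(2L * n - 1L)
  if (nint >= 2L) parent[2:nint] <- 1:(nint - 1L)
  parent[nint + 1:(n - 1L)] <- 1:nint      # one leaf child per internal node
  parent[2L * n - 1L] <- nint              # the deepest internal gets two leaves
  mftree(parent)
}

#' @rdname comb_tree
#' @export
star_tree <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(leaf_tree())
  mftree(c(0L, rep(1L, n)))
}

#' @rdname comb_tree
#' @export
leaf_tree <- function() mftree(0L)

#' @rdname comb_tree
#' @export
fs_tree <- function(ns) {
  ns <- as.integer(ns)
  if (length(ns) == 0L) return(leaf_tree())
  if (any(ns < 2L)) stop("all factors of a fully symmetric tree must be >= 2")
  sub <- fs_tree(ns[-1L])
  join_trees(rep(list(sub), ns[1L]))
}

#' @rdname comb_tree
#' @export
join_trees <- function(...) {
  trees <- list(...)
  if (length(trees) == 1L && is.list(trees[[1L]]) && !inherits(trees[[1L]], "mftree"))
    trees <- trees[[1L]]
  if (length(trees) < 2L)
    stop("join requires at least two subtrees (a single child would create ",
         "an out-degree-1 node)")
  trees <- lapply(trees, as_mftree)
  sizes <- vapply(trees, function(t) length(t$parent), integer(1))
  parent <- integer(1L + sum(sizes))
  offset <- 1L
  labelled <- all(vapply(trees, function(t) !is.null(t$labels), logical(1)))
  labels <- if (labelled) rep(NA_character_, length(parent)) else NULL
  for (i in seq_along(trees)) {
    p <- trees[[i]]$parent
    p[1L] <- 1L - offset                  # subtree root attaches to new root
    parent[offset + seq_along(p)] <- p + offset
    if (labelled) labels[offset + seq_along(p)] <- trees[[i]]$labels
    offset <- offset + sizes[i]
  }
  mftree(parent, labels)
}
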