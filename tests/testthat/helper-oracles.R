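# Independent oracles used across the suite.  These deliberately take the
# slow, definition-level route (recursive matching, pairwise LCA scans,
# exhaustive set-partition enumeration) so they share no code path with the
# implementations they check.

# subtrees rooted at the children of the root, as standalone mftrees
root_subtrees <- function(tree) {
  tree <- as_mftree(tree)
  p <- tree$parent
  n <- length(p)
  kids <- which(p == 1L)
  lapply(kids, function(v) {
    inset <- logical(n)
    inset[v] <- TRUE
    if (v < n) for (u in (v + 1L):n) if (inset[p[u]]) inset[u] <- TRUE
    ids <- which(inset)
    newp <- match(p[ids], ids)
    newp[1L] <- 0L
    mftree(as.integer(newp),
           labels = if (is.null(tree$labels)) NULL else tree$labels[ids])
  })
}

# brute-force isomorphism of unlabeled shapes by recursive child matching
iso_bruteforce <- function(t1, t2) {
  if (n_leaves(t1) != n_leaves(t2)) return(FALSE)
  c1 <- root_subtrees(t1)
  c2 <- root_subtrees(t2)
  if (length(c1) != length(c2)) return(FALSE)
  if (length(c1) == 0L) return(TRUE)
  used <- logical(length(c2))
  for (a in c1) {
    hit <- FALSE
    for (j in seq_along(c2)) {
      if (!used[j] && iso_bruteforce(a, c2[[j]])) {
        used[j] <- TRUE
        hit <- TRUE
        break
      }
    }
    if (!hit) return(FALSE)
  }
  TRUE
}

# total cophenetic index by its definition: sum over unordered leaf pairs
# of the depth of the lowest common ancestor
phi_bruteforce <- function(tree) {
  tree <- as_mftree(tree)
  p <- tree$parent
  depth <- node_depths(tree)
  leaves <- which(out_degrees(tree) == 0L)
  ancestors <- function(v) {
    out <- v
    while (p[v] != 0L) {
      v <- p[v]
      out <- c(out, v)
    }
    out
  }
  tot <- 0
  if (length(leaves) >= 2L) {
    for (i in seq_along(leaves)[-1L]) {
      ai <- ancestors(leaves[i])
      for (j in seq_len(i - 1L)) {
        lca <- intersect(ai, ancestors(leaves[j]))[1L]
        tot <- tot + depth[lca]
      }
    }
  }
  tot
}

# canonical code that keeps leaf labels: identifies labelled trees
labelled_code <- function(tree) {
  tree <- as_mftree(tree)
  subs <- root_subtrees(tree)
  if (length(subs) == 0L)
    return(tree$labels[1L] %||% "*")
  paste0("(", paste(sort(vapply(subs, labelled_code, character(1)),
                         method = "radix"), collapse = ","), ")")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# exhaustive enumeration of labelled multifurcating trees on a label set,
# via all set partitions into >= 2 blocks (oracle for count_phylo_trees
# and the uniform sampler)
set_partitions_all <- function(labels) {
  # all partitions of labels (possibly one block)
  if (length(labels) == 0L) return(list(list()))
  first <- labels[1L]
  rest <- labels[-1L]
  out <- list()
  for (p in set_partitions_all(rest)) {
    # add `first` to each existing block, or as a new block
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(p, list(first))
  }
  out
}

enumerate_labelled_trees <- function(labels) {
  if (length(labels) == 1L) return(list(mftree(0L, labels = labels)))
  out <- list()
  for (p in set_partitions_all(labels)) {
    if (length(p) < 2L) next
    block_trees <- lapply(p, enumerate_labelled_trees)
    for (combo in cartesian_mix(block_trees))
      out[[length(out) + 1L]] <- join_trees(combo)
  }
  # distinct up to labelled isomorphism
  codes <- vapply(out, labelled_code, character(1))
  out[!duplicated(codes)]
}

cartesian_mix <- function(lists) {
  acc <- list(list())
  for (l in lists)
    acc <- unlist(lapply(acc, function(a) lapply(l, function(x) c(a, list(x)))),
                  recursive = FALSE)
  acc
}

children_list_oracle <- function(tree) {
  p <- tree$parent
  lapply(seq_along(p), function(v) which(p == v))
}

bifurcating_shapes <- function(n) {
  Filter(function(t) all(out_degrees(t) %in% c(0L, 2L)), enumerate_shapes(n))
}
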