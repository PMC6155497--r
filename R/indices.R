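#' Colless and quadratic Colless indices (bifurcating trees)
#'
#' For a bifurcating tree, the Colless index is the sum over internal nodes
#' of `|k1 - k2|`, where `k1, k2` are the numbers of descendant leaves of
#' the node's two children; the quadratic version sums `(k1 - k2)^2`.
#' Both are exact integers, zero exactly on the fully symmetric bifurcating
#' trees (with `2^m` leaves), and maximal exactly at the comb, where
#' `colless(comb_tree(n)) == choose(n - 1, 2)`.  Non-bifurcating input is
#' an error: use [colless_like] for multifurcating trees.
#'
#' @param tree an [mftree] (or anything [as_mftree] accepts).
#' @return A nonnegative integer-valued numeric scalar.
#' @examples
#' colless(comb_tree(10))  # 36
#' @export
colless <- function(tree) {
  sum(abs(colless_child_diffs(tree)))
}

#' @rdname colless
#' @export
quadratic_colless <- function(tree) {
  sum(colless_child_diffs(tree)^2)
}

colless_child_diffs <- function(tree) {
  tree <- as_mftree(tree)
  deg <- out_degrees(tree)
  internal <- which(deg > 0L)
  if (any(deg[internal] != 2L))
    stop("the Colless index is defined for bifurcating trees only; ",
         "use colless_like() for multifurcating trees")
  if (length(internal) == 0L) return(numeric(0))
  kap <- kappa_values(tree)
  kids <- children_list(tree)
  vapply(internal, function(v) {
    k <- kap[kids[[v]]]
    k[1L] - k[2L]
  }, numeric(1))
}

#' Colless-like balance index C_{D,f}
#'
#' Generalizes the Colless index to multifurcating trees.  Fix a
#' [dissimilarity] `D` and a [weight_function] `f`.  The *balance value* of
#' an internal node is `D` applied to the f-sizes of the subtrees rooted at
#' its children, and `C_{D,f}(T)` is the sum of the balance values over all
#' internal nodes.  It is computed in a single linear-time post-order pass
#' and satisfies the join recursion
#' `C_{D,f}(T1 * ... * Tk) = sum_i C_{D,f}(Ti) + D(delta_f(T1), ..., delta_f(Tk))`.
#'
#' `C_{D,f}` is zero on every fully symmetric tree; it is *sound* (zero
#' **only** there) whenever distinct fully symmetric trees always have
#' distinct f-sizes, which holds for `f(n) = ln(n + e)` and `f(n) = e^n`
#' with any dissimilarity, but fails for e.g. the leaf count, node count,
#' polynomial and integer-base exponential weights (see
#' [find_fsize_collisions]).
#'
#' On bifurcating trees, `C_{MDM,f} = (f(0) + f(2))/2 * C`,
#' `C_{sd,f} = (f(0) + f(2))/sqrt(2) * C` and
#' `C_{var,f} = (f(0) + f(2))^2 / 2 * C^(2)`, with `C` the Colless and
#' `C^(2)` the quadratic Colless index.
#'
#' @param tree an [mftree] (or anything [as_mftree] accepts).
#' @param D a [dissimilarity] or name (`"mdm"`, `"var"`, `"sd"`); default
#'   the mean deviation from the median.
#' @param f a [weight_function] or preset name; default `ln(n + e)`.
#' @param norm if `TRUE`, divide by the maximum of `C_{D,f}` over all
#'   shapes with the same number of leaves (see [max_colless_like]); only
#'   available for the `(D, f)` pairs with a known closed-form maximum.
#' @return A nonnegative numeric scalar (in `[0, 1]` when `norm = TRUE`).
#' @examples
#' colless_like(comb_tree(4), "mdm", "exp_n")  # 1.5 * (exp(2) + 1)
#' @export
colless_like <- function(tree, D = "mdm", f = "ln_n_plus_e", norm = FALSE) {
  tree <- as_mftree(tree)
  D <- dissimilarity(D)
  f <- weight_function(f)
  deg <- out_degrees(tree)
  p <- tree$parent
  n <- length(p)
  delta <- f$fn(deg)
  for (v in n:2) if (n >= 2L) delta[p[v]] <- delta[p[v]] + delta[v]
  internal <- which(deg > 0L)
  if (length(internal) == 0L) return(0)
  kids <- children_list(tree)
  val <- sum(vapply(internal, function(v) D$fn(delta[kids[[v]]]), numeric(1)))
  if (norm) {
    nl <- sum(deg == 0L)
    if (nl <= 2L) return(0)
    val <- val / max_colless_like(nl, D, f)
  }
  val
}

#' Sackin index
#'
#' The sum of the depths of the leaves.  Defined for any multifurcating
#' tree; its range over shapes with `n` leaves runs from `n` (the star) to
#' `(n + 2)(n - 1)/2` (the comb).  The normalized version maps that range
#' to `[0, 1]` (0 for `n <= 2`, where all shapes coincide).
#'
#' @param tree an [mftree] (or anything [as_mftree] accepts).
#' @param norm normalize to `[0, 1]`?
#' @return A nonnegative numeric scalar.
#' @examples
#' sackin(fs_tree(c(2, 3)))  # 12
#' @export
sackin <- function(tree, norm = FALSE) {
  tree <- as_mftree(tree)
  deg <- out_degrees(tree)
  s <- sum(node_depths(tree)[deg == 0L])
  if (norm) {
    n <- sum(deg == 0L)
    if (n <= 2L) return(0)
    s <- (s - n) / ((n + 2) * (n - 1) / 2 - n)
  }
  s
}

#' Total cophenetic index
#'
#' The sum over all unordered pairs of leaves of the depth of their lowest
#' common ancestor.  Computed in linear time as the sum of
#' `choose(kappa_v, 2)` over the non-root internal nodes `v` (each internal
#' node `v` is the LCA-or-ancestor contribution of one unit of depth for
#' every leaf pair below it).  Range over shapes with `n` leaves: 0 (the
#' star) to `choose(n, 3)` (the comb); `norm = TRUE` divides by the
#' maximum.
#'
#' @param tree an [mftree] (or anything [as_mftree] accepts).
#' @param norm normalize to `[0, 1]`?
#' @return A nonnegative numeric scalar.
#' @examples
#' total_cophenetic(fs_tree(c(3, 2)))  # 3
#' @export
total_cophenetic <- function(tree, norm = FALSE) {
  tree <- as_mftree(tree)
  deg <- out_degrees(tree)
  kap <- kappa_values(tree)
  internal <- which(deg > 0L)
  phi <- if (length(internal) <= 1L) 0
         else sum(choose(kap[setdiff(internal, 1L)], 2))
  if (norm) {
    n <- sum(deg == 0L)
    if (n <= 2L) return(0)
    phi <- phi / choose(n, 3)
  }
  phi
}

#' All balance indices of a tree
#'
#' Convenience wrapper computing the Sackin index, total cophenetic index
#' and Colless-like index (and, for bifurcating trees, the Colless and
#' quadratic Colless indices) of a tree, raw or normalized.
#'
#' @inheritParams colless_like
#' @return A one-row data frame.
#' @export
balance_indices <- function(tree, D = "mdm", f = "ln_n_plus_e", norm = FALSE) {
  tree <- as_mftree(tree)
  bif <- all(out_degrees(tree) %in% c(0L, 2L)) && n_leaves(tree) >= 2L
  data.frame(
    n = n_leaves(tree),
    colless_like = colless_like(tree, D, f, norm = norm),
    sackin = sackin(tree, norm = norm),
    total_cophenetic = total_cophenetic(tree, norm = norm),
    colless = if (bif) colless(tree) else NA_real_,
    quadratic_colless = if (bif) quadratic_colless(tree) else NA_real_
  )
}

#' Count ties among index values
#'
#' The number of unordered pairs of equal values in a vector, values being
#' compared after rounding to a given number of significant digits
#' (default 16, i.e. at double precision).  Ties measure an index's
#' inability to rank distinct trees.
#'
#' @param values numeric vector of index values.
#' @param digits significant digits retained before comparison.
#' @return A nonnegative integer count of tied pairs.
#' @examples
#' count_ties(c(1, 1, 2))  # 1
#' @export
count_ties <- function(values, digits = 16L) {
  r <- signif(values, digits)
  tab <- tabulate(match(r, unique(r)))
  sum(choose(tab, 2))
}
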