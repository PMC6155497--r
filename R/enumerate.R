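# Canonical codes, isomorphism, exhaustive enumeration and counting of
# tree shapes / phylogenetic trees, ordered factorizations, full symmetry.

.mb_cache <- new.env(parent = emptyenv())

#' Canonical code of a tree shape
#'
#' Computes a string code characterizing the isomorphism class of the shape
#' of a tree: two trees have equal codes exactly when their shapes are
#' isomorphic as unlabeled rooted trees.  The code of a leaf is `*`; the
#' code of an internal node wraps the lexicographically sorted codes of its
#' children in parentheses, so equal codes cannot arise from distinct
#' classes.
#'
#' @param tree an [mftree] (labels are ignored).
#' @return A character scalar.
#' @examples
#' canonical_code(fs_tree(c(2, 3))) == canonical_code(fs_tree(c(3, 2)))
#' @export
canonical_code <- function(tree) {
  tree <- as_mftree(tree)
  node_codes(tree)[1L]
}

# per-node canonical codes, children before parents
node_codes <- function(tree) {
  n <- length(tree$parent)
  deg <- out_degrees(tree)
  kids <- children_list(tree)
  code <- character(n)
  for (v in n:1) {
    code[v] <- if (deg[v] == 0L) "*"
               else paste0("(",
                           paste(sort(code[kids[[v]]], method = "radix"),
                                 collapse = ","),
                           ")")
  }
  code
}

#' Ordered factorizations of an integer
#'
#' All tuples `(n1, ..., nk)` with every `ni >= 2` and product `n`; for
#' `n = 1` the single empty tuple.  Each tuple characterizes one fully
#' symmetric tree shape with `n` leaves, so the number of tuples is the
#' number of such shapes, H(n).
#'
#' @param n a positive integer.
#' @return A list of integer vectors.
#' @examples
#' ordered_factorizations(6)  # (6), (2,3), (3,2)
#' @export
ordered_factorizations <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n == 1L) return(list(integer(0)))
  res <- list()
  for (d in 2:n) {
    if (n %% d == 0L) {
      for (rest in ordered_factorizations(n %/% d))
        res[[length(res) + 1L]] <- c(d, rest)
    }
  }
  res
}

#' Test a tree for full symmetry
#'
#' A tree is fully symmetric when, at every internal node, the subtrees
#' rooted at its children are mutually isomorphic.  Every fully symmetric
#' shape with `n` leaves corresponds to an ordered factorization
#' `n = n1 * ... * nk` (see [fs_tree]); `fs_signature` recovers it.
#'
#' @param tree an [mftree].
#' @return `is_fully_symmetric`: a logical scalar.  `fs_signature`: the
#'   integer vector `(n1, ..., nk)` when the tree is fully symmetric
#'   (`integer(0)` for the single leaf), otherwise `NULL`.
#' @examples
#' is_fully_symmetric(star_tree(4))
#' fs_signature(fs_tree(c(3, 2)))
#' @export
is_fully_symmetric <- function(tree) {
  tree <- as_mftree(tree)
  code <- node_codes(tree)
  kids <- children_list(tree)
  deg <- out_degrees(tree)
  for (v in which(deg > 0L)) {
    ck <- code[kids[[v]]]
    if (any(ck != ck[1L])) return(FALSE)
  }
  TRUE
}

#' @rdname is_fully_symmetric
#' @export
fs_signature <- function(tree) {
  tree <- as_mftree(tree)
  if (!is_fully_symmetric(tree)) return(NULL)
  kids <- children_list(tree)
  deg <- out_degrees(tree)
  sig <- integer(0)
  v <- 1L
  while (deg[v] > 0L) {
    sig <- c(sig, deg[v])
    v <- kids[[v]][1L]
  }
  sig
}

#' Exhaustively enumerate tree shapes
#'
#' Generates all isomorphism classes of rooted trees (without out-degree-1
#' nodes) with exactly `n` leaves, by recursive decomposition of the root
#' into a multiset of at least two smaller shapes.  The classes are
#' pairwise non-isomorphic and exhaustive; their number is [count_shapes].
#' The number of shapes grows fast (tens of thousands at `n = 12`), so a
#' guard refuses larger `n` unless raised explicitly.
#'
#' @param n number of leaves.
#' @param guard largest `n` accepted (default 12).
#' @return A list of [mftree] shapes.
#' @examples
#' length(enumerate_shapes(5))  # 12
#' @export
enumerate_shapes <- function(n, guard = 12L) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n > guard)
    stop("enumerate_shapes(", n, ") exceeds the guard (", guard,
         "); raise 'guard' explicitly for exhaustive work at this size")
  key <- paste0("shapes", n)
  if (!is.null(.mb_cache[[key]])) return(.mb_cache[[key]])
  res <- if (n == 1L) list(leaf_tree()) else {
    out <- list()
    for (part in int_partitions(n)) {      # non-increasing, >= 2 parts
      sizes <- sort(unique(part), decreasing = TRUE)
      per_size <- lapply(sizes, function(s) {
        mult <- sum(part == s)
        multiset_choose(enumerate_shapes(s, guard = guard), mult)
      })
      for (combo in cartesian_lists(per_size)) {
        children <- do.call(c, combo)
        out[[length(out) + 1L]] <- join_trees(children)
      }
    }
    out
  }
  .mb_cache[[key]] <- res
  res
}

# integer partitions of n with at least two parts, parts non-increasing
int_partitions <- function(n) {
  parts_rec <- function(n, maxpart) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (p in min(n, maxpart):1L)
      for (rest in parts_rec(n - p, p))
        out[[length(out) + 1L]] <- c(p, rest)
    out
  }
  Filter(function(p) length(p) >= 2L, parts_rec(n, n - 1L))
}

# all multisets of size m from a list of items (combinations with repetition)
multiset_choose <- function(items, m) {
  pick <- function(start, m) {
    if (m == 0L) return(list(list()))
    out <- list()
    for (i in start:length(items))
      for (rest in pick(i, m - 1L))
        out[[length(out) + 1L]] <- c(list(items[[i]]), rest)
    out
  }
  pick(1L, m)
}

cartesian_lists <- function(lists) {
  out <- list(list())
  for (l in lists) {
    out <- unlist(lapply(out, function(acc)
      lapply(l, function(x) c(acc, list(x)))), recursive = FALSE)
  }
  out
}

#' Count tree shapes and phylogenetic trees
#'
#' `count_shapes(n)` is the number of isomorphism classes of rooted
#' multifurcating trees with `n` leaves; `count_phylo_trees(n)` the number
#' of phylogenetic trees (leaves bijectively labelled `1..n`).  Both are
#' computed by integer recurrences over root decompositions: shapes as
#' multisets of at least two smaller shapes, labelled trees via forests of
#' labelled trees.  Values are exact while below 2^53 (shapes up to
#' `n = 28`, labelled trees up to `n = 15`); beyond that they are
#' double-precision approximations.
#'
#' @param n number of leaves.
#' @return A numeric scalar (an exact integer value while representable).
#' @examples
#' count_phylo_trees(4)  # 26
#' count_shapes(6)       # 33
#' @export
count_shapes <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  shape_count_table(n)[n]
}

shape_count_table <- function(N) {
  key <- paste0("scount", N)
  cached <- .mb_cache[["scount"]]
  if (!is.null(cached) && length(cached) >= N) return(cached[seq_len(N)])
  s <- numeric(N)
  s[1] <- 1
  # dp[j+1]: multisets of shapes with <= i-1 leaves each, totaling j leaves
  dp <- numeric(N + 1)
  dp[1] <- 1
  for (i in seq_len(N)) {
    if (i >= 2) s[i] <- dp[i + 1]
    types <- s[i]
    if (types > 0 && i <= N) {
      new <- dp
      maxm <- N %/% i
      for (m in seq_len(maxm)) {
        w <- choose(types + m - 1, m)
        idx <- (i * m):N
        new[idx + 1] <- new[idx + 1] + w * dp[idx - i * m + 1]
      }
      dp <- new
    }
  }
  .mb_cache[["scount"]] <- s
  s
}

#' @rdname count_shapes
#' @export
count_phylo_trees <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  phylo_count_tables(n)$t[n]
}

# t[n]: labelled multifurcating trees on n leaves; f[n]: labelled forests
# (unordered, >= 1 block); f[n] = 2 t[n] for n >= 2.
phylo_count_tables <- function(N) {
  cached <- .mb_cache[["pcount"]]
  if (!is.null(cached) && length(cached$t) >= N)
    return(lapply(cached, function(x) x[seq_len(N)]))
  t <- numeric(N); f <- numeric(N)
  t[1] <- 1; f[1] <- 1
  f0 <- 1
  if (N >= 2) {
    for (n in 2:N) {
      acc <- 0
      for (s in 1:(n - 1)) {
        frest <- if (n - s == 0) f0 else f[n - s]
        acc <- acc + choose(n - 1, s - 1) * t[s] * frest
      }
      t[n] <- acc
      f[n] <- 2 * acc
    }
  }
  res <- list(t = t, f = f)
  .mb_cache[["pcount"]] <- res
  res
}
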