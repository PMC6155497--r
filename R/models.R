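#' Random multifurcating trees under the alpha-gamma model
#'
#' Grows a phylogenetic tree on leaves `1..n` by the Markov branching rules
#' of the alpha-gamma model (`0 <= gamma <= alpha <= 1`).  Starting from
#' the two-leaf tree, at each step with `m` leaves the new leaf attaches:
#'
#' * to a pendant edge, each with weight `1 - alpha` (the edge is
#'   subdivided and the new leaf becomes sister to that leaf);
#' * to an internal edge — including the planted edge above the root —
#'   each with weight `gamma` (subdivision again; choosing the planted edge
#'   places the new leaf as sister to the whole tree);
#' * to an internal node of out-degree `k`, with weight
#'   `(k - 1) alpha - gamma` (the new leaf becomes an extra child, creating
#'   or extending a multifurcation).
#'
#' The weights total `m - alpha`.  With `alpha == gamma` the node weights
#' vanish for binary nodes, so every tree is bifurcating and the model
#' reduces to Ford's alpha model (including the Yule model at
#' `alpha = 0` and the uniform model on bifurcating trees at
#' `alpha = 1/2`).  Leaves are labelled in order of addition.  Randomness
#' comes from R's RNG: call `set.seed()` for reproducibility.
#'
#' @param n number of leaves (`>= 2`).
#' @param alpha,gamma model parameters with `0 <= gamma <= alpha <= 1`.
#' @return A labelled [mftree].
#' @examples
#' set.seed(1)
#' rtree_alpha_gamma(8, alpha = 0.7, gamma = 0.4)
#' @export
rtree_alpha_gamma <- function(n, alpha, gamma) {
  n <- as.integer(n)
  if (n < 2L) stop("n must be at least 2")
  if (!(gamma >= 0 && gamma <= alpha && alpha <= 1))
    stop("need 0 <= gamma <= alpha <= 1")
  # growth arrays; parent indices are arbitrary here and renumbered at the end
  parent <- c(0L, 1L, 1L)
  leaf_rank <- c(NA_integer_, 1L, 2L)      # order of leaf addition
  m <- 2L
  while (m < n) {
    deg <- tabulate(parent[parent != 0L], nbins = length(parent))
    leaves <- which(deg == 0L)
    internals <- which(deg > 0L)
    w <- c(rep(1 - alpha, length(leaves)),        # pendant edges
           rep(gamma, length(internals)),         # edge above each internal
           (deg[internals] - 1L) * alpha - gamma) # attach at node
    who <- c(leaves, internals, internals)
    what <- rep(c("pendant", "edge", "node"),
                c(length(leaves), length(internals), length(internals)))
    pick <- sample.int(length(w), 1L, prob = w)
    v <- who[pick]
    new_leaf <- length(parent) + 1L
    if (what[pick] == "node") {
      parent <- c(parent, v)
    } else {
      # subdivide the edge above v (for the root this is the planted edge)
      mid <- length(parent) + 1L
      new_leaf <- length(parent) + 2L
      parent <- c(parent, parent[v], 0L)
      parent[new_leaf] <- mid
      parent[v] <- mid
    }
    leaf_rank <- c(leaf_rank, rep(NA_integer_, length(parent) - length(leaf_rank)))
    leaf_rank[new_leaf] <- m + 1L
    m <- m + 1L
  }
  relabel_growth_tree(parent, leaf_rank)
}

# renumber an arbitrary parent array (root has parent 0) into mftree form,
# labelling leaves by their addition rank
relabel_growth_tree <- function(parent, leaf_rank) {
  nn <- length(parent)
  kids <- vector("list", nn)
  root <- which(parent == 0L)
  for (v in seq_len(nn)) if (parent[v] != 0L)
    kids[[parent[v]]] <- c(kids[[parent[v]]], v)
  newid <- integer(nn)
  order_old <- integer(nn)
  queue <- root
  nxt <- 0L
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    nxt <- nxt + 1L
    newid[v] <- nxt
    order_old[nxt] <- v
    queue <- c(queue, kids[[v]])
  }
  p2 <- integer(nn)
  for (v in seq_len(nn)) if (parent[v] != 0L) p2[newid[v]] <- newid[parent[v]]
  labels <- rep(NA_character_, nn)
  lf <- !is.na(leaf_rank)
  labels[newid[which(lf)]] <- as.character(leaf_rank[lf])
  mftree(p2, labels)
}

#' Random phylogenetic tree under the uniform model
#'
#' Samples uniformly from all multifurcating phylogenetic trees on leaves
#' `1..n` (every internal node with at least two children), by
#' count-weighted recursive decomposition: the root's partition of the
#' label set into `k >= 2` blocks is drawn with probability proportional to
#' the product of the numbers of trees on each block, using the exact
#' labelled-tree and labelled-forest counts of [count_phylo_trees].  Counts
#' are held in doubles, so block probabilities are exact up to `n = 15` and
#' carry ~1e-16 relative error beyond; the count table overflows for
#' `n > ~170`.
#'
#' @param n number of leaves (`>= 1`).
#' @return A labelled [mftree].
#' @examples
#' set.seed(1)
#' rtree_uniform(5)
#' @export
rtree_uniform <- function(n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  tabs <- phylo_count_tables(max(n, 2L))
  if (!all(is.finite(tabs$t)))
    stop("tree counts overflow double precision at this n")
  build <- function(labels) {
    k <- length(labels)
    if (k == 1L) return(mftree(0L, labels = labels))
    blocks <- sample_forest_blocks(labels, tabs)
    join_trees(lapply(blocks, build))
  }
  build(as.character(seq_len(n)))
}

# partition `labels` (length >= 2) into >= 2 blocks with probability
# proportional to prod_i t(|block_i|): the root decomposition of a
# uniformly random tree
sample_forest_blocks <- function(labels, tabs) {
  t <- tabs$t; f <- c(1, tabs$f)           # f[m+1] = forests on m leaves
  blocks <- list()
  first_level <- TRUE
  while (length(labels) > 0L) {
    m <- length(labels)
    if (m == 1L) { blocks[[length(blocks) + 1L]] <- labels; break }
    smax <- if (first_level) m - 1L else m  # top level: forbid a single block
    s <- 1:smax
    w <- choose(m - 1, s - 1) * t[s] * f[m - s + 1]
    size <- sample.int(smax, 1L, prob = w)
    others <- if (size > 1L) sample(labels[-1L], size - 1L) else character(0)
    block <- c(labels[1L], others)
    blocks[[length(blocks) + 1L]] <- block
    labels <- setdiff(labels, block)
    first_level <- FALSE
  }
  blocks
}

#' Simulate the null distribution of a balance index
#'
#' Draws `N` random trees with `n` leaves under a null model
#' (`"alpha_gamma"` or `"uniform"`), computes a balance index on each, and
#' returns the sorted sample with its metadata.  Deterministic given
#' `seed`.
#'
#' @param index index name: `"colless_like"`, `"sackin"`, `"cophenetic"`,
#'   `"colless"`, or `"quadratic_colless"`.
#' @param model `"alpha_gamma"` or `"uniform"`.
#' @param n leaves per tree.
#' @param N number of replicates.
#' @param alpha,gamma alpha-gamma parameters (ignored for the uniform
#'   model).
#' @param D,f dissimilarity and weight function for `"colless_like"`.
#' @param norm compute the normalized index?
#' @param seed integer seed (optional).
#' @return An object of class `index_distribution`: list with the sorted
#'   `values` and the simulation metadata.
#' @examples
#' d <- simulate_index_distribution("sackin", "uniform", n = 5, N = 200,
#'                                  seed = 1)
#' percentile_of(7, d)
#' @export
simulate_index_distribution <- function(index = "colless_like",
                                        model = c("alpha_gamma", "uniform"),
                                        n, N,
                                        alpha = NULL, gamma = NULL,
                                        D = "mdm", f = "ln_n_plus_e",
                                        norm = FALSE, seed = NULL) {
  model <- match.arg(model)
  n <- as.integer(n); N <- as.integer(N)
  stopifnot(n >= 2L, N >= 1L)
  if (model == "alpha_gamma" && (is.null(alpha) || is.null(gamma)))
    stop("alpha and gamma are required for the alpha-gamma model")
  ifun <- index_function(index, D = D, f = f, norm = norm)
  if (!is.null(seed)) set.seed(seed)
  values <- vapply(seq_len(N), function(i) {
    tr <- if (model == "alpha_gamma") rtree_alpha_gamma(n, alpha, gamma)
          else rtree_uniform(n)
    ifun(tr)
  }, numeric(1))
  structure(list(values = sort(values), index = index, model = model,
                 n = n, N = N, alpha = alpha, gamma = gamma,
                 D = dissimilarity(D)$name, f = weight_function(f)$name,
                 norm = norm, seed = seed),
            class = "index_distribution")
}

index_function <- function(index, D = "mdm", f = "ln_n_plus_e", norm = FALSE) {
  switch(index,
         colless_like = function(t) colless_like(t, D, f, norm = norm),
         sackin = function(t) sackin(t, norm = norm),
         cophenetic = function(t) total_cophenetic(t, norm = norm),
         colless = colless,
         quadratic_colless = quadratic_colless,
         stop("unknown index: ", index))
}

#' @export
print.index_distribution <- function(x, ...) {
  pars <- if (x$model == "alpha_gamma")
    sprintf(" (alpha = %g, gamma = %g)", x$alpha, x$gamma) else ""
  cat(sprintf("<index_distribution> %s under %s%s: n = %d, N = %d\n",
              x$index, x$model, pars, x$n, x$N))
  print(summary(x$values))
  invisible(x)
}

#' Percentile of a value within a simulated distribution
#'
#' Midrank convention: `100 * (#{sample < value} + 0.5 * #{sample ==
#' value}) / N`, so a value tied with the whole sample sits at the 50th
#' percentile.
#'
#' @param value a numeric scalar.
#' @param dist an `index_distribution` or a numeric sample.
#' @return A percentile in `[0, 100]`.
#' @export
percentile_of <- function(value, dist) {
  v <- if (inherits(dist, "index_distribution")) dist$values else as.numeric(dist)
  if (length(v) == 0L) stop("empty distribution")
  100 * (sum(v < value) + 0.5 * sum(v == value)) / length(v)
}

#' Goodness-of-fit tests between an observed and a reference sample
#'
#' Two nonparametric comparisons of an observed index sample against a
#' simulated reference distribution: Pearson's chi-squared test over
#' equal-probability bins of the reference, and the two-sample
#' Kolmogorov-Smirnov test with a bootstrap null (resampling both samples
#' from the pooled data), which remains valid in the presence of ties.
#'
#' @param observed,reference numeric samples (non-empty; `observed` needs
#'   at least `bins` values).
#' @param bins number of equal-probability bins for the chi-squared test.
#' @param bootstrap_reps bootstrap replicates for the KS p-value.
#' @param seed optional seed for the bootstrap.
#' @return A list with `chisq_stat`, `chisq_p`, `ks_stat`, `ks_p`.
#' @export
gof_tests <- function(observed, reference, bins = 10L,
                      bootstrap_reps = 1000L, seed = NULL) {
  if (length(observed) < bins)
    stop("need at least as many observations as bins")
  if (length(reference) == 0L) stop("empty reference sample")
  if (!is.null(seed)) set.seed(seed)
  breaks <- unique(stats::quantile(reference, probs = seq(0, 1, length.out = bins + 1)))
  breaks[1L] <- -Inf; breaks[length(breaks)] <- Inf
  ref_counts <- table(cut(reference, breaks))
  obs_counts <- table(cut(observed, breaks))
  expected <- length(observed) * as.numeric(ref_counts) / length(reference)
  keep <- expected > 0
  chisq_stat <- sum((as.numeric(obs_counts)[keep] - expected[keep])^2 /
                      expected[keep])
  df <- sum(keep) - 1L
  chisq_p <- stats::pchisq(chisq_stat, df = df, lower.tail = FALSE)
  ks_stat <- ks_statistic(observed, reference)
  pooled <- c(observed, reference)
  na <- length(observed); nb <- length(reference)
  boot <- vapply(seq_len(bootstrap_reps), function(i) {
    ks_statistic(sample(pooled, na, replace = TRUE),
                 sample(pooled, nb, replace = TRUE))
  }, numeric(1))
  ks_p <- (1 + sum(boot >= ks_stat)) / (bootstrap_reps + 1)
  list(chisq_stat = chisq_stat, chisq_p = chisq_p,
       ks_stat = ks_stat, ks_p = ks_p)
}

ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  max(abs(stats::ecdf(a)(pts) - stats::ecdf(b)(pts)))
}

#' Persist or reload a simulated index distribution
#'
#' Writes the sample as a two-column CSV (`replicate`, `value`) with a JSON
#' sidecar (`<path>.json`) holding the metadata (index, model, parameters,
#' `n`, `N`, seed), mirroring a precomputed-distribution database.
#' `read_index_distribution` reverses it.
#'
#' @param dist an `index_distribution`.
#' @param path CSV path.
#' @return `write_index_distribution` returns `path` invisibly;
#'   `read_index_distribution` an `index_distribution`.
#' @export
write_index_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "index_distribution"))
  utils::write.csv(data.frame(replicate = seq_along(dist$values),
                              value = dist$values),
                   path, row.names = FALSE)
  meta <- dist[setdiff(names(dist), "values")]
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(path)
}

#' @rdname write_index_distribution
#' @export
read_index_distribution <- function(path) {
  values <- utils::read.csv(path)$value
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(c(list(values = sort(values)), meta), class = "index_distribution")
}
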