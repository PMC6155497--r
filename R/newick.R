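#' Read trees from Newick
#'
#' Parses one or more Newick strings into [mftree] objects.  Branch lengths,
#' internal node labels and bracketed comments are accepted on input and
#' discarded (with a single warning per call).  Leaves may be entirely
#' unlabeled, in which case the result is an unlabeled tree shape; a mix of
#' labelled and unlabeled leaves is rejected, as are duplicate labels and
#' out-degree-1 nodes.
#'
#' @param text a character vector of Newick strings (each possibly holding
#'   several `;`-terminated trees).
#' @param file path to a Newick file, one or more trees, as an alternative
#'   to `text`.
#' @return A single [mftree] if the input holds one tree, otherwise a list
#'   of them.
#' @examples
#' read_newick("((1,2),(3,4));")
#' @export
read_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) {
    if (is.null(file)) stop("supply 'text' or 'file'")
    text <- readLines(file, warn = FALSE)
  }
  text <- paste(text, collapse = "\n")
  if (grepl("\\[", text)) {
    text <- gsub("\\[[^]]*\\]", "", text)
    warning("Newick comments [...] discarded")
  }
  pieces <- trimws(strsplit(text, ";", fixed = TRUE)[[1L]])
  n_semis <- lengths(regmatches(text, gregexpr(";", text, fixed = TRUE)))
  pieces <- pieces[nzchar(pieces)]
  if (length(pieces) == 0L) {
    if (n_semis >= 1L) return(leaf_tree())  # ";" is the unlabeled single leaf
    stop("no tree found in input")
  }
  dropped <- FALSE
  trees <- lapply(pieces, function(s) {
    r <- parse_one_newick(s)
    if (attr(r, "dropped")) dropped <<- TRUE
    attr(r, "dropped") <- NULL
    r
  })
  if (dropped)
    warning("branch lengths and/or internal node labels discarded")
  if (length(trees) == 1L) trees[[1L]] else trees
}

parse_one_newick <- function(s) {
  s <- trimws(s)
  if (!grepl("(", s, fixed = TRUE)) {
    # single leaf, e.g. "a" (ape cannot parse these)
    lab <- sub(":.*$", "", s)
    t <- if (nzchar(lab)) mftree(0L, labels = lab) else leaf_tree()
    attr(t, "dropped") <- grepl(":", s, fixed = TRUE)
    return(t)
  }
  n_open <- nchar(gsub("[^(]", "", s))
  n_close <- nchar(gsub("[^)]", "", s))
  if (n_open != n_close) stop("malformed Newick string: ", s)
  phy <- tryCatch(ape::read.tree(text = paste0(s, ";")),
                  error = function(e) NULL)
  if (is.null(phy) || is.null(phy$edge))
    stop("malformed Newick string: ", s)
  dropped <- !is.null(phy$edge.length) ||
    (!is.null(phy$node.label) && any(nzchar(phy$node.label), na.rm = TRUE))
  deg <- tabulate(phy$edge[, 1L], nbins = length(phy$tip.label) + phy$Nnode)
  if (any(deg == 1L))
    stop("out-degree-1 node in Newick input: rooted trees here must have ",
         "every internal node with at least two children")
  lab <- phy$tip.label
  empty <- is.na(lab) | lab == ""
  if (any(empty) && !all(empty))
    stop("either all leaves must be labelled or none")
  t <- as_mftree.phylo(phy)
  attr(t, "dropped") <- dropped
  t
}

#' Write a tree in Newick format
#'
#' Serializes an [mftree].  Labelled trees round-trip through [read_newick]
#' with identical labels; unlabeled shapes serialize with empty leaf labels
#' and round-trip up to isomorphism.
#'
#' @param tree an [mftree] (or anything [as_mftree] accepts).
#' @param file optional path; when given the string is written there and
#'   returned invisibly.
#' @return The Newick string.
#' @export
write_newick <- function(tree, file = NULL) {
  tree <- as_mftree(tree)
  p <- tree$parent
  n <- length(p)
  deg <- out_degrees(tree)
  lab <- if (is.null(tree$labels)) rep("", n) else {
    l <- tree$labels
    l[is.na(l)] <- ""
    l
  }
  part <- character(n)
  kids <- children_list(tree)
  for (v in n:1) {
    part[v] <- if (deg[v] == 0L) lab[v]
               else paste0("(", paste(part[kids[[v]]], collapse = ","), ")")
  }
  out <- paste0(part[1L], ";")
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}
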