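# Tree data model, constructors, Newick I/O, isomorphism, enumeration.

test_that("constructors build the advertised shapes", {
  expect_equal(n_leaves(comb_tree(5)), 5)
  expect_equal(tree_depth(star_tree(7)), 1)
  expect_equal(n_leaves(fs_tree(c(2, 3))), 6)
  expect_equal(tree_depth(fs_tree(c(2, 3))), 2)
  expect_equal(n_leaves(fs_tree(c(2, 2, 2, 7))), 56)
  # comb: every internal node has a leaf child
  cb <- comb_tree(6)
  kap <- kappa_values(cb)
  deg <- out_degrees(cb)
  kids <- split(2:length(cb$parent), cb$parent[-1])
  has_leaf_child <- vapply(kids, function(k) any(deg[k] == 0L), logical(1))
  expect_true(all(has_leaf_child))
  # cherry three ways
  expect_equal(canonical_code(comb_tree(2)), canonical_code(star_tree(2)))
  expect_equal(canonical_code(fs_tree(2)), canonical_code(star_tree(2)))
  # FS_{2,3}: root of degree 2, each child a 3-star
  t23 <- fs_tree(c(2, 3))
  expect_equal(out_degrees(t23)[1], 2L)
  expect_true(all(vapply(root_subtrees(t23), function(s)
    isTRUE(all.equal(canonical_code(s), canonical_code(star_tree(3)))),
    logical(1))))
})

test_that("degenerate trees are rejected", {
  expect_error(mftree(c(0L, 1L)), "out-degree-1")
  expect_error(join_trees(star_tree(3)), "at least two")
  expect_error(read_newick("((a,b));"), "out-degree-1")
  expect_error(read_newick("((1,2"), "malformed")
  expect_error(read_newick("((a,b),(a,c));"), "duplicate")
  expect_error(read_newick("((a,b),(,));"), "all leaves")
})

test_that("kappa, depth and degree bookkeeping are consistent", {
  for (tr in list(comb_tree(7), fs_tree(c(3, 2, 2)), star_tree(9),
                  join_trees(comb_tree(3), star_tree(4), leaf_tree()))) {
    kap <- kappa_values(tr)
    deg <- out_degrees(tr)
    expect_equal(kap[1], n_leaves(tr))
    expect_true(all(kap[deg == 0L] == 1L))
    kids <- children_list_oracle(tr)
    for (v in which(deg > 0L)) expect_equal(kap[v], sum(kap[kids[[v]]]))
    d <- node_depths(tr)
    expect_equal(d[1], 0L)
    expect_true(all(d[-1] == d[tr$parent[-1]] + 1L))
  }
})

test_that("Newick parsing handles labels, lengths and shape-only input", {
  st <- read_newick("(1,2,3);")
  expect_equal(tree_depth(st), 1)
  expect_setequal(leaf_labels(st), c("1", "2", "3"))
  t4 <- read_newick("((1,2),(3,4));")
  expect_equal(canonical_code(t4), canonical_code(fs_tree(c(2, 2))))
  expect_warning(t3 <- read_newick("((1,2)x:1.0,3);"), "discarded")
  expect_equal(canonical_code(t3), canonical_code(comb_tree(3)))
  # all-unlabeled input yields a shape
  sh <- read_newick("((,),(,,));")
  expect_null(sh$labels)
  expect_equal(n_leaves(sh), 5)
  # single leaf
  lf <- read_newick("a;")
  expect_equal(n_leaves(lf), 1)
  expect_equal(leaf_labels(lf), "a")
  expect_equal(write_newick(lf), "a;")
})

test_that("Newick round-trips preserve isomorphism class and labels", {
  expect_equal(write_newick(read_newick("(1,2,3);")), "(1,2,3);")
  set.seed(11)
  for (i in 1:100) {
    tr <- rtree_alpha_gamma(sample(2:12, 1), alpha = 0.8, gamma = 0.3)
    tr2 <- read_newick(write_newick(tr))
    expect_equal(canonical_code(tr2), canonical_code(tr))
    expect_equal(labelled_code(tr2), labelled_code(tr))
  }
  # shape round-trip (empty labels)
  sh <- fs_tree(c(2, 3))
  expect_equal(canonical_code(read_newick(write_newick(sh))),
               canonical_code(sh))
  expect_equal(write_newick(leaf_tree()), ";")
  expect_equal(n_leaves(read_newick(";")), 1)
})

test_that("phylo interop preserves structure", {
  tr <- read_newick("((a,b),(c,(d,e)),f);")
  phy <- ape::as.phylo(tr)
  expect_s3_class(phy, "phylo")
  back <- as_mftree(phy)
  expect_equal(labelled_code(back), labelled_code(tr))
  rt <- as_mftree(ape::rtree(40))
  expect_equal(n_leaves(rt), 40)
})

test_that("canonical codes agree with brute-force isomorphism", {
  expect_false(canonical_code(fs_tree(c(2, 3))) ==
                 canonical_code(fs_tree(c(3, 2))))
  shapes <- enumerate_shapes(5)
  for (i in seq_along(shapes)) {
    for (j in seq_along(shapes)) {
      expect_equal(canonical_code(shapes[[i]]) == canonical_code(shapes[[j]]),
                   iso_bruteforce(shapes[[i]], shapes[[j]]),
                   info = paste(i, j))
    }
  }
})

test_that("shape enumeration is exhaustive and duplicate-free", {
  expect_length(enumerate_shapes(1), 1)
  expect_length(enumerate_shapes(4), 5)
  s5 <- enumerate_shapes(5)
  expect_length(s5, 12)
  expect_false(anyDuplicated(vapply(s5, canonical_code, character(1))) > 0)
  for (n in 1:8) {
    sh <- enumerate_shapes(n)
    expect_length(sh, count_shapes(n))
    expect_true(all(vapply(sh, n_leaves, numeric(1)) == n))
    codes <- vapply(sh, canonical_code, character(1))
    expect_false(anyDuplicated(codes) > 0)
  }
  expect_error(enumerate_shapes(13), "guard")
})

test_that("phylogenetic tree counts match exhaustive labelled enumeration", {
  expect_equal(count_phylo_trees(1), 1)
  expect_equal(count_phylo_trees(2), 1)
  for (n in 2:5)
    expect_equal(count_phylo_trees(n),
                 length(enumerate_labelled_trees(as.character(1:n))))
})

test_that("ordered factorizations count fully symmetric trees", {
  f6 <- ordered_factorizations(6)
  expect_length(f6, 3)
  expect_true(any(vapply(f6, identical, logical(1), c(2L, 3L))))
  expect_identical(ordered_factorizations(1), list(integer(0)))
  f8 <- ordered_factorizations(8)
  expect_length(f8, 4)
  expect_true(any(vapply(f8, identical, logical(1), c(2L, 2L, 2L))))
  # each factorization expands to a distinct shape
  for (n in c(6, 8, 12)) {
    codes <- vapply(ordered_factorizations(n),
                    function(s) canonical_code(fs_tree(s)), character(1))
    expect_false(anyDuplicated(codes) > 0)
  }
})

test_that("full-symmetry detection inverts the constructor", {
  expect_true(is_fully_symmetric(fs_tree(c(3, 2))))
  expect_equal(fs_signature(fs_tree(c(3, 2))), c(3L, 2L))
  expect_equal(fs_signature(leaf_tree()), integer(0))
  expect_false(is_fully_symmetric(comb_tree(4)))
  expect_null(fs_signature(comb_tree(4)))
  # both children subtend 4 leaves yet the tree is asymmetric
  tricky <- join_trees(star_tree(4), fs_tree(c(2, 2)))
  expect_false(is_fully_symmetric(tricky))
  kap <- kappa_values(tricky)
  expect_equal(sort(kap[tricky$parent == 1L]), c(4L, 4L))
})
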