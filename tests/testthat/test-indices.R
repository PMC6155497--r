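# Balance indices: Colless, quadratic Colless, Colless-like, Sackin,
# total cophenetic, normalization and ties.

test_that("Colless index values and comb maximality", {
  expect_equal(colless(fs_tree(c(2, 2))), 0)
  expect_equal(colless(comb_tree(4)), 3)       # choose(3, 2)
  expect_equal(colless(comb_tree(10)), 36)
  expect_error(colless(star_tree(3)), "colless_like")
  # the comb is the unique bifurcating maximum
  for (n in 4:8) {
    shapes <- bifurcating_shapes(n)
    vals <- vapply(shapes, colless, numeric(1))
    expect_equal(max(vals), choose(n - 1, 2))
    hit <- which(vals == max(vals))
    expect_length(hit, 1)
    expect_equal(canonical_code(shapes[[hit]]), canonical_code(comb_tree(n)))
  }
})

test_that("quadratic Colless values and the variance identity", {
  expect_equal(quadratic_colless(fs_tree(c(2, 2, 2))), 0)
  expect_equal(quadratic_colless(comb_tree(4)), 5)   # 4 + 1 + 0
  for (n in 3:8) for (tr in bifurcating_shapes(n)) {
    for (f in list(weight_function("ln_n_plus_e"), weight_function("exp_n"),
                   weight_function("tau"), weight_function("theta"))) {
      s <- f$fn(0) + f$fn(2)
      expect_equal(colless_like(tr, "var", f), s^2 / 2 * quadratic_colless(tr))
    }
  }
})

test_that("Colless-like restricts to the Colless index on bifurcating trees", {
  for (n in 3:8) for (tr in bifurcating_shapes(n)) {
    for (f in list(weight_function("ln_n_plus_e"), weight_function("exp_n"),
                   weight_function("tau"), weight_function("theta"))) {
      s <- f$fn(0) + f$fn(2)
      expect_equal(colless_like(tr, "mdm", f), s / 2 * colless(tr))
      expect_equal(colless_like(tr, "sd", f), s / sqrt(2) * colless(tr))
    }
  }
})

test_that("Colless-like vanishes on every fully symmetric tree", {
  sigs <- c(list(integer(0)), unlist(lapply(2:24, ordered_factorizations),
                                     recursive = FALSE))
  for (s in sigs) for (D in c("mdm", "var", "sd"))
    expect_equal(colless_like(fs_tree(s), D, "ln_n_plus_e"), 0)
  expect_equal(colless_like(comb_tree(4), "mdm", "exp_n"),
               1.5 * (exp(2) + 1))
})

test_that("Colless-like satisfies the join recursion", {
  set.seed(9)
  Ds <- c("mdm", "var", "sd")
  fs <- c("ln_n_plus_e", "exp_n", "tau", "kappa")
  for (i in 1:15) {
    k <- sample(2:4, 1)
    parts <- lapply(seq_len(k), function(j) {
      n <- sample(1:6, 1)
      sh <- enumerate_shapes(n)
      sh[[sample(length(sh), 1)]]
    })
    joined <- join_trees(parts)
    for (D in Ds) for (f in fs) {
      Dfn <- dissimilarity(D)$fn
      expect_equal(colless_like(joined, D, f),
                   sum(vapply(parts, colless_like, numeric(1), D = D, f = f)) +
                     Dfn(vapply(parts, f_size, numeric(1), f = f)))
    }
  }
})

test_that("Sackin index: spot values and comb/star endpoints", {
  expect_equal(sackin(fs_tree(c(2, 3))), 12)
  expect_equal(sackin(fs_tree(c(3, 2))), 12)
  expect_equal(sackin(star_tree(6)), 6)
  expect_equal(sackin(comb_tree(4)), 9)
  for (n in 2:10) {
    expect_equal(sackin(comb_tree(n)), (n + 2) * (n - 1) / 2)
    expect_equal(sackin(star_tree(n)), n)
  }
})

test_that("total cophenetic index: fast formula, endpoints and LCA oracle", {
  expect_equal(total_cophenetic(fs_tree(c(2, 3))), 6)
  expect_equal(total_cophenetic(fs_tree(c(3, 2))), 3)
  expect_equal(total_cophenetic(comb_tree(5)), 10)
  for (n in 2:10) {
    expect_equal(total_cophenetic(star_tree(n)), 0)
    expect_equal(total_cophenetic(comb_tree(n)), choose(n, 3))
  }
  for (n in 1:7) for (tr in enumerate_shapes(n))
    expect_equal(total_cophenetic(tr), phi_bruteforce(tr))
})

test_that("normalized indices hit their range endpoints", {
  for (n in c(3, 5, 8)) {
    expect_equal(sackin(star_tree(n), norm = TRUE), 0)
    expect_equal(sackin(comb_tree(n), norm = TRUE), 1)
    expect_equal(total_cophenetic(star_tree(n), norm = TRUE), 0)
    expect_equal(total_cophenetic(comb_tree(n), norm = TRUE), 1)
    expect_equal(colless_like(comb_tree(n), "mdm", "ln_n_plus_e", norm = TRUE), 1)
  }
  expect_equal(colless_like(comb_tree(6), "var", "ln_n_plus_e", norm = TRUE), 1)
  # the normalization denominator is the exhaustive maximum
  bf <- brute_force_extrema(6, "var", "ln_n_plus_e")
  expect_equal(bf$maximum, max_colless_like(6, "var", "ln_n_plus_e"))
  # degenerate sizes normalize to 0
  expect_equal(sackin(comb_tree(2), norm = TRUE), 0)
  expect_equal(colless_like(comb_tree(2), "mdm", "ln_n_plus_e", norm = TRUE), 0)
  # normalized values stay in [0, 1] across all shapes
  for (tr in enumerate_shapes(6)) {
    v <- colless_like(tr, "mdm", "ln_n_plus_e", norm = TRUE)
    expect_gte(v, 0); expect_lte(v, 1)
  }
  expect_error(colless_like(comb_tree(5), "mdm", "pow:3", norm = TRUE),
               "hypothesis")
  expect_error(max_colless_like(5, function(x) diff(range(x)), "ln_n_plus_e"),
               "no known maximum")
})

test_that("tie counting rounds to significant digits", {
  expect_equal(count_ties(c(1, 1, 2)), 1)
  expect_equal(count_ties(c(1, 2, 3, 4)), 0)
  expect_equal(count_ties(rep(7, 4)), 6)
  expect_equal(count_ties(c(1, 1 + 1e-13, 2), digits = 12), 1)
  expect_equal(count_ties(c(1, 1 + 1e-13, 2), digits = 16), 0)
  # over all 5-leaf shapes, zeros of a sound index are exactly the fully
  # symmetric shapes
  shapes <- enumerate_shapes(6)
  vals <- vapply(shapes, colless_like, numeric(1))
  zero <- vals == 0
  expect_equal(sum(zero), 3)               # FS_6, FS_{2,3}, FS_{3,2}
  expect_true(all(vapply(shapes[zero], is_fully_symmetric, logical(1))))
  expect_gte(count_ties(vals), choose(3, 2))
})

test_that("balance_indices aggregates raw and normalized values", {
  df <- balance_indices(comb_tree(5))
  expect_equal(df$colless, 6)
  expect_equal(df$sackin, 14)
  dfn <- balance_indices(star_tree(5), norm = TRUE)
  expect_equal(dfn$colless_like, 0)
  expect_true(is.na(dfn$colless))
})

test_that("Colless-like runs in linear time on large trees", {
  set.seed(1)
  big <- as_mftree(ape::rtree(10000))
  elapsed <- system.time(v <- colless_like(big, "mdm", "ln_n_plus_e"))["elapsed"]
  expect_gt(v, 0)
  expect_lt(elapsed, 5)
})
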