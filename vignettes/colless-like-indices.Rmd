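---
title: "Colless-like balance indices for multifurcating trees"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Colless-like balance indices for multifurcating trees}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multibalance)
```

## The model

The *balance* of a rooted phylogenetic tree measures how evenly the
children of each node split the descendant leaves, and is the most widely
used summary of tree shape when testing macroevolutionary hypotheses.  The
classical Colless index,
$$C(T) = \sum_{v \in V_{int}(T)} |\kappa_{v_1} - \kappa_{v_2}|,$$
with $\kappa_{v_i}$ the leaf counts under the two children of $v$, is
defined only for bifurcating trees.  Real phylogenies — consensus trees
especially — are full of multifurcations, and the naive generalization
(apply a spread measure to the children's leaf counts, or node counts, and
sum over internal nodes) is defective: there are trees in which every node
has children with identical leaf counts *and* identical node counts that
are nevertheless not symmetric.  `join_trees(star_tree(4), fs_tree(c(2, 2)))`
is a minimal witness for leaf counts: both root subtrees hold 4 leaves, all
deeper nodes are symmetric, yet the two subtrees have different shapes.

The repair implemented here replaces the leaf count by the **f-size**
$$\delta_f(T) = \sum_{v \in V(T)} f(\deg(v)),$$
a weighted count of all nodes by out-degree, for a weight function
$f:\mathbb{N}\to\mathbb{R}_{\ge 0}$.  Fixing also a **dissimilarity** $D$
(permutation-invariant, nonnegative, zero exactly on constant vectors),
the **Colless-like index** is
$$C_{D,f}(T) = \sum_{v \in V_{int}(T)} D\bigl(\delta_f(T_{v_1}), \dots,
\delta_f(T_{v_k})\bigr).$$
It vanishes on every *fully symmetric* tree (all children of every node
carry isomorphic subtrees).  The index is called **sound** when the
converse holds as well, and soundness turns out to depend only on $f$: it
holds exactly when no two distinct fully symmetric trees share an f-size.
Fully symmetric trees with $n$ leaves correspond to ordered factorizations
$n = n_1 \cdots n_k$ (all $n_i \ge 2$), and their f-sizes have the closed
form implemented in `fs_f_size()`, which makes the collision scan in
`find_fsize_collisions()` cheap.

Natural choices of $f$ fail.  Leaf count ($\kappa$), node count ($\tau$),
arc count ($\theta$), every polynomial, every integer power $n^d$, and
integer-base exponentials and logarithms all collide — e.g.
$\delta_{n^3}$ takes the value 3288 on both $FS_{2,10,4}$ and $FS_{6,8}$,
and $\delta_{2^n}$ takes 26 on $FS_{2,3}$ and $FS_{3,2}$
(`fsize_collision_examples()` recomputes the full gallery).  Two choices
provably work for every dissimilarity, and are the ones this package
promotes:

* $f(n) = \ln(n + e)$ (`"ln_n_plus_e"`, the default), and
* $f(n) = e^n$ (`"exp_n"`).

Both proofs rest on the transcendence of $e$: an equality of f-sizes
forces an equality of integer polynomials, which forces the trees to be
equal.  That argument dictates how the package *tests* equality of
f-sizes: floating-point comparison would be unsound in both directions.

## Exact comparison of f-sizes

`find_fsize_collisions()` groups fully symmetric trees by an exact key
rather than by a floating value:

* integer-valued $f$ (counts, integer powers/bases, integer quadratics):
  exact integer comparison, falling back to rounded comparison only above
  $2^{53}$, where doubles stop being exact;
* $f(n) = e^n$: the **degree profile** (multiset of node out-degrees) —
  by the polynomial argument, equal f-sizes are equivalent to equal
  profiles;
* $f(n) = \ln(n + e)$: the integer exponent multiset of
  $e^{\delta_f} = e^{n_1\cdots n_k}\prod_i (n_i + e)^{n_1\cdots n_{i-1}}$,
  with equal bases merged;
* anything else: doubles rounded to 12 significant digits, with the group
  flagged `exact = FALSE`.

The original design called for 50-digit arbitrary-precision arithmetic in
the fallback branch; no arbitrary-precision backend is declared here, and
none of the soundness results needs one — every case they rely on has an
exact integer key.  The 12-digit rounding is deliberately permissive: for
a *collision scan* a false merge only adds a candidate group that the
`exact` flag marks as numeric, whereas a false split would hide a genuine
collision, so the rounding errs toward merging.

Large `exp_n` sizes are a real numerical hazard: $e^{n}$ overflows the
double range near $n = 709$, and ties within $10^{-16}$ relative error are
indistinguishable in floats.  This is one motivation for preferring
$\ln(n+e)$ in practice, the other being interpretability of its extremal
trees (below).

## Maximally unbalanced trees and normalization

Minimum values are 0 at the fully symmetric trees (for sound $f$), so the
range of $C_{D,f}$ over $n$-leaf shapes is set by its maximum.  Two
regimes exist, and they differ instructively:

* For any $f$ with $0 < f(k) < f(k-1) + f(2)$ for all $k \ge 3$ — a
  slow-growth condition that $\ln(n+e)$ satisfies and that
  `comb_hypothesis_holds()` verifies numerically up to a configurable
  degree (default 1000) — the unique maximum is at the **comb** $K_n$:
  $$C_{MDM,f}(K_n) = \tfrac{f(0)+f(2)}{4}(n-1)(n-2), \quad
  C_{sd,f}(K_n) = \tfrac{f(0)+f(2)}{2\sqrt 2}(n-1)(n-2),$$
  $$C_{var,f}(K_n) = \tfrac{(f(0)+f(2))^2}{12}(n-1)(n-2)(2n-3).$$
* For $f(n) = e^n$ the unique maximum sits at the join of a single leaf
  with the $(n-1)$-star, $FS_1 \star FS_{n-1}$, with values
  $\tfrac12(e^{n-1}+n-2)$ (MDM), $\tfrac{1}{\sqrt 2}(e^{n-1}+n-2)$ (sd)
  and $\tfrac12(e^{n-1}+n-2)^2$ (var) — except at $n = 4$ under MDM and
  sd, where the comb wins with $\tfrac32(e^2+1)$ resp.
  $\tfrac{3}{\sqrt2}(e^2+1)$.

So the growth pace of $f$ changes what "maximally unbalanced" means: a
slowly growing $f$ blames depth (the comb), a fast one blames a single
huge polytomy.  `max_colless_like()` and `argmax_trees()` implement the
closed forms; `brute_force_extrema()` re-derives both from exhaustive
enumeration, and the test suite checks their agreement for $n \le 7$
(90 shapes at $n = 7$), including the $n = 4$ exception.  Two boundary
decisions are the package's own: at $n = 2$ the only shape is the cherry,
which is fully symmetric, so the maximum is defined as 0 even though the
$e^n$ closed form would evaluate to a positive number there; and
normalized indices at $n \le 2$ return 0, since all shapes coincide and
the normalizing denominator vanishes.

Normalization divides by these maxima (after subtracting the minimum,
which is $n$ for Sackin, 0 for the cophenetic and Colless-like indices),
giving values in $[0,1]$ comparable across leaf counts.  Normalized
Colless-like values are only defined for $D \in \{$MDM, var, sd$\}$
with $f$ either `exp_n` or a function passing the comb hypothesis; any
other pair raises an error rather than silently running an exponential
exhaustive search.

The sd formulas are $\sqrt2$ times the MDM ones, which follows from the
two-point identities $MDM(x,y) = |x-y|/2$ and $sd(x,y) = |x-y|/\sqrt2$;
on bifurcating trees these identities give exact proportionality to the
classical (quadratic) Colless index:
$C_{MDM,f} = \tfrac{f(0)+f(2)}{2} C$,
$C_{sd,f} = \tfrac{f(0)+f(2)}{\sqrt2} C$,
$C_{var,f} = \tfrac{(f(0)+f(2))^2}{2} C^{(2)}$.
These identities double as strong implementation cross-checks and are
asserted over every bifurcating shape with up to 8 leaves.

Two conventions matter for reproducing any of these constants: the median
of an even-length vector is the midpoint of the central order statistics,
and the variance is the *sample* variance (denominator $k-1$).  Changing
either rescales every extremal value.

## Classical indices

`sackin()` (sum of leaf depths) and `total_cophenetic()` (sum over leaf
pairs of the depth of the lowest common ancestor) are provided for
comparison.  The cophenetic index is computed in linear time as
$\sum_v \binom{\kappa_v}{2}$ over non-root internal nodes; the
quadratic-time pairwise-LCA definition survives only as a test oracle.
Both indices tie distinct fully symmetric trees apart (e.g.
$S(FS_6) = 6$ but $S(FS_{2,3}) = 12$), which is precisely the behaviour a
sound Colless-like index avoids.

## Null models

`rtree_alpha_gamma()` grows a tree leaf by leaf under the alpha-gamma
Markov branching model.  The growth weights at a step with $m$ leaves are:
$1-\alpha$ per pendant edge, $\gamma$ per internal edge *including the
planted edge above the root*, and $(k-1)\alpha - \gamma$ per internal node
of out-degree $k$; they total $m - \alpha$.  The model's source
formulation leaves room for interpretation on whether the planted root
edge carries weight $\gamma$; this package includes it, because that rule
reproduces the two structural facts used as checks: with
$\alpha = \gamma$ every binary-node weight vanishes and the process is
Ford's bifurcating alpha model, and the one-step probability that the
3-leaf tree is a star is $(\alpha-\gamma)/(2-\alpha)$, which the tests
verify by simulation.  Exact distributional agreement with other
implementations of the model is not guaranteed beyond these facts.

`rtree_uniform()` samples exactly uniformly over all labelled
multifurcating trees by count-weighted recursive decomposition of the
label set, using the labelled-tree/forest recurrences behind
`count_phylo_trees()`.  The counts are kept in doubles: they are exact
integers up to $n = 15$ and carry $\sim 10^{-16}$ relative error beyond,
which perturbs sampling probabilities imperceptibly; the table overflows
around $n = 170$, where the sampler stops with an error rather than
degrade.  Uniformity is verified by chi-squared tests against the
exhaustively enumerated 4 labelled trees on 3 leaves and 26 on 4 leaves
(20,000 draws each, rejection level $10^{-3}$).

`simulate_index_distribution()` ties models to indices and is
seed-reproducible; `percentile_of()` uses the midrank convention for
ties (the convention is this package's choice; nothing in the theory
prescribes one).  `gof_tests()` compares an observed sample to a
simulated reference with Pearson's chi-squared over equal-probability
bins of the reference and a two-sample Kolmogorov–Smirnov statistic whose
p-value is bootstrapped from the pooled sample — the bootstrap sidesteps
the classical KS test's failure under ties, which are pervasive in
integer-valued indices.

## What the synthetic generators do and do not show

All tests run on programmatically constructed inputs: combs, stars, fully
symmetric trees, exhaustive enumerations ($|T^*_n| \le 261$ for
$n \le 8$), and simulated alpha-gamma/uniform forests.  These cover the
combinatorial claims completely — the identities are exact and the
enumerations exhaustive — but they are not real phylogenies: empirical
trees have label sets, metadata, branch lengths (discarded here), and
shape distributions that fit neither null model well.  Passing tests
therefore certify the mathematics and the implementation, not any claim
about what balance values real data will take.  Problem sizes were chosen
so the whole suite exercises every exhaustive claim the theory makes at
the sizes where exhaustion is feasible: extremal verification at
$n \le 7$, proportionality and comb-uniqueness at $n \le 8$, soundness
equivalence at $n \le 7$, collision scans to 60 leaves.

## Degenerate inputs and numerical choices

* The single-leaf tree is admitted everywhere; every index on it is 0,
  its fully-symmetric signature is the empty factorization, and it
  serializes as `";"`.
* Out-degree-1 nodes are rejected at every entry point (construction,
  Newick parsing, `phylo` conversion), since the tree class is defined
  without them.
* Branch lengths, internal labels and comments in Newick input are
  discarded with one warning per call: all indices here are purely
  topological.
* Tie counting (`count_ties()`) compares values after rounding to 16
  significant digits by default — effectively double precision — so that
  exact-integer indices compare exactly while floating indices are not
  split by representation noise.
* Canonical codes sort child codes lexicographically with radix (C
  locale) ordering, making the isomorphism test deterministic across
  platforms; equal codes merge, so ties cannot arise.
* `enumerate_shapes()` guards at $n = 12$ (tens of thousands of shapes)
  and requires an explicit override beyond.

## Known limitations

* Branch-length-aware statistics, unrooted trees and tree rearrangement
  are out of scope.
* Closed-form maxima (hence normalization) exist only for the documented
  $(D, f)$ pairs; user dissimilarities get raw values only.
* `exp_n` overflows for trees with internal degrees or depths in the
  several hundreds; prefer `ln_n_plus_e` for large trees.
* The collision scan's fallback branch is floating-point (12 significant
  digits) for weight functions with no exact key, e.g. non-integer,
  non-transcendental bases.
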