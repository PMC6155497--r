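# Soundness of Colless-like indices: a Colless-like index C_{D,f} vanishes
# exactly on the fully symmetric trees if and only if no two distinct fully
# symmetric trees share an f-size.  This file groups fully symmetric trees
# by f-size with exact comparison wherever the structure of f permits.

#' Detect f-size collisions among fully symmetric trees
#'
#' Enumerates every fully symmetric tree shape with at most `max_leaves`
#' leaves (one per ordered factorization of each leaf count) and groups
#' those with equal f-size.  A non-empty report exhibits pairs witnessing
#' that `C_{D,f}` is not sound for any dissimilarity `D`; an empty report
#' means no collision exists among these trees.
#'
#' Equality of f-sizes is decided exactly whenever possible:
#' * integer-exact `f` (counts, integer powers and bases, integer
#'   quadratics): exact integer comparison (falling back to rounded
#'   floating comparison above 2^53);
#' * `f(n) = e^n`: equality of degree profiles, which by transcendence of
#'   `e` is equivalent to equality of the f-sizes;
#' * `f(n) = ln(n + e)` (and `log_r(n + r)` with transcendental `r`):
#'   equality of the integer exponent multisets of the factorization
#'   `e^delta = e^{n1...nk} * prod_i (n_i + e)^{n1...n_{i-1}}`;
#' * anything else: floating values rounded to 12 significant digits, and
#'   the group is flagged `exact = FALSE`.
#'
#' @param f a [weight_function] or preset name.
#' @param max_leaves largest leaf count scanned (`>= 2`).
#' @return An object of class `collision_report`: a list with fields `f`,
#'   `max_leaves` and `groups`, each group holding `signatures` (list of
#'   integer vectors), the common `value`, and an `exact` flag.
#' @examples
#' find_fsize_collisions("exp_base:2", 6)   # FS_{2,3} and FS_{3,2} at 26
#' find_fsize_collisions("ln_n_plus_e", 30) # empty: this f is sound
#' @export
find_fsize_collisions <- function(f, max_leaves) {
  f <- weight_function(f)
  max_leaves <- as.integer(max_leaves)
  stopifnot(max_leaves >= 2L)
  sigs <- list(integer(0))
  for (n in 2:max_leaves) sigs <- c(sigs, ordered_factorizations(n))
  keyed <- vapply(sigs, function(s) fs_size_key(s, f), character(1))
  exact <- !grepl("^num:", keyed)
  groups <- split(seq_along(sigs), keyed)
  groups <- Filter(function(ix) length(ix) > 1L, groups)
  groups <- lapply(groups, function(ix) {
    list(signatures = sigs[ix],
         value = fs_f_size(sigs[[ix[1L]]], f),
         exact = exact[ix[1L]])
  })
  names(groups) <- NULL
  structure(list(f = f$name, max_leaves = max_leaves, groups = groups),
            class = "collision_report")
}

# exact-comparison key for the f-size of the fully symmetric tree `ns`
fs_size_key <- function(ns, f) {
  if (f$name %in% c("exp_n")) {
    prof <- if (length(ns)) degree_profile(fs_tree(ns)) else c(`0` = 1L)
    return(paste0("prof:", paste(names(prof), prof, sep = ":", collapse = ";")))
  }
  if (f$name %in% c("ln_n_plus_e")) {
    if (length(ns) == 0L) return("lexp:1|")
    coef <- c(1, cumprod(ns[-length(ns)]))
    agg <- tapply(coef, ns, sum)            # merge equal bases n_i
    agg <- agg[order(as.integer(names(agg)))]
    return(paste0("lexp:", prod(ns), "|",
                  paste(names(agg), agg, sep = "^", collapse = "*")))
  }
  v <- fs_f_size(ns, f)
  if (f$exactness == "integer" && abs(v) < 2^53)
    return(paste0("int:", sprintf("%.0f", v)))
  paste0("num:", signif(v, 12))
}

#' @export
print.collision_report <- function(x, ...) {
  cat(sprintf("<collision_report> f = %s, fully symmetric trees up to %d leaves\n",
              x$f, x$max_leaves))
  if (length(x$groups) == 0L) {
    cat("  no f-size collisions: C_{D,f} is sound on trees assembled from these\n")
  } else {
    for (g in x$groups) {
      sig_str <- vapply(g$signatures, function(s)
        if (length(s)) paste0("FS_{", paste(s, collapse = ","), "}")
        else "FS_1", character(1))
      cat(sprintf("  %s  ->  delta_f = %s%s\n",
                  paste(sig_str, collapse = " = "),
                  format(g$value, digits = 12),
                  if (g$exact) "" else " (numeric comparison)"))
    }
  }
  invisible(x)
}

#' @export
as.data.frame.collision_report <- function(x, ...) {
  if (length(x$groups) == 0L)
    return(data.frame(group = integer(0), signature = character(0),
                      value = numeric(0), exact = logical(0)))
  do.call(rbind, lapply(seq_along(x$groups), function(i) {
    g <- x$groups[[i]]
    data.frame(group = i,
               signature = vapply(g$signatures, paste, character(1),
                                  collapse = ","),
               value = g$value, exact = g$exact)
  }))
}

#' Recompute the classic f-size collision identities
#'
#' Recomputes, from tree structure alone, the textbook collision pairs that
#' witness non-soundness of natural weight functions, and checks each
#' against its closed-form value: the quadratic-weight coefficient identity
#' `delta_f(FS_{2,2,2,7}) = delta_f(FS_{14,4}) = 420 a + 70 b + 71 c`, the
#' cubic and quartic power collisions (3288 and 4744), the base-2
#' exponential collision (26), the `log_a(n)` and `log_a(n + 1)` collisions
#' expressed through the exact exponentiated products (`a^delta` = 8 and
#' 196608), and the `log_2(n + 2)` collision (`81 + log2(11)`).
#'
#' @return A data frame with one row per identity: the weight function, the
#'   two signatures, the two recomputed values, the expected common value
#'   and whether all three agree.
#' @export
fsize_collision_examples <- function() {
  rows <- list(
    list(f = "quadratic (n^2 coefficient)", s1 = c(2, 2, 2, 7), s2 = c(14, 4),
         v = function(s) fs_f_size(s, weight_function("pow", d = 2)),
         expected = 420),
    list(f = "quadratic (n coefficient)", s1 = c(2, 2, 2, 7), s2 = c(14, 4),
         v = function(s) fs_f_size(s, "theta"), expected = 70),
    list(f = "quadratic (constant coefficient)", s1 = c(2, 2, 2, 7), s2 = c(14, 4),
         v = function(s) fs_f_size(s, "tau"), expected = 71),
    list(f = "pow:3", s1 = c(2, 10, 4), s2 = c(6, 8),
         v = function(s) fs_f_size(s, "pow:3"), expected = 3288),
    list(f = "pow:4", s1 = c(2, 6, 2, 3), s2 = c(8, 3),
         v = function(s) fs_f_size(s, "pow:4"), expected = 4744),
    list(f = "exp_base:2", s1 = c(2, 3), s2 = c(3, 2),
         v = function(s) fs_f_size(s, "exp_base:2"), expected = 26),
    list(f = "log_a(n), a^delta", s1 = c(2, 2), s2 = 8L,
         v = function(s) log_product_value(s, shift = 0), expected = 8),
    list(f = "log_a(n+1), a^delta", s1 = c(2, 3, 3), s2 = c(5, 7),
         v = function(s) log_product_value(s, shift = 1), expected = 196608),
    list(f = "log_base:2 (f(n)=log2(n+2))", s1 = c(9, 6), s2 = c(20, 2),
         v = function(s) fs_f_size(s, "log_base:2"),
         expected = 81 + log2(11))
  )
  do.call(rbind, lapply(rows, function(r) {
    v1 <- r$v(r$s1); v2 <- r$v(r$s2)
    data.frame(f = r$f,
               signature1 = paste(r$s1, collapse = ","),
               signature2 = paste(r$s2, collapse = ","),
               value1 = v1, value2 = v2, expected = r$expected,
               pass = isTRUE(all.equal(v1, r$expected, tolerance = 1e-12)) &&
                      isTRUE(all.equal(v2, r$expected, tolerance = 1e-12)))
  }))
}

#' Exact exponentiated f-size for logarithmic weights
#'
#' For `f(n) = log_a(n + shift)` with `f(0) = 0` (any base `a > 1`), the
#' f-size of a fully symmetric tree satisfies
#' `a^delta_f = prod over nodes of (deg(v) + shift)` (empty factors for
#' leaves when `shift = 0` contribute via `f(0) = 0`, i.e. a factor 1).
#' This integer product is base-independent and compares f-sizes exactly.
#'
#' @param ns fully symmetric signature (integer vector, factors `>= 2`).
#' @param shift the additive shift inside the logarithm (0 or 1).
#' @return The integer product `a^delta_f`.
#' @export
log_product_value <- function(ns, shift = 1) {
  ns <- as.integer(ns)
  if (length(ns) == 0L) return(1)
  deg <- out_degrees(fs_tree(ns))
  prod((deg + shift)[deg > 0L])
}
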