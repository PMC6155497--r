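#' Maximum of a Colless-like index and its maximally unbalanced trees
#'
#' Closed-form maximum of `C_{D,f}` over all shapes with `n` leaves, and
#' the shape(s) attaining it, for `D` one of `"mdm"`, `"var"`, `"sd"` and
#' two families of weight functions:
#'
#' * Slowly growing `f` with `0 < f(k) < f(k-1) + f(2)` for all `k >= 3`
#'   (the default `ln(n + e)` qualifies; the hypothesis is verified
#'   numerically by [comb_hypothesis_holds]).  The maximum is attained
#'   exactly at the comb, with values
#'   `(f(0)+f(2))/4 * (n-1)(n-2)` (MDM),
#'   `(f(0)+f(2))/(2 sqrt 2) * (n-1)(n-2)` (sd), and
#'   `(f(0)+f(2))^2/12 * (n-1)(n-2)(2n-3)` (var).
#' * `f(n) = e^n`.  The maximum is attained exactly at the join of a leaf
#'   with the `(n-1)`-star, with values `(e^{n-1}+n-2)/2` (MDM),
#'   `(e^{n-1}+n-2)/sqrt(2)` (sd) and `(e^{n-1}+n-2)^2/2` (var) — except at
#'   `n = 4` for MDM and sd, where the comb wins with value
#'   `3/2 (e^2+1)` resp. `3/sqrt(2) (e^2+1)`.
#'
#' For `n <= 2` there is a single shape and the maximum is 0.  The
#' closed forms hold from `n = 3` up; [brute_force_extrema] verifies them
#' exhaustively at small `n`.
#'
#' @param n number of leaves (`n >= 2`).
#' @param D dissimilarity name or object: one of `"mdm"`, `"var"`, `"sd"`.
#' @param f a [weight_function] or preset name: `"exp_n"`, or any function
#'   passing the comb hypothesis (e.g. `"ln_n_plus_e"`).
#' @return `max_colless_like`: a numeric scalar.  `argmax_trees`: a list of
#'   [mftree] shapes attaining it.
#' @examples
#' max_colless_like(4, "mdm", "exp_n")  # 1.5 * (exp(2) + 1) at the comb
#' @export
max_colless_like <- function(n, D = "mdm", f = "ln_n_plus_e") {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  D <- dissimilarity(D)
  f <- weight_function(f)
  if (!D$name %in% c("mdm", "var", "sd"))
    stop("no known maximum for dissimilarity '", D$name, "'")
  if (n == 2L) return(0)
  if (f$name == "exp_n") {
    if (n == 4L && D$name %in% c("mdm", "sd")) {
      base <- 3 * (exp(2) + 1)
      return(switch(D$name, mdm = base / 2, sd = base / sqrt(2)))
    }
    s <- exp(n - 1) + n - 2
    return(switch(D$name, mdm = s / 2, sd = s / sqrt(2), var = s^2 / 2))
  }
  if (!comb_hypothesis_holds(f))
    stop("weight function '", f$name, "' does not satisfy the comb-maximum ",
         "hypothesis 0 < f(k) < f(k-1) + f(2); no closed-form maximum known")
  s <- f$fn(0L) + f$fn(2L)
  switch(D$name,
         mdm = s / 4 * (n - 1) * (n - 2),
         sd = s / (2 * sqrt(2)) * (n - 1) * (n - 2),
         var = s^2 / 12 * (n - 1) * (n - 2) * (2 * n - 3))
}

#' @rdname max_colless_like
#' @export
argmax_trees <- function(n, D = "mdm", f = "ln_n_plus_e") {
  n <- as.integer(n)
  stopifnot(n >= 2L)
  D <- dissimilarity(D)
  f <- weight_function(f)
  max_colless_like(n, D, f)  # validates the (D, f) pair
  if (n == 2L) return(list(comb_tree(2)))
  if (f$name == "exp_n") {
    if (n == 4L && D$name %in% c("mdm", "sd")) return(list(comb_tree(4)))
    return(list(join_trees(leaf_tree(), star_tree(n - 1L))))
  }
  list(comb_tree(n))
}

#' Check the comb-maximum hypothesis on a weight function
#'
#' Verifies numerically that `0 < f(k) < f(k - 1) + f(2)` for
#' `k = 3, ..., k_max`.  Under this hypothesis the comb is the unique
#' maximally unbalanced tree for `C_{MDM,f}`, `C_{sd,f}` and `C_{var,f}`.
#'
#' @param f a [weight_function] or preset name.
#' @param k_max largest degree checked (default 1000).
#' @return `TRUE` or `FALSE`.
#' @export
comb_hypothesis_holds <- function(f, k_max = 1000L) {
  f <- weight_function(f)
  k <- 3:k_max
  v <- f$fn(k)
  all(v > 0) && all(v < f$fn(k - 1L) + f$fn(2L))
}

#' Exhaustive extremal search over all shapes
#'
#' Evaluates `C_{D,f}` on every shape with `n` leaves (via
#' [enumerate_shapes]) and returns the exact maximum together with the full
#' set of shapes attaining it.  Serves as the independent check of the
#' closed forms in [max_colless_like].
#'
#' @param n number of leaves (kept small: subject to the enumeration
#'   guard).
#' @param D a [dissimilarity] or name.
#' @param f a [weight_function] or preset name.
#' @param guard passed to [enumerate_shapes].
#' @param tol relative tolerance when grouping values at the maximum.
#' @return A list with fields `n`, `D`, `f`, `maximum`, `argmax` (list of
#'   [mftree]), `n_shapes` and `method = "exhaustive"`.
#' @examples
#' brute_force_extrema(5, "mdm", "ln_n_plus_e")$maximum
#' @export
brute_force_extrema <- function(n, D = "mdm", f = "ln_n_plus_e",
                                guard = 12L, tol = 1e-12) {
  D <- dissimilarity(D)
  f <- weight_function(f)
  shapes <- enumerate_shapes(n, guard = guard)
  vals <- vapply(shapes, colless_like, numeric(1), D = D, f = f)
  mx <- max(vals)
  hit <- which(vals >= mx - tol * (1 + abs(mx)))
  list(n = as.integer(n), D = D$name, f = f$name,
       maximum = mx, argmax = shapes[hit],
       n_shapes = length(shapes), method = "exhaustive")
}
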