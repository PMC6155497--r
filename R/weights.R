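#' Weight functions for f-sizes
#'
#' A weight function maps node out-degrees (nonnegative integers) to
#' nonnegative reals and induces the *f-size* of a tree, the sum of
#' `f(out-degree)` over all its nodes (see [f_size]).  Presets:
#'
#' * `"kappa"` — `f(0) = 1`, `f(n > 0) = 0`: the f-size is the number of
#'   leaves.
#' * `"tau"` — `f == 1`: the number of nodes.
#' * `"theta"` — `f(n) = n`: the number of arcs.
#' * `"ln_n_plus_e"` — `f(n) = ln(n + e)`; defines a sound Colless-like
#'   index, the package default.
#' * `"exp_n"` — `f(n) = e^n`; also sound, but weighs high degrees heavily.
#' * `"pow"` — `f(n) = n^d` (parameter `d`).
#' * `"exp_base"` — `f(n) = r^n` (parameter `r`).
#' * `"log_base"` — `f(n) = log_r(n + r)` (parameter `r`).
#' * `"quadratic"` — `f(n) = a n^2 + b n + c` (parameters `a`, `b`, `c`).
#' * `"custom"` — any user function via `fn`.
#'
#' The `exactness` field records whether values are exact integers
#' ("integer"), carry a transcendental basis supporting exact symbolic
#' comparison ("transcendental": `exp_n`, `ln_n_plus_e`), or are generic
#' floating-point ("numeric"); [find_fsize_collisions] keys off it.
#'
#' @param name preset name (see above), or a spec string such as
#'   `"pow:3"`, `"exp_base:2"`, `"quadratic:1,0,0"`.
#' @param d,r,a,b,c preset parameters.
#' @param fn for `"custom"`: a vectorized function of nonnegative integers
#'   returning nonnegative values.
#' @param label optional display name for custom functions.
#' @return An object of class `weight_function` with fields `name`, `fn`,
#'   `exactness` and `params`.
#' @examples
#' f <- weight_function("pow", d = 3)
#' f_size(fs_tree(c(6, 8)), f)  # 3288
#' @export
weight_function <- function(name = "ln_n_plus_e", d = NULL, r = NULL,
                            a = NULL, b = NULL, c = NULL, fn = NULL,
                            label = NULL) {
  if (inherits(name, "weight_function")) return(name)
  if (grepl(":", name, fixed = TRUE)) {
    sp <- strsplit(name, ":", fixed = TRUE)[[1L]]
    pars <- as.numeric(strsplit(sp[2L], ",", fixed = TRUE)[[1L]])
    return(switch(sp[1L],
      pow = weight_function("pow", d = pars[1L]),
      exp_base = weight_function("exp_base", r = pars[1L]),
      log_base = weight_function("log_base", r = pars[1L]),
      quadratic = weight_function("quadratic",
                                  a = pars[1L], b = pars[2L], c = pars[3L]),
      stop("unknown weight function spec: ", name)))
  }
  is_int <- function(x) all(x == round(x))
  w <- switch(name,
    kappa = list(fn = function(n) as.numeric(n == 0), exactness = "integer"),
    tau = list(fn = function(n) rep(1, length(n)), exactness = "integer"),
    theta = list(fn = function(n) as.numeric(n), exactness = "integer"),
    ln_n_plus_e = list(fn = function(n) log(n + exp(1)),
                       exactness = "transcendental"),
    exp_n = list(fn = function(n) exp(n), exactness = "transcendental"),
    pow = {
      stopifnot(!is.null(d), d >= 0)
      list(fn = function(n) n^d,
           exactness = if (is_int(d)) "integer" else "numeric",
           params = list(d = d))
    },
    exp_base = {
      stopifnot(!is.null(r), r > 0)
      list(fn = function(n) r^n,
           exactness = if (is_int(r)) "integer" else "numeric",
           params = list(r = r))
    },
    log_base = {
      stopifnot(!is.null(r), r > 1)
      list(fn = function(n) log(n + r, base = r),
           exactness = "numeric", params = list(r = r))
    },
    quadratic = {
      stopifnot(!is.null(a), !is.null(b), !is.null(c))
      list(fn = function(n) a * n^2 + b * n + c,
           exactness = if (is_int(c(a, b, c))) "integer" else "numeric",
           params = list(a = a, b = b, c = c))
    },
    custom = {
      stopifnot(is.function(fn))
      list(fn = fn, exactness = "numeric")
    },
    stop("unknown weight function: ", name)
  )
  vals <- w$fn(0:8)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("weight function must be finite and nonnegative on small degrees")
  structure(list(name = if (!is.null(label)) label else name,
                 fn = w$fn, exactness = w$exactness,
                 params = w$params %||% list()),
            class = "weight_function")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.weight_function <- function(x, ...) {
  pars <- if (length(x$params))
    paste0("(", paste(names(x$params), unlist(x$params), sep = "=",
                      collapse = ", "), ")")
  else ""
  cat(sprintf("<weight_function> %s%s [%s]\n", x$name, pars, x$exactness))
  invisible(x)
}

#' Degree profile of a tree
#'
#' The multiset of node out-degrees: for every out-degree `k` occurring in
#' the tree, the number `m_k` of nodes with that out-degree (leaves count
#' at `k = 0`).  The profile determines the f-size for every weight
#' function, `delta_f = sum_k m_k f(k)`, and serves as an exact equality
#' surrogate for `f(n) = e^n`, whose f-sizes coincide exactly when the
#' profiles do.
#'
#' @param tree an [mftree].
#' @return A named integer vector, names the out-degrees in increasing
#'   order.
#' @examples
#' degree_profile(fs_tree(c(2, 2, 2, 7)))  # 56 leaves, 7 binary, 8 septary
#' @export
degree_profile <- function(tree) {
  tree <- as_mftree(tree)
  deg <- out_degrees(tree)
  ks <- sort(unique(deg))
  m <- vapply(ks, function(k) sum(deg == k), integer(1))
  names(m) <- ks
  m
}

#' f-size of a tree
#'
#' The f-size `delta_f(T)` is the sum over all nodes of `f(out-degree)`,
#' for a [weight_function] `f`.  It satisfies the join recursion
#' `delta_f(T1 * ... * Tk) = delta_f(T1) + ... + delta_f(Tk) + f(k)`.
#' For integer-exact weight functions the result is an exact integer
#' (while below 2^53).
#'
#' @param tree an [mftree] (labels are ignored).
#' @param f a [weight_function] or preset name.
#' @return A numeric scalar.
#' @examples
#' f_size(comb_tree(7), "ln_n_plus_e")  # 7 + 6 ln(2 + e)
#' @export
f_size <- function(tree, f = "ln_n_plus_e") {
  f <- weight_function(f)
  m <- degree_profile(tree)
  sum(m * f$fn(as.integer(names(m))))
}

#' f-size of a fully symmetric tree in closed form
#'
#' For the fully symmetric tree with signature `ns = (n1, ..., nk)`,
#' `delta_f = n1...nk f(0) + n1...n_{k-1} f(nk) + ... + n1 f(n2) + f(n1)`,
#' evaluated without building the tree.  Equals
#' `f_size(fs_tree(ns), f)`.
#'
#' @param ns integer vector of factors (each `>= 2`; empty for the single
#'   leaf).
#' @param f a [weight_function] or preset name.
#' @return A numeric scalar.
#' @examples
#' fs_f_size(c(2, 3), "exp_base:2")  # 26
#' @export
fs_f_size <- function(ns, f = "ln_n_plus_e") {
  f <- weight_function(f)
  ns <- as.integer(ns)
  if (length(ns) == 0L) return(f$fn(0L))
  if (any(ns < 2L)) stop("all factors must be >= 2")
  coef <- c(1, cumprod(ns[-length(ns)]))   # n1...n_{i-1} for each i
  prod(ns) * f$fn(0L) + sum(coef * f$fn(ns))
}
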