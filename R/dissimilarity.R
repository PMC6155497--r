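#' Dissimilarities on finite real vectors
#'
#' A dissimilarity is a nonnegative function on finite real vectors that is
#' invariant under permutation of its entries and vanishes exactly on
#' constant vectors.  Three are built in:
#'
#' * `mdm(x)` — mean deviation from the median, with the even-length median
#'   taken as the midpoint of the two central order statistics, so
#'   `mdm(c(x, y)) == abs(x - y) / 2`.
#' * `svar(x)` — sample variance (denominator `k - 1`), so
#'   `svar(c(x, y)) == (x - y)^2 / 2`.  Note this is the *sample* variance;
#'   the population variance would rescale every variance-based result.
#' * `ssd(x)` — sample standard deviation, `sqrt(svar(x))`.
#'
#' `svar` and `ssd` require at least two entries (length-1 vectors signal a
#' caller bug: internal tree nodes always have at least two children).
#'
#' @param x a numeric vector of finite values.
#' @return A nonnegative numeric scalar.
#' @examples
#' mdm(c(1, 2, 3, 4))  # 1
#' svar(c(1, 5))       # 8
#' @export
mdm <- function(x) {
  check_diss_input(x, min_len = 1L)
  mean(abs(x - stats::median(x)))
}

#' @rdname mdm
#' @export
svar <- function(x) {
  check_diss_input(x, min_len = 2L)
  stats::var(x)
}

#' @rdname mdm
#' @export
ssd <- function(x) {
  check_diss_input(x, min_len = 2L)
  stats::sd(x)
}

check_diss_input <- function(x, min_len) {
  if (length(x) < min_len)
    stop("dissimilarity input must have at least ", min_len, " entries")
  if (!all(is.finite(x))) stop("dissimilarity input must be finite")
  invisible(x)
}

.diss_registry <- new.env(parent = emptyenv())

new_dissimilarity <- function(name, fn) {
  structure(list(name = name, fn = fn), class = "dissimilarity")
}

#' @export
print.dissimilarity <- function(x, ...) {
  cat(sprintf("<dissimilarity> %s\n", x$name))
  invisible(x)
}

#' Look up or register a dissimilarity
#'
#' `dissimilarity()` resolves a name (built-ins: `"mdm"`, `"var"`, `"sd"`,
#' plus anything registered), a bare function, or an existing dissimilarity
#' object.  `register_dissimilarity()` adds a user dissimilarity to the
#' registry after spot-checking the two defining axioms on a randomized
#' battery: permutation invariance, zero on constant vectors, and nonzero
#' on perturbed (non-constant) vectors.  A detected violation rejects the
#' registration and names the failing axiom.
#'
#' @param D a name, function, or `dissimilarity` object.
#' @param name registry name for the new dissimilarity.
#' @param fn a function of a numeric vector (length >= 2) returning a
#'   nonnegative scalar.
#' @param checks number of randomized axiom checks (0 to skip).
#' @return A `dissimilarity` object.
#' @examples
#' register_dissimilarity("range", function(x) diff(range(x)))
#' dissimilarity("range")
#' @export
dissimilarity <- function(D = "mdm") {
  if (inherits(D, "dissimilarity")) return(D)
  if (is.function(D)) return(new_dissimilarity("user", D))
  if (!is.character(D)) stop("cannot interpret this as a dissimilarity")
  built_in <- switch(D, mdm = mdm, var = svar, sd = ssd, NULL)
  if (!is.null(built_in)) return(new_dissimilarity(D, built_in))
  reg <- .diss_registry[[D]]
  if (is.null(reg)) stop("unknown dissimilarity: ", D)
  reg
}

#' @rdname dissimilarity
#' @export
register_dissimilarity <- function(name, fn, checks = 50L) {
  stopifnot(is.character(name), length(name) == 1L, is.function(fn))
  if (checks > 0L) check_dissimilarity_axioms(fn, checks)
  obj <- new_dissimilarity(name, fn)
  .diss_registry[[name]] <- obj
  invisible(obj)
}

check_dissimilarity_axioms <- function(fn, checks) {
  # run the randomized battery without disturbing the caller's RNG stream
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(20180925L)
  for (i in seq_len(checks)) {
    k <- sample(2:10, 1L)
    x <- round(stats::rnorm(k, sd = 5), 3)
    v <- fn(x)
    if (!is.finite(v) || v < 0)
      stop("axiom violation: dissimilarity must be finite and nonnegative")
    if (abs(fn(sample(x)) - v) > 1e-9 * (1 + abs(v)))
      stop("axiom violation (i): not invariant under permutations")
    cst <- rep(round(stats::rnorm(1), 3), k)
    if (abs(fn(cst)) > 1e-12)
      stop("axiom violation (ii): nonzero on a constant vector")
    y <- cst
    y[1L] <- y[1L] + sample(c(-2, -1, 1, 2), 1L)
    if (fn(y) <= 0)
      stop("axiom violation (ii): zero on a non-constant vector")
  }
  invisible(TRUE)
}
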