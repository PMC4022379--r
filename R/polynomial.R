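# A monomial is a sorted integer vector of 1-based variable indices; the
# empty vector is the constant monomial 1. Square-freeness is implied by the
# set representation (over GF(2), x^2 = x, so exponents above 1 collapse).

#' Construct a square-free monomial
#'
#' Reduces a raw exponent vector (or an explicit support set) to its
#' square-free form: over the two-element field `x^2 = x`, so a monomial is
#' fully described by the set of variables appearing with positive exponent.
#'
#' @param exponents Integer vector of non-negative exponents, one per
#'   variable; alternatively use `support`.
#' @param support Integer vector of variable indices (1-based); overrides
#'   `exponents`.
#' @return Sorted integer vector of variable indices; `integer(0)` is the
#'   constant monomial 1.
#' @examples
#' monomial(exponents = c(2, 0, 3))  # x1^2 * x3^3 -> x1 * x3
#' monomial(support = c(3, 1))
#' @export
monomial <- function(exponents = NULL, support = NULL) {
  if (!is.null(support)) {
    support <- as.integer(support)
    if (any(support < 1L)) stop("variable indices are 1-based")
    return(sort(unique(support)))
  }
  if (is.null(exponents)) return(integer(0))
  exponents <- as.integer(exponents)
  if (any(exponents < 0L)) stop("exponents must be non-negative")
  sort(which(exponents >= 1L))
}

# fixed-width key: sorts monomials lexicographically and identifies them
# uniquely ("." is the constant monomial 1)
mono_key <- function(mo) {
  if (length(mo) == 0L) "." else paste(sprintf("%03d", mo), collapse = "")
}

#' Construct a Boolean polynomial over GF(2)
#'
#' A Boolean polynomial is a set of square-free monomials with implicit
#' coefficient 1; addition is modulo 2, so monomials occurring an even number
#' of times cancel on construction. The empty set is the zero polynomial.
#'
#' @param monomials List of monomials (integer support vectors as returned by
#'   [monomial()]).
#' @param n Number of variables of the ambient polynomial ring.
#' @return An object of class `bpds_polynomial`.
#' @examples
#' # x1 + x2*x3 on 3 variables
#' boolean_polynomial(list(1L, c(2L, 3L)), n = 3)
#' @export
boolean_polynomial <- function(monomials = list(), n) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  if (n > 999L) stop("at most 999 variables are supported")
  monos <- lapply(monomials, function(mo) monomial(support = mo))
  key <- "0"
  if (length(monos)) {
    if (any(vapply(monos, function(mo) length(mo) && max(mo) > n, logical(1))))
      stop("monomial references a variable beyond n = ", n)
    keys <- vapply(monos, mono_key, character(1))
    ord <- order(lengths(monos), keys, method = "radix")
    monos <- monos[ord]; keys <- keys[ord]
    # canonical order makes duplicates adjacent: cancel even runs mod 2
    runs <- rle(keys)
    keep <- runs$values[runs$lengths %% 2L == 1L]
    sel <- match(keep, keys)
    monos <- monos[sel]
    key <- if (length(monos)) paste(keys[sel], collapse = "|") else "0"
  }
  structure(list(monomials = monos, n = n, key = key),
            class = "bpds_polynomial")
}

#' @export
#' @rdname boolean_polynomial
poly_zero <- function(n) boolean_polynomial(list(), n)

#' @export
#' @rdname boolean_polynomial
poly_one <- function(n) boolean_polynomial(list(integer(0)), n)

is_zero_poly <- function(p) length(p$monomials) == 0L

#' GF(2) polynomial arithmetic
#'
#' Addition is the symmetric difference of monomial sets (mod-2
#' cancellation); multiplication distributes over monomial pairs with
#' square-free reduction of each product.
#'
#' @param p,q Objects of class `bpds_polynomial` on the same number of
#'   variables.
#' @return A `bpds_polynomial`.
#' @export
poly_add <- function(p, q) {
  stopifnot(p$n == q$n)
  boolean_polynomial(c(p$monomials, q$monomials), p$n)
}

#' @rdname poly_add
#' @export
poly_mul <- function(p, q) {
  stopifnot(p$n == q$n)
  if (is_zero_poly(p) || is_zero_poly(q)) return(poly_zero(p$n))
  prods <- list()
  k <- 0L
  for (a in p$monomials) for (b in q$monomials) {
    k <- k + 1L
    prods[[k]] <- sort(unique(c(a, b)))  # union: square-free product
  }
  boolean_polynomial(prods, p$n)
}

#' Evaluate a Boolean polynomial at one or more binary states
#'
#' @param p A `bpds_polynomial`.
#' @param state Binary vector of length `n`, or a matrix with `n` columns
#'   (one state per row).
#' @return A bit, or an integer vector of bits (one per row).
#' @examples
#' p <- boolean_polynomial(list(1L, c(2L, 3L)), n = 3)
#' eval_polynomial(p, c(1, 1, 1))  # 1 + 1 = 0 mod 2
#' @export
eval_polynomial <- function(p, state) {
  if (is.matrix(state)) {
    if (ncol(state) != p$n) stop("state matrix must have ", p$n, " columns")
    acc <- integer(nrow(state))
    for (mo in p$monomials) {
      if (length(mo) == 0L) term <- rep(1L, nrow(state))
      else {
        term <- state[, mo[1L]]
        for (j in mo[-1L]) term <- term * state[, j]
      }
      acc <- xor(acc, term)
    }
    return(as.integer(acc))
  }
  if (length(state) != p$n) stop("state must have length ", p$n)
  acc <- 0L
  for (mo in p$monomials) acc <- xor(acc, as.integer(prod(state[mo])))
  as.integer(acc)
}

#' Total degree of a Boolean polynomial
#'
#' The maximum support size over the polynomial's monomials; the zero
#' polynomial and the constant 1 have degree 0.
#'
#' @param p A `bpds_polynomial`.
#' @return Non-negative integer.
#' @export
total_degree <- function(p) {
  if (is_zero_poly(p)) return(0L)
  max(lengths(p$monomials))
}

#' Construct a polynomial dynamical model
#'
#' An ordered tuple of coordinate polynomials `(f1, ..., fn)`, all on the same
#' `n` variables, defining a synchronous map of the Boolean state space into
#' itself.
#'
#' @param coords List of `n` objects of class `bpds_polynomial`.
#' @param variables Optional character vector of variable names (defaults to
#'   `x1..xn`).
#' @return An object of class `bpds_model`.
#' @export
polynomial_model <- function(coords, variables = NULL) {
  n <- length(coords)
  stopifnot(n >= 1L)
  for (p in coords) {
    if (!inherits(p, "bpds_polynomial")) stop("coords must be bpds_polynomial")
    if (p$n != n) stop("all coordinate polynomials must share n = ", n)
  }
  if (is.null(variables)) variables <- paste0("x", seq_len(n))
  stopifnot(length(variables) == n)
  structure(list(coords = coords, n = n, variables = variables),
            class = "bpds_model")
}

#' Synchronous dynamics of a polynomial model
#'
#' `model_step` applies all coordinate functions to the same input state;
#' `simulate_model` iterates it, returning the trajectory as a matrix whose
#' first row is the initial state. `sequential_step` updates coordinates one
#' at a time in a given order, each update seeing the previous ones (used to
#' check schedule invariance of fixed points).
#'
#' @param f A `bpds_model`.
#' @param state Binary vector of length `n`.
#' @param steps Trajectory length (number of rows, including the initial
#'   state); must be at least 1.
#' @param order Permutation of `1..n` giving the update order.
#' @return `model_step`/`sequential_step`: a state; `simulate_model`: a
#'   `steps` x `n` binary matrix.
#' @examples
#' f <- polynomial_model(list(
#'   boolean_polynomial(list(2L), 2),
#'   boolean_polynomial(list(1L), 2)))
#' model_step(f, c(1, 0))      # swap -> (0, 1)
#' simulate_model(f, c(1, 0), 4)
#' @export
model_step <- function(f, state) {
  if (length(state) != f$n) stop("state must have length ", f$n)
  vapply(f$coords, eval_polynomial, integer(1), state = state)
}

#' @rdname model_step
#' @export
simulate_model <- function(f, state, steps) {
  steps <- as.integer(steps)
  if (steps < 1L) stop("steps must be at least 1")
  traj <- matrix(0L, nrow = steps, ncol = f$n)
  traj[1L, ] <- as.integer(state)
  if (steps > 1L) for (t in 2:steps) traj[t, ] <- model_step(f, traj[t - 1L, ])
  colnames(traj) <- f$variables
  traj
}

#' @rdname model_step
#' @export
sequential_step <- function(f, state, order) {
  order <- as.integer(order)
  if (!identical(sort(order), seq_len(f$n)))
    stop("order must be a permutation of 1..n")
  s <- as.integer(state)
  for (i in order) s[i] <- eval_polynomial(f$coords[[i]], s)
  s
}

#' Knock out a node of a model
#'
#' Returns the perturbed model in which the silenced node's coordinate
#' function is replaced by the zero polynomial, all other coordinates
#' unchanged. This is the model against which knock-out/RNAi series are
#' scored.
#'
#' @param f A `bpds_model`.
#' @param r Index of the node to silence.
#' @return A `bpds_model`.
#' @export
knockout_model <- function(f, r) {
  r <- as.integer(r)
  if (r < 1L || r > f$n) stop("knock-out index out of range")
  coords <- f$coords
  coords[[r]] <- poly_zero(f$n)
  polynomial_model(coords, f$variables)
}

all_states <- function(n) {
  # rows enumerate {0,1}^n; column 1 is the fastest-cycling bit
  S <- matrix(0L, nrow = 2L^n, ncol = n)
  for (j in seq_len(n))
    S[, j] <- rep(rep(c(0L, 1L), each = 2L^(j - 1L)), length.out = 2L^n)
  S
}

#' Fixed points (steady states) of a polynomial model
#'
#' In this framework the fixed points are independent of the update schedule,
#' so they characterize long-run behavior shared by synchronous and
#' sequential simulation. Exhaustive enumeration checks all `2^n` states and
#' is capped at `exhaustive_limit` variables; above it, a sampling mode
#' iterates the model from random initial states and reports only the fixed
#' points discovered, flagged as non-exhaustive.
#'
#' @param f A `bpds_model`.
#' @param method `"exhaustive"` (default for `n <= exhaustive_limit`) or
#'   `"sampling"`.
#' @param exhaustive_limit Largest `n` for which all states are enumerated.
#' @param samples,max_iter Sampling-mode controls: number of random starts
#'   and iteration cap per start.
#' @return Binary matrix with one fixed point per row (possibly 0 rows) and
#'   attribute `exhaustive` (logical).
#' @export
steady_states <- function(f, method = NULL, exhaustive_limit = 20L,
                          samples = 1000L, max_iter = 200L) {
  n <- f$n
  if (is.null(method))
    method <- if (n <= exhaustive_limit) "exhaustive" else "sampling"
  method <- match.arg(method, c("exhaustive", "sampling"))
  if (method == "exhaustive") {
    if (n > exhaustive_limit)
      stop("n = ", n, " exceeds the exhaustive limit; use method = \"sampling\"")
    S <- all_states(n)
    nxt <- matrix(0L, nrow = nrow(S), ncol = n)
    for (i in seq_len(n)) nxt[, i] <- eval_polynomial(f$coords[[i]], S)
    fixed <- S[rowSums(S != nxt) == 0L, , drop = FALSE]
    colnames(fixed) <- f$variables
    attr(fixed, "exhaustive") <- TRUE
    return(fixed)
  }
  seen <- new.env(parent = emptyenv())
  found <- list()
  for (k in seq_len(samples)) {
    s <- sample(c(0L, 1L), n, replace = TRUE)
    for (it in seq_len(max_iter)) {
      nx <- model_step(f, s)
      if (all(nx == s)) {
        key <- paste(s, collapse = "")
        if (is.null(seen[[key]])) {
          seen[[key]] <- TRUE
          found[[length(found) + 1L]] <- s
        }
        break
      }
      s <- nx
    }
  }
  fixed <- if (length(found)) do.call(rbind, found)
           else matrix(integer(0), nrow = 0L, ncol = n)
  colnames(fixed) <- f$variables
  attr(fixed, "exhaustive") <- FALSE
  fixed
}

#' Adjacency matrix of a model's wiring diagram
#'
#' Entry `V[i, j]` is 1 when variable `j` appears in some monomial of the
#' i-th coordinate function, i.e. node `j` regulates node `i`. Constant
#' coordinates have empty support and contribute no edges.
#'
#' @param f A `bpds_model`.
#' @return `n` x `n` binary matrix with variable names on both dimensions.
#' @export
adjacency_matrix <- function(f) {
  V <- matrix(0L, nrow = f$n, ncol = f$n,
              dimnames = list(f$variables, f$variables))
  for (i in seq_len(f$n)) {
    sup <- unique(unlist(f$coords[[i]]$monomials))
    if (length(sup)) V[i, sup] <- 1L
  }
  V
}

#' @export
print.bpds_polynomial <- function(x, ...) {
  cat(format_polynomial(x), "\n")
  invisible(x)
}

#' @export
print.bpds_model <- function(x, ...) {
  cat(format_model(x), sep = "\n")
  invisible(x)
}

#' @export
format.bpds_polynomial <- function(x, ...) format_polynomial(x)
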