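# The algebraic restriction of the model search space: m, Phi, and the
# monomial basis of bounded support.

#' Total length of a set of time-series fragments
#'
#' Each fragment of length `alpha` prescribes `alpha - 1` state transitions;
#' the total length `m` is the number of prescribed transitions summed over
#' fragments. Length-1 fragments contribute nothing.
#'
#' @param series_lengths Integer vector of fragment lengths (each >= 1).
#' @return Integer `m`.
#' @examples
#' total_length(c(5, 5))   # 8
#' @export
total_length <- function(series_lengths) {
  if (length(series_lengths) == 0L) stop("no series supplied")
  series_lengths <- as.integer(series_lengths)
  if (any(series_lengths < 1L)) stop("series lengths must be >= 1")
  sum(series_lengths) - length(series_lengths)
}

#' Support bound for interpolating polynomials
#'
#' A polynomial interpolating data at `m` points never needs a monomial whose
#' support exceeds `floor(log2(m))`: the admissibility criterion for an
#' exponent vector `a` is `prod(a_i + 1) <= m`, which for square-free
#' monomials reads `2^|supp| <= m`.
#'
#' @param m Total length (number of prescribed transitions), `m >= 1`.
#' @return Integer bound `Phi`.
#' @examples
#' support_bound(16)   # 4
#' support_bound(1023) # 9
#' @export
support_bound <- function(m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 1L) stop("m must be a positive integer")
  # integer-exact floor(log2(m)): largest phi with 2^phi <= m
  phi <- 0L
  while (2^(phi + 1L) <= m) phi <- phi + 1L
  phi
}

#' Dimension of the restricted monomial space
#'
#' The monomials on `n` variables with support size at most `Phi` form a
#' vector space over GF(2) of dimension `sum_{i=0}^{Phi} choose(n, i)`;
#' `Phi >= n` recovers the full space of dimension `2^n`.
#'
#' @param n Number of variables.
#' @param phi Support bound.
#' @return Exact integer count (as a double for large values; exact while
#'   below 2^53).
#' @examples
#' search_space_dimension(20, 4)  # 6196
#' @export
search_space_dimension <- function(n, phi) {
  n <- as.integer(n); phi <- as.integer(phi)
  if (phi < 0L) stop("phi must be non-negative")
  if (phi >= n) return(2^n)
  sum(choose(n, 0:phi))
}

#' Enumerate the restricted monomial set
#'
#' All monomials with support size at most `phi`, in a fixed deterministic
#' order: by support size, then lexicographically on variable indices. The
#' constant monomial 1 (empty support) comes first.
#'
#' @param n Number of variables.
#' @param phi Support bound (`phi >= 0`).
#' @return List of monomials (integer support vectors).
#' @export
enumerate_monomials <- function(n, phi) {
  n <- as.integer(n); phi <- as.integer(phi)
  if (phi < 0L) stop("phi must be non-negative")
  phi <- min(phi, n)
  out <- list(integer(0))
  for (k in seq_len(phi)) {
    combs <- utils::combn(n, k)
    for (c_i in seq_len(ncol(combs)))
      out[[length(out) + 1L]] <- as.integer(combs[, c_i])
  }
  out
}

#' Admissibility of a monomial for a given total length
#'
#' A square-free monomial can appear in a minimal interpolator of `m` data
#' points only if `2^|supp| <= m` (equivalently `|supp| <= floor(log2 m)`).
#'
#' @param mono A monomial (integer support vector).
#' @param m Total length, `m >= 1`.
#' @return Logical.
#' @export
is_admissible <- function(mono, m) {
  if (m < 1L) stop("m must be a positive integer")
  2^length(mono) <= m
}

#' Search-space specification
#'
#' Bundles the quantities describing the restricted search space: the total
#' length `m` of the input fragments, the global support bound
#' `Phi = floor(log2 m)`, and optional per-coordinate refinements
#' `Phi_i <= Phi` (e.g. from known bounds on the number of regulator binding
#' sites).
#'
#' @param n Number of variables.
#' @param m Total length.
#' @param per_coordinate_phi Optional integer vector of `n` bounds.
#' @return An object of class `bpds_search_space`.
#' @export
search_space_spec <- function(n, m, per_coordinate_phi = NULL) {
  phi <- support_bound(m)
  if (!is.null(per_coordinate_phi)) {
    per_coordinate_phi <- as.integer(per_coordinate_phi)
    stopifnot(length(per_coordinate_phi) == n)
    if (any(per_coordinate_phi > phi))
      stop("per-coordinate bounds cannot exceed the global bound Phi = ", phi)
  }
  structure(list(n = as.integer(n), m = as.integer(m), phi = phi,
                 per_coordinate_phi = per_coordinate_phi),
            class = "bpds_search_space")
}

coordinate_phi <- function(spec, i) {
  if (is.null(spec$per_coordinate_phi)) spec$phi else spec$per_coordinate_phi[i]
}

#' @export
print.bpds_search_space <- function(x, ...) {
  cat(sprintf("Search space: n = %d, m = %d transitions, Phi = %d (dimension %s)\n",
              x$n, x$m, x$phi,
              format(search_space_dimension(x$n, x$phi), big.mark = ",")))
  invisible(x)
}
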