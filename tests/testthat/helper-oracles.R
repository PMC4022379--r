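# Independent oracles and small generators used across the test files.

# All 2^n binary states as rows (column 1 cycles fastest).
oracle_states <- function(n) {
  S <- matrix(0L, nrow = 2L^n, ncol = n)
  for (j in seq_len(n))
    S[, j] <- rep(rep(c(0L, 1L), each = 2L^(j - 1L)), length.out = 2L^n)
  S
}

# Build a logic-expression string whose truth table is `bits` (one value per
# row of oracle_states(n)), as an OR of minterms. The empty function is "0".
minterm_expression <- function(bits, n) {
  S <- oracle_states(n)
  rows <- which(bits == 1L)
  if (length(rows) == 0L) return("0")
  terms <- vapply(rows, function(r) {
    lits <- vapply(seq_len(n), function(j)
      if (S[r, j] == 1L) paste0("x", j) else paste0("NOT x", j), character(1))
    paste0("(", paste(lits, collapse = " AND "), ")")
  }, character(1))
  paste(terms, collapse = " OR ")
}

# Truth table of a polynomial over all states.
poly_truth_table <- function(p) eval_polynomial(p, oracle_states(p$n))

# Solve A x = b over GF(2); returns TRUE if a solution exists. Independent
# Gaussian-elimination oracle for interpolator-existence checks.
gf2_solvable <- function(A, b) {
  A <- A %% 2L; b <- b %% 2L
  M <- cbind(A, b)
  nr <- nrow(M); nc <- ncol(A)
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(M[row:nr, col] == 1L)
    if (length(piv) == 0L) next
    piv <- piv[1L] + row - 1L
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    for (r in seq_len(nr)) if (r != row && M[r, col] == 1L)
      M[r, ] <- (M[r, ] + M[row, ]) %% 2L
    row <- row + 1L
    if (row > nr) break
  }
  # inconsistent iff some row is (0 ... 0 | 1)
  !any(rowSums(M[, seq_len(nc), drop = FALSE]) == 0L & M[, nc + 1L] == 1L)
}

# A random polynomial within the restricted space.
random_test_poly <- function(n, phi, max_monomials = 3L) {
  k <- sample.int(max_monomials, 1L)
  monos <- lapply(seq_len(k), function(j) {
    size <- sample.int(phi + 1L, 1L) - 1L
    if (size == 0L) integer(0) else sort(sample.int(n, size))
  })
  boolean_polynomial(monos, n)
}

random_test_model <- function(n, phi = n, max_monomials = 3L) {
  polynomial_model(lapply(seq_len(n), function(i)
    random_test_poly(n, phi, max_monomials)))
}

expect_poly_equal <- function(p, q) expect_identical(p$key, q$key)

model_key_for_tests <- function(f)
  paste(vapply(f$coords, `[[`, character(1), "key"), collapse = ";")

# Study-condition fixture + short EA config used by the heavier tests; the
# EA size is chosen so a run finishes in seconds at n = 5.
recovery_config <- function(seed, xi = 0) {
  ea_config(population_size = 60L, generations = 200L, seed = seed, xi = xi)
}
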