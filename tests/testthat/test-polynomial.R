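# Square-free GF(2) polynomial algebra, Boolean translation, and dynamics.

test_that("Boolean connectives translate to their polynomial forms", {
  expect_poly_equal(boolean_to_polynomial("NOT x1", 1),
                    parse_polynomial_text("x1 + 1", 1))
  expect_poly_equal(boolean_to_polynomial("x1 OR x2", 2),
                    parse_polynomial_text("x1 + x2 + x1*x2", 2))
  expect_poly_equal(boolean_to_polynomial("x1 AND x2", 2),
                    parse_polynomial_text("x1*x2", 2))
  expect_poly_equal(boolean_to_polynomial("x1 XOR x2", 2),
                    parse_polynomial_text("x1 + x2", 2))
  # mod-2 cancellation: XOR of a variable with itself vanishes
  expect_true(length(boolean_to_polynomial("x1 XOR x1", 1)$monomials) == 0L)
  # idempotence: x AND x = x (square-free reduction through the product)
  expect_poly_equal(boolean_to_polynomial("x1 AND x1", 1),
                    parse_polynomial_text("x1", 1))
})

test_that("expression parser honours precedence and rejects malformed input", {
  # NOT > AND > XOR > OR
  p <- boolean_to_polynomial("NOT x1 AND x2 OR x3", 3)
  q <- boolean_to_polynomial("((NOT x1) AND x2) OR x3", 3)
  expect_poly_equal(p, q)
  expect_error(boolean_to_polynomial("x9", 3), "unknown variable")
  expect_error(boolean_to_polynomial("x1 AND", 2), "malformed|unexpected")
  expect_error(boolean_to_polynomial("x1 %% x2", 2), "malformed")
  expect_error(boolean_to_polynomial("(x1 OR x2", 2), "missing")
})

test_that("raw exponent vectors reduce to square-free supports", {
  expect_identical(monomial(exponents = c(2L)), 1L)          # x1^2 -> x1
  expect_identical(monomial(exponents = c(3L, 2L)), c(1L, 2L))
  expect_identical(monomial(exponents = c(0L)), integer(0))  # x1^0 -> 1
  expect_error(monomial(exponents = c(-1L)), "non-negative")
})

test_that("evaluation sums monomial products modulo 2", {
  p <- parse_polynomial_text("x1 + x2*x3", 3)
  expect_identical(eval_polynomial(p, c(1, 1, 1)), 0L)
  expect_identical(eval_polynomial(p, c(0, 1, 1)), 1L)
  expect_identical(eval_polynomial(poly_zero(3), c(1, 0, 1)), 0L)
  expect_error(eval_polynomial(p, c(1, 0)), "length")
  # matrix evaluation agrees with row-wise evaluation
  S <- oracle_states(3)
  expect_identical(eval_polynomial(p, S),
                   vapply(seq_len(nrow(S)), function(r)
                     eval_polynomial(p, S[r, ]), integer(1)))
})

test_that("synchronous step and simulation follow the update rule", {
  swap <- polynomial_model(list(parse_polynomial_text("x2", 2),
                                parse_polynomial_text("x1", 2)))
  expect_identical(model_step(swap, c(1, 0)), c(0L, 1L))
  id2 <- polynomial_model(list(parse_polynomial_text("x1", 2),
                               parse_polynomial_text("x2", 2)))
  expect_identical(model_step(id2, c(1, 0)), c(1L, 0L))
  f3 <- polynomial_model(list(parse_polynomial_text("x1 + 1", 2),
                              parse_polynomial_text("x1*x2", 2)))
  expect_identical(model_step(f3, c(0, 0)), c(1L, 0L))

  traj <- simulate_model(id2, c(1, 0), 3)
  expect_identical(unname(traj), matrix(c(1L, 0L), 3, 2, byrow = TRUE))
  neg <- polynomial_model(list(parse_polynomial_text("x1 + 1", 1)))
  expect_identical(unname(simulate_model(neg, 0, 4)[, 1]), c(0L, 1L, 0L, 1L))
  expect_error(simulate_model(neg, 0, 0), "steps")
})

test_that("knock-outs zero one coordinate and are idempotent", {
  f <- polynomial_model(list(parse_polynomial_text("x2", 3),
                             parse_polynomial_text("x1*x3", 3),
                             parse_polynomial_text("x1 + 1", 3)))
  ko <- knockout_model(f, 2)
  expect_true(length(ko$coords[[2]]$monomials) == 0L)
  expect_poly_equal(ko$coords[[1]], f$coords[[1]])
  expect_poly_equal(ko$coords[[3]], f$coords[[3]])
  expect_identical(model_key_for_tests(knockout_model(ko, 2)),
                   model_key_for_tests(ko))
  zero <- polynomial_model(lapply(1:3, function(i) poly_zero(3)))
  expect_identical(model_key_for_tests(knockout_model(zero, 1)),
                   model_key_for_tests(zero))
  expect_error(knockout_model(f, 4), "out of range")
})

test_that("steady-state enumeration finds exactly the fixed points", {
  id2 <- polynomial_model(list(parse_polynomial_text("x1", 2),
                               parse_polynomial_text("x2", 2)))
  expect_equal(nrow(steady_states(id2)), 4L)
  swap <- polynomial_model(list(parse_polynomial_text("x2", 2),
                                parse_polynomial_text("x1", 2)))
  ss <- steady_states(swap)
  expect_identical(unname(ss[order(ss[, 1]), ]),
                   matrix(c(0L, 0L, 1L, 1L), 2, 2, byrow = TRUE))
  neg <- polynomial_model(list(parse_polynomial_text("x1 + 1", 1)))
  expect_equal(nrow(steady_states(neg)), 0L)
  expect_true(attr(steady_states(neg), "exhaustive"))
  # above the exhaustive cap: explicit sampling only
  expect_error(steady_states(id2, method = "exhaustive",
                             exhaustive_limit = 1L), "exhaustive")
  set.seed(1)
  samp <- steady_states(id2, method = "sampling", samples = 50)
  expect_false(attr(samp, "exhaustive"))
  expect_true(all(apply(samp, 1, function(s) all(model_step(id2, s) == s))))
})

test_that("sequential update agrees with hand evaluation and fixes the fixed points", {
  swap <- polynomial_model(list(parse_polynomial_text("x2", 2),
                                parse_polynomial_text("x1", 2)))
  expect_identical(sequential_step(swap, c(1, 0), c(1, 2)), c(0L, 0L))
  id2 <- polynomial_model(list(parse_polynomial_text("x1", 2),
                               parse_polynomial_text("x2", 2)))
  expect_identical(sequential_step(id2, c(1, 0), c(2, 1)), c(1L, 0L))
  # any fixed point is invariant under any order
  ss <- steady_states(swap)
  for (k in seq_len(nrow(ss)))
    expect_identical(sequential_step(swap, ss[k, ], c(2, 1)),
                     unname(ss[k, ]))
  expect_error(sequential_step(swap, c(1, 0), c(1, 1)), "permutation")
})

test_that("adjacency extraction reads variable occurrence, constants give no edges", {
  f <- polynomial_model(list(parse_polynomial_text("x2", 2),
                             parse_polynomial_text("x1*x2", 2)))
  expect_identical(unname(adjacency_matrix(f)),
                   matrix(c(0L, 1L, 1L, 1L), 2, 2, byrow = TRUE))
  zero <- polynomial_model(list(poly_zero(2), poly_zero(2)))
  expect_true(all(adjacency_matrix(zero) == 0L))
  ones <- polynomial_model(list(poly_one(2), poly_one(2)))
  expect_true(all(adjacency_matrix(ones) == 0L))
})

test_that("total degree is the maximum support size", {
  expect_identical(total_degree(parse_polynomial_text("x1 + x2*x3", 3)), 2L)
  expect_identical(total_degree(poly_one(3)), 0L)
  expect_identical(total_degree(poly_zero(3)), 0L)
  expect_identical(total_degree(parse_polynomial_text("x1*x2*x3*x4", 4)), 4L)
})

test_that("translation reproduces every truth table on two variables", {
  S <- oracle_states(2)
  for (code in 0:15) {
    bits <- as.integer(intToBits(code))[1:4]
    p <- boolean_to_polynomial(minterm_expression(bits, 2), 2)
    expect_identical(poly_truth_table(p), bits)
  }
})

test_that("distinct square-free polynomials have distinct truth tables (n = 2)", {
  monos <- enumerate_monomials(2, 2)
  tables <- character(0)
  for (code in 0:15) {
    subset <- monos[as.logical(intToBits(code))[1:4]]
    p <- boolean_polynomial(subset, 2)
    tables <- c(tables, paste(poly_truth_table(p), collapse = ""))
  }
  expect_equal(length(unique(tables)), 16L)
})

test_that("algebra laws hold and evaluation is a ring homomorphism", {
  set.seed(42)
  for (rep in 1:25) {
    n <- sample(2:4, 1)
    p <- random_test_poly(n, n)
    q <- random_test_poly(n, n)
    expect_true(length(poly_add(p, p)$monomials) == 0L)      # p + p = 0
    expect_poly_equal(poly_mul(p, poly_one(n)), p)           # p * 1 = p
    s <- sample(c(0L, 1L), n, replace = TRUE)
    expect_identical(eval_polynomial(poly_add(p, q), s),
                     as.integer(xor(eval_polynomial(p, s),
                                    eval_polynomial(q, s))))
    expect_identical(eval_polynomial(poly_mul(p, q), s),
                     eval_polynomial(p, s) * eval_polynomial(q, s))
  }
})

test_that("model text format round-trips through file I/O", {
  f <- polynomial_model(list(parse_polynomial_text("x2*x1 + 1", 3),
                             poly_zero(3),
                             parse_polynomial_text("x1 + x2 + x3", 3)))
  path <- withr::local_tempfile(fileext = ".txt")
  write_model(f, path)
  g <- read_model(path)
  expect_identical(model_key_for_tests(g), model_key_for_tests(f))
  # canonical text: a second write is byte-identical
  path2 <- withr::local_tempfile(fileext = ".txt")
  write_model(g, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("SIF and adjacency TSV exports round-trip", {
  f <- polynomial_model(list(parse_polynomial_text("x2", 3),
                             parse_polynomial_text("x1*x3", 3),
                             poly_one(3)))
  V <- adjacency_matrix(f)
  sif <- withr::local_tempfile(fileext = ".sif")
  write_sif(V, sif)
  expect_identical(read_sif(sif, variables = f$variables), V)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_adjacency_tsv(V, tsv)
  expect_identical(read_adjacency_tsv(tsv), V)
})
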