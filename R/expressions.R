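# Boolean logic expressions and the plain-text polynomial/model formats.

tokenize_expr <- function(expr) {
  pat <- "\\(|\\)|[A-Za-z][A-Za-z0-9_]*|[01]|&&?|\\|\\|?|!|\\^"
  starts <- gregexpr(pat, expr)[[1]]
  if (starts[1] == -1) stop("malformed expression: ", expr)
  toks <- regmatches(expr, gregexpr(pat, expr))[[1]]
  rest <- gsub(pat, "", expr)
  if (grepl("[^[:space:]]", rest))
    stop("malformed expression, unexpected characters in: ", expr)
  toks
}

#' Translate a Boolean logic expression to its square-free polynomial
#'
#' Applies the classical translation between Boolean logic and polynomial
#' arithmetic over the two-element field: `x AND y -> x*y`,
#' `x OR y -> x + y + x*y`, `NOT x -> x + 1`, and `XOR` is addition itself.
#' The result is the unique square-free polynomial with the same truth table.
#'
#' @param expr Character scalar: an expression over variables `x1..xn` using
#'   `AND`, `OR`, `NOT`, `XOR` (case-insensitive; `&`, `|`, `!`, `^` also
#'   accepted), parentheses, and the constants `0`/`1`. Precedence:
#'   `NOT` > `AND` > `XOR` > `OR`.
#' @param n Number of variables.
#' @return A `bpds_polynomial`.
#' @examples
#' boolean_to_polynomial("NOT x1", 1)        # x1 + 1
#' boolean_to_polynomial("x1 OR x2", 2)      # x1 + x2 + x1*x2
#' boolean_to_polynomial("x1 XOR x1", 1)     # 0
#' @export
boolean_to_polynomial <- function(expr, n) {
  n <- as.integer(n)
  toks <- tokenize_expr(expr)
  pos <- 1L
  peek <- function() if (pos <= length(toks)) toks[pos] else NA_character_
  take <- function() { t <- peek(); pos <<- pos + 1L; t }
  is_op <- function(t, names) !is.na(t) && toupper(t) %in% names

  parse_atom <- function() {
    t <- take()
    if (is.na(t)) stop("malformed expression: unexpected end")
    if (t == "(") {
      p <- parse_or()
      if (!identical(take(), ")")) stop("malformed expression: missing ')'")
      return(p)
    }
    if (t == "0") return(poly_zero(n))
    if (t == "1") return(poly_one(n))
    if (grepl("^[Xx][0-9]+$", t)) {
      j <- as.integer(sub("^[Xx]", "", t))
      if (j < 1L || j > n) stop("unknown variable ", t, " for n = ", n)
      return(boolean_polynomial(list(j), n))
    }
    stop("unknown token '", t, "' in expression")
  }
  parse_not <- function() {
    if (is_op(peek(), c("NOT", "!"))) {
      take()
      return(poly_add(parse_not(), poly_one(n)))
    }
    parse_atom()
  }
  parse_and <- function() {
    p <- parse_not()
    while (is_op(peek(), c("AND", "&", "&&"))) {
      take()
      p <- poly_mul(p, parse_not())
    }
    p
  }
  parse_xor <- function() {
    p <- parse_and()
    while (is_op(peek(), c("XOR", "^"))) {
      take()
      p <- poly_add(p, parse_and())
    }
    p
  }
  parse_or <- function() {
    p <- parse_xor()
    while (is_op(peek(), c("OR", "|", "||"))) {
      take()
      q <- parse_xor()
      p <- poly_add(poly_add(p, q), poly_mul(p, q))
    }
    p
  }
  out <- parse_or()
  if (pos <= length(toks))
    stop("malformed expression: trailing tokens from '", toks[pos], "'")
  out
}

#' Parse and format polynomials in the plain-text model format
#'
#' Terms are `x<j>*x<k>*...`, `1`, or `0`, joined by `+`; whitespace is
#' ignored. A model file has one line per coordinate: `f<i> = <polynomial>`.
#' Formatting is canonical (monomials ordered by support size then
#' lexicographically), so read/write round-trips are stable.
#'
#' @param text Character scalar holding one polynomial.
#' @param n Number of variables.
#' @return `parse_polynomial_text`: a `bpds_polynomial`;
#'   `format_polynomial`: a character scalar.
#' @examples
#' parse_polynomial_text("x2*x1 + 1", n = 3)
#' @export
parse_polynomial_text <- function(text, n) {
  text <- gsub("[[:space:]]", "", text)
  if (text == "") stop("empty polynomial text")
  terms <- strsplit(text, "+", fixed = TRUE)[[1]]
  if (any(terms == "")) stop("malformed polynomial text: ", text)
  monos <- list()
  for (term in terms) {
    if (term == "0") next
    if (term == "1") { monos[[length(monos) + 1L]] <- integer(0); next }
    facs <- strsplit(term, "*", fixed = TRUE)[[1]]
    if (!all(grepl("^[Xx][0-9]+$", facs)))
      stop("malformed term '", term, "'")
    idx <- as.integer(sub("^[Xx]", "", facs))
    if (any(idx < 1L) || any(idx > n))
      stop("variable out of range in term '", term, "' for n = ", n)
    monos[[length(monos) + 1L]] <- monomial(support = idx)
  }
  boolean_polynomial(monos, n)
}

#' @rdname parse_polynomial_text
#' @param p A `bpds_polynomial`.
#' @export
format_polynomial <- function(p) {
  if (is_zero_poly(p)) return("0")
  terms <- vapply(p$monomials, function(mo) {
    if (length(mo) == 0L) "1" else paste0("x", mo, collapse = "*")
  }, character(1))
  paste(terms, collapse = " + ")
}

format_model <- function(f) {
  vapply(seq_len(f$n), function(i)
    sprintf("f%d = %s", i, format_polynomial(f$coords[[i]])), character(1))
}

#' Read and write models in the plain-text format
#'
#' One line per coordinate, `f<i> = <term> + <term> + ...`; blank lines and
#' `#` comments are skipped. Round-trips are stable.
#'
#' @param path File path.
#' @param f A `bpds_model`.
#' @param variables Optional variable names to attach on read.
#' @return `read_model`: a `bpds_model`; `write_model`: `path`, invisibly.
#' @export
read_model <- function(path, variables = NULL) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^f([0-9]+)[[:space:]]*=(.*)$", lines))
  if (any(lengths(m) != 3L)) stop("malformed model line in ", path)
  idx <- as.integer(vapply(m, `[`, character(1), 2L))
  n <- length(lines)
  if (!identical(sort(idx), seq_len(n)))
    stop("model file must define f1..fn exactly once each")
  coords <- vector("list", n)
  for (k in seq_along(lines))
    coords[[idx[k]]] <- parse_polynomial_text(m[[k]][3L], n)
  polynomial_model(coords, variables)
}

#' @rdname read_model
#' @export
write_model <- function(f, path) {
  writeLines(format_model(f), path)
  invisible(path)
}

#' Export a wiring diagram as SIF or dense adjacency TSV
#'
#' SIF lines read `<regulator>\tregulates\t<target>`, one per edge
#' `V[i, j] = 1` (j regulates i). The adjacency TSV is the dense matrix with
#' variable names as header row and first column.
#'
#' @param V Binary adjacency matrix (targets in rows, regulators in columns).
#' @param path Output path.
#' @param variables Variable names; defaults to the matrix dimnames or
#'   `x1..xn`.
#' @return `path`, invisibly.
#' @export
write_sif <- function(V, path, variables = NULL) {
  if (is.null(variables)) variables <- colnames(V)
  if (is.null(variables)) variables <- paste0("x", seq_len(ncol(V)))
  lines <- character(0)
  for (i in seq_len(nrow(V))) for (j in seq_len(ncol(V)))
    if (V[i, j] == 1L)
      lines <- c(lines, paste(variables[j], "regulates", variables[i],
                              sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sif
#' @param n Network size (needed when the SIF mentions only some variables).
#' @return `read_sif`: a binary adjacency matrix.
#' @export
read_sif <- function(path, variables = NULL, n = NULL) {
  lines <- readLines(path)
  lines <- lines[trimws(lines) != ""]
  parts <- strsplit(lines, "\t")
  if (length(parts) && any(lengths(parts) != 3L))
    stop("malformed SIF line in ", path)
  src <- vapply(parts, `[`, character(1), 1L)
  dst <- vapply(parts, `[`, character(1), 3L)
  if (is.null(variables)) {
    variables <- unique(c(src, dst))
    xs <- grepl("^x[0-9]+$", variables)
    if (all(xs) && !is.null(n)) variables <- paste0("x", seq_len(n))
    else variables <- sort(variables, method = "radix")
  }
  V <- matrix(0L, length(variables), length(variables),
              dimnames = list(variables, variables))
  for (k in seq_along(src)) {
    if (!(src[k] %in% variables) || !(dst[k] %in% variables))
      stop("SIF mentions unknown variable")
    V[dst[k], src[k]] <- 1L
  }
  V
}

#' @rdname write_sif
#' @export
write_adjacency_tsv <- function(V, path, variables = NULL) {
  if (is.null(variables)) variables <- colnames(V)
  if (is.null(variables)) variables <- paste0("x", seq_len(ncol(V)))
  df <- data.frame(variable = variables, V, check.names = FALSE)
  colnames(df) <- c("variable", variables)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sif
#' @export
read_adjacency_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  V <- as.matrix(df[, -1, drop = FALSE])
  rownames(V) <- df[[1]]
  storage.mode(V) <- "integer"
  V
}
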