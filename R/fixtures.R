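# Synthetic fixtures: planted models and their trajectories, so the whole
# pipeline is testable without external data.

# sample one integer uniformly from [a, b] (safe when a == b)
sample_range <- function(a, b, size = 1L) {
  if (a == b) rep(a, size) else sample(seq(a, b), size, replace = TRUE)
}

#' Specification for a synthetic planted-model fixture
#'
#' Defaults describe the standard validation condition used throughout the
#' package: a 5-node network of in-degree at most 2, four wildtype and two
#' knock-out series of 10 points each (54 transitions, so the support bound
#' is 5 and the planted monomials are comfortably admissible), noiseless.
#'
#' @param n Number of nodes.
#' @param max_in_degree Cap on regulators per node.
#' @param monomials_per_coordinate Length-2 range of monomial counts per
#'   coordinate.
#' @param num_wildtype_series,num_ko_series Series counts.
#' @param series_length Length-2 range of series lengths (each >= 2).
#' @param xi Noise fraction injected into the generated series.
#' @param seed Integer seed.
#' @return An object of class `bpds_fixture_spec`.
#' @export
fixture_spec <- function(n = 5L, max_in_degree = 2L,
                         monomials_per_coordinate = c(1L, 2L),
                         num_wildtype_series = 4L, num_ko_series = 2L,
                         series_length = c(10L, 10L), xi = 0, seed = 1L) {
  stopifnot(max_in_degree <= n, all(series_length >= 2L),
            num_wildtype_series >= 1L)
  structure(list(n = as.integer(n), max_in_degree = as.integer(max_in_degree),
                 monomials_per_coordinate = as.integer(monomials_per_coordinate),
                 num_wildtype_series = as.integer(num_wildtype_series),
                 num_ko_series = as.integer(num_ko_series),
                 series_length = as.integer(series_length),
                 xi = xi, seed = as.integer(seed)),
            class = "bpds_fixture_spec")
}

#' Draw a random planted model
#'
#' Each coordinate picks at most `max_in_degree` regulators and builds 1 or
#' more distinct monomials over them, so the wiring diagram has bounded
#' in-degree by construction. Seeded and reproducible.
#'
#' @param spec A `bpds_fixture_spec`.
#' @return A `bpds_model`.
#' @export
random_model <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n
  coords <- lapply(seq_len(n), function(i) {
    d <- sample.int(spec$max_in_degree, 1L)
    regulators <- sort(sample.int(n, d))
    k <- sample_range(spec$monomials_per_coordinate[1],
                      spec$monomials_per_coordinate[2])
    # distinct non-empty subsets of the regulator set
    subsets <- list()
    for (size in seq_len(d))
      subsets <- c(subsets, utils::combn(regulators, size, simplify = FALSE))
    k <- min(k, length(subsets))
    monos <- subsets[sample.int(length(subsets), k)]
    # occasionally negate (add the constant 1) for richer dynamics
    if (stats::runif(1) < 0.5) monos <- c(monos, list(integer(0)))
    boolean_polynomial(monos, n)
  })
  polynomial_model(coords)
}

#' Generate time series from a planted model
#'
#' Wildtype series are synchronous trajectories of the model from uniformly
#' random initial states; knock-out series simulate the perturbed model
#' (silenced coordinate zeroed) for cyclically chosen targets. Optional
#' bit-flip noise at fraction `xi` is injected afterwards. Refuses (unless
#' `allow_out_of_space`) specs whose planted in-degree exceeds the support
#' bound of the generated data, which would put the planted model outside
#' the admissible search space.
#'
#' @param f A `bpds_model` (the planted truth).
#' @param spec A `bpds_fixture_spec`.
#' @param allow_out_of_space Skip the admissibility refusal.
#' @return A `bpds_series_set`; the noiseless set regenerates itself exactly
#'   under `f`.
#' @export
generate_series <- function(f, spec, allow_out_of_space = FALSE) {
  set.seed(spec$seed + 1L)
  n <- f$n
  lens <- sample_range(spec$series_length[1], spec$series_length[2],
                       spec$num_wildtype_series + spec$num_ko_series)
  m <- sum(lens - 1L)
  if (!allow_out_of_space && spec$max_in_degree > support_bound(m))
    stop("planted in-degree ", spec$max_in_degree,
         " exceeds the support bound ", support_bound(m),
         " of the generated data; enlarge the series or pass allow_out_of_space")
  series <- list()
  for (s in seq_len(spec$num_wildtype_series)) {
    s0 <- sample(c(0L, 1L), n, replace = TRUE)
    series[[s]] <- time_series(simulate_model(f, s0, lens[s]),
                               label = sprintf("wt%d", s))
  }
  for (q in seq_len(spec$num_ko_series)) {
    r <- ((q - 1L) %% n) + 1L
    s0 <- sample(c(0L, 1L), n, replace = TRUE)
    idx <- spec$num_wildtype_series + q
    series[[idx]] <- time_series(
      simulate_model(knockout_model(f, r), s0, lens[idx]),
      kind = "knockout", ko_target = r, label = sprintf("ko%d_x%d", q, r))
  }
  tss <- time_series_set(series, xi = spec$xi, variables = f$variables)
  if (spec$xi > 0) tss <- inject_noise(tss, spec$xi, spec$seed + 2L)$tss
  tss
}

#' Canned small fixtures
#'
#' Three fixed networks used throughout the examples and tests:
#' `toggle3`, a 3-node negation ring with no fixed points (a pure
#' oscillator); `irma5`, a synthetic 5-gene, 8-edge network shaped like the
#' yeast IRMA benchmark circuit (one feedback loop; gene names only -- the
#' rules are this package's own, not the biological system); and
#' `parasegment21`, a synthetic sparse 21-variable network shaped like a
#' one-parasegment segment-polarity system (structure only).
#'
#' @return Named list; each element has `model`, `gold` (a `bpds_network`),
#'   and `name`.
#' @export
canned_fixtures <- function() {
  toggle3 <- polynomial_model(list(
    parse_polynomial_text("x3 + 1", 3),
    parse_polynomial_text("x1", 3),
    parse_polynomial_text("x2", 3)))

  irma_vars <- c("CBF1", "GAL4", "SWI5", "GAL80", "ASH1")
  irma_rules <- list(
    "x3 + x3*x5",        # CBF1 = SWI5 AND NOT ASH1
    "x1 + x1*x4",        # GAL4 = CBF1 AND NOT GAL80
    "x2",                # SWI5 = GAL4
    "x3",                # GAL80 = SWI5
    "x3 + x3*x4")        # ASH1 = SWI5 AND NOT GAL80
  irma5 <- polynomial_model(lapply(irma_rules, parse_polynomial_text, n = 5),
                            variables = irma_vars)

  para_coords <- lapply(seq_len(21L), function(i) {
    prev <- function(k) ((i - 1L - k) %% 21L) + 1L
    txt <- switch(as.character(i %% 3L),
                  "1" = sprintf("x%d*x%d", prev(1L), prev(2L)),
                  "2" = sprintf("x%d + 1", prev(1L)),
                  sprintf("x%d + x%d + x%d*x%d",
                          prev(2L), prev(1L), prev(2L), prev(1L)))
    parse_polynomial_text(txt, 21L)
  })
  parasegment21 <- polynomial_model(para_coords)

  fixtures <- list(
    toggle3 = list(model = toggle3, name = "toggle3"),
    irma5 = list(model = irma5, name = "irma5"),
    parasegment21 = list(model = parasegment21, name = "parasegment21"))
  for (nm in names(fixtures)) {
    V <- adjacency_matrix(fixtures[[nm]]$model)
    edges <- which(V == 1L, arr.ind = TRUE)
    vars <- fixtures[[nm]]$model$variables
    fixtures[[nm]]$gold <- gold_network(
      cbind(vars[edges[, "col"]], vars[edges[, "row"]]),
      n = fixtures[[nm]]$model$n, variables = vars)
  }
  fixtures
}
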