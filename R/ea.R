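# The evolutionary algorithm: per-coordinate candidate pools scored by
# one-step fit, n-point crossover assembly of whole models, cloning of
# elites, mutation of monomial terms, and Latin hypercube parameter
# sampling.

#' Evolutionary-algorithm configuration
#'
#' @param population_size Number of candidate models per generation (>= 2).
#' @param generations Generation cap.
#' @param mutation_rate Per-coordinate probability of a monomial mutation.
#' @param crossover_rate Probability that an offspring is assembled by
#'   per-coordinate crossover rather than copied from a selected parent.
#' @param clone_fraction Fraction of the population carried over unchanged
#'   (elitism), in `[0, 1)`.
#' @param tournament_size Tournament size for selection.
#' @param max_monomials_per_coordinate Cap on monomials per coordinate
#'   polynomial.
#' @param weights A [fitness_weights()] object.
#' @param xi Assumed noise fraction: models with `H_f <= xi` are
#'   data-consistent, and reaching one (plus stagnation) stops the run.
#' @param seed Integer seed; fixed seed gives a bit-reproducible run.
#' @param output_family_size Number of top models reported.
#' @return An object of class `bpds_ea_config`.
#' @export
ea_config <- function(population_size = 200L, generations = 500L,
                      mutation_rate = 0.2, crossover_rate = 0.8,
                      clone_fraction = 0.05, tournament_size = 3L,
                      max_monomials_per_coordinate = 4L,
                      weights = fitness_weights(), xi = 0, seed = 1L,
                      output_family_size = 10L) {
  cfg <- list(population_size = as.integer(population_size),
              generations = as.integer(generations),
              mutation_rate = mutation_rate, crossover_rate = crossover_rate,
              clone_fraction = clone_fraction,
              tournament_size = as.integer(tournament_size),
              max_monomials_per_coordinate =
                as.integer(max_monomials_per_coordinate),
              weights = weights, xi = xi, seed = as.integer(seed),
              output_family_size = as.integer(output_family_size))
  if (cfg$population_size < 2L) stop("population_size must be >= 2")
  for (r in c("mutation_rate", "crossover_rate"))
    if (cfg[[r]] < 0 || cfg[[r]] > 1) stop(r, " must lie in [0, 1]")
  if (cfg$clone_fraction < 0 || cfg$clone_fraction >= 1)
    stop("clone_fraction must lie in [0, 1)")
  if (cfg$xi < 0 || cfg$xi >= 1) stop("xi must lie in [0, 1)")
  structure(cfg, class = "bpds_ea_config")
}

# Sample a random monomial with support <= phi. Support sizes k >= 1 are
# weighted 2^-k, reflecting the sparsity of regulatory wiring; the constant
# monomial (k = 0, needed for any NOT-containing rule) draws the same weight
# as size 1. Variable choice is weighted by max(rho_ij, 0.05) when a prior
# row is supplied.
random_monomial <- function(n, phi, prior_row = NULL) {
  phi <- min(phi, n)
  if (phi < 1L) return(integer(0))
  sizes <- 0:phi
  k <- sample(sizes, 1L, prob = c(0.5, 2^(-seq_len(phi))))
  if (k == 0L) return(integer(0))
  w <- if (is.null(prior_row)) rep(1, n) else pmax(prior_row, 0.05)
  sort(sample.int(n, k, prob = w))
}

#' Initialize a population of candidate models
#'
#' Each coordinate polynomial is a random set of monomials from the
#' restricted space (1 to `max_monomials_per_coordinate` of them); when a
#' prior is supplied, variable choice within monomials is biased by the
#' corresponding prior row (sampling weight proportional to
#' `max(rho_ij, 0.05)`).
#'
#' @param spec A `bpds_search_space`.
#' @param priors List with optional `bio`/`reveng` priors; the bio prior
#'   biases sampling.
#' @param config A `bpds_ea_config`.
#' @param variables Optional variable names for the models.
#' @return List of `bpds_model`.
#' @export
init_population <- function(spec, priors = list(), config = ea_config(),
                            variables = NULL) {
  n <- spec$n
  bias <- if (!is.null(priors$bio)) priors$bio$rho else NULL
  lapply(seq_len(config$population_size), function(ind) {
    coords <- lapply(seq_len(n), function(i) {
      k <- sample.int(config$max_monomials_per_coordinate, 1L)
      monos <- lapply(seq_len(k), function(j)
        random_monomial(n, coordinate_phi(spec, i),
                        if (is.null(bias)) NULL else bias[i, ]))
      boolean_polynomial(monos, n)
    })
    polynomial_model(coords, variables)
  })
}

#' Mutate a coordinate polynomial
#'
#' With probability `mutation_rate`, applies one operation chosen uniformly
#' among: add a random monomial from the restricted space, remove a random
#' monomial, or replace one monomial by a random one. The result stays
#' within the restricted space and the monomial cap.
#'
#' @param p A `bpds_polynomial`.
#' @param spec A `bpds_search_space`.
#' @param config A `bpds_ea_config`.
#' @param i Coordinate index (for per-coordinate support bounds and prior
#'   bias).
#' @param prior_row Optional prior row to bias new monomials.
#' @param force Apply an operation unconditionally (used when refreshing the
#'   per-coordinate candidate pools).
#' @return A `bpds_polynomial`.
#' @export
mutate_polynomial <- function(p, spec, config, i = 1L, prior_row = NULL,
                              force = FALSE) {
  if (!force && stats::runif(1) >= config$mutation_rate) return(p)
  phi <- coordinate_phi(spec, i)
  k <- length(p$monomials)
  ops <- c(if (k < config$max_monomials_per_coordinate) "add",
           if (k >= 1L) c("remove", "replace"))
  if (is.null(ops)) ops <- "add"
  op <- if (length(ops) == 1L) ops else sample(ops, 1L)
  monos <- p$monomials
  if (op == "add") {
    new <- random_monomial(p$n, phi, prior_row)
    monos <- c(monos, list(new))  # duplicate cancels mod 2 (removal)
  } else if (op == "remove") {
    monos <- monos[-sample.int(k, 1L)]
  } else {
    monos[[sample.int(k, 1L)]] <- random_monomial(p$n, phi, prior_row)
  }
  boolean_polynomial(monos, p$n)
}

# tournament: pick `size` entrants, return index of the best score
tournament_pick <- function(scores, size) {
  entrants <- sample.int(length(scores), min(size, length(scores)))
  entrants[which.max(scores[entrants])]
}

#' Assemble a model from per-coordinate candidate pools
#'
#' The divide-and-conquer crossover: coordinate `i` of the offspring is
#' drawn from pool `i` by tournament on the coordinate-level score (one-step
#' fit plus prior-row agreement and complexity). The assembled model is then
#' scored as a whole by the caller.
#'
#' @param pools List of `n` pools; pool `i` is a list with elements `polys`
#'   (list of `bpds_polynomial`) and `scores` (numeric).
#' @param config A `bpds_ea_config`.
#' @param variables Optional variable names.
#' @return A `bpds_model`.
#' @export
crossover_assemble <- function(pools, config = ea_config(), variables = NULL) {
  coords <- lapply(pools, function(pool)
    pool$polys[[tournament_pick(pool$scores, config$tournament_size)]])
  polynomial_model(coords, variables)
}

model_key <- function(f)
  paste(vapply(f$coords, `[[`, character(1), "key"), collapse = ";")

#' Run the evolutionary search
#'
#' The main loop. Each generation: (1) coordinate candidates are scored by
#' one-step fit, prior-row agreement, and complexity; (2) new models are
#' assembled by per-coordinate tournament crossover; (3) whole models are
#' scored by the multi-objective fitness; (4) the elite `clone_fraction` is
#' cloned unchanged; (5) the rest are mutated. The run stops when the
#' generation cap is reached, or when some model attains `H_f <= xi` and the
#' best total fitness has improved by less than 1e-9 over 20 generations.
#'
#' @param tss A `bpds_series_set`, already broken at inconsistencies (see
#'   [infer()] for the convenience wrapper).
#' @param priors List with optional elements `bio` and `reveng`.
#' @param config A `bpds_ea_config`.
#' @return An object of class `bpds_result`: ranked model `family` with
#'   fitness reports, `consensus_adjacency` (edge frequencies over the
#'   family), `search_space`, `config`, and a per-generation `log`.
#' @export
evolve <- function(tss, priors = list(), config = ea_config()) {
  if (length(find_inconsistencies(tss)) > 0L)
    stop("time-series set has inconsistencies; run break_inconsistencies first")
  m <- total_length(series_lengths(tss))
  if (m < 1L) stop("no transitions in the input (m = 0); cannot infer")
  spec <- search_space_spec(tss$n, m)
  set.seed(config$seed)
  n <- tss$n
  tt <- transition_table(tss)
  w <- config$weights
  bias <- if (!is.null(priors$bio)) priors$bio$rho else NULL

  # For small n the inner loop runs on truth tables: each unique coordinate
  # polynomial is evaluated once on all 2^n states, after which one-step
  # prediction and free-run simulation are integer table lookups, with
  # XOR + popcount giving Hamming mismatch counts. Exactly equivalent to
  # the direct evaluation path (asserted in the test suite).
  use_tt <- n <= 12L
  if (use_tt) {
    S_all <- all_states(n)
    pow2 <- as.integer(2^(seq_len(n) - 1L))
    idx_all <- 0:(2L^n - 1L)
    popcount <- integer(2L^n)
    for (b in seq_len(n)) popcount <- popcount + (idx_all %/% pow2[b]) %% 2L
    tt_cache <- new.env(parent = emptyenv())
    get_tt <- function(p, key) {
      v <- tt_cache[[key]]
      if (is.null(v)) {
        v <- eval_polynomial(p, S_all)
        tt_cache[[key]] <- v
      }
      v
    }
    zero_tt <- integer(2L^n)
    state_idx <- function(pts) as.integer(pts %*% pow2)
    # per-group free-run scaffolding (fragments simulated in lockstep)
    sim_groups <- lapply(split(seq_along(tss$series),
                               vapply(tss$series, pool_key, character(1))),
                         function(grp) {
      lens <- vapply(grp, function(s) nrow(tss$series[[s]]$points), integer(1))
      obs <- matrix(NA_integer_, length(grp), max(lens))
      for (k in seq_along(grp))
        obs[k, seq_len(lens[k])] <- state_idx(tss$series[[grp[k]]]$points)
      ts1 <- tss$series[[grp[1L]]]
      list(series = grp, lens = lens, obs = obs,
           ko = if (ts1$kind == "knockout") ts1$ko_target else 0L)
    })
    x_idx <- state_idx(tt$X)
  }

  hfi_cache <- new.env(parent = emptyenv())
  get_hfi <- function(i, p, key) {
    ck <- paste0(i, "|", key)
    v <- hfi_cache[[ck]]
    if (is.null(v)) {
      v <- if (use_tt && nrow(tt$X) > 0L) {
        own_ko <- tt$ko == i
        pred <- integer(length(x_idx))
        if (any(!own_ko)) pred[!own_ko] <- get_tt(p, key)[x_idx[!own_ko] + 1L]
        sum(pred != tt$Y[, i]) / tt$alpha_total
      } else coordinate_hamming(p, i, tss, tt)
      hfi_cache[[ck]] <- v
    }
    v
  }

  fast_model_hamming <- function(f, coord_keys) {
    tts <- lapply(seq_len(n), function(i) get_tt(f$coords[[i]], coord_keys[i]))
    nser <- length(tss$series)
    d_mu <- numeric(nser)
    bits <- numeric(nser)
    is_wt <- vapply(tss$series, function(ts) ts$kind == "wildtype", logical(1))
    for (grp in sim_groups) {
      tg <- tts
      if (grp$ko > 0L) tg[[grp$ko]] <- zero_tt
      bits[grp$series] <- grp$lens * n
      s <- grp$obs[, 1L]
      d <- numeric(length(grp$series))
      for (t in seq_len(max(grp$lens) - 1L) + 1L) {
        active <- which(grp$lens >= t)
        if (length(active) == 0L) break
        sa <- s[active] + 1L
        pred <- integer(length(active))
        for (i in seq_len(n)) pred <- pred + tg[[i]][sa] * pow2[i]
        d[active] <- d[active] + popcount[bitwXor(pred, grp$obs[active, t]) + 1L]
        s[active] <- pred
      }
      d_mu[grp$series] <- d
    }
    h_wt <- if (any(is_wt)) sum(d_mu[is_wt]) / sum(bits[is_wt]) else NA_real_
    h_ko <- if (any(!is_wt)) sum(d_mu[!is_wt]) / sum(bits[!is_wt]) else NA_real_
    list(h_f = sum(d_mu) / sum(bits), h_wildtype = h_wt, h_knockout = h_ko,
         d_mu = d_mu)
  }
  coord_score <- function(i, p, key) {
    phi_i <- coordinate_phi(spec, i)
    comp <- if (phi_i == 0L) 0 else total_degree(p) / phi_i
    sc <- w$w_hp * (1 - get_hfi(i, p, key)) + w$w_c * (1 - comp)
    if (!is.null(priors$bio)) sc <- sc + w$w_b * prior_row_score(p, i, priors$bio)
    if (!is.null(priors$reveng))
      sc <- sc + w$w_re * prior_row_score(p, i, priors$reveng)
    sc
  }
  fit_cache <- new.env(parent = emptyenv())
  evaluate_model <- function(f, key) {
    fit <- fit_cache[[key]]
    if (!is.null(fit)) return(fit)
    coord_keys <- vapply(f$coords, `[[`, character(1), "key")
    mh <- if (use_tt) fast_model_hamming(f, coord_keys) else model_hamming(f, tss)
    h_fi <- vapply(seq_len(n), function(i)
      get_hfi(i, f$coords[[i]], coord_keys[i]), numeric(1))
    comp <- complexity_score(f, spec$phi)
    bio <- prior_score(f, priors$bio)
    reveng <- prior_score(f, priors$reveng)
    total <- w$w_hm * (1 - mh$h_f) + w$w_hp * mean(1 - h_fi) +
      w$w_c * (1 - comp$model) +
      (if (is.null(bio)) 0 else w$w_b * bio$model) +
      (if (is.null(reveng)) 0 else w$w_re * reveng$model)
    fit <- structure(list(
      h_f = mh$h_f, h_wildtype = mh$h_wildtype, h_knockout = mh$h_knockout,
      d_mu = mh$d_mu, h_fi = h_fi,
      model_fit = w$w_hm * (1 - mh$h_f),
      polynomial_fit = w$w_hp * (1 - h_fi),
      complexity = comp$per_coordinate, model_complexity = comp$model,
      bio_score = if (is.null(bio)) NA_real_ else bio$model,
      reveng_score = if (is.null(reveng)) NA_real_ else reveng$model,
      data_consistent = mh$h_f <= config$xi + 1e-12,
      total = total), class = "bpds_fitness")
    fit_cache[[key]] <- fit
    fit
  }

  population <- init_population(spec, priors, config, tss$variables)
  n_elite <- max(1L, as.integer(round(config$clone_fraction *
                                        config$population_size)))
  pool_size <- config$population_size
  log_gen <- integer(0); log_best <- numeric(0); log_hf <- numeric(0)
  stagnation_window <- 20L

  # persistent per-coordinate candidate pools (the lower tier of the
  # divide-and-conquer search), seeded from the initial model population
  ranked_pool <- function(i, polys) {
    pkeys <- vapply(polys, `[[`, character(1), "key")
    uniq <- !duplicated(pkeys)
    polys <- polys[uniq]; pkeys <- pkeys[uniq]
    scores <- vapply(seq_along(polys), function(j)
      coord_score(i, polys[[j]], pkeys[j]), numeric(1))
    degs <- vapply(polys, total_degree, integer(1))
    keep <- order(-scores, degs, pkeys,
                  method = "radix")[seq_len(min(pool_size, length(polys)))]
    list(polys = polys[keep], keys = pkeys[keep], scores = scores[keep])
  }
  pools <- lapply(seq_len(n), function(i)
    ranked_pool(i, lapply(population, function(f) f$coords[[i]])))

  for (gen in seq_len(config$generations)) {
    keys <- vapply(population, model_key, character(1))
    fits <- lapply(seq_along(population), function(j)
      evaluate_model(population[[j]], keys[j]))
    totals <- vapply(fits, `[[`, numeric(1), "total")
    comps <- vapply(fits, `[[`, numeric(1), "model_complexity")
    rank_order <- order(-totals, comps, keys, method = "radix")
    best <- rank_order[1L]
    log_gen <- c(log_gen, gen)
    log_best <- c(log_best, totals[best])
    log_hf <- c(log_hf, fits[[best]]$h_f)
    if (gen >= stagnation_window && fits[[best]]$h_f <= config$xi + 1e-12) {
      window <- log_best[(gen - stagnation_window + 1L):gen]
      if (max(window) - min(window) < 1e-9) break
    }
    if (gen == config$generations) break

    # lower tier: refresh each coordinate pool by mutating
    # tournament-selected members, then re-rank (pool elites survive)
    for (i in seq_len(n)) {
      parents <- pools[[i]]
      fresh <- lapply(seq_len(max(pool_size %/% 2L, 1L)), function(j)
        mutate_polynomial(
          parents$polys[[tournament_pick(parents$scores,
                                         config$tournament_size)]],
          spec, config, i,
          prior_row = if (is.null(bias)) NULL else bias[i, ],
          force = TRUE))
      model_coords <- lapply(population, function(f) f$coords[[i]])
      pools[[i]] <- ranked_pool(i, c(parents$polys, fresh, model_coords))
    }

    # upper tier: clone elites, assemble offspring from the pools, mutate
    elites <- population[rank_order[seq_len(n_elite)]]
    offspring <- vector("list", config$population_size - n_elite)
    for (j in seq_along(offspring)) {
      child <- if (stats::runif(1) < config$crossover_rate)
        crossover_assemble(pools, config, tss$variables)
      else population[[tournament_pick(totals, config$tournament_size)]]
      coords <- child$coords
      for (i in seq_len(n))
        coords[[i]] <- mutate_polynomial(
          coords[[i]], spec, config, i,
          if (is.null(bias)) NULL else bias[i, ])
      offspring[[j]] <- polynomial_model(coords, tss$variables)
    }
    population <- c(elites, offspring)
  }

  # final ranking over the last evaluated population, deduplicated
  keys <- vapply(population, model_key, character(1))
  fits <- lapply(seq_along(population), function(j)
    evaluate_model(population[[j]], keys[j]))
  uniq <- !duplicated(keys)
  population <- population[uniq]; fits <- fits[uniq]; keys <- keys[uniq]
  totals <- vapply(fits, `[[`, numeric(1), "total")
  comps <- vapply(fits, `[[`, numeric(1), "model_complexity")
  rank_order <- order(-totals, comps, keys, method = "radix")
  fam_idx <- rank_order[seq_len(min(config$output_family_size,
                                    length(rank_order)))]
  family <- lapply(fam_idx, function(j)
    list(model = population[[j]], fitness = fits[[j]]))
  consensus <- Reduce(`+`, lapply(family, function(e)
    adjacency_matrix(e$model))) / length(family)
  structure(list(
    family = family, consensus_adjacency = consensus,
    search_space = spec, config = config,
    log = data.frame(generation = log_gen, best_total = log_best,
                     best_h_f = log_hf)), class = "bpds_result")
}

#' Infer a family of Boolean dynamic models from time-series data
#'
#' Convenience entry point: breaks the input at inconsistencies, then runs
#' [evolve()].
#'
#' @inheritParams evolve
#' @return A `bpds_result`.
#' @export
infer <- function(tss, priors = list(), config = ea_config()) {
  evolve(break_inconsistencies(tss), priors, config)
}

#' Consensus network of an inference result
#'
#' Thresholds the edge-frequency matrix accumulated over the output family:
#' an edge is kept when at least `threshold` of the family's models contain
#' it.
#'
#' @param result A `bpds_result`.
#' @param threshold Frequency threshold in `(0, 1]`.
#' @return Binary adjacency matrix.
#' @export
consensus_network <- function(result, threshold = 0.5) {
  V <- (result$consensus_adjacency >= threshold) * 1L
  storage.mode(V) <- "integer"
  V
}

#' @export
print.bpds_result <- function(x, ...) {
  best <- x$family[[1L]]
  cat(sprintf("BPDS inference result: family of %d models, %d generations run\n",
              length(x$family), nrow(x$log)))
  print(x$search_space)
  cat(sprintf("Best model: total fitness %.4f, H_f = %.4f (%s)\n",
              best$fitness$total, best$fitness$h_f,
              if (best$fitness$data_consistent) "data-consistent"
              else "not data-consistent"))
  cat(format_model(best$model), sep = "\n")
  invisible(x)
}

#' Latin hypercube sampling of EA parameter sets
#'
#' Splits each parameter's range into `n_sets` equal strata and draws one
#' point per stratum, with strata permuted independently per parameter (the
#' standard LHS projection property). Integer-valued parameters are rounded.
#'
#' @param param_ranges Named list of length-2 numeric ranges; names must be
#'   `ea_config` arguments (e.g. `population_size`, `mutation_rate`).
#' @param n_sets Number of parameter sets to draw.
#' @param seed Integer seed.
#' @param base Base `bpds_ea_config` supplying the unsampled parameters.
#' @return List of `n_sets` `bpds_ea_config` objects; the raw design matrix
#'   is attached as attribute `design`.
#' @export
lhs_sample <- function(param_ranges, n_sets, seed,
                       base = ea_config()) {
  stopifnot(length(param_ranges) >= 1L, n_sets >= 1L)
  integer_params <- c("population_size", "generations", "tournament_size",
                      "max_monomials_per_coordinate", "output_family_size")
  set.seed(seed)
  U <- lhs::randomLHS(n_sets, length(param_ranges))
  colnames(U) <- names(param_ranges)
  design <- U
  configs <- vector("list", n_sets)
  weight_params <- c("w_hm", "w_hp", "w_c", "w_b", "w_re")
  for (s in seq_len(n_sets)) {
    cfg <- unclass(base)
    for (p in names(param_ranges)) {
      r <- param_ranges[[p]]
      val <- r[1] + (r[2] - r[1]) * U[s, p]
      if (p %in% integer_params) val <- as.integer(round(val))
      design[s, p] <- val
      if (p %in% weight_params) cfg$weights[[p]] <- val else cfg[[p]] <- val
    }
    configs[[s]] <- do.call(ea_config, cfg)
  }
  attr(configs, "design") <- design
  configs
}
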