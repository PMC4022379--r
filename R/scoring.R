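# Fitness components: free-run model fit, one-step coordinate fit,
# complexity, and prior-knowledge agreement, plus their weighted sum.

#' Fitness weights
#'
#' Non-negative weights for the multi-objective fitness: `w_hm` (model-level
#' data fit), `w_hp` (coordinate-level data fit), `w_c` (complexity,
#' rewarding low total degree), `w_b` (biological prior), `w_re`
#' (reverse-engineering/meta-inference prior).
#'
#' @param w_hm,w_hp,w_c,w_b,w_re Non-negative reals; at least one positive.
#' @return An object of class `bpds_weights`.
#' @export
fitness_weights <- function(w_hm = 1, w_hp = 1, w_c = 0.1, w_b = 0.5,
                            w_re = 0.5) {
  w <- c(w_hm = w_hm, w_hp = w_hp, w_c = w_c, w_b = w_b, w_re = w_re)
  if (any(w < 0)) stop("weights must be non-negative")
  if (all(w == 0)) stop("at least one weight must be positive")
  structure(as.list(w), class = "bpds_weights")
}

#' Model-level goodness of fit (free-run Hamming score)
#'
#' For each fragment, the model is iterated synchronously from the fragment's
#' first observed state for the fragment's full length; knock-out fragments
#' use the perturbed model with the silenced coordinate zeroed. The Hamming
#' score is the total bit disagreement divided by `n * sum(alpha)`; wildtype
#' and knock-out contributions combine by total bit count.
#'
#' @param f A `bpds_model`.
#' @param tss A `bpds_series_set`, already broken at inconsistencies.
#' @return List: `h_f` (combined score in `[0, 1]`), `h_wildtype`, `h_knockout`
#'   (NA when absent), `d_mu` (per-fragment mismatch counts).
#' @export
model_hamming <- function(f, tss) {
  if (length(tss$series) == 0L) stop("empty time-series set")
  nser <- length(tss$series)
  d_mu <- numeric(nser)
  bits <- numeric(nser)
  is_wt <- vapply(tss$series, function(ts) ts$kind == "wildtype", logical(1))
  groups <- split(seq_len(nser),
                  vapply(tss$series, pool_key, character(1)))
  for (grp in groups) {
    ts1 <- tss$series[[grp[1L]]]
    g <- if (ts1$kind == "knockout") knockout_model(f, ts1$ko_target) else f
    lens <- vapply(grp, function(s) nrow(tss$series[[s]]$points), integer(1))
    bits[grp] <- lens * tss$n
    # simulate all fragments of the group in lockstep, masking finished ones
    S <- do.call(rbind, lapply(grp, function(s)
      tss$series[[s]]$points[1L, , drop = FALSE]))
    for (t in seq_len(max(lens) - 1L) + 1L) {
      active <- which(lens >= t)
      if (length(active) == 0L) break
      Sa <- S[active, , drop = FALSE]
      nxt <- matrix(0L, nrow(Sa), tss$n)
      for (i in seq_len(tss$n))
        nxt[, i] <- eval_polynomial(g$coords[[i]], Sa)
      obs <- do.call(rbind, lapply(grp[active], function(s)
        tss$series[[s]]$points[t, , drop = FALSE]))
      d_mu[grp[active]] <- d_mu[grp[active]] + rowSums(nxt != obs)
      S[active, ] <- nxt
    }
  }
  h_wt <- if (any(is_wt)) sum(d_mu[is_wt]) / sum(bits[is_wt]) else NA_real_
  h_ko <- if (any(!is_wt)) sum(d_mu[!is_wt]) / sum(bits[!is_wt]) else NA_real_
  list(h_f = sum(d_mu) / sum(bits), h_wildtype = h_wt, h_knockout = h_ko,
       d_mu = d_mu)
}

#' Stack the observed transitions of a series set
#'
#' Collects every within-fragment (from, to) state pair for one-step
#' scoring: `X` holds the observed predecessor states, `Y` the observed
#' successors, `ko` the knock-out target of the fragment each row came from
#' (0 for wildtype), and `alpha_total` the summed fragment lengths
#' (the denominator of the coordinate Hamming score). Precompute once and
#' pass to [coordinate_hamming()] when scoring many candidates.
#'
#' @param tss A `bpds_series_set`.
#' @return List with `X`, `Y`, `ko`, `alpha_total`.
#' @export
transition_table <- function(tss) {
  X <- list(); Y <- list(); ko <- list()
  for (ts in tss$series) {
    a <- nrow(ts$points)
    if (a < 2L) next
    X[[length(X) + 1L]] <- ts$points[-a, , drop = FALSE]
    Y[[length(Y) + 1L]] <- ts$points[-1L, , drop = FALSE]
    ko[[length(ko) + 1L]] <- rep(if (ts$kind == "knockout") ts$ko_target else 0L,
                                 a - 1L)
  }
  if (length(X) == 0L)
    return(list(X = matrix(integer(0), 0L, tss$n),
                Y = matrix(integer(0), 0L, tss$n), ko = integer(0),
                alpha_total = sum(series_lengths(tss))))
  list(X = do.call(rbind, X), Y = do.call(rbind, Y),
       ko = unlist(ko), alpha_total = sum(series_lengths(tss)))
}

#' Coordinate-level goodness of fit (one-step Hamming score)
#'
#' Under the synchronous schedule, the value of node `i` at time `t` depends
#' only on the observed full state at `t - 1`, so each coordinate function is
#' scored on its own: predictions `f_i(t_j)` are compared against the
#' observed column `i` at `t_{j+1}` over every transition of every fragment.
#' Fragments knocking out node `i` itself use the zero function (prediction
#' 0); other knock-out targets leave `f_i` unchanged. The score divides total
#' mismatches by the summed fragment lengths.
#'
#' @param p_i A `bpds_polynomial`, the candidate for coordinate `i`.
#' @param i Coordinate index.
#' @param tss A `bpds_series_set`, already broken at inconsistencies.
#' @param tt Optional precomputed [transition_table()] of `tss`.
#' @return Scalar score in `[0, 1]`.
#' @export
coordinate_hamming <- function(p_i, i, tss, tt = NULL) {
  i <- as.integer(i)
  if (i < 1L || i > tss$n) stop("coordinate index out of range")
  if (is.null(tt)) tt <- transition_table(tss)
  if (nrow(tt$X) == 0L) return(0)
  own_ko <- tt$ko == i
  pred <- integer(nrow(tt$X))
  if (any(!own_ko))
    pred[!own_ko] <- eval_polynomial(p_i, tt$X[!own_ko, , drop = FALSE])
  mism <- sum(pred != tt$Y[, i])
  mism / tt$alpha_total
}

#' Complexity score of a model
#'
#' Each coordinate's complexity is the ratio of its total degree to the
#' support bound `Phi`; the model complexity is the coordinate average. Lower
#' is simpler; the weighted fitness rewards `1 - complexity`.
#'
#' @param f A `bpds_model`.
#' @param phi Support bound of the search space.
#' @return List: `per_coordinate` (vector of ratios) and `model` (mean).
#' @export
complexity_score <- function(f, phi) {
  degs <- vapply(f$coords, total_degree, integer(1))
  if (any(degs > phi))
    stop("coordinate total degree exceeds Phi = ", phi,
         "; candidate is outside the search space")
  per <- if (phi == 0L) rep(0, f$n) else degs / phi
  list(per_coordinate = per, model = mean(per))
}

#' Prior-knowledge agreement score
#'
#' For prior matrix `rho` (probability that node `j` regulates node `i`) and
#' model adjacency `V`, the per-entry agreement is `beta[i, j] = rho[i, j]`
#' when the edge is present and `1 - rho[i, j]` when absent. Coordinate
#' scores average over regulators; the model score averages over
#' coordinates. An uninformative prior (`rho = 0.5` everywhere) scores 0.5
#' for every model.
#'
#' @param f A `bpds_model`.
#' @param prior A `bpds_prior` (or `NULL`, returning `NULL`).
#' @return List: `per_coordinate` and `model`, both in `[0, 1]`.
#' @export
prior_score <- function(f, prior) {
  if (is.null(prior)) return(NULL)
  if (prior$n != f$n) stop("prior matrix dimension mismatch")
  V <- adjacency_matrix(f)
  beta <- ifelse(V == 1L, prior$rho, 1 - prior$rho)
  per <- rowMeans(beta)
  list(per_coordinate = as.numeric(per), model = mean(per))
}

prior_row_score <- function(p_i, i, prior) {
  # coordinate-level prior agreement from the polynomial's own support
  sup <- unique(unlist(p_i$monomials))
  v <- integer(prior$n)
  if (length(sup)) v[sup] <- 1L
  mean(ifelse(v == 1L, prior$rho[i, ], 1 - prior$rho[i, ]))
}

#' Full multi-objective fitness of a candidate model
#'
#' The weighted sum
#' `w_hm*(1 - H_f) + w_hp*mean_i(1 - H_fi) + w_c*(1 - complexity) +
#' w_b*BioScore + w_re*RevEngScore`. Missing priors contribute nothing. The
#' report also flags the model data-consistent when `H_f <= xi`, the assumed
#' noise fraction: models are allowed to disagree with the data commensurate
#' with expected noise.
#'
#' @param f A `bpds_model`.
#' @param tss A `bpds_series_set`, already broken at inconsistencies.
#' @param priors List with optional elements `bio` and `reveng`
#'   (`bpds_prior`).
#' @param weights A `bpds_weights`.
#' @param spec A `bpds_search_space` (for `Phi`).
#' @param tt Optional precomputed [transition_table()].
#' @return An object of class `bpds_fitness` carrying all components.
#' @export
total_fitness <- function(f, tss, priors = list(), weights = fitness_weights(),
                          spec, tt = NULL) {
  if (is.null(tt)) tt <- transition_table(tss)
  mh <- model_hamming(f, tss)
  h_fi <- vapply(seq_len(f$n), function(i)
    coordinate_hamming(f$coords[[i]], i, tss, tt), numeric(1))
  comp <- complexity_score(f, spec$phi)
  bio <- prior_score(f, priors$bio)
  reveng <- prior_score(f, priors$reveng)
  total <- weights$w_hm * (1 - mh$h_f) +
    weights$w_hp * mean(1 - h_fi) +
    weights$w_c * (1 - comp$model) +
    (if (is.null(bio)) 0 else weights$w_b * bio$model) +
    (if (is.null(reveng)) 0 else weights$w_re * reveng$model)
  structure(list(
    h_f = mh$h_f, h_wildtype = mh$h_wildtype, h_knockout = mh$h_knockout,
    d_mu = mh$d_mu, h_fi = h_fi,
    model_fit = weights$w_hm * (1 - mh$h_f),
    polynomial_fit = weights$w_hp * (1 - h_fi),
    complexity = comp$per_coordinate, model_complexity = comp$model,
    bio_score = if (is.null(bio)) NA_real_ else bio$model,
    reveng_score = if (is.null(reveng)) NA_real_ else reveng$model,
    data_consistent = mh$h_f <= tss$xi + 1e-12,
    total = total), class = "bpds_fitness")
}

#' @export
print.bpds_fitness <- function(x, ...) {
  cat(sprintf("Fitness: total = %.4f, H_f = %.4f (%s), mean H_fi = %.4f, complexity = %.3f\n",
              x$total, x$h_f,
              if (x$data_consistent) "data-consistent" else "inconsistent",
              mean(x$h_fi), x$model_complexity))
  if (!is.na(x$bio_score))
    cat(sprintf("  BioScore = %.3f\n", x$bio_score))
  if (!is.na(x$reveng_score))
    cat(sprintf("  RevEngScore = %.3f\n", x$reveng_score))
  invisible(x)
}

fitness_to_list <- function(fit) {
  lapply(unclass(fit), function(v) if (is.numeric(v)) unname(v) else v)
}
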