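# Discretization of continuous time courses. Binary (s = 2) output feeds
# the inference engine; s > 2 levels exist only for export to external
# tools in meta-inference workflows.

discretize_column <- function(values, thresholds) {
  # ties at a threshold go down: level = #(thresholds strictly below value)
  vapply(values, function(v) sum(v > thresholds), integer(1))
}

#' Quantile discretization of continuous series
#'
#' Per-variable thresholds at the `j/s` quantiles (j = 1..s-1) of that
#' variable's values pooled across all supplied series; values at or below a
#' threshold take the lower level. Invariant under strictly monotone
#' per-column transforms. Constant columns discretize to 0 (no information;
#' a warning is emitted).
#'
#' @param tss A `bpds_series_set` of continuous series.
#' @param s Number of levels (>= 2). Only `s = 2` output is binary and usable
#'   by the inference engine.
#' @return A `bpds_series_set`; binary when `s = 2`, otherwise integer levels
#'   `0..s-1` flagged continuous (for export only).
#' @examples
#' ts <- time_series(matrix(c(1, 2, 3, 4), ncol = 1), continuous = TRUE)
#' tss <- time_series_set(list(ts))
#' discretize_quantile(tss, 2)$series[[1]]$points  # 0 0 1 1
#' @export
discretize_quantile <- function(tss, s = 2L) {
  discretize_with(tss, s, function(pooled, s) {
    if (length(unique(pooled)) == 1L) return(NULL)  # constant column
    stats::quantile(pooled, probs = seq_len(s - 1L) / s, names = FALSE,
                    type = 7)
  })
}

#' Interval (equal-width) discretization of continuous series
#'
#' Per-variable equal-width bins over the pooled `[min, max]` range; the
#' maximum maps to the top level. Constant columns discretize to 0.
#'
#' @inheritParams discretize_quantile
#' @return A `bpds_series_set`.
#' @export
discretize_interval <- function(tss, s = 2L) {
  discretize_with(tss, s, function(pooled, s) {
    lo <- min(pooled); hi <- max(pooled)
    if (lo == hi) return(NULL)
    lo + (hi - lo) * seq_len(s - 1L) / s
  })
}

discretize_with <- function(tss, s, threshold_fn) {
  s <- as.integer(s)
  if (s < 2L) stop("number of levels must be at least 2")
  pooled <- do.call(rbind, lapply(tss$series, `[[`, "points"))
  if (any(!is.finite(pooled))) stop("continuous data must be finite")
  thresholds <- vector("list", tss$n)
  for (j in seq_len(tss$n)) {
    thr <- threshold_fn(pooled[, j], s)
    if (is.null(thr)) {
      warning("column ", tss$variables[j],
              " is constant; discretized to all 0")
      thr <- Inf  # everything below -> level 0
    }
    thresholds[[j]] <- thr
  }
  series <- lapply(tss$series, function(ts) {
    disc <- ts$points
    for (j in seq_len(ncol(disc)))
      disc[, j] <- discretize_column(ts$points[, j], thresholds[[j]])
    time_series(disc, kind = ts$kind, ko_target = ts$ko_target,
                label = ts$label, continuous = s > 2L)
  })
  time_series_set(series, xi = tss$xi, variables = tss$variables)
}
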