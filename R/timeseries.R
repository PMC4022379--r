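# Binary time-series containers, inconsistency handling, noise injection,
# and the TSV/JSON file formats.

#' Construct a time series
#'
#' A single time course: an `alpha` x `n` matrix of measurements (binary for
#' inference; real-valued for continuous series awaiting discretization),
#' labelled wildtype or knock-out. Knock-out series carry the index of the
#' silenced node.
#'
#' @param points Numeric matrix, one row per time point.
#' @param kind `"wildtype"` or `"knockout"`.
#' @param ko_target Index of the silenced node (knock-out series only).
#' @param label Free-text label.
#' @param continuous Logical: set for real-valued series; binary entries are
#'   enforced otherwise.
#' @return An object of class `bpds_series`.
#' @export
time_series <- function(points, kind = c("wildtype", "knockout"),
                        ko_target = NULL, label = "", continuous = FALSE) {
  kind <- match.arg(kind)
  points <- as.matrix(points)
  if (nrow(points) < 1L) stop("a series needs at least one time point")
  if (!continuous) {
    if (!all(points %in% c(0, 1))) stop("binary series entries must be 0/1")
    storage.mode(points) <- "integer"
  }
  if (kind == "knockout") {
    if (is.null(ko_target)) stop("knock-out series need ko_target")
    ko_target <- as.integer(ko_target)
    if (ko_target < 1L || ko_target > ncol(points))
      stop("ko_target out of range")
  } else if (!is.null(ko_target)) {
    stop("wildtype series cannot carry ko_target")
  }
  structure(list(points = points, kind = kind, ko_target = ko_target,
                 label = label, continuous = continuous),
            class = "bpds_series")
}

#' Construct a set of time series
#'
#' Orders wildtype series first, then perturbation series, and records the
#' assumed noise fraction `xi`: the proportion of entries presumed flipped by
#' measurement noise or discretization, with which inferred models are
#' allowed to disagree.
#'
#' @param series List of `bpds_series` sharing the same number of variables.
#' @param xi Assumed noise fraction in `[0, 1)`.
#' @param variables Optional variable names.
#' @return An object of class `bpds_series_set`.
#' @export
time_series_set <- function(series, xi = 0, variables = NULL) {
  stopifnot(length(series) >= 1L)
  n <- ncol(series[[1L]]$points)
  for (ts in series) {
    if (!inherits(ts, "bpds_series")) stop("series must be bpds_series objects")
    if (ncol(ts$points) != n) stop("all series must share n")
  }
  if (xi < 0 || xi >= 1) stop("xi must lie in [0, 1)")
  if (is.null(variables)) variables <- paste0("x", seq_len(n))
  stopifnot(length(variables) == n)
  kinds <- vapply(series, `[[`, character(1), "kind")
  series <- c(series[kinds == "wildtype"], series[kinds == "knockout"])
  structure(list(series = series, xi = xi, n = n, variables = variables),
            class = "bpds_series_set")
}

#' @export
print.bpds_series_set <- function(x, ...) {
  kinds <- vapply(x$series, `[[`, character(1), "kind")
  cat(sprintf("Time-series set: %d variables, %d series (%d wildtype, %d knock-out), xi = %g\n",
              x$n, length(x$series), sum(kinds == "wildtype"),
              sum(kinds == "knockout"), x$xi))
  invisible(x)
}

series_lengths <- function(tss) vapply(tss$series, function(s) nrow(s$points),
                                       integer(1))

# Pooling key: a deterministic model must explain all wildtype series
# jointly; each knock-out target is explained by its own perturbed model, so
# targets pool separately.
pool_key <- function(ts) {
  if (ts$kind == "wildtype") "wildtype" else paste0("ko:", ts$ko_target)
}

state_key <- function(row) paste(row, collapse = "")

#' Find inconsistent transitions in a time-series set
#'
#' A state is inconsistent when, within the pooled transitions of one group
#' (all wildtype series together; each knock-out target separately), it is
#' observed to transition to two or more distinct successor states --
#' precluding a deterministic explanation.
#'
#' @param tss A `bpds_series_set`.
#' @return List with one entry per inconsistent state: `state` (binary
#'   vector), `successors` (matrix of distinct successors), `pool` (group
#'   key).
#' @export
find_inconsistencies <- function(tss) {
  out <- list()
  for (pk in unique(vapply(tss$series, pool_key, character(1)))) {
    succ <- new.env(parent = emptyenv())
    for (ts in tss$series) {
      if (pool_key(ts) != pk) next
      pts <- ts$points
      if (nrow(pts) < 2L) next
      for (j in seq_len(nrow(pts) - 1L)) {
        k <- state_key(pts[j, ])
        succ[[k]] <- unique(rbind(succ[[k]], pts[j + 1L, , drop = FALSE]))
      }
    }
    for (k in ls(succ)) {
      if (nrow(succ[[k]]) >= 2L) {
        out[[length(out) + 1L]] <- list(
          state = as.integer(strsplit(k, "")[[1]]),
          successors = succ[[k]], pool = pk)
      }
    }
  }
  out
}

#' Break a time-series set at its inconsistencies
#'
#' Removes every transition out of an inconsistent state (no successor is
#' preferred over another) by splitting the affected series into maximal
#' consistent fragments. Fragments of length 1 are retained but contribute no
#' transitions to the total length `m`. Idempotent.
#'
#' @param tss A `bpds_series_set`.
#' @return A `bpds_series_set` of consistent fragments.
#' @export
break_inconsistencies <- function(tss) {
  inc <- find_inconsistencies(tss)
  if (length(inc) == 0L) return(tss)
  bad <- new.env(parent = emptyenv())
  for (e in inc) bad[[paste0(e$pool, "|", state_key(e$state))]] <- TRUE
  frags <- list()
  for (ts in tss$series) {
    pts <- ts$points
    pk <- pool_key(ts)
    cut_after <- logical(max(nrow(pts) - 1L, 0L))
    if (nrow(pts) >= 2L) for (j in seq_len(nrow(pts) - 1L))
      cut_after[j] <- !is.null(bad[[paste0(pk, "|", state_key(pts[j, ]))]])
    start <- 1L
    piece <- 0L
    for (j in seq_len(nrow(pts))) {
      end_here <- j == nrow(pts) || cut_after[j]
      if (end_here) {
        piece <- piece + 1L
        lab <- if (piece == 1L && j == nrow(pts)) ts$label
               else sprintf("%s#%d", ts$label, piece)
        frags[[length(frags) + 1L]] <- time_series(
          pts[start:j, , drop = FALSE], kind = ts$kind,
          ko_target = ts$ko_target, label = lab,
          continuous = ts$continuous)
        start <- j + 1L
      }
    }
  }
  time_series_set(frags, xi = tss$xi, variables = tss$variables)
}

#' Inject bit-flip noise into a binary time-series set
#'
#' Flips exactly `round(xi * total_points * n)` uniformly chosen distinct bit
#' positions (rounding half up), emulating the noise model under which the
#' inference is validated. Seeded and reproducible.
#'
#' @param tss A `bpds_series_set` (binary).
#' @param xi Noise fraction in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `tss` (the noisy copy) and `flips` (data frame of
#'   series/row/column positions flipped).
#' @export
inject_noise <- function(tss, xi, seed) {
  if (xi < 0 || xi >= 1) stop("xi must lie in [0, 1)")
  total_points <- sum(series_lengths(tss))
  n_bits <- total_points * tss$n
  n_flips <- floor(xi * n_bits + 0.5)  # round half up
  flat <- data.frame(series = integer(0), row = integer(0), col = integer(0))
  for (s in seq_along(tss$series)) {
    pts <- tss$series[[s]]$points
    flat <- rbind(flat, expand.grid(series = s, row = seq_len(nrow(pts)),
                                    col = seq_len(ncol(pts))))
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  picks <- if (n_flips > 0L) sample(nrow(flat), n_flips) else integer(0)
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  noisy <- tss
  flips <- flat[picks, , drop = FALSE]
  for (k in seq_len(nrow(flips))) {
    s <- flips$series[k]
    noisy$series[[s]]$points[flips$row[k], flips$col[k]] <-
      1L - noisy$series[[s]]$points[flips$row[k], flips$col[k]]
  }
  rownames(flips) <- NULL
  list(tss = noisy, flips = flips)
}

#' Read and write time-series sets as TSV blocks with a JSON manifest
#'
#' The TSV holds one block per series, blocks separated by blank lines. Each
#' block starts with `#series <label> kind=<wildtype|knockout> ko=<name|->`,
#' then a header of variable names, then one tab-separated row per time
#' point. A manifest JSON (`<path stem>_manifest.json`) records variables,
#' `xi`, and per-series metadata, and is written beside every output.
#'
#' @param tss A `bpds_series_set`.
#' @param path TSV path.
#' @return `write_timeseries`: `path` invisibly; `read_timeseries`: a
#'   `bpds_series_set`.
#' @export
write_timeseries <- function(tss, path) {
  lines <- character(0)
  for (ts in tss$series) {
    ko_name <- if (ts$kind == "knockout") tss$variables[ts$ko_target] else "-"
    lines <- c(lines, sprintf("#series %s kind=%s ko=%s",
                              ifelse(ts$label == "", "-", ts$label),
                              ts$kind, ko_name),
               paste(tss$variables, collapse = "\t"),
               apply(ts$points, 1L, paste, collapse = "\t"),
               "")
  }
  writeLines(lines[-length(lines)], path)
  manifest <- list(
    variables = tss$variables, xi = tss$xi,
    series = lapply(tss$series, function(ts) list(
      label = ts$label, kind = ts$kind,
      ko = if (ts$kind == "knockout") tss$variables[ts$ko_target] else NULL)))
  jsonlite::write_json(manifest, manifest_path(path), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

manifest_path <- function(path)
  paste0(tools::file_path_sans_ext(path), "_manifest.json")

#' @rdname write_timeseries
#' @param xi Noise fraction to attach when no manifest is found.
#' @export
read_timeseries <- function(path, xi = NULL) {
  lines <- readLines(path)
  heads <- grep("^#series ", lines)
  if (length(heads) == 0L) stop("no series blocks found in ", path)
  if (is.null(xi)) {
    mp <- manifest_path(path)
    xi <- if (file.exists(mp)) jsonlite::read_json(mp)$xi else 0
  }
  series <- list()
  variables <- NULL
  bounds <- c(heads, length(lines) + 1L)
  for (b in seq_along(heads)) {
    block <- lines[heads[b]:(bounds[b + 1L] - 1L)]
    block <- block[trimws(block) != "" | seq_along(block) == 1L]
    hdr <- block[1L]
    parts <- regmatches(hdr, regexec("^#series (\\S+) kind=(\\S+) ko=(\\S+)$",
                                     hdr))[[1]]
    if (length(parts) != 4L) stop("malformed series header: ", hdr)
    vars <- strsplit(block[2L], "\t", fixed = TRUE)[[1]]
    if (is.null(variables)) variables <- vars
    else if (!identical(vars, variables))
      stop("series blocks disagree on variable names")
    rows <- block[-(1:2)]
    rows <- rows[trimws(rows) != ""]
    vals <- do.call(rbind, lapply(strsplit(rows, "\t", fixed = TRUE),
                                  as.numeric))
    continuous <- any(vals != round(vals)) || any(vals < 0) || any(vals > 1)
    ko <- NULL
    if (parts[3L] == "knockout") {
      ko <- match(parts[4L], variables)
      if (is.na(ko)) stop("unknown knock-out variable ", parts[4L])
    }
    series[[b]] <- time_series(vals, kind = parts[3L], ko_target = ko,
                               label = ifelse(parts[2L] == "-", "", parts[2L]),
                               continuous = continuous)
  }
  time_series_set(series, xi = xi, variables = variables)
}

#' Read and write prior-probability matrices
#'
#' An `n` x `n` matrix of probabilities `rho[i, j]` that node `j` causally
#' influences node `i`, stored as TSV with variable names as header row and
#' first column.
#'
#' @param rho Matrix with entries in `[0, 1]`.
#' @param path File path.
#' @param source `"bio"` or `"reveng"` provenance tag.
#' @param variables Optional variable names (defaults to the matrix
#'   dimnames or `x1..xn`).
#' @return `read_prior`: a `bpds_prior`; `write_prior`: `path` invisibly.
#' @export
prior_matrix <- function(rho, source = c("bio", "reveng"), variables = NULL) {
  source <- match.arg(source)
  rho <- as.matrix(rho)
  if (nrow(rho) != ncol(rho)) stop("prior matrix must be square")
  if (any(rho < 0) || any(rho > 1)) stop("prior entries must lie in [0, 1]")
  if (is.null(variables)) variables <- colnames(rho)
  if (is.null(variables)) variables <- paste0("x", seq_len(ncol(rho)))
  dimnames(rho) <- list(variables, variables)
  structure(list(rho = rho, source = source, n = ncol(rho),
                 variables = variables), class = "bpds_prior")
}

#' @rdname prior_matrix
#' @export
write_prior <- function(prior, path) {
  df <- data.frame(variable = prior$variables, prior$rho, check.names = FALSE)
  colnames(df) <- c("variable", prior$variables)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname prior_matrix
#' @export
read_prior <- function(path, source = "bio") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  rho <- as.matrix(df[, -1, drop = FALSE])
  rownames(rho) <- df[[1]]
  prior_matrix(rho, source = source, variables = df[[1]])
}
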