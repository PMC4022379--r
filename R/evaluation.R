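# Scoring inferred networks and dynamics against a gold standard.

#' Gold-standard network
#'
#' @param edges Two-column matrix or data frame of directed edges
#'   (regulator, target), by variable name or 1-based index.
#' @param n Network size.
#' @param variables Optional variable names.
#' @return An object of class `bpds_network` holding the adjacency matrix
#'   (targets in rows, regulators in columns).
#' @export
gold_network <- function(edges, n, variables = NULL) {
  if (is.null(variables)) variables <- paste0("x", seq_len(n))
  V <- matrix(0L, n, n, dimnames = list(variables, variables))
  edges <- as.matrix(edges)
  for (k in seq_len(nrow(edges))) {
    src <- edges[k, 1]; dst <- edges[k, 2]
    j <- if (grepl("^[0-9]+$", src)) as.integer(src) else match(src, variables)
    i <- if (grepl("^[0-9]+$", dst)) as.integer(dst) else match(dst, variables)
    if (is.na(i) || is.na(j)) stop("edge references unknown variable")
    V[i, j] <- 1L
  }
  structure(list(V = V, n = n, variables = variables), class = "bpds_network")
}

half_up <- function(x, digits = 2L) floor(x * 10^digits + 0.5) / 10^digits

#' Compare an inferred network against a gold standard
#'
#' Directed-edge confusion counts and the derived PPV (precision), recall
#' (TPR), and FPR. An inferred edge in the gold network is a true positive;
#' an inferred edge absent from it -- including a wrong-direction edge whose
#' true counterpart is not separately inferred -- is a false positive, and
#' the unrecovered true edge counts as a false negative. The negative
#' universe is all ordered pairs excluding self-loops (include them with
#' `include_self_loops`), minus the gold edges.
#'
#' @param inferred Binary adjacency matrix (targets in rows, regulators in
#'   columns), or a `bpds_network`.
#' @param gold A `bpds_network` or binary adjacency matrix.
#' @param include_self_loops Count the diagonal in the pair universe?
#' @return List of class `bpds_confusion`: counts `tp`, `fp`, `fn`, `tn`;
#'   raw `ppv`, `recall`, `fpr`; 2-decimal half-up `ppv_rounded`,
#'   `recall_rounded`; and `ppv_defined` (FALSE when no edge was inferred).
#' @export
compare_networks <- function(inferred, gold, include_self_loops = FALSE) {
  Vi <- if (inherits(inferred, "bpds_network")) inferred$V else inferred
  Vg <- if (inherits(gold, "bpds_network")) gold$V else gold
  if (!all(dim(Vi) == dim(Vg))) stop("network dimension mismatch")
  n <- nrow(Vi)
  mask <- matrix(TRUE, n, n)
  if (!include_self_loops) diag(mask) <- FALSE
  vi <- Vi == 1L & mask
  vg <- Vg == 1L & mask
  tp <- sum(vi & vg)
  fp <- sum(vi & !vg)
  fn <- sum(!vi & vg)
  tn <- sum(!vi & !vg & mask)
  ppv_defined <- (tp + fp) > 0L
  ppv <- if (ppv_defined) tp / (tp + fp) else 0
  recall <- if (tp + fn > 0L) tp / (tp + fn) else 0
  fpr <- if (fp + tn > 0L) fp / (fp + tn) else 0
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn,
                 ppv = ppv, recall = recall, fpr = fpr,
                 ppv_rounded = half_up(ppv), recall_rounded = half_up(recall),
                 ppv_defined = ppv_defined), class = "bpds_confusion")
}

#' @export
print.bpds_confusion <- function(x, ...) {
  cat(sprintf("TP %d  FP %d  FN %d  TN %d | PPV %.2f  Recall %.2f  FPR %.3f\n",
              x$tp, x$fp, x$fn, x$tn, x$ppv_rounded, x$recall_rounded, x$fpr))
  invisible(x)
}

#' ROC-space location of a confusion result
#'
#' @param counts A `bpds_confusion`.
#' @return List `fpr`, `tpr`, and `above_no_discrimination` (strictly above
#'   the diagonal).
#' @export
roc_point <- function(counts) {
  list(fpr = counts$fpr, tpr = counts$recall,
       above_no_discrimination = counts$recall > counts$fpr)
}

#' Steady states of a reference list retrieved by a model
#'
#' Which of a set of reference states are fixed points of the model, and the
#' retrieved fraction -- the headline measure of how well an inferred
#' dynamic model reproduces known attractor patterns.
#'
#' @param f A `bpds_model`.
#' @param reference Binary matrix of reference states, one per row.
#' @return List: `retrieved` (logical per reference state), `states` (the
#'   retrieved subset), `fraction`.
#' @export
steady_state_retrieval <- function(f, reference) {
  reference <- as.matrix(reference)
  if (ncol(reference) != f$n) stop("reference states must have n columns")
  retrieved <- vapply(seq_len(nrow(reference)), function(k)
    all(model_step(f, reference[k, ]) == reference[k, ]), logical(1))
  list(retrieved = retrieved,
       states = reference[retrieved, , drop = FALSE],
       fraction = if (nrow(reference)) mean(retrieved) else NA_real_)
}
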