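# Skeleton and orientation-aware precision/recall/F-score against a
# reference network. Orientation-aware ("CPDAG") scores reclassify every
# skeleton-true edge whose orientation status disagrees with the reference
# CPDAG as a false positive: TP' = TP - TP_misorient, FP' = FP + TP_misorient.

fscore_of <- function(prec, rec) {
  if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
}

edge_status_map <- function(g) {
  if (nrow(g$edges) == 0L) {
    return(list(keys = character(0), from = character(0), directed = logical(0)))
  }
  keys <- mapply(edge_key, g$edges$from, g$edges$to, USE.NAMES = FALSE)
  list(keys = keys, from = g$edges$from, directed = g$edges$directed)
}

check_same_nodes <- function(predicted, reference) {
  if (!setequal(predicted$nodes, reference$nodes)) {
    abort("predicted and reference graphs must share the same node set.")
  }
}

#' Skeleton precision, recall and F-score
#'
#' Compares the unordered adjacencies of a predicted network against a
#' reference: `Prec = TP/(TP+FP)`, `Rec = TP/(TP+FN)`,
#' `F = 2 Prec Rec / (Prec + Rec)`. Empty denominators score 0 by
#' convention (flagged in `undefined_precision`), matching the behavior of
#' benchmark curves at very small sample sizes.
#'
#' @param predicted,reference `mixed_graph` objects over the same node set
#'   (edge marks are ignored; only adjacencies count).
#' @return A one-row tibble with `tp`, `fp`, `fn`, `precision`, `recall`,
#'   `fscore`, `undefined_precision`.
#' @export
skeleton_scores <- function(predicted, reference) {
  check_same_nodes(predicted, reference)
  p <- edge_status_map(predicted)
  r <- edge_status_map(reference)
  tp <- sum(p$keys %in% r$keys)
  fp <- length(p$keys) - tp
  fn <- length(r$keys) - tp
  undef <- (tp + fp) == 0L
  prec <- if (undef) 0 else tp / (tp + fp)
  rec <- if ((tp + fn) == 0L) 0 else tp / (tp + fn)
  tibble::tibble(
    tp = tp, fp = fp, fn = fn,
    precision = prec, recall = rec, fscore = fscore_of(prec, rec),
    undefined_precision = undef
  )
}

# number of skeleton-true predicted edges whose orientation status differs
# from the reference: undirected vs directed either way, or opposite arrows
count_misoriented <- function(predicted, reference) {
  p <- edge_status_map(predicted)
  r <- edge_status_map(reference)
  common <- intersect(p$keys, r$keys)
  if (length(common) == 0L) return(0L)
  pi <- match(common, p$keys)
  ri <- match(common, r$keys)
  same <- (!p$directed[pi] & !r$directed[ri]) |
    (p$directed[pi] & r$directed[ri] & p$from[pi] == r$from[ri])
  sum(!same)
}

#' Orientation-aware (CPDAG) precision, recall and F-score
#'
#' Extends [skeleton_scores()] by penalizing misorientations: every
#' skeleton-true edge whose orientation status differs from the reference
#' CPDAG (directed in one and undirected in the other, or directed
#' oppositely) counts as `TP_misorient`, giving `TP' = TP - TP_misorient`
#' and `FP' = FP + TP_misorient`, with `Prec' = TP'/(TP'+FP')` and
#' `Rec' = TP'/(TP+FN)` (the recall denominator keeps the skeleton positives
#' so misorientation penalizes the numerator only).
#'
#' @param predicted A `mixed_graph` (partially directed prediction).
#' @param reference_cpdag The reference CPDAG as a `mixed_graph` (convert a
#'   true DAG with [cpdag_of_dag()]).
#' @return A one-row tibble with skeleton counts/metrics plus
#'   `tp_misorient`, `precision_cpdag`, `recall_cpdag`, `fscore_cpdag`.
#' @export
cpdag_scores <- function(predicted, reference_cpdag) {
  sk <- skeleton_scores(predicted, reference_cpdag)
  mis <- count_misoriented(predicted, reference_cpdag)
  tp2 <- sk$tp - mis
  fp2 <- sk$fp + mis
  undef <- (tp2 + fp2) == 0L
  prec <- if (undef) 0 else tp2 / (tp2 + fp2)
  rec <- if ((sk$tp + sk$fn) == 0L) 0 else tp2 / (sk$tp + sk$fn)
  dplyr::mutate(
    sk,
    tp_misorient = mis,
    precision_cpdag = prec, recall_cpdag = rec,
    fscore_cpdag = fscore_of(prec, rec)
  )
}

#' Evaluate a prediction against a true DAG
#'
#' Convenience wrapper: converts the true DAG to its reference CPDAG and
#' reports both skeleton and orientation-aware metrics in one row.
#'
#' @param predicted A `mixed_graph`.
#' @param true_dag The generating DAG as a `mixed_graph` (all edges
#'   directed, acyclic).
#' @return A one-row tibble (see [cpdag_scores()]).
#' @export
evaluate_against_dag <- function(predicted, true_dag) {
  cpdag_scores(predicted, cpdag_of_dag(true_dag))
}
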