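# Orientation of the skeleton: unshielded triples are ranked by the absolute
# value of their (shifted) conditional 3-point information and swept in
# decreasing order. Negative triples orient as v-structures (rule R0);
# positive triples propagate an existing arrowhead through the middle node
# (rule R1). Conflicting orientations are skipped: an arrowhead, once
# placed, is never reversed, and the less likely triple is ignored together
# with its propagations. Rules R2/R3 are deliberately not applied: they
# enforce acyclicity rather than a likelihood preference, so the output may
# contain directed cycles.

#' Orient a reconstructed skeleton
#'
#' Step 2 of the two-step reconstruction. For every unshielded triple
#' `x - z - y`, the conditional 3-point information
#' `I'(x;y;z | sepset(x,y) \ z)` is computed from the separation sets of
#' step 1. Triples are processed in decreasing `|I'|`: a negative triple
#' orients `x -> z <- y` unless either arrowhead contradicts an existing
#' orientation; a positive triple with exactly one link already pointing
#' into `z` propagates the orientation out of `z`. Sweeps repeat until a
#' full pass changes nothing; triples with `I' = 0` are never used. Ties in
#' `|I'|` break lexicographically on `(z, x, y)`.
#'
#' @param skel A `threeoff2_skeleton` from [reconstruct_skeleton()].
#' @param data The dataset used for step 1.
#' @param score,rank As in [reconstruct_skeleton()]; defaults reuse the
#'   skeleton's settings.
#' @return A list of class `threeoff2_orientation`: `graph` (partially
#'   directed `mixed_graph`) and `triples` (tibble with per-triple
#'   information values and verdicts: `v_structure`, `non_v`,
#'   `skipped_conflict`, or `unused`).
#' @export
orient_skeleton <- function(skel, data, score = NULL, rank = NULL) {
  if (!inherits(skel, "threeoff2_skeleton")) {
    abort("`skel` must come from reconstruct_skeleton().")
  }
  ds <- as_categorical_dataset(data)
  score <- score %||% skel$score
  mode <- resolve_rank_mode(rank %||% skel$rank_mode, score)
  nm <- ds$variable_names
  cache <- new.env(parent = emptyenv())

  trip <- unshielded_triples(skel$graph)
  if (nrow(trip) == 0L) {
    return(structure(
      list(
        graph = skel$graph,
        triples = tibble::tibble(
          x = character(0), z = character(0), y = character(0),
          cond = character(0), I3 = numeric(0), I3_shifted = numeric(0),
          verdict = character(0)
        )
      ),
      class = "threeoff2_orientation"
    ))
  }

  scores <- purrr::pmap(trip, function(x, z, y) {
    sep <- skel$sepsets[[edge_key(x, y)]] %||% character(0)
    cond <- setdiff(sep, z)
    xi <- match(x, nm); yi <- match(y, nm); zi <- match(z, nm)
    ui <- match(cond, nm)
    t3 <- triple_information_idx(ds, xi, yi, zi, ui, score, cache)
    tibble::tibble(
      x = x, z = z, y = y, cond = paste(cond, collapse = ","),
      I3 = t3$I3, I3_shifted = t3$I3_shifted
    )
  })
  trip <- dplyr::bind_rows(scores)
  trip$I3_used <- if (mode == "shifted") trip$I3_shifted else trip$I3
  ord <- order(-abs(trip$I3_used), trip$z, trip$x, trip$y, method = "radix")
  trip <- trip[ord, ]
  trip$verdict <- "pending"

  a <- graph_to_amat(skel$graph)
  is_dir <- function(i, j) a[i, j] == 1L && a[j, i] == 0L   # i -> j
  is_und <- function(i, j) a[i, j] == 1L && a[j, i] == 1L
  orient <- function(i, j) a[j, i] <<- 0L                   # set i -> j

  repeat {
    changed <- FALSE
    for (k in seq_len(nrow(trip))) {
      if (trip$verdict[k] != "pending") next
      xi <- match(trip$x[k], skel$graph$nodes)
      zi <- match(trip$z[k], skel$graph$nodes)
      yi <- match(trip$y[k], skel$graph$nodes)
      i3 <- trip$I3_used[k]
      if (i3 < 0) {
        # R0: orient the v-structure unless an arrowhead out of z exists
        if (is_dir(zi, xi) || is_dir(zi, yi)) {
          trip$verdict[k] <- "skipped_conflict"
        } else {
          if (is_und(xi, zi)) { orient(xi, zi); changed <- TRUE }
          if (is_und(yi, zi)) { orient(yi, zi); changed <- TRUE }
          trip$verdict[k] <- "v_structure"
        }
      } else if (i3 > 0) {
        into_x <- is_dir(xi, zi)
        into_y <- is_dir(yi, zi)
        if (into_x && into_y) {
          # both links already collide on z: contradicts the non-v verdict
          trip$verdict[k] <- "skipped_conflict"
        } else if (into_x && is_und(zi, yi)) {
          orient(zi, yi); changed <- TRUE
          trip$verdict[k] <- "non_v"
        } else if (into_y && is_und(zi, xi)) {
          orient(zi, xi); changed <- TRUE
          trip$verdict[k] <- "non_v"
        } else if ((into_x && is_dir(zi, yi)) || (into_y && is_dir(zi, xi))) {
          trip$verdict[k] <- "non_v"   # already a consistent chain
        }
        # otherwise: no arrowhead into z yet; stays pending
      } else {
        trip$verdict[k] <- "unused"    # no likelihood preference
      }
    }
    if (!changed) break
  }
  trip$verdict[trip$verdict == "pending"] <- "unused"

  structure(
    list(
      graph = amat_to_graph(a),
      triples = trip[, c("x", "z", "y", "cond", "I3", "I3_shifted", "I3_used", "verdict")]
    ),
    class = "threeoff2_orientation"
  )
}

#' @export
print.threeoff2_orientation <- function(x, ...) {
  cat(sprintf(
    "<threeoff2_orientation> %d directed / %d edges; %d v-structures, %d propagations, %d conflicts\n",
    sum(x$graph$edges$directed), nrow(x$graph$edges),
    sum(x$triples$verdict == "v_structure"),
    sum(x$triples$verdict == "non_v"),
    sum(x$triples$verdict == "skipped_conflict")
  ))
  invisible(x)
}
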