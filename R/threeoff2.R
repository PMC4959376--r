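#' Reconstruct a partially directed network from categorical data
#'
#' The full two-step pipeline: [reconstruct_skeleton()] (iterative take-off
#' of ranked conditional 3-point information from every pairwise mutual
#' information, with NML or MDL finite-size corrections) followed by
#' [orient_skeleton()] (v-structure orientation and propagation in
#' decreasing likelihood order). The result is a partially directed graph:
#' edges whose direction is not identifiable from observational
#' independencies remain undirected.
#'
#' @param data A data frame (or `categorical_dataset`) of categorical
#'   observations, rows = samples, columns = variables.
#' @param score Complexity score: `"nml"` (normalized maximum likelihood,
#'   default) or `"mdl"` (MDL/BIC).
#' @param rank `"auto"` (default: shifted information with NML, raw with
#'   MDL), `"shifted"`, or `"raw"`.
#' @param max_cond_size Optional cap on conditioning-set size.
#' @param skeleton_only If `TRUE`, skip the orientation step.
#' @return An object of class `threeoff2_fit` with elements `graph` (the
#'   partially directed `mixed_graph`), `skeleton`, `sepsets`, `edges`,
#'   `triples`, `trace`, and the run settings. Use [tidy()] for the edge
#'   list, [glance()] for a one-row summary, [autoplot()] to draw the
#'   network.
#' @examples
#' net <- bn_fixture("collider_plus_child")
#' fit <- threeoff2(sample_bn(net, 2000, seed = 1))
#' tidy(fit)
#' glance(fit)
#' @export
threeoff2 <- function(data, score = c("nml", "mdl"), rank = "auto",
                      max_cond_size = Inf, skeleton_only = FALSE) {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  mode <- resolve_rank_mode(rank, score)
  skel <- reconstruct_skeleton(ds, score = score, rank = mode,
                               max_cond_size = max_cond_size)
  if (skeleton_only) {
    graph <- skel$graph
    triples <- NULL
  } else {
    ori <- orient_skeleton(skel, ds, score = score, rank = mode)
    graph <- ori$graph
    triples <- ori$triples
  }
  structure(
    list(
      graph = graph,
      skeleton = skel$graph,
      sepsets = skel$sepsets,
      edges = skel$edges,
      triples = triples,
      trace = skel$trace,
      score = score, rank_mode = mode,
      max_cond_size = max_cond_size,
      n = ds$n, variable_names = ds$variable_names,
      levels = ds$levels
    ),
    class = "threeoff2_fit"
  )
}

#' @export
print.threeoff2_fit <- function(x, ...) {
  cat(sprintf(
    "<threeoff2_fit> %d variables, N = %d (%s score, %s information)\n",
    length(x$variable_names), x$n, toupper(x$score), x$rank_mode
  ))
  nd <- sum(x$graph$edges$directed)
  cat(sprintf("  %d edges (%d directed, %d undirected)\n",
              nrow(x$graph$edges), nd, nrow(x$graph$edges) - nd))
  print(x$graph)
  invisible(x)
}

#' Tidy the edges of a reconstructed network
#'
#' @param x A `threeoff2_fit`.
#' @param ... Unused.
#' @return A tibble with one row per edge of the final graph: `from`, `to`,
#'   `mark` (`"--"` or `"->"`), and the final conditional 2-point
#'   information of the underlying pair.
#' @method tidy threeoff2_fit
#' @export
tidy.threeoff2_fit <- function(x, ...) {
  e <- x$graph$edges
  if (nrow(e) == 0L) {
    return(tibble::tibble(
      from = character(0), to = character(0), mark = character(0),
      I2 = numeric(0), I2_shifted = numeric(0)
    ))
  }
  keys <- mapply(edge_key, e$from, e$to, USE.NAMES = FALSE)
  st <- x$edges
  st_keys <- mapply(edge_key, st$x, st$y, USE.NAMES = FALSE)
  idx <- match(keys, st_keys)
  tibble::tibble(
    from = e$from, to = e$to,
    mark = ifelse(e$directed, "->", "--"),
    I2 = st$I2[idx], I2_shifted = st$I2_shifted[idx]
  )
}

#' One-row summary of a reconstruction
#'
#' @param x A `threeoff2_fit`.
#' @param ... Unused.
#' @return A one-row tibble: sample size, variable count, score settings,
#'   edge counts and v-structure count.
#' @method glance threeoff2_fit
#' @export
glance.threeoff2_fit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_vars = length(x$variable_names),
    score = x$score,
    rank_mode = x$rank_mode,
    n_edges = nrow(x$graph$edges),
    n_directed = sum(x$graph$edges$directed),
    n_sepsets = length(x$sepsets),
    n_v_structures = if (is.null(x$triples)) NA_integer_ else {
      sum(x$triples$verdict == "v_structure")
    }
  )
}

#' Plot a reconstructed network
#'
#' Draws the partially directed graph with a deterministic force-directed
#' layout; directed edges carry arrowheads.
#'
#' @param object A `threeoff2_fit` or `mixed_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threeoff2_fit
#' @export
autoplot.threeoff2_fit <- function(object, ...) {
  autoplot.mixed_graph(object$graph, ...)
}

#' @rdname autoplot.threeoff2_fit
#' @method autoplot mixed_graph
#' @export
autoplot.mixed_graph <- function(object, ...) {
  g <- object
  ig <- igraph::graph_from_data_frame(
    if (nrow(g$edges) > 0) g$edges[, c("from", "to")] else
      data.frame(from = character(0), to = character(0)),
    directed = TRUE, vertices = data.frame(name = g$nodes)
  )
  set.seed(42L) # layout only; fixed for reproducible figures
  xy <- igraph::layout_with_fr(ig)
  nodes <- tibble::tibble(name = g$nodes, x = xy[, 1], y = xy[, 2])
  p <- ggplot2::ggplot(nodes, ggplot2::aes(x = .data$x, y = .data$y))
  if (nrow(g$edges) > 0) {
    seg <- tibble::tibble(
      x = nodes$x[match(g$edges$from, nodes$name)],
      y = nodes$y[match(g$edges$from, nodes$name)],
      xend = nodes$x[match(g$edges$to, nodes$name)],
      yend = nodes$y[match(g$edges$to, nodes$name)],
      directed = g$edges$directed
    )
    # shorten directed segments so arrowheads sit outside the node label
    shrink <- 0.12
    seg <- dplyr::mutate(
      seg,
      xend2 = .data$xend - shrink * (.data$xend - .data$x),
      yend2 = .data$yend - shrink * (.data$yend - .data$y)
    )
    p <- p +
      ggplot2::geom_segment(
        data = dplyr::filter(seg, !.data$directed),
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
        color = "grey40"
      ) +
      ggplot2::geom_segment(
        data = dplyr::filter(seg, .data$directed),
        ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend2, yend = .data$yend2),
        color = "steelblue4",
        arrow = ggplot2::arrow(length = ggplot2::unit(0.12, "inches"), type = "closed")
      )
  }
  p +
    ggplot2::geom_label(ggplot2::aes(label = .data$name), size = 3.2) +
    ggplot2::theme_void()
}
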