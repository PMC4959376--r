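# Skeleton reconstruction: starting from the complete undirected graph,
# iteratively pick the edge with the highest rank R(xy;z|{u_i}) (the most
# likely indirect contribution), take its best contributor off the 2-point
# information, and remove the edge once the shifted conditional 2-point
# information turns negative (a structural independency). Candidate
# contributors for an edge are the current neighbors of its endpoints;
# cached ranks are recomputed lazily when a neighborhood changes.

#' Reconstruct a network skeleton by iterative take-off
#'
#' Step 1 of the two-step reconstruction. Every pair starts connected;
#' pairs with `I'(x;y) < 0` are removed immediately (empty separation set).
#' Remaining edges repeatedly receive their most likely contributor — the
#' eligible candidate `z` maximizing the lower-bound score `S_lb`, ranked
#' across edges by `R(xy;z|{u_i})` — until either the shifted conditional
#' 2-point information `I'(x;y|{u_i})` turns negative (edge removed, the
#' accumulated contributors recorded as its separation set) or no eligible
#' contributor remains (edge settled, i.e. kept).
#'
#' With `rank = "raw"` (the recommended pairing for MDL, selected by
#' `"auto"`), contributors are ranked by raw information terms, while the
#' removal test still uses the complexity-shifted criterion.
#'
#' @param data A `categorical_dataset` or data frame of categorical
#'   observations.
#' @param score Complexity score, `"nml"` (default) or `"mdl"`.
#' @param rank `"auto"` (shifted for NML, raw for MDL), `"shifted"`, or
#'   `"raw"`.
#' @param max_cond_size Optional cap on the conditioning-set size
#'   (default unbounded).
#' @return A list of class `threeoff2_skeleton`: `graph` (undirected
#'   `mixed_graph`), `sepsets` (named list keyed `"a|b"`), `edges` (tibble
#'   of per-edge states), `trace` (tibble of take-off events).
#' @export
reconstruct_skeleton <- function(data, score = c("nml", "mdl"),
                                 rank = "auto", max_cond_size = Inf) {
  ds <- as_categorical_dataset(data)
  score <- match.arg(score)
  mode <- resolve_rank_mode(rank, score)
  if (ds$n < 2) abort("skeleton reconstruction requires N >= 2 samples.")
  v <- length(ds$variable_names)
  if (v < 2) abort("need at least two variables.")
  nm <- ds$variable_names
  cache <- new.env(parent = emptyenv())

  adj <- matrix(TRUE, v, v); diag(adj) <- FALSE
  edges <- list()
  sepsets <- list()
  trace <- list()
  step <- 0L
  push_trace <- function(x, y, event, z, rank_val, i2s) {
    step <<- step + 1L
    trace[[step]] <<- tibble::tibble(
      step = step, x = nm[x], y = nm[y], event = event,
      z = if (is.na(z)) NA_character_ else nm[z],
      rank = rank_val, I2_shifted = i2s
    )
  }

  # initialization over all pairs; single-level variables carry no
  # information (I = 0 with zero complexity), so they end up isolated
  for (x in seq_len(v - 1L)) for (y in (x + 1L):v) {
    e <- edge_information_idx(ds, x, y, integer(0), score, cache)
    key <- edge_key(nm[x], nm[y])
    if (e$I2_shifted < 0 || ds$levels[x] == 1L || ds$levels[y] == 1L) {
      adj[x, y] <- adj[y, x] <- FALSE
      sepsets[[key]] <- character(0)
      edges[[key]] <- list(x = x, y = y, cond = integer(0), I2 = e$I2,
                           I2_shifted = e$I2_shifted, status = "removed",
                           best_z = NA_integer_, rank = 0, dirty = FALSE,
                           trace_I2s = e$I2_shifted)
      push_trace(x, y, "init_remove", NA_integer_, NA_real_, e$I2_shifted)
    } else {
      edges[[key]] <- list(x = x, y = y, cond = integer(0), I2 = e$I2,
                           I2_shifted = e$I2_shifted, status = "active",
                           best_z = NA_integer_, rank = 0, dirty = TRUE,
                           trace_I2s = e$I2_shifted)
    }
  }

  candidates_of <- function(e) {
    cand <- which(adj[e$x, ] | adj[e$y, ])
    setdiff(cand, c(e$x, e$y, e$cond))
  }

  repeat {
    # lazily refresh stale ranks
    for (key in names(edges)) {
      e <- edges[[key]]
      if (e$status != "active" || !e$dirty) next
      if (length(e$cond) >= max_cond_size) {
        e$best_z <- NA_integer_; e$rank <- 0
      } else {
        b <- best_contributor_idx(ds, e$x, e$y, e$cond, candidates_of(e),
                                  score, mode, cache)
        e$best_z <- b$z; e$rank <- b$rank
      }
      if (is.na(e$best_z)) {
        e$status <- "settled"
        push_trace(e$x, e$y, "settle", NA_integer_, NA_real_, e$I2_shifted)
      }
      e$dirty <- FALSE
      edges[[key]] <- e
    }

    live <- Filter(function(e) e$status == "active" && !is.na(e$best_z), edges)
    if (length(live) == 0L) break
    # top rank; ties broken lexicographically on endpoint then contributor names
    ranks <- vapply(live, `[[`, numeric(1), "rank")
    tie_key <- vapply(live, function(e) {
      paste(nm[e$x], nm[e$y], nm[e$best_z], sep = "\r")
    }, character(1))
    top <- names(live)[order(-ranks, tie_key, method = "radix")][1]
    e <- edges[[top]]
    z <- e$best_z
    e$cond <- c(e$cond, z)
    upd <- edge_information_idx(ds, e$x, e$y, e$cond, score, cache)
    e$I2 <- upd$I2
    e$I2_shifted <- upd$I2_shifted
    e$trace_I2s <- c(e$trace_I2s, upd$I2_shifted)
    push_trace(e$x, e$y, "ablate", z, e$rank, upd$I2_shifted)

    if (upd$I2_shifted < 0) {
      e$status <- "removed"
      e$best_z <- NA_integer_
      e$rank <- 0
      adj[e$x, e$y] <- adj[e$y, e$x] <- FALSE
      sepsets[[top]] <- nm[e$cond]
      edges[[top]] <- e
      push_trace(e$x, e$y, "remove", z, NA_real_, upd$I2_shifted)
      # neighborhoods of the endpoints changed: candidate sets shrank
      for (key in names(edges)) {
        o <- edges[[key]]
        if (o$status == "active" && (o$x %in% c(e$x, e$y) || o$y %in% c(e$x, e$y) ||
                                     !is.na(o$best_z) && o$best_z %in% c(e$x, e$y))) {
          edges[[key]]$dirty <- TRUE
        }
      }
    } else {
      e$dirty <- TRUE
      edges[[top]] <- e
    }
  }

  kept <- Filter(function(e) e$status != "removed", edges)
  graph <- mixed_graph(nm, if (length(kept)) {
    tibble::tibble(
      from = vapply(kept, function(e) nm[e$x], character(1)),
      to = vapply(kept, function(e) nm[e$y], character(1)),
      directed = FALSE
    )
  } else {
    NULL
  })
  edges_tbl <- dplyr::bind_rows(lapply(unname(edges), function(e) {
    tibble::tibble(
      x = nm[e$x], y = nm[e$y],
      cond = paste(nm[e$cond], collapse = ","),
      I2 = e$I2, I2_shifted = e$I2_shifted, status = e$status
    )
  }))
  structure(
    list(
      graph = graph,
      sepsets = sepsets,
      edges = edges_tbl,
      trace = if (length(trace)) dplyr::bind_rows(trace) else tibble::tibble(),
      edge_states = edges,
      score = score, rank_mode = mode,
      variable_names = nm
    ),
    class = "threeoff2_skeleton"
  )
}

#' @export
print.threeoff2_skeleton <- function(x, ...) {
  cat(sprintf(
    "<threeoff2_skeleton> %d nodes, %d edges kept, %d pairs separated (%s/%s)\n",
    length(x$graph$nodes), nrow(x$graph$edges), length(x$sepsets),
    x$score, x$rank_mode
  ))
  invisible(x)
}
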