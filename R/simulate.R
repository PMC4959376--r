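# Synthetic-data generation: discrete Bayesian networks (DAG + CPTs),
# ancestral forward sampling, random-DAG generation and the named fixtures
# that make every pipeline stage testable without external downloads.

#' Create a discrete Bayesian network
#'
#' A Bayesian network is a DAG plus, for each node, a conditional
#' probability table over all joint parent states. Parent states are indexed
#' in mixed-radix order with the *first* parent varying fastest, so a CPT is
#' a matrix with `prod(r_parents)` rows (1 for root nodes) and `r_node`
#' columns, each row summing to 1.
#'
#' @param nodes Character vector of node names.
#' @param parents Named list mapping each node to its (possibly empty)
#'   character vector of parents; acyclicity is checked.
#' @param cpts Named list of CPT matrices as described above.
#' @param labels Optional named list of per-node level labels; defaults to
#'   `"0", "1", ...`.
#' @return An object of class `bayes_net`.
#' @export
bayes_net <- function(nodes, parents, cpts, labels = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node names.")
  parents <- parents[nodes]
  cpts <- cpts[nodes]
  if (any(vapply(parents, is.null, logical(1)))) abort("every node needs a parents entry.")
  if (any(vapply(cpts, is.null, logical(1)))) abort("every node needs a CPT.")
  levels <- vapply(cpts, ncol, integer(1))
  for (v in nodes) {
    pa <- parents[[v]]
    if (!all(pa %in% nodes)) abort(sprintf("unknown parent of %s.", v))
    if (v %in% pa) abort("a node cannot be its own parent.")
    expect_rows <- if (length(pa) == 0L) 1L else prod(levels[pa])
    if (nrow(cpts[[v]]) != expect_rows) {
      abort(sprintf("CPT of %s has %d rows; expected %d.", v, nrow(cpts[[v]]), expect_rows))
    }
    if (any(cpts[[v]] < 0) || any(abs(rowSums(cpts[[v]]) - 1) > 1e-12)) {
      abort(sprintf("CPT rows of %s must be distributions summing to 1.", v))
    }
  }
  if (is.null(labels)) {
    labels <- lapply(levels, function(r) as.character(seq_len(r) - 1L))
  }
  if (sum(lengths(parents)) > 0) {
    ig <- igraph::graph_from_data_frame(
      data.frame(from = unlist(parents, use.names = FALSE),
                 to = rep(nodes, lengths(parents))),
      directed = TRUE, vertices = data.frame(name = nodes)
    )
    if (!igraph::is_dag(ig)) abort("parent structure must be acyclic.")
  }
  structure(
    list(nodes = nodes, parents = parents, cpts = cpts,
         levels = setNames(as.integer(levels), nodes), labels = labels[nodes]),
    class = "bayes_net"
  )
}

#' @export
print.bayes_net <- function(x, ...) {
  cat(sprintf("<bayes_net> %d nodes, %d edges\n", length(x$nodes),
              sum(lengths(x$parents))))
  for (v in x$nodes) {
    pa <- x$parents[[v]]
    cat(sprintf("  %s (%d levels)%s\n", v, x$levels[[v]],
                if (length(pa)) paste0(" <- ", paste(pa, collapse = ", ")) else ""))
  }
  invisible(x)
}

#' DAG of a Bayesian network
#'
#' @param net A `bayes_net`.
#' @return A `mixed_graph` with one directed edge per parent-child pair.
#' @export
bn_dag <- function(net) {
  from <- unlist(net$parents, use.names = FALSE)
  to <- rep(net$nodes, lengths(net$parents))
  mixed_graph(net$nodes, if (length(from)) {
    tibble::tibble(from = from, to = to, directed = TRUE)
  } else {
    NULL
  })
}

bn_topological_order <- function(net) {
  ig <- igraph::graph_from_data_frame(
    if (sum(lengths(net$parents)) > 0) {
      data.frame(
        from = unlist(net$parents, use.names = FALSE),
        to = rep(net$nodes, lengths(net$parents))
      )
    } else {
      data.frame(from = character(0), to = character(0))
    },
    directed = TRUE, vertices = data.frame(name = net$nodes)
  )
  names(igraph::topo_sort(ig, mode = "out"))
}

#' Forward-sample observations from a Bayesian network
#'
#' Ancestral (topological-order) sampling: each node is drawn from its CPT
#' row given the already-sampled parent states. The same seed always yields
#' the identical dataset.
#'
#' @param net A `bayes_net`.
#' @param n Number of samples (`>= 1`).
#' @param seed Optional integer seed (the caller's RNG state is preserved).
#' @return A tibble of `n` rows with one character column per node, columns
#'   in the network's node order.
#' @examples
#' net <- bn_fixture("chain")
#' sample_bn(net, 5, seed = 1)
#' @export
sample_bn <- function(net, n, seed = NULL) {
  if (!inherits(net, "bayes_net")) abort("`net` must be a bayes_net.")
  if (n < 1) abort("`n` must be at least 1.")
  n <- as.integer(n)
  with_seed(seed, {
    codes <- matrix(0L, n, length(net$nodes), dimnames = list(NULL, net$nodes))
    for (v in bn_topological_order(net)) {
      cpt <- net$cpts[[v]]
      r <- ncol(cpt)
      pa <- net$parents[[v]]
      row_idx <- if (length(pa) == 0L) {
        rep.int(1L, n)
      } else {
        rp <- net$levels[pa]
        mult <- cumprod(c(1, rp[-length(rp)]))
        as.integer((codes[, pa, drop = FALSE] - 1L) %*% mult) + 1L
      }
      cum <- t(apply(cpt, 1L, cumsum))
      if (r == 1L) {
        codes[, v] <- 1L
      } else {
        u <- runif(n)
        codes[, v] <- 1L + as.integer(rowSums(u > cum[row_idx, , drop = FALSE]))
      }
    }
    cols <- lapply(net$nodes, function(v) net$labels[[v]][codes[, v]])
    names(cols) <- net$nodes
    tibble::as_tibble(cols)
  })
}

#' Random discrete Bayesian network
#'
#' Draws a DAG with a uniform-random topological order, adding edges between
#' randomly chosen order-respecting pairs until the target edge count
#' `round(avg_degree * n_nodes / 2)` is reached, never exceeding
#' `max_in_degree`. CPT rows are either symmetric-Dirichlet draws
#' (`cpt = "dirichlet"`) or a deterministic strong-dependence scheme
#' (`cpt = "strong"`): each joint parent state puts probability 0.85 on a
#' preferred child level that grades with the mean parent level, spreading
#' the rest uniformly, so every edge carries marginally visible dependence.
#'
#' @param n_nodes Number of nodes.
#' @param avg_degree Target average degree (edges ~ `avg_degree * n / 2`).
#' @param max_in_degree Maximum number of parents per node.
#' @param levels_range Range of per-node level counts, e.g. `c(2, 3)`.
#' @param dirichlet_alpha Symmetric Dirichlet concentration for
#'   `cpt = "dirichlet"` rows (default 0.5).
#' @param seed Optional integer seed.
#' @param cpt CPT style, `"dirichlet"` (default) or `"strong"`.
#' @return A `bayes_net`.
#' @export
random_bn <- function(n_nodes, avg_degree = 2.5, max_in_degree = 2,
                      levels_range = c(2, 2), dirichlet_alpha = 0.5,
                      seed = NULL, cpt = c("dirichlet", "strong")) {
  cpt <- match.arg(cpt)
  if (n_nodes < 1) abort("`n_nodes` must be positive.")
  target <- round(avg_degree * n_nodes / 2)
  if (target > max_in_degree * (n_nodes - 1)) {
    abort("infeasible degree constraints: target edge count exceeds max_in_degree capacity.")
  }
  with_seed(seed, {
    nodes <- sprintf("V%02d", seq_len(n_nodes))
    ord <- sample(nodes)                     # uniform random topological order
    pairs <- which(upper.tri(matrix(0, n_nodes, n_nodes)), arr.ind = TRUE)
    pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
    parents <- setNames(rep(list(character(0)), n_nodes), nodes)
    added <- 0L
    for (k in seq_len(nrow(pairs))) {
      if (added >= target) break
      from <- ord[pairs[k, 1]]
      to <- ord[pairs[k, 2]]
      if (length(parents[[to]]) < max_in_degree) {
        parents[[to]] <- c(parents[[to]], from)
        added <- added + 1L
      }
    }
    lv_choices <- seq(levels_range[1], levels_range[2])
    levels <- setNames(
      if (length(lv_choices) == 1L) rep(lv_choices, n_nodes) else
        sample(lv_choices, n_nodes, replace = TRUE),
      nodes
    )
    cpts <- lapply(nodes, function(v) {
      r <- levels[[v]]
      pa <- parents[[v]]
      nrows <- if (length(pa) == 0L) 1L else prod(levels[pa])
      if (cpt == "dirichlet") {
        m <- matrix(rgamma(nrows * r, shape = dirichlet_alpha), nrows, r)
        m[m == 0] <- 1e-12
        m / rowSums(m)
      } else {
        strong_cpt(r, levels[pa])
      }
    })
    names(cpts) <- nodes
    bayes_net(nodes, parents, cpts)
  })
}

# strong-dependence CPT: the preferred child level carries 0.85 mass and
# grades with the mean normalized parent level, so every joint parent state
# pins the child sharply; roots are uniform
strong_cpt <- function(r, r_parents) {
  if (length(r_parents) == 0L) {
    return(matrix(1 / r, 1L, r))
  }
  nrows <- prod(r_parents)
  if (r == 1L) return(matrix(1, nrows, 1L))
  m <- matrix(0, nrows, r)
  for (j in seq_len(nrows)) {
    # decode mixed-radix parent state (first parent fastest)
    s <- j - 1L
    frac <- 0
    for (i in seq_along(r_parents)) {
      code <- s %% r_parents[i]
      s <- s %/% r_parents[i]
      frac <- frac + (if (r_parents[i] > 1) code / (r_parents[i] - 1) else 0.5)
    }
    frac <- frac / length(r_parents)
    pref <- 1L + as.integer(floor(frac * (r - 1) + 0.5))
    m[j, ] <- (1 - 0.85) / (r - 1)
    m[j, pref] <- 0.85
  }
  m
}

#' Named fixture networks
#'
#' Small hand-set networks with strong, analytically transparent
#' dependencies:
#' \describe{
#'   \item{`chain`}{`x -> z -> y`, each link a 0.9-probability copy; by the
#'     Markov property `I(x;y|z) = 0`.}
#'   \item{`fork`}{`x <- z -> y`, 0.9 copies; same independence structure as
#'     the chain (Markov equivalent).}
#'   \item{`v_structure`}{`x -> z <- y` with independent uniform `x`, `y`
#'     and a leaky-AND CPT (see below): marginally
#'     `I(x;y) = 0`, but conditioning on `z` creates dependence.}
#'   \item{`collider_plus_child`}{the v-structure plus a 0.9-copy child
#'     `z -> w`; its CPDAG keeps `z -> w` directed.}
#'   \item{`mini_benchmark`}{8 binary nodes, 10 edges (average degree 2.5,
#'     maximum in-degree 2): roots `A`; `A -> B`, `A -> C` (0.85 copies);
#'     colliders `B -> D <- C` and `B -> G <- C` with leaky-AND CPTs; chain
#'     `D -> E -> F` (0.85 copies); collider `G -> H <- F` (leaky-AND).}
#' }
#'
#' @param name Fixture name; see Details.
#' @return A `bayes_net`.
#' @export
bn_fixture <- function(name = c("chain", "fork", "v_structure",
                                "collider_plus_child", "mini_benchmark")) {
  name <- match.arg(name)
  copy2 <- function(p) matrix(c(p, 1 - p, 1 - p, p), 2L, 2L, byrow = TRUE)
  unif2 <- matrix(0.5, 1L, 2L)
  # collider CPT, rows in parent-state order (0,0),(1,0),(0,1),(1,1) (first
  # parent fastest): a leaky AND gate, P(child = 1) = 0.97 when both parents
  # are on, 0.03 with exactly one, 0.30 with none. A symmetric XOR would
  # hide the parent-child dependence marginally (no observational method
  # could keep those edges), and CPTs with P(1|0,0) = P(1|1,1) create
  # unfaithful cancellations two generations down; this gate keeps every
  # dependence the reconstruction needs above 0.06 nats (0.09 within the
  # mini-benchmark joint) while root pairs stay exactly independent.
  collider2 <- function() {
    p1 <- c(0.30, 0.03, 0.03, 0.97)
    matrix(c(1 - p1, p1), 4L, 2L)
  }
  switch(name,
    chain = bayes_net(
      c("x", "z", "y"),
      list(x = character(0), z = "x", y = "z"),
      list(x = unif2, z = copy2(0.9), y = copy2(0.9))
    ),
    fork = bayes_net(
      c("x", "z", "y"),
      list(x = "z", z = character(0), y = "z"),
      list(x = copy2(0.9), z = unif2, y = copy2(0.9))
    ),
    v_structure = bayes_net(
      c("x", "z", "y"),
      list(x = character(0), z = c("x", "y"), y = character(0)),
      list(x = unif2, z = collider2(), y = unif2)
    ),
    collider_plus_child = bayes_net(
      c("x", "z", "y", "w"),
      list(x = character(0), z = c("x", "y"), y = character(0), w = "z"),
      list(x = unif2, z = collider2(), y = unif2, w = copy2(0.9))
    ),
    mini_benchmark = bayes_net(
      c("A", "B", "C", "D", "E", "F", "G", "H"),
      list(
        A = character(0), B = "A", C = "A",
        D = c("B", "C"), E = "D", F = "E",
        G = c("B", "C"), H = c("G", "F")
      ),
      list(
        A = unif2, B = copy2(0.85), C = copy2(0.85),
        D = collider2(), E = copy2(0.85), F = copy2(0.85),
        G = collider2(), H = collider2()
      )
    )
  )
}

#' Serialize / load a Bayesian network as JSON
#'
#' A plain JSON schema: `nodes` (ordered names), and per node its `levels`,
#' `labels`, `parents`, and CPT rows (`cpt`, rows in mixed-radix parent
#' state order, first parent fastest).
#'
#' @param net A `bayes_net`.
#' @param path File path.
#' @return `bn_write_json()` returns `path` invisibly; `bn_read_json()`
#'   returns a `bayes_net`.
#' @export
bn_write_json <- function(net, path) {
  obj <- list(
    nodes = net$nodes,
    variables = lapply(net$nodes, function(v) {
      list(
        levels = net$levels[[v]],
        labels = net$labels[[v]],
        parents = net$parents[[v]],
        cpt = unname(apply(net$cpts[[v]], 1L, function(x) x, simplify = FALSE))
      )
    })
  )
  names(obj$variables) <- net$nodes
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname bn_write_json
#' @export
bn_read_json <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  nodes <- obj$nodes
  vars <- obj$variables
  parents <- lapply(nodes, function(v) {
    p <- vars[[v]]$parents
    if (is.null(p) || length(p) == 0L) character(0) else as.character(p)
  })
  names(parents) <- nodes
  cpts <- lapply(nodes, function(v) {
    cpt <- vars[[v]]$cpt
    if (is.list(cpt)) cpt <- do.call(rbind, cpt)
    if (is.null(dim(cpt))) cpt <- matrix(cpt, nrow = 1L)
    cpt
  })
  names(cpts) <- nodes
  labels <- lapply(nodes, function(v) as.character(vars[[v]]$labels))
  names(labels) <- nodes
  bayes_net(nodes, parents, cpts, labels)
}
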