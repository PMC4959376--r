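# Mixed (partially directed) graphs: nodes plus edges each marked undirected
# ("--") or directed ("->"). At most one edge per unordered pair, no
# self-loops; undirected edges are stored with endpoints in canonical
# (lexicographic) order.

#' Create a mixed graph
#'
#' @param nodes Character vector of node identifiers.
#' @param edges A data frame with columns `from`, `to` and either a logical
#'   `directed` column or a character `mark` column (`"--"` undirected,
#'   `"->"` directed). Default: no edges.
#' @return An object of class `mixed_graph`.
#' @examples
#' mixed_graph(c("a", "b", "c"), data.frame(from = "a", to = "b", directed = TRUE))
#' @export
mixed_graph <- function(nodes, edges = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) abort("duplicate node identifiers.")
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- tibble::tibble(from = character(0), to = character(0), directed = logical(0))
  } else {
    edges <- tibble::as_tibble(edges)
    if (!"directed" %in% names(edges)) {
      if (!"mark" %in% names(edges)) abort("edges need a `directed` or `mark` column.")
      edges$directed <- edges$mark == "->"
    }
    edges <- edges[, c("from", "to", "directed")]
    edges$from <- as.character(edges$from)
    edges$to <- as.character(edges$to)
    if (!all(c(edges$from, edges$to) %in% nodes)) abort("edge endpoint not in node set.")
    if (any(edges$from == edges$to)) abort("self-loops are not allowed.")
    # canonical order for undirected edges
    flip <- !edges$directed & edges$from > edges$to
    tmp <- edges$from[flip]; edges$from[flip] <- edges$to[flip]; edges$to[flip] <- tmp
    if (anyDuplicated(t(apply(cbind(edges$from, edges$to), 1, sort)))) {
      abort("at most one edge per unordered pair.")
    }
  }
  structure(list(nodes = nodes, edges = edges), class = "mixed_graph")
}

#' @export
print.mixed_graph <- function(x, ...) {
  nd <- sum(x$edges$directed)
  cat(sprintf(
    "<mixed_graph> %d nodes, %d edges (%d directed, %d undirected)\n",
    length(x$nodes), nrow(x$edges), nd, nrow(x$edges) - nd
  ))
  if (nrow(x$edges) > 0) {
    marks <- ifelse(x$edges$directed, "->", "--")
    cat(paste0("  ", x$edges$from, " ", marks, " ", x$edges$to, collapse = "\n"), "\n")
  }
  invisible(x)
}

# adjacency encoding: A[i,j] = 1 and A[j,i] = 1 -> undirected i - j;
# A[i,j] = 1, A[j,i] = 0 -> directed i -> j
graph_to_amat <- function(g) {
  v <- length(g$nodes)
  a <- matrix(0L, v, v, dimnames = list(g$nodes, g$nodes))
  if (nrow(g$edges) > 0) {
    fi <- match(g$edges$from, g$nodes)
    ti <- match(g$edges$to, g$nodes)
    a[cbind(fi, ti)] <- 1L
    und <- !g$edges$directed
    a[cbind(ti[und], fi[und])] <- 1L
  }
  a
}

amat_to_graph <- function(a) {
  nodes <- rownames(a)
  idx <- which(a == 1L, arr.ind = TRUE)
  keep <- idx[a[cbind(idx[, 2], idx[, 1])] == 0L | idx[, 1] < idx[, 2], , drop = FALSE]
  if (nrow(keep) == 0L) return(mixed_graph(nodes))
  directed <- a[cbind(keep[, 2], keep[, 1])] == 0L
  mixed_graph(nodes, tibble::tibble(
    from = nodes[keep[, 1]], to = nodes[keep[, 2]], directed = directed
  ))
}

graph_is_dag <- function(g) {
  if (nrow(g$edges) == 0L) return(TRUE)
  if (!all(g$edges$directed)) return(FALSE)
  ig <- igraph::graph_from_data_frame(
    g$edges[, c("from", "to")], directed = TRUE,
    vertices = data.frame(name = g$nodes)
  )
  igraph::is_dag(ig)
}

# Meek propagation rules R1-R3 to closure on an adjacency-coded PDAG.
# R1: a -> b, b - c, a/c nonadjacent        => b -> c
# R2: a -> b -> c, a - c                    => a -> c
# R3: a - b, a - c, a - d, c -> b, d -> b,
#     c/d nonadjacent                       => a -> b
meek_closure <- function(a, rules = 1:3) {
  v <- nrow(a)
  repeat {
    changed <- FALSE
    adj <- (a == 1L) | (t(a) == 1L)
    dir <- (a == 1L) & (t(a) == 0L)   # dir[i,j]: i -> j
    und <- (a == 1L) & (t(a) == 1L)
    if (1 %in% rules) {
      for (b in seq_len(v)) {
        ins <- which(dir[, b])
        outs <- which(und[b, ])
        for (cc in outs) for (aa in ins) {
          if (!adj[aa, cc]) {
            a[cc, b] <- 0L # orient b -> c
            changed <- TRUE
            und[b, cc] <- und[cc, b] <- FALSE
            dir[b, cc] <- TRUE
            break
          }
        }
      }
    }
    if (2 %in% rules) {
      for (aa in seq_len(v)) for (cc in which(und[aa, ])) {
        if (any(dir[aa, ] & dir[, cc])) {
          a[cc, aa] <- 0L # orient a -> c
          changed <- TRUE
          und[aa, cc] <- und[cc, aa] <- FALSE
          dir[aa, cc] <- TRUE
        }
      }
    }
    if (3 %in% rules) {
      for (aa in seq_len(v)) for (bb in which(und[aa, ])) {
        cd <- which(und[aa, ] & dir[, bb])
        if (length(cd) >= 2L) {
          na_pair <- FALSE
          for (i in seq_along(cd)) for (j in seq_along(cd)) {
            if (i < j && !adj[cd[i], cd[j]]) na_pair <- TRUE
          }
          if (na_pair) {
            a[bb, aa] <- 0L # orient a -> b
            changed <- TRUE
            und[aa, bb] <- und[bb, aa] <- FALSE
            dir[aa, bb] <- TRUE
          }
        }
      }
    }
    if (!changed) break
  }
  a
}

#' CPDAG of a DAG
#'
#' Converts a DAG to the canonical representative of its Markov equivalence
#' class: the skeleton with v-structure arrowheads kept and all further
#' orientations implied by the Meek propagation rules R1-R3; every other
#' edge is left undirected.
#'
#' @param dag A `mixed_graph` whose edges are all directed and acyclic.
#' @return A `mixed_graph` (the CPDAG).
#' @examples
#' g <- mixed_graph(c("x", "y", "z"),
#'   data.frame(from = c("x", "z"), to = c("z", "y"), directed = TRUE))
#' cpdag_of_dag(g) # chain: fully undirected
#' @export
cpdag_of_dag <- function(dag) {
  if (!inherits(dag, "mixed_graph")) abort("`dag` must be a mixed_graph.")
  if (!graph_is_dag(dag)) abort("input must be a directed acyclic graph.")
  d <- graph_to_amat(dag)                 # d[i,j] = 1 iff i -> j in the DAG
  v <- nrow(d)
  adj <- (d == 1L) | (t(d) == 1L)
  a <- matrix(0L, v, v, dimnames = dimnames(d))
  a[adj] <- 1L                            # start fully undirected
  # keep v-structure arrowheads: x -> z <- y with x,y nonadjacent
  for (z in seq_len(v)) {
    pa <- which(d[, z] == 1L)
    if (length(pa) >= 2L) {
      for (i in seq_along(pa)) for (j in seq_along(pa)) {
        if (i < j && !adj[pa[i], pa[j]]) {
          a[z, pa[i]] <- 0L
          a[z, pa[j]] <- 0L
        }
      }
    }
  }
  amat_to_graph(meek_closure(a, rules = 1:3))
}

#' Enumerate the unshielded triples of a graph
#'
#' All triples `x - z - y` (any edge marks) whose flanking pair `x`, `y` is
#' non-adjacent; each unordered triple is listed once, with `x < y`
#' lexicographically.
#'
#' @param graph A `mixed_graph`.
#' @return A tibble with columns `x`, `z`, `y`.
#' @export
unshielded_triples <- function(graph) {
  a <- graph_to_amat(graph)
  adj <- (a == 1L) | (t(a) == 1L)
  nodes <- graph$nodes
  res <- list()
  for (z in seq_along(nodes)) {
    nb <- which(adj[z, ])
    if (length(nb) >= 2L) {
      for (i in seq_along(nb)) for (j in seq_along(nb)) {
        if (i < j && !adj[nb[i], nb[j]]) {
          pair <- sort(nodes[c(nb[i], nb[j])], method = "radix")
          res[[length(res) + 1L]] <- c(pair[1], nodes[z], pair[2])
        }
      }
    }
  }
  if (length(res) == 0L) {
    return(tibble::tibble(x = character(0), z = character(0), y = character(0)))
  }
  m <- do.call(rbind, res)
  tibble::tibble(x = m[, 1], z = m[, 2], y = m[, 3])
}

#' Write / read a mixed graph as an edge-list TSV
#'
#' Tab-separated columns `node_a`, `mark`, `node_b` with mark `"--"`
#' (undirected) or `"->"` (directed). Isolated nodes are preserved through a
#' header comment line listing the full node set.
#'
#' @param graph A `mixed_graph`.
#' @param path Output (or input) file path.
#' @return `write_graph_tsv()` returns `path` invisibly; `read_graph_tsv()`
#'   returns a `mixed_graph`.
#' @export
write_graph_tsv <- function(graph, path) {
  lines <- c(
    paste0("# nodes: ", paste(graph$nodes, collapse = ",")),
    "node_a\tmark\tnode_b"
  )
  if (nrow(graph$edges) > 0) {
    marks <- ifelse(graph$edges$directed, "->", "--")
    lines <- c(lines, paste(graph$edges$from, marks, graph$edges$to, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_graph_tsv
#' @export
read_graph_tsv <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  nodes <- character(0)
  if (length(lines) > 0 && startsWith(lines[1], "# nodes:")) {
    nodes <- strsplit(sub("^# nodes:\\s*", "", lines[1]), ",")[[1]]
    lines <- lines[-1]
  }
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) > 0 && startsWith(lines[1], "node_a")) lines <- lines[-1]
  if (length(lines) == 0L) return(mixed_graph(nodes))
  parts <- do.call(rbind, strsplit(lines, "\t"))
  if (ncol(parts) != 3L) abort("malformed edge list: expected 3 tab-separated columns.")
  nodes <- union(nodes, c(parts[, 1], parts[, 3]))
  mixed_graph(nodes, tibble::tibble(
    from = parts[, 1], to = parts[, 3], directed = parts[, 2] == "->"
  ))
}
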