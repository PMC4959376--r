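# Independent oracles used across the test files. These deliberately avoid
# the package's own computational paths: brute-force enumeration, direct
# entropy expansions via base::table(), and exhaustive orientation search.

# brute-force multinomial normalization constant: sum over all compositions
# l_1 + ... + l_r = n of n!/(l_1!...l_r!) prod (l_k/n)^(l_k)
oracle_multinomial_constant <- function(n, r) {
  if (n == 0) return(1)
  total <- 0
  recurse <- function(remaining, parts_left, acc) {
    if (parts_left == 1L) {
      l <- c(acc, remaining)
      term <- exp(lfactorial(n) - sum(lfactorial(l)) +
                    sum(ifelse(l > 0, l * log(l / n), 0)))
      total <<- total + term
      return(invisible(NULL))
    }
    for (l1 in 0:remaining) recurse(remaining - l1, parts_left - 1L, c(acc, l1))
  }
  recurse(n, r, integer(0))
  total
}

# entropy of a joint distribution of data-frame columns via base::table
oracle_entropy <- function(df, cols) {
  if (length(cols) == 0L) return(0)
  counts <- as.vector(table(df[, cols, drop = FALSE]))
  counts <- counts[counts > 0]
  n <- sum(counts)
  -sum((counts / n) * log(counts / n))
}

# 3-point information by the full seven-entropy expansion
oracle_i3_expansion <- function(df, x, y, z) {
  oracle_entropy(df, x) + oracle_entropy(df, y) + oracle_entropy(df, z) -
    oracle_entropy(df, c(x, y)) - oracle_entropy(df, c(x, z)) -
    oracle_entropy(df, c(y, z)) + oracle_entropy(df, c(x, y, z))
}

oracle_cmi <- function(df, x, y, cond = character(0)) {
  oracle_entropy(df, c(x, cond)) + oracle_entropy(df, c(y, cond)) -
    oracle_entropy(df, c(x, y, cond)) - oracle_entropy(df, cond)
}

# random complete-case categorical data frame
random_cat_df <- function(n, v, levels = 2:3) {
  as.data.frame(lapply(seq_len(v), function(i) {
    r <- if (length(levels) == 1L) levels else sample(levels, 1)
    as.character(sample.int(r, n, replace = TRUE) - 1L)
  }), col.names = paste0("v", seq_len(v)))
}

# CPDAG by exhaustive search: enumerate every orientation of the DAG's
# skeleton, keep the acyclic ones with identical v-structures, and mark an
# edge directed only when all equivalent DAGs agree on its direction
oracle_cpdag <- function(dag) {
  edges <- dag$edges
  nodes <- dag$nodes
  stopifnot(all(edges$directed))
  m <- nrow(edges)
  vstructs <- function(e) {
    # canonical strings "a>z<b" for colliders with nonadjacent parents
    adj <- unique(rbind(e[, c("from", "to")],
                        stats::setNames(e[, c("to", "from")], c("from", "to"))))
    res <- character(0)
    for (z in nodes) {
      pa <- e$from[e$to == z]
      if (length(pa) >= 2) {
        for (i in seq_along(pa)) for (j in seq_along(pa)) {
          if (i < j) {
            p <- sort(c(pa[i], pa[j]))
            shielded <- any(adj$from == p[1] & adj$to == p[2])
            if (!shielded) res <- c(res, paste(p[1], z, p[2], sep = ">"))
          }
        }
      }
    }
    sort(res)
  }
  is_acyclic <- function(e) {
    ig <- igraph::graph_from_data_frame(e[, c("from", "to")], directed = TRUE,
                                        vertices = data.frame(name = nodes))
    igraph::is_dag(ig)
  }
  ref_vs <- vstructs(edges)
  same_dir <- rep(TRUE, m)   # all equivalent DAGs orient like the input
  any_flip <- rep(FALSE, m)
  for (mask in 0:(2^m - 1)) {
    flip <- as.logical(bitwAnd(mask, 2^(seq_len(m) - 1)))
    e2 <- edges
    e2$from[flip] <- edges$to[flip]
    e2$to[flip] <- edges$from[flip]
    if (is_acyclic(e2) && identical(vstructs(e2), ref_vs)) {
      any_flip <- any_flip | flip
    }
  }
  # an edge is directed in the CPDAG iff no equivalent DAG flips it
  mixed_graph(nodes, tibble::tibble(
    from = edges$from, to = edges$to, directed = !any_flip
  ))
}

# exact-recovery check of a fit against the true-DAG CPDAG
graphs_identical <- function(a, b) {
  key <- function(g) {
    if (nrow(g$edges) == 0) return(character(0))
    marks <- ifelse(g$edges$directed, "->", "--")
    sort(paste(g$edges$from, marks, g$edges$to))
  }
  setequal(a$nodes, b$nodes) && identical(key(a), key(b))
}
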