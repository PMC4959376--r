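test_that("mixed graphs canonicalize and validate edges", {
  g <- mixed_graph(c("b", "a"), data.frame(from = "b", to = "a", directed = FALSE))
  expect_equal(g$edges$from, "a") # undirected edges stored in canonical order
  expect_error(mixed_graph("a", data.frame(from = "a", to = "a", directed = TRUE)),
               "self-loops")
  expect_error(
    mixed_graph(c("a", "b"),
                data.frame(from = c("a", "b"), to = c("b", "a"),
                           directed = c(TRUE, TRUE))),
    "one edge"
  )
  expect_error(mixed_graph("a", data.frame(from = "a", to = "q", directed = TRUE)),
               "node set")
})

test_that("graph TSV round-trips including isolated nodes", {
  g <- mixed_graph(c("a", "b", "c", "lonely"),
                   data.frame(from = c("a", "b"), to = c("b", "c"),
                              directed = c(TRUE, FALSE)))
  path <- tempfile(fileext = ".tsv")
  write_graph_tsv(g, path)
  g2 <- read_graph_tsv(path)
  expect_setequal(g2$nodes, g$nodes)
  expect_equal(g2$edges, g$edges)
})

test_that("CPDAG conversion handles textbook cases", {
  chain <- mixed_graph(c("x", "z", "y"),
                       data.frame(from = c("x", "z"), to = c("z", "y"), directed = TRUE))
  cp <- cpdag_of_dag(chain)
  expect_false(any(cp$edges$directed)) # three Markov-equivalent orientations
  vs <- mixed_graph(c("x", "z", "y"),
                    data.frame(from = c("x", "y"), to = c("z", "z"), directed = TRUE))
  cp2 <- cpdag_of_dag(vs)
  expect_true(all(cp2$edges$directed)) # unique member of its class
  expect_true(all(cp2$edges$to == "z"))
  # collider plus child: v-structure kept, z -> w kept by propagation
  g4 <- mixed_graph(c("x", "z", "y", "w"),
                    data.frame(from = c("x", "y", "z"), to = c("z", "z", "w"),
                               directed = TRUE))
  cp4 <- cpdag_of_dag(g4)
  expect_true(all(cp4$edges$directed))
  # cyclic input is rejected
  cyc <- mixed_graph(c("a", "b", "c"),
                     data.frame(from = c("a", "b", "c"), to = c("b", "c", "a"),
                                directed = TRUE))
  expect_error(cpdag_of_dag(cyc), "acyclic")
})

test_that("CPDAG conversion agrees with exhaustive equivalence-class search", {
  withr::local_seed(15)
  for (rep in 1:20) {
    nv <- sample(4:5, 1)
    net <- random_bn(nv, avg_degree = sample(c(1.5, 2, 2.5), 1),
                     max_in_degree = 3, seed = 500 + rep)
    dag <- bn_dag(net)
    if (nrow(dag$edges) == 0) next
    expect_true(graphs_identical(cpdag_of_dag(dag), oracle_cpdag(dag)),
                label = sprintf("random DAG %d", rep))
  }
})

test_that("skeleton metrics reproduce the printed formulas", {
  nodes <- letters[1:5]
  ref <- mixed_graph(nodes, data.frame(from = c("a", "b"), to = c("b", "c"),
                                       directed = FALSE))
  expect_equal(skeleton_scores(ref, ref)$fscore, 1)
  empty <- mixed_graph(nodes)
  sc <- skeleton_scores(empty, ref)
  expect_equal(sc$precision, 0)
  expect_equal(sc$recall, 0)
  expect_equal(sc$fscore, 0)
  expect_true(sc$undefined_precision)
  # TP = 2, FP = 2, FN = 0 -> Prec = 0.5, Rec = 1, F = 2/3
  pred <- mixed_graph(nodes, data.frame(
    from = c("a", "b", "c", "d"), to = c("b", "c", "d", "e"), directed = FALSE))
  sc2 <- skeleton_scores(pred, ref)
  expect_equal(sc2[, c("tp", "fp", "fn")], tibble::tibble(tp = 2L, fp = 2L, fn = 0L))
  expect_equal(sc2$precision, 0.5)
  expect_equal(sc2$recall, 1)
  expect_equal(sc2$fscore, 2 / 3)
  expect_error(skeleton_scores(mixed_graph("zz"), ref), "node set")
})

test_that("misorientation accounting matches the primed definitions", {
  nodes <- c("x", "z", "y")
  ref <- mixed_graph(nodes, data.frame(from = c("x", "y"), to = c("z", "z"),
                                       directed = TRUE))
  # identical prediction: no misorientation, primed = unprimed
  r0 <- cpdag_scores(ref, ref)
  expect_equal(r0$tp_misorient, 0L)
  expect_equal(r0$precision_cpdag, r0$precision)
  expect_equal(r0$fscore_cpdag, r0$fscore)
  # correct skeleton, both edges left undirected: TP' = 0
  und <- mixed_graph(nodes, data.frame(from = c("x", "y"), to = c("z", "z"),
                                       directed = FALSE))
  r1 <- cpdag_scores(und, ref)
  expect_equal(r1$tp_misorient, 2L)
  expect_equal(r1$precision_cpdag, 0)
  expect_equal(r1$recall_cpdag, 0)
  # one of two edges reversed: TP' = 1, FP' = 1, Rec' = 1/2
  rev1 <- mixed_graph(nodes, data.frame(from = c("x", "z"), to = c("z", "y"),
                                        directed = TRUE))
  r2 <- cpdag_scores(rev1, ref)
  expect_equal(r2$tp_misorient, 1L)
  expect_equal(r2$precision_cpdag, 1 / 2) # TP' = 1, FP' = FP + 1 = 1
  expect_equal(r2$recall_cpdag, 1 / 2)    # TP' / (TP + FN) = 1/2
})

test_that("metrics degrade monotonically and primed never exceed unprimed", {
  withr::local_seed(23)
  nodes <- letters[1:6]
  ref <- mixed_graph(nodes, data.frame(
    from = c("a", "b", "c", "d"), to = c("b", "c", "d", "e"),
    directed = c(TRUE, FALSE, FALSE, TRUE)))
  pred <- mixed_graph(nodes, data.frame(
    from = c("a", "b", "c"), to = c("b", "c", "d"),
    directed = c(TRUE, TRUE, FALSE)))
  base <- cpdag_scores(pred, ref)
  expect_lte(base$precision_cpdag, base$precision)
  expect_lte(base$recall_cpdag, base$recall)
  # adding a spurious edge cannot raise precision
  spur <- mixed_graph(nodes, rbind(pred$edges,
                                   tibble::tibble(from = "a", to = "f", directed = FALSE)))
  expect_lte(cpdag_scores(spur, ref)$precision, base$precision)
  # dropping a true edge cannot raise recall
  less <- mixed_graph(nodes, pred$edges[-1, ])
  expect_lte(cpdag_scores(less, ref)$recall, base$recall)
})
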