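test_that("multiplex aggregation prefers the primary layer's edges", {
  g <- toy_multihet()
  prot <- g$components$prot
  scores <- list(phys = c(p1 = 0.1, p2 = 0.1, p3 = 0.1, p4 = 0.4),
                 func = c(p2 = 0.3, p3 = 0.1, p5 = 0.2))
  agg <- aggregate_multiplex(prot, primary_layer = "phys", scores = scores)
  expect_setequal(agg$nodes, c("p1", "p2", "p3", "p4", "p5"))
  # p2-p3 exists in both layers: physical weight (2) wins over func (5)
  e23 <- agg$edges[agg$edges$from == "p2" & agg$edges$to == "p3", ]
  expect_equal(e23$weight, 2)
  expect_equal(e23$layer, "phys")
  # p3-p5 only in func: carried over
  expect_true(any(agg$edges$from == "p3" & agg$edges$to == "p5"))
  # replica scores averaged: p2 in both layers
  expect_equal(unname(agg$scores["p2"]), 0.2)
  expect_equal(unname(agg$scores["p4"]), 0.4)

  # choosing func as primary flips the precedence
  agg2 <- aggregate_multiplex(prot, primary_layer = "func", scores = scores)
  expect_equal(agg2$edges[agg2$edges$from == "p2" &
                            agg2$edges$to == "p3", "weight"], 5)
  expect_error(aggregate_multiplex(prot, primary_layer = "nope"), "unknown")

  # single-layer aggregation is the identity
  met <- g$components$met
  aggm <- aggregate_multiplex(met)
  expect_setequal(aggm$nodes, c("m1", "m2", "m3"))
  expect_equal(nrow(aggm$edges), 2L)
})

test_that("module expansion restricts each original layer", {
  g <- toy_multihet()
  prot <- g$components$prot
  ex <- expand_module(c("p2", "p3", "p5"), prot)
  expect_named(ex, c("phys", "func"))
  expect_setequal(ex$phys$nodes, c("p2", "p3"))
  expect_equal(nrow(ex$phys$edges), 1L)  # only p2-p3 survives
  expect_setequal(ex$func$nodes, c("p2", "p3", "p5"))
  expect_equal(nrow(ex$func$edges), 2L)
  # full node set: expansion returns the original layers
  full <- expand_module(unique(unlist(lapply(prot$layers, `[[`, "nodes"))),
                        prot)
  expect_equal(nrow(full$phys$edges), nrow(prot$layers$phys$edges))
  # module confined to one layer leaves the other empty
  only1 <- expand_module("p1", prot)
  expect_equal(length(only1$func$nodes), 0L)
})

test_that("score shifting retains the requested fraction", {
  p <- c(5, 3, 8, 1, 9)
  w <- shift_scores(p, 0.5)
  expect_equal(sum(w >= 0), 3L)  # ceiling(5 * 0.5)
  expect_equal(which.max(w), which.max(p))
  # positive affine transforms leave the sign pattern unchanged
  w2 <- shift_scores(2 * p + 7, 0.5)
  expect_equal(sign(w), sign(w2))
  for (f in c(0.2, 0.4, 0.8)) {
    pp <- runif(37)
    expect_equal(sum(shift_scores(pp, f) >= 0), ceiling(37 * f))
  }
  wd <- shift_scores(rep(2, 5), 0.5)
  expect_true(attr(wd, "degenerate"))
  expect_equal(as.numeric(wd), rep(0, 5))
  expect_error(shift_scores(p, 1.2), "retention_fraction")
})

test_that("the connected-subgraph heuristic honors its contract on paths", {
  path3 <- igraph::make_graph(~ a - b, b - c)
  # +2 -1 +2: bridging pays
  expect_equal(sort(mwcs_heuristic(path3, c(2, -1, 2))), 1:3)
  # +2 -5 +2: bridging too expensive; a single positive end remains
  sel <- mwcs_heuristic(path3, c(2, -5, 2))
  expect_length(sel, 1L)
  expect_true(sel %in% c(1L, 3L))
  # all-positive connected graph is returned whole
  expect_equal(sort(mwcs_heuristic(path3, c(1, 1, 1))), 1:3)
  # a single positive node among hostile neighbors stands alone
  star <- igraph::make_star(4, mode = "undirected", center = 1)
  expect_equal(mwcs_heuristic(star, c(-3, 5, -3, -3)), 2L)
  # no positive node: empty selection
  expect_length(mwcs_heuristic(path3, c(-1, -2, -1)), 0L)
})

test_that("the heuristic stays near the exhaustive optimum and connected", {
  set.seed(17)
  for (rep in 1:30) {
    n <- sample(5:11, 1)
    repeat {
      gr <- igraph::sample_gnp(n, runif(1, 0.25, 0.5))
      if (igraph::is_connected(gr)) break
    }
    w <- rnorm(n)
    if (all(w <= 0)) w[sample(n, 1)] <- 0.5
    sel <- mwcs_heuristic(gr, w)
    expect_true(igraph::is_connected(igraph::induced_subgraph(gr, sel)))
    expect_gte(sum(w[sel]), max(w) - 1e-12)  # at least the best single node
    expect_gte(sum(w[sel]), 0.9 * mwcs_bruteforce(gr, w))
  }
})

test_that("subnetwork scores reward seed strength and cohesion", {
  gr <- igraph::make_graph(~ a - b, b - c, c - a, d - e, f)
  seeds <- c(a = 3, b = 3, c = 3, d = 3, e = 3, f = 0)
  s_conn <- score_subnetwork(c("a", "b", "c"), seeds, gr)
  s_frag <- score_subnetwork(c("a", "d", "f"), seeds, gr)
  expect_gt(s_conn, s_frag)  # same seeds, fragmentation penalized

  # the full network has experimental term ~ 0 by standardization
  s_full <- score_subnetwork(igraph::V(gr)$name, seeds, gr)
  expect_lt(abs(attr(s_full, "experimental")), 1e-12)

  s_one <- score_subnetwork("a", seeds, gr)
  expect_true(is.finite(s_one))
  expect_equal(attr(s_one, "topological"), 0)  # no internal edges
  expect_error(score_subnetwork(character(0), seeds, gr), "empty")
})

test_that("the search shrinks monotonically to a connected module", {
  g <- rand_er_mh(150, 0.05, seed = 3)
  idx <- build_index(g)
  seeds <- stats::setNames(de_seed_values(idx$n, seed = 5), idx$table$node)
  m <- amend_run(g, seeds, n_target = 25)
  expect_s3_class(m, "module_result")
  expect_true(all(diff(m$iterations$n_nodes) < 0))
  expect_lte(m$n_iterations,
             ceiling(log(150 / 25) / log(2)) + 2)  # decay bound
  # the selected module is connected on its induced edge set
  ig <- igraph::graph_from_data_frame(
    m$module$edges, directed = FALSE,
    vertices = m$module$nodes$node_key)
  expect_true(igraph::is_connected(ig))
  expect_equal(m$iterations$score[m$best_iteration],
               max(m$iterations$score))
  # provenance columns are populated
  expect_true(all(nchar(m$module$nodes$layers) > 0))
})

test_that("a target at or above the graph size stops after one iteration", {
  g <- rand_er_mh(40, 0.15, seed = 13)
  idx <- build_index(g)
  seeds <- stats::setNames(runif(idx$n), idx$table$node)
  m <- amend_run(g, seeds, n_target = 500)
  expect_equal(m$n_iterations, 1L)
  # the module is the connected-subgraph extraction of the whole network
  expect_gte(nrow(m$module$nodes), 39L)
})

test_that("uniform seeds still produce a topology-driven module", {
  g <- generate_graph(synthetic_spec(n_nodes = 120, seed = 19))
  idx <- build_index(g)
  seeds <- stats::setNames(rep(1, idx$n), idx$table$node)
  expect_no_error(m <- amend_run(g, seeds, n_target = 20))
  expect_gte(nrow(m$module$nodes), 1L)
})

test_that("aggregate, extract, expand round-trips across layers", {
  g <- toy_multihet()
  idx <- build_index(g)
  seeds <- list(prot = c(p1 = 0.5, p2 = 3, p3 = 4, p4 = 0.1, p5 = 2),
                met = c(m1 = 0.2, m2 = 2, m3 = 0.3))
  m <- amend_run(g, seeds, n_target = 5, lambda = 0.4, delta = 0.3)
  nodes_by_comp <- split(m$module$nodes$node, m$module$nodes$component)
  # expanded per-layer subgraphs union back to the module's node set
  for (cid in names(nodes_by_comp)) {
    ex <- m$module$layers[[cid]]
    expect_setequal(unique(unlist(lapply(ex, `[[`, "nodes"))),
                    nodes_by_comp[[cid]])
    # every expanded edge existed in its source layer
    for (lid in names(ex)) {
      orig <- g$components[[cid]]$layers[[lid]]$edges
      ok <- paste(ex[[lid]]$edges$from, ex[[lid]]$edges$to) %in%
        paste(orig$from, orig$to)
      expect_true(all(ok))
    }
  }
  # module edges within a multiplex component carry primary-layer weights
  prot_edges <- m$module$edges[grepl("^prot", m$module$edges$from) &
                                 grepl("^prot", m$module$edges$to), ]
  if (nrow(prot_edges)) {
    agg <- aggregate_multiplex(g$components$prot, "phys")
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    want <- stats::setNames(agg$edges$weight,
                            key(agg$edges$from, agg$edges$to))
    got_key <- key(sub("^prot::", "", prot_edges$from),
                   sub("^prot::", "", prot_edges$to))
    expect_equal(unname(want[got_key]), prot_edges$weight)
  }
})

test_that("iteration-of-removal bookkeeping covers every aggregated node", {
  g <- rand_er_mh(100, 0.06, seed = 23)
  idx <- build_index(g)
  seeds <- stats::setNames(de_seed_values(idx$n, seed = 7), idx$table$node)
  m <- amend_run(g, seeds, n_target = 20)
  expect_length(m$removal_iteration, length(unique(idx$table$node)))
  removed <- m$removal_iteration[!is.na(m$removal_iteration)]
  expect_true(all(removed >= 1 & removed <= m$n_iterations))
  # nodes of the final iteration's subnetwork are never marked removed
  last_nodes <- m$module$nodes$node_key
  if (m$best_iteration == m$n_iterations)
    expect_true(all(is.na(m$removal_iteration[last_nodes])))
})
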