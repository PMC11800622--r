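test_that("layers validate edges, collapse duplicates, and reject bad input", {
  ly <- mh_layer("L1", data.frame(from = c("a", "b", "a"),
                                  to = c("b", "c", "b"),
                                  weight = c(1, 2, 3)))
  expect_setequal(ly$nodes, c("a", "b", "c"))
  expect_equal(nrow(ly$edges), 2L)
  ab <- ly$edges[ly$edges$from == "a" & ly$edges$to == "b", ]
  expect_equal(ab$weight, 4)  # duplicate pair summed

  expect_error(mh_layer("L1", data.frame(from = "a", to = "b", weight = -1)),
               "nonnegative")
  expect_error(mh_layer("L1", data.frame(from = "a", to = "a")), "self-loop")
  expect_silent(mh_layer("L1", data.frame(from = "a", to = "a"),
                         allow_selfloops = TRUE))
  # missing weights default to 1
  expect_equal(mh_layer("L1", data.frame(from = "a", to = "b"))$edges$weight, 1)
})

test_that("simplex constraints on tau and eta are enforced", {
  l1 <- mh_layer("L1", data.frame(from = "a", to = "b"))
  l2 <- mh_layer("L2", data.frame(from = "a", to = "c"))
  expect_error(mh_component("c1", list(l1, l2), tau = c(0.6, 0.6)),
               "simplex")
  expect_error(mh_graph(mh_component("c1", list(l1, l2)), eta = c(0.5, 0.7)),
               "length")
  g <- mh_graph(mh_component("c1", list(l1, l2)))
  expect_equal(unname(g$components$c1$tau), c(0.5, 0.5))
  expect_equal(unname(g$eta), 1)
})

test_that("layers with zero node overlap are accepted and uncoupled", {
  l1 <- mh_layer("L1", data.frame(from = "a", to = "b"))
  l2 <- mh_layer("L2", data.frame(from = "x", to = "y"))
  g <- mh_graph(mh_component("c1", list(l1, l2)))
  idx <- build_index(g)
  blocks <- amendr:::adjacency_blocks(g, idx)
  expect_equal(length(blocks$inter_layer@x), 0L)
  # and a shared node does get coupled
  l3 <- mh_layer("L2", data.frame(from = "a", to = "y"))
  g2 <- mh_graph(mh_component("c1", list(l1, l3)))
  b2 <- amendr:::adjacency_blocks(g2, build_index(g2))
  expect_gt(sum(b2$inter_layer), 0)
})

test_that("the global index is a deterministic bijection over replicas", {
  g <- toy_multihet()
  idx <- build_index(g)
  # 4 (phys) + 3 (func) + 3 (mmi) replicas; shared ids counted per layer
  expect_equal(idx$n, 4L + 3L + 3L)
  # round trip (component, layer, node) -> i -> (component, layer, node)
  for (i in seq_len(idx$n)) {
    row <- idx$table[i, ]
    expect_identical(index_of(idx, row$component, row$layer, row$node), i)
  }
  # node ids are lexicographic within each (component, layer) block
  for (blk in split(idx$table$node,
                    paste(idx$table$component, idx$table$layer)))
    expect_identical(blk, sort(blk, method = "radix"))
  expect_true(is.na(index_of(idx, "prot", "phys", "nope")))
})

test_that("config round trip preserves node and edge sets", {
  dir <- withr::local_tempdir()
  g <- generate_graph(synthetic_spec(n_components = 2, n_layers = 2,
                                     n_nodes = 30, overlap = 0.5,
                                     bipartite_density = 0.05, seed = 4))
  cfg <- write_graph_files(g, dir)
  g2 <- read_graph(cfg)
  expect_identical(names(g2$components), names(g$components))
  for (cid in names(g$components)) {
    for (lid in names(g$components[[cid]]$layers)) {
      a <- g$components[[cid]]$layers[[lid]]
      b <- g2$components[[cid]]$layers[[lid]]
      expect_setequal(a$nodes, b$nodes)
      ka <- paste(a$edges$from, a$edges$to, signif(a$edges$weight, 12))
      kb <- paste(b$edges$from, b$edges$to, signif(b$edges$weight, 12))
      expect_setequal(ka, kb)
    }
  }
  expect_equal(g2$lambda, g$lambda)
  expect_equal(unname(g2$eta), unname(g$eta))
  # a second round trip is the identity on what the first produced
  dir2 <- withr::local_tempdir()
  g3 <- read_graph(write_graph_files(g2, dir2))
  expect_equal(g3$components$c1$layers$L1$edges,
               g2$components$c1$layers$L1$edges)
})

test_that("a one-layer TSV config is echoed verbatim into the graph", {
  dir <- withr::local_tempdir()
  writeLines(c("source\ttarget\tweight", "a\tb\t1", "b\tc\t2", "c\td\t1"),
             file.path(dir, "edges.tsv"))
  yaml::write_yaml(list(components = list(list(id = "c1", layers = list(
    list(id = "L1", edges = "edges.tsv"))))), file.path(dir, "config.yaml"))
  g <- read_graph(file.path(dir, "config.yaml"))
  expect_equal(build_index(g)$n, 4L)
  expect_equal(sort(g$components$c1$layers$L1$nodes), c("a", "b", "c", "d"))
})

test_that("bipartite endpoints are checked against their components", {
  dir <- withr::local_tempdir()
  writeLines(c("source\ttarget\tweight", "a\tb\t1"), file.path(dir, "l1.tsv"))
  writeLines(c("source\ttarget\tweight", "x\ty\t1"), file.path(dir, "l2.tsv"))
  writeLines(c("source\ttarget\tweight", "a\tzz\t1"), file.path(dir, "bp.tsv"))
  yaml::write_yaml(list(
    components = list(list(id = "c1", layers = list(list(id = "L1",
                                                         edges = "l1.tsv"))),
                      list(id = "c2", layers = list(list(id = "L1",
                                                         edges = "l2.tsv")))),
    bipartite = list(list(between = list("c1", "c2"), edges = "bp.tsv"))),
    file.path(dir, "config.yaml"))
  err <- tryCatch(read_graph(file.path(dir, "config.yaml")),
                  error = function(e) conditionMessage(e))
  expect_match(err, "zz")
  expect_match(err, "bp.tsv")
})

test_that("graph config violating the tau simplex is rejected with the constraint", {
  dir <- withr::local_tempdir()
  writeLines(c("source\ttarget\tweight", "a\tb\t1"), file.path(dir, "l1.tsv"))
  writeLines(c("source\ttarget\tweight", "a\tc\t1"), file.path(dir, "l2.tsv"))
  yaml::write_yaml(list(components = list(list(
    id = "c1", tau = c(0.6, 0.6),
    layers = list(list(id = "L1", edges = "l1.tsv"),
                  list(id = "L2", edges = "l2.tsv"))))),
    file.path(dir, "config.yaml"))
  expect_error(read_graph(file.path(dir, "config.yaml")), "sum == 1")
})

test_that("written modules round-trip through GraphML", {
  dir <- withr::local_tempdir()
  g <- rand_er_mh(40, 0.15, seed = 11)
  idx <- build_index(g)
  seeds <- stats::setNames(de_seed_values(idx$n, seed = 2), idx$table$node)
  m <- amend_run(g, seeds, n_target = 10)
  files <- write_module(m, dir)
  expect_true(all(file.exists(files)))
  ig <- igraph::read_graph(file.path(dir, "module.graphml"),
                           format = "graphml")
  expect_setequal(igraph::V(ig)$name, m$module$nodes$node_key)
  expect_equal(igraph::ecount(ig), nrow(m$module$edges))
  log <- jsonlite::read_json(file.path(dir, "run.json"))
  expect_equal(length(log$iterations), m$n_iterations)
})

test_that("empty modules are written without error", {
  dir <- withr::local_tempdir()
  m <- structure(list(
    module = list(nodes = data.frame(node_key = character(),
                                     component = character(),
                                     node = character(), seed = numeric(),
                                     score = numeric()),
                  edges = data.frame(from = character(), to = character(),
                                     weight = numeric())),
    iterations = data.frame(), best_iteration = integer(0),
    stopping_reason = "no_positive_weights",
    removal_iteration = numeric(0), n_iterations = 0L),
    class = "module_result")
  files <- write_module(m, dir)
  expect_true(all(file.exists(files)))
})
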