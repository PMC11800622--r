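# Typed representation of multiplex-heterogeneous graphs: layers of weighted
# undirected edges grouped into components, bipartite couplings between
# components, and a deterministic global replica index.

#' Create a graph layer
#'
#' A layer is an undirected, weighted graph over string node identifiers. It is
#' the elementary building block of a multiplex component: layers of one
#' component share a node type (e.g. proteins) but carry different edge types
#' (e.g. physical vs. functional interactions).
#'
#' Duplicate edges over the same unordered node pair are collapsed by summing
#' their weights. Self-loops are rejected unless `allow_selfloops = TRUE`.
#'
#' @param layer_id Character scalar naming the layer.
#' @param edges Data frame with columns `from`, `to` and optionally `weight`
#'   (defaults to 1). May be `NULL` for an edgeless layer.
#' @param nodes Optional character vector of node ids; the node set is the
#'   union of `nodes` and all edge endpoints.
#' @param allow_selfloops Keep `u == v` edges instead of raising an error.
#' @return An object of class `mh_layer` with fields `layer_id`, `nodes`,
#'   `edges`.
#' @export
mh_layer <- function(layer_id, edges = NULL, nodes = NULL,
                     allow_selfloops = FALSE) {
  stopifnot(is.character(layer_id), length(layer_id) == 1L)
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  }
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  if (!all(c("from", "to") %in% names(edges)))
    stop("edges must have columns 'from' and 'to'")
  if (is.null(edges$weight)) edges$weight <- rep(1, nrow(edges))
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  edges$weight <- as.numeric(edges$weight)
  edges$weight[is.na(edges$weight)] <- 1
  if (any(edges$weight < 0))
    stop("edge weights must be nonnegative in layer '", layer_id, "'")
  loops <- edges$from == edges$to
  if (any(loops) && !allow_selfloops)
    stop("self-loops are not allowed in layer '", layer_id,
         "' (node '", edges$from[which(loops)[1L]], "')")
  # collapse duplicate unordered pairs by summing weights
  a <- pmin(edges$from, edges$to)
  b <- pmax(edges$from, edges$to)
  key <- paste(a, b, sep = "\r")
  if (anyDuplicated(key)) {
    w <- tapply(edges$weight, key, sum)
    first <- !duplicated(key)
    edges <- data.frame(from = a[first], to = b[first],
                        weight = as.numeric(w[key[first]]),
                        stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(from = a, to = b, weight = edges$weight,
                        stringsAsFactors = FALSE)
  }
  nodes <- unique(c(as.character(nodes), edges$from, edges$to))
  structure(list(layer_id = layer_id, nodes = nodes, edges = edges),
            class = "mh_layer")
}

#' Create a multiplex component
#'
#' A component groups one or more layers over a common node type. Replicas of
#' the same node id in different layers are coupled by inter-layer edges during
#' transition-matrix assembly. Layer node sets may differ, including zero
#' overlap.
#'
#' @param component_id Character scalar naming the component.
#' @param layers List of [mh_layer()] objects.
#' @param tau Numeric vector of per-layer seed weights on the simplex
#'   (`sum(tau) == 1`, `tau >= 0`); uniform when `NULL`.
#' @return An object of class `mh_component`.
#' @export
mh_component <- function(component_id, layers, tau = NULL) {
  stopifnot(is.character(component_id), length(component_id) == 1L)
  if (inherits(layers, "mh_layer")) layers <- list(layers)
  stopifnot(length(layers) >= 1L,
            all(vapply(layers, inherits, logical(1), "mh_layer")))
  ids <- vapply(layers, `[[`, character(1), "layer_id")
  if (anyDuplicated(ids))
    stop("duplicate layer_id in component '", component_id, "'")
  names(layers) <- ids
  if (is.null(tau)) tau <- rep(1 / length(layers), length(layers))
  check_simplex(tau, length(layers),
                sprintf("tau for component '%s'", component_id))
  names(tau) <- ids
  structure(list(component_id = component_id, layers = layers, tau = tau),
            class = "mh_component")
}

#' Create a multiplex-heterogeneous graph
#'
#' Components (one per node type) are connected by bipartite edge sets. The
#' crosstalk parameters govern, for every source replica, how much transition
#' probability is allocated to switching layers within a multiplex (`lambda`)
#' and to jumping between components along bipartite edges (`delta`).
#'
#' @param components List of [mh_component()] objects.
#' @param bipartite List of couplings, each a list with fields `between`
#'   (character vector of two component ids) and `edges` (data frame `from`,
#'   `to`, optional `weight`; `from` in the first component, `to` in the
#'   second).
#' @param eta Numeric vector of per-component seed weights on the simplex;
#'   uniform when `NULL`.
#' @param lambda Layer-switch probability in `[0, 1]`.
#' @param delta Component-jump probability in `[0, 1]`.
#' @param interlayer_weight Weight given to the coupling edge between replicas
#'   of a shared node id in two layers of one multiplex (default 1).
#' @return An object of class `mh_graph`.
#' @export
mh_graph <- function(components, bipartite = list(), eta = NULL,
                     lambda = 0.5, delta = 0.5, interlayer_weight = 1) {
  if (inherits(components, "mh_component")) components <- list(components)
  stopifnot(length(components) >= 1L,
            all(vapply(components, inherits, logical(1), "mh_component")))
  ids <- vapply(components, `[[`, character(1), "component_id")
  if (anyDuplicated(ids)) stop("duplicate component_id")
  names(components) <- ids
  if (is.null(eta)) eta <- rep(1 / length(components), length(components))
  check_simplex(eta, length(components), "eta")
  names(eta) <- ids
  stopifnot(length(lambda) == 1L, lambda >= 0, lambda <= 1,
            length(delta) == 1L, delta >= 0, delta <= 1,
            interlayer_weight >= 0)
  bipartite <- lapply(bipartite, function(bp) {
    stopifnot(is.list(bp), length(bp$between) == 2L)
    if (!all(bp$between %in% ids))
      stop("bipartite coupling references unknown component: ",
           paste(setdiff(bp$between, ids), collapse = ", "))
    ed <- as.data.frame(bp$edges, stringsAsFactors = FALSE)
    if (is.null(ed$weight)) ed$weight <- rep(1, nrow(ed))
    ed$from <- as.character(ed$from); ed$to <- as.character(ed$to)
    ed$weight <- as.numeric(ed$weight)
    if (any(ed$weight < 0)) stop("bipartite edge weights must be nonnegative")
    for (side in 1:2) {
      comp <- components[[bp$between[side]]]
      known <- unique(unlist(lapply(comp$layers, `[[`, "nodes")))
      col <- if (side == 1) ed$from else ed$to
      bad <- setdiff(col, known)
      if (length(bad))
        stop("bipartite edge endpoint '", bad[1L],
             "' not found in component '", bp$between[side], "'",
             if (!is.null(bp$file)) paste0(" (file: ", bp$file, ")") else "")
    }
    list(between = bp$between, edges = ed, file = bp$file)
  })
  structure(list(components = components, bipartite = bipartite, eta = eta,
                 lambda = lambda, delta = delta,
                 interlayer_weight = interlayer_weight),
            class = "mh_graph")
}

check_simplex <- function(x, n, what, tol = 1e-8) {
  if (length(x) != n)
    stop(what, " must have length ", n)
  if (any(x < 0) || abs(sum(x) - 1) > tol)
    stop(what, " violates the simplex constraint: weights must satisfy ",
         "sum == 1 and all >= 0 (got sum = ", format(sum(x)), ")")
  invisible(x)
}

#' @export
print.mh_graph <- function(x, ...) {
  idx <- build_index(x)
  cat("mh_graph:", length(x$components), "component(s),",
      nrow(idx$table), "replicas\n")
  for (comp in x$components) {
    cat("  component '", comp$component_id, "': ", length(comp$layers),
        " layer(s)\n", sep = "")
    for (lay in comp$layers)
      cat("    layer '", lay$layer_id, "': ", length(lay$nodes), " nodes, ",
          nrow(lay$edges), " edges\n", sep = "")
  }
  cat("  bipartite couplings:", length(x$bipartite),
      "| lambda =", x$lambda, "| delta =", x$delta, "\n")
  invisible(x)
}

#' Build the global replica index
#'
#' Maps every `(component, layer, node)` replica to an integer in `1..N`.
#' Ordering is deterministic: components in graph order, layers in component
#' order, node ids lexicographic within each layer. A node present in two
#' layers gets two distinct indices.
#'
#' @param g An [mh_graph()].
#' @return An object of class `mh_index` with fields `table` (data frame
#'   `component`, `layer`, `node`) and `n`.
#' @export
build_index <- function(g) {
  stopifnot(inherits(g, "mh_graph"))
  comp <- character(0); lay <- character(0); node <- character(0)
  for (cm in g$components) {
    for (ly in cm$layers) {
      ns <- sort(ly$nodes, method = "radix")
      comp <- c(comp, rep(cm$component_id, length(ns)))
      lay <- c(lay, rep(ly$layer_id, length(ns)))
      node <- c(node, ns)
    }
  }
  tbl <- data.frame(component = comp, layer = lay, node = node,
                    stringsAsFactors = FALSE)
  lookup <- seq_len(nrow(tbl))
  names(lookup) <- index_key(comp, lay, node)
  structure(list(table = tbl, lookup = lookup, n = nrow(tbl)),
            class = "mh_index")
}

index_key <- function(component, layer, node) {
  paste(component, layer, node, sep = "\r")
}

#' Look up global indices of replicas
#'
#' @param index An `mh_index`.
#' @param component,layer,node Character vectors (recycled to common length).
#' @return Integer vector of global indices; `NA` for unknown replicas.
#' @export
index_of <- function(index, component, layer, node) {
  unname(index$lookup[index_key(component, layer, node)])
}

#' @export
print.mh_index <- function(x, ...) {
  cat("mh_index over", x$n, "replicas\n")
  invisible(x)
}

# Sparse symmetric adjacency of one layer over `nodes` (lexicographic order).
layer_adjacency <- function(layer, nodes = sort(layer$nodes, method = "radix")) {
  n <- length(nodes)
  ed <- layer$edges
  i <- match(ed$from, nodes); j <- match(ed$to, nodes)
  keep <- !is.na(i) & !is.na(j)
  i <- i[keep]; j <- j[keep]; w <- ed$weight[keep]
  off <- i != j
  Matrix::sparseMatrix(i = c(i, j[off]), j = c(j, i[off]), x = c(w, w[off]),
                       dims = c(n, n), dimnames = list(nodes, nodes))
}

#' Read a multiplex-heterogeneous graph from a declarative config file
#'
#' The config is a YAML document naming components, their layers (each backed
#' by an edge-list TSV with header `source<TAB>target<TAB>weight`, or a GraphML
#' file), bipartite couplings between components, and the parameters `eta`,
#' `tau`, `lambda`, `delta`, `interlayer_weight`. Relative file paths are
#' resolved against the config's directory. Missing weights default to 1;
#' omitted `eta`/`tau` default to uniform.
#'
#' @param config_path Path to the YAML config.
#' @return An [mh_graph()].
#' @examples
#' \dontrun{g <- read_graph("config.yaml")}
#' @export
read_graph <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  base <- dirname(normalizePath(config_path))
  resolve <- function(p) if (file.exists(p)) p else file.path(base, p)
  comps <- lapply(cfg$components, function(cc) {
    layers <- lapply(cc$layers, function(ll) {
      if (!is.null(ll$edges)) {
        path <- resolve(ll$edges)
        if (!file.exists(path)) stop("edge list not found: ", path)
        ed <- utils::read.delim(path, stringsAsFactors = FALSE)
        names(ed)[1:2] <- c("from", "to")
        if (ncol(ed) >= 3) names(ed)[3] <- "weight"
        mh_layer(ll$id, ed)
      } else if (!is.null(ll$graphml)) {
        path <- resolve(ll$graphml)
        if (!file.exists(path)) stop("graphml file not found: ", path)
        ig <- igraph::read_graph(path, format = "graphml")
        ed <- igraph::as_data_frame(ig, what = "edges")
        ed <- data.frame(from = ed$from, to = ed$to,
                         weight = if ("weight" %in% names(ed)) ed$weight else 1,
                         stringsAsFactors = FALSE)
        mh_layer(ll$id, ed, nodes = igraph::V(ig)$name)
      } else stop("layer '", ll$id, "' needs an 'edges' or 'graphml' entry")
    })
    mh_component(cc$id, layers, tau = unlist(cc$tau))
  })
  bip <- lapply(cfg$bipartite, function(bb) {
    path <- resolve(bb$edges)
    if (!file.exists(path)) stop("bipartite edge list not found: ", path)
    ed <- utils::read.delim(path, stringsAsFactors = FALSE)
    names(ed)[1:2] <- c("from", "to")
    if (ncol(ed) >= 3) names(ed)[3] <- "weight"
    list(between = unlist(bb$between), edges = ed, file = path)
  })
  mh_graph(comps, bipartite = bip, eta = unlist(cfg$eta),
           lambda = cfg$lambda %||% 0.5, delta = cfg$delta %||% 0.5,
           interlayer_weight = cfg$interlayer_weight %||% 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a per-layer seed value table
#'
#' Seed tables are TSVs with header `node_id<TAB>value`, one value per node;
#' values must be nonnegative.
#'
#' @param path Path to the TSV.
#' @return Named numeric vector.
#' @export
read_seed_table <- function(path) {
  tb <- utils::read.delim(path, stringsAsFactors = FALSE)
  v <- as.numeric(tb[[2]])
  if (any(v < 0, na.rm = TRUE)) stop("seed values must be nonnegative: ", path)
  stats::setNames(v, as.character(tb[[1]]))
}

#' Convert the full replica graph to igraph
#'
#' Builds an undirected igraph whose vertices are replicas (named
#' `component::layer::node`, with attributes `component`, `layer`, `node`) and
#' whose edges are the union of intra-layer edges, inter-layer couplings, and
#' inter-component bipartite edges, each carrying `weight` and `type`.
#'
#' @param g An [mh_graph()].
#' @param index Optional pre-built [build_index()].
#' @return An igraph object.
#' @export
as_igraph_replicas <- function(g, index = build_index(g)) {
  blocks <- adjacency_blocks(g, index)
  edge_df <- function(A, type) {
    tp <- Matrix::summary(A)
    tp <- tp[tp$i < tp$j, , drop = FALSE]
    if (!nrow(tp))
      return(data.frame(from = integer(), to = integer(), weight = numeric(),
                        type = character()))
    data.frame(from = tp$i, to = tp$j, weight = tp$x, type = type,
               stringsAsFactors = FALSE)
  }
  ed <- rbind(edge_df(blocks$intra, "intra"),
              edge_df(blocks$inter_layer, "inter_layer"),
              edge_df(blocks$inter_component, "inter_component"))
  ig <- igraph::make_empty_graph(n = index$n, directed = FALSE)
  igraph::V(ig)$name <- index_key(index$table$component, index$table$layer,
                                  index$table$node)
  igraph::V(ig)$component <- index$table$component
  igraph::V(ig)$layer <- index$table$layer
  igraph::V(ig)$node <- index$table$node
  if (nrow(ed))
    ig <- igraph::add_edges(ig, rbind(ed$from, ed$to),
                            weight = ed$weight, type = ed$type)
  ig
}

#' Write a module result to disk
#'
#' Writes `module.graphml` (node attributes: component, layer, node, seed
#' value, diffusion score), `nodes.tsv`, `edges.tsv`, and `run.json` (the
#' per-iteration log with sizes and scores) under `out_dir`.
#'
#' @param m A `module_result` from [amend_run()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the vector of files written.
#' @export
write_module <- function(m, out_dir) {
  stopifnot(inherits(m, "module_result"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  nodes <- m$module$nodes
  edges <- m$module$edges
  ig <- igraph::graph_from_data_frame(
    edges[, c("from", "to", "weight")],
    directed = FALSE,
    vertices = data.frame(name = nodes$node_key, component = nodes$component,
                          node = nodes$node, seed = nodes$seed,
                          score = nodes$score, stringsAsFactors = FALSE))
  f_graphml <- file.path(out_dir, "module.graphml")
  igraph::write_graph(ig, f_graphml, format = "graphml")
  f_nodes <- file.path(out_dir, "nodes.tsv")
  utils::write.table(nodes, f_nodes, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_edges <- file.path(out_dir, "edges.tsv")
  utils::write.table(edges, f_edges, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  f_log <- file.path(out_dir, "run.json")
  jsonlite::write_json(list(iterations = m$iterations,
                            stopping_reason = m$stopping_reason,
                            best_iteration = m$best_iteration),
                       f_log, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(f_graphml, f_nodes, f_edges, f_log))
}
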