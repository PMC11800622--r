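# The iterative active-module search: diffuse, shift scores around a retention
# quantile, extract a maximum-weight connected subgraph on the aggregated
# graph, score it, shrink, repeat; the best-scoring iteration is the module.

#' Aggregate a multiplex component into a single graph
#'
#' The aggregated node set is the union of the layers' node sets. The edge set
#' preferentially uses the primary layer: all primary-layer edges are kept,
#' and an edge from a later layer is added only if that unordered node pair is
#' not yet present. Per-node scores are summarized over the node's replicas
#' with `summary_fn` (default mean).
#'
#' @param component An [mh_component()].
#' @param primary_layer Layer id whose edge set takes precedence; defaults to
#'   the first layer.
#' @param scores Named list by layer id of named numeric score vectors (one
#'   entry per node of that layer), or `NULL` for no scores.
#' @param summary_fn Function reducing a node's replica scores to one value.
#' @return List with `nodes` (character), `edges` (data frame `from`, `to`,
#'   `weight`, `layer`), `scores` (named numeric or `NULL`).
#' @export
aggregate_multiplex <- function(component, primary_layer = NULL, scores = NULL,
                                summary_fn = mean) {
  stopifnot(inherits(component, "mh_component"))
  lids <- names(component$layers)
  if (is.null(primary_layer)) primary_layer <- lids[1L]
  if (!primary_layer %in% lids)
    stop("unknown primary layer '", primary_layer, "' in component '",
         component$component_id, "'")
  order_l <- c(primary_layer, setdiff(lids, primary_layer))
  nodes <- sort(unique(unlist(lapply(component$layers, `[[`, "nodes"))),
                method = "radix")
  seen <- character(0)
  parts <- list()
  for (lid in order_l) {
    ed <- component$layers[[lid]]$edges
    if (!nrow(ed)) next
    key <- paste(pmin(ed$from, ed$to), pmax(ed$from, ed$to), sep = "\r")
    keep <- !key %in% seen & !duplicated(key)
    if (any(keep)) {
      parts[[lid]] <- data.frame(from = ed$from[keep], to = ed$to[keep],
                                 weight = ed$weight[keep], layer = lid,
                                 stringsAsFactors = FALSE)
      seen <- c(seen, key[keep])
    }
  }
  edges <- if (length(parts)) do.call(rbind, parts)
  else data.frame(from = character(), to = character(), weight = numeric(),
                  layer = character(), stringsAsFactors = FALSE)
  rownames(edges) <- NULL
  agg_scores <- NULL
  if (!is.null(scores)) {
    vals <- lapply(nodes, function(v) {
      unlist(lapply(lids, function(lid) {
        sv <- scores[[lid]]
        if (!is.null(sv) && v %in% names(sv)) sv[[v]] else NULL
      }))
    })
    agg_scores <- stats::setNames(
      vapply(vals, function(v) if (length(v)) summary_fn(v) else NA_real_,
             numeric(1)), nodes)
  }
  list(nodes = nodes, edges = edges, scores = agg_scores)
}

#' Expand an aggregated module back into per-layer subgraphs
#'
#' Each original layer is restricted to the module nodes and any edges between
#' them; a module node absent from a layer is simply absent there.
#'
#' @param nodes Character vector of module node ids.
#' @param component The original [mh_component()].
#' @return Named list (by layer id) of [mh_layer()] objects.
#' @export
expand_module <- function(nodes, component) {
  stopifnot(inherits(component, "mh_component"))
  out <- lapply(component$layers, function(ly) {
    nn <- intersect(ly$nodes, nodes)
    ed <- ly$edges[ly$edges$from %in% nn & ly$edges$to %in% nn, , drop = FALSE]
    mh_layer(ly$layer_id, ed, nodes = nn)
  })
  names(out) <- names(component$layers)
  out
}

node_key <- function(component, node) paste(component, node, sep = "::")

# Build the aggregated heterogeneous graph as an igraph: each multiplex
# component collapsed around its primary layer, bipartite edges preserved.
# Vertex attributes: component, node, score.
aggregate_graph <- function(g, p = NULL, index = NULL, primary_layers = NULL,
                            summary_fn = mean) {
  vn <- character(0); vc <- character(0); vnode <- character(0)
  vscore <- numeric(0)
  edges <- list()
  for (cid in names(g$components)) {
    comp <- g$components[[cid]]
    scores <- NULL
    if (!is.null(p)) {
      scores <- lapply(names(comp$layers), function(lid) {
        rows <- which(index$table$component == cid & index$table$layer == lid)
        stats::setNames(p[rows], index$table$node[rows])
      })
      names(scores) <- names(comp$layers)
    }
    agg <- aggregate_multiplex(comp, primary_layer = primary_layers[[cid]],
                               scores = scores, summary_fn = summary_fn)
    vn <- c(vn, node_key(cid, agg$nodes))
    vc <- c(vc, rep(cid, length(agg$nodes)))
    vnode <- c(vnode, agg$nodes)
    vscore <- c(vscore, if (!is.null(agg$scores)) unname(agg$scores)
                else rep(NA_real_, length(agg$nodes)))
    if (nrow(agg$edges))
      edges[[cid]] <- data.frame(from = node_key(cid, agg$edges$from),
                                 to = node_key(cid, agg$edges$to),
                                 weight = agg$edges$weight,
                                 stringsAsFactors = FALSE)
  }
  for (bp in g$bipartite) {
    ed <- bp$edges
    ed <- ed[node_key(bp$between[1L], ed$from) %in% vn &
               node_key(bp$between[2L], ed$to) %in% vn, , drop = FALSE]
    if (nrow(ed))
      edges[[length(edges) + 1L]] <-
        data.frame(from = node_key(bp$between[1L], ed$from),
                   to = node_key(bp$between[2L], ed$to),
                   weight = ed$weight, stringsAsFactors = FALSE)
  }
  ed <- if (length(edges)) do.call(rbind, edges)
  else data.frame(from = character(), to = character(), weight = numeric())
  ig <- igraph::graph_from_data_frame(
    ed, directed = FALSE,
    vertices = data.frame(name = vn, component = vc, node = vnode,
                          score = vscore, stringsAsFactors = FALSE))
  ig
}

#' Shift diffusion scores into signed node weights
#'
#' Standardizes the scores on the current subnetwork (`z = (p - mean) / sd`)
#' and subtracts the quantile `q` chosen so that `ceiling(n *
#' retention_fraction)` nodes receive nonnegative weight. The sign pattern is
#' invariant under positive affine transforms of `p`, and the top-scoring node
#' always has the maximum weight.
#'
#' @param p Numeric scores.
#' @param retention_fraction Fraction of nodes to keep nonnegative, in
#'   `(0, 1)`.
#' @return Numeric weights with attribute `degenerate` (`TRUE` when the scores
#'   are constant, in which case all weights are 0).
#' @export
shift_scores <- function(p, retention_fraction) {
  stopifnot(retention_fraction > 0, retention_fraction < 1)
  n <- length(p)
  s <- stats::sd(p)
  if (!is.finite(s) || s == 0)
    return(structure(rep(0, n), degenerate = TRUE))
  z <- (p - mean(p)) / s
  k <- ceiling(n * retention_fraction)
  q <- sort(z, decreasing = TRUE)[k]
  structure(z - q, degenerate = FALSE)
}

#' Maximum-weight connected subgraph heuristic
#'
#' Finds a connected node set with large total signed weight: (1) connected
#' clusters of positive-weight nodes are contracted into supernodes carrying
#' the summed weight; (2) supernode pairs are linked by cheapest paths, where
#' traversing a negative node costs its absolute weight; (3) on a minimum-cost
#' spanning structure of the supernodes, the maximum-weight subtree is kept by
#' dynamic programming (evaluated from every root); (4) the result is the
#' union of kept supernodes' members and the nodes on the connecting paths.
#' The returned weight is always at least the best single positive cluster's
#' weight, and the set is connected by construction.
#'
#' @param graph An igraph.
#' @param w Signed node weights aligned with `V(graph)`.
#' @return Sorted integer vector of vertex indices; empty when no node has
#'   positive weight.
#' @export
mwcs_heuristic <- function(graph, w) {
  n <- igraph::vcount(graph)
  stopifnot(length(w) == n)
  pos <- which(w > 0)
  if (!length(pos)) return(integer(0))
  sub <- igraph::induced_subgraph(graph, pos)
  cl <- igraph::components(sub)
  nc <- cl$no
  members <- split(pos, cl$membership)
  cw <- vapply(members, function(m) sum(w[m]), numeric(1))
  if (nc == 1L) return(sort(pos))

  cost <- pmax(-w, 0)
  en <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  ew <- (cost[en[, 1L]] + cost[en[, 2L]]) / 2
  # cheapest node-cost paths from every positive node (cluster endpoints cost 0)
  dall <- igraph::distances(graph, v = pos, weights = ew)
  rowcl <- cl$membership
  dcn <- do.call(rbind, lapply(seq_len(nc), function(a) {
    rows <- which(rowcl == a)
    if (length(rows) == 1L) dall[rows, ]
    else apply(dall[rows, , drop = FALSE], 2L, min)
  }))
  dC <- vapply(seq_len(nc), function(b)
    apply(dcn[, members[[b]], drop = FALSE], 1L, min), numeric(nc))
  if (nc == 1L) dC <- matrix(dC, 1L, 1L)

  # spanning structure over supernodes (per reachable group)
  ut <- which(upper.tri(dC) & is.finite(dC), arr.ind = TRUE)
  superg <- igraph::make_empty_graph(n = nc, directed = FALSE)
  if (nrow(ut))
    superg <- igraph::add_edges(superg, rbind(ut[, 1L], ut[, 2L]),
                                weight = dC[ut])
  mstg <- igraph::mst(superg, weights = igraph::E(superg)$weight)

  best <- list(value = -Inf, clusters = integer(0), edges = NULL)
  ewt <- igraph::E(mstg)$weight %||% numeric(0)
  for (root in seq_len(nc)) {
    dd <- igraph::dfs(mstg, root, unreachable = FALSE, father = TRUE)
    ord <- as.integer(dd$order)
    ord <- ord[!is.na(ord)]
    parent <- as.integer(dd$father)
    vs <- setdiff(ord, root)
    pedge <- integer(nc)
    if (length(vs))
      pedge[vs] <- igraph::get_edge_ids(mstg,
                                        as.vector(rbind(parent[vs], vs)))
    val <- cw
    keep_edge <- logical(igraph::ecount(mstg))
    for (v in rev(ord)) {
      if (v == root) next
      gain <- val[v] - ewt[pedge[v]]
      if (gain > 0) {
        val[parent[v]] <- val[parent[v]] + gain
        keep_edge[pedge[v]] <- TRUE
      }
    }
    if (val[root] > best$value) {
      sel_flag <- logical(nc)
      sel_flag[root] <- TRUE
      for (v in ord) {
        if (v == root) next
        sel_flag[v] <- sel_flag[parent[v]] && keep_edge[pedge[v]]
      }
      best <- list(value = val[root], clusters = which(sel_flag),
                   edges = pedge[which(sel_flag & seq_len(nc) != root)])
    }
  }

  out <- unlist(members[best$clusters], use.names = FALSE)
  if (length(best$edges)) {
    mst_ends <- igraph::ends(mstg, igraph::E(mstg), names = FALSE)
    for (e in best$edges) {
      a <- mst_ends[e, 1L]; b <- mst_ends[e, 2L]
      rows <- which(rowcl == a)
      dsub <- dall[rows, members[[b]], drop = FALSE]
      hit <- which(dsub == min(dsub), arr.ind = TRUE)[1L, ]
      from_v <- pos[rows[hit[1L]]]
      to_v <- members[[b]][hit[2L]]
      path <- igraph::shortest_paths(graph, from = from_v, to = to_v,
                                     weights = ew)$vpath[[1L]]
      out <- c(out, as.integer(path))
    }
  }
  out <- sort(unique(out))
  # second candidate: sequential attachment with connector-cost sharing (a
  # connector already paid for is free for later attachments), best prefix
  alt <- mwcs_greedy_attach(graph, w, members, cw)
  if (sum(w[alt]) > sum(w[out])) alt else out
}

# Greedy Steiner-style growth: start from the heaviest positive cluster,
# repeatedly attach the cluster with the best net gain (cluster weight minus
# cheapest connection cost to the current set), zeroing the cost of nodes
# once included; the running best total marks the returned set.
mwcs_greedy_attach <- function(graph, w, members, cw) {
  cost <- pmax(-w, 0)
  en <- igraph::ends(graph, igraph::E(graph), names = FALSE)
  start <- which.max(cw)
  S <- members[[start]]
  cost[S] <- 0
  total <- cw[start]
  best_total <- total; best_S <- S
  remaining <- setdiff(seq_along(members), start)
  nv <- igraph::vcount(graph)
  while (length(remaining)) {
    ew <- c((cost[en[, 1L]] + cost[en[, 2L]]) / 2, rep(0, length(S)))
    ag <- igraph::add_edges(igraph::add_vertices(graph, 1L),
                            rbind(nv + 1L, S))
    d <- as.numeric(igraph::distances(ag, v = nv + 1L, weights = ew))
    att <- vapply(remaining, function(b) min(d[members[[b]]]), numeric(1))
    gains <- cw[remaining] - att
    k <- which.max(gains)
    if (!is.finite(gains[k])) break
    b <- remaining[k]
    tgt <- members[[b]][which.min(d[members[[b]]])]
    path <- igraph::shortest_paths(ag, from = nv + 1L, to = tgt,
                                   weights = ew)$vpath[[1L]]
    add <- union(setdiff(as.integer(path), nv + 1L), members[[b]])
    new <- setdiff(add, S)
    total <- total + sum(w[new])
    S <- union(S, new)
    cost[S] <- 0
    remaining <- remaining[-k]
    if (total > best_total) {
      best_total <- total
      best_S <- S
    }
  }
  sort(best_S)
}

#' Score a candidate subnetwork
#'
#' The score is the product of an experimental term (mean seed value of the
#' module nodes, standardized against the full input network) and a
#' topological term (fraction of module nodes in the module's largest
#' connected component, times `mean degree / (mean degree + 1)` of the induced
#' subgraph). Higher is better; a fragmented or seed-poor module scores low.
#'
#' @param nodes Vertex names (or indices) of the candidate module.
#' @param seeds Named numeric seed values covering the graph's vertices.
#' @param graph igraph over which connectivity and degree are measured.
#' @param baseline List with `mean` and `sd` of the seed values on the full
#'   input network; computed from `seeds` when `NULL`.
#' @return Numeric score with attributes `experimental` and `topological`.
#' @export
score_subnetwork <- function(nodes, seeds, graph, baseline = NULL) {
  if (!length(nodes)) stop("cannot score an empty subnetwork")
  if (is.null(baseline))
    baseline <- list(mean = mean(seeds), sd = stats::sd(seeds))
  sdv <- if (is.finite(baseline$sd) && baseline$sd > 0) baseline$sd else 1
  z <- (seeds[if (is.character(nodes)) nodes else
    igraph::V(graph)$name[nodes]] - baseline$mean) / sdv
  experimental <- mean(z, na.rm = TRUE)
  sub <- igraph::induced_subgraph(graph, nodes)
  comp <- igraph::components(sub)
  frac <- max(comp$csize) / length(nodes)
  md <- mean(igraph::degree(sub))
  topological <- frac * md / (md + 1)
  structure(experimental * topological, experimental = experimental,
            topological = topological)
}

# Induce the multiplex-heterogeneous subgraph on a per-component node id set,
# dropping emptied layers/components and renormalizing tau/eta proportionally.
subgraph_mh <- function(g, keep) {
  comps <- list(); eta_keep <- numeric(0)
  for (cid in names(g$components)) {
    nodes <- keep[[cid]]
    if (is.null(nodes) || !length(nodes)) next
    comp <- g$components[[cid]]
    layers <- list(); tau_keep <- numeric(0)
    for (lid in names(comp$layers)) {
      ly <- comp$layers[[lid]]
      nn <- intersect(ly$nodes, nodes)
      if (!length(nn)) next
      ed <- ly$edges[ly$edges$from %in% nn & ly$edges$to %in% nn,
                     , drop = FALSE]
      layers[[lid]] <- mh_layer(lid, ed, nodes = nn)
      tau_keep <- c(tau_keep, comp$tau[[lid]])
    }
    if (!length(layers)) next
    tau_keep <- if (sum(tau_keep) > 0) tau_keep / sum(tau_keep)
    else rep(1 / length(layers), length(layers))
    comps[[cid]] <- mh_component(cid, layers, tau = tau_keep)
    eta_keep <- c(eta_keep, g$eta[[cid]])
  }
  if (!length(comps)) stop("subgraph induction removed every component")
  eta_keep <- if (sum(eta_keep) > 0) eta_keep / sum(eta_keep)
  else rep(1 / length(comps), length(comps))
  bip <- list()
  for (bp in g$bipartite) {
    if (!all(bp$between %in% names(comps))) next
    n1 <- intersect(unique(unlist(lapply(comps[[bp$between[1L]]]$layers,
                                         `[[`, "nodes"))), bp$edges$from)
    n2 <- intersect(unique(unlist(lapply(comps[[bp$between[2L]]]$layers,
                                         `[[`, "nodes"))), bp$edges$to)
    ed <- bp$edges[bp$edges$from %in% n1 & bp$edges$to %in% n2, , drop = FALSE]
    if (nrow(ed)) bip[[length(bip) + 1L]] <- list(between = bp$between,
                                                  edges = ed)
  }
  mh_graph(comps, bipartite = bip, eta = eta_keep, lambda = g$lambda,
           delta = g$delta, interlayer_weight = g$interlayer_weight)
}

# Raw (unnormalized) seed value per replica, 0 where unmeasured.
raw_seed_values <- function(g, values, index) {
  out <- numeric(index$n)
  for (cid in names(g$components)) {
    comp <- g$components[[cid]]
    for (lid in names(comp$layers)) {
      v <- if (is.numeric(values)) values
      else if (is.list(values)) {
        vc <- values[[cid]]
        if (is.numeric(vc)) vc else if (is.list(vc)) vc[[lid]] else NULL
      } else NULL
      if (is.null(v)) next
      rows <- which(index$table$component == cid & index$table$layer == lid)
      hit <- match(index$table$node[rows], names(v))
      out[rows] <- ifelse(is.na(hit), 0, v[hit])
    }
  }
  out
}

#' Iterative active-module identification
#'
#' Runs the diffuse-filter-extract loop on a multiplex-heterogeneous graph:
#' per iteration, the transition matrix of the current subnetwork is
#' assembled, seed values are diffused by random walk with restart (optionally
#' biased and/or degree-bias adjusted), scores are aggregated over multiplex
#' layers, shifted into signed weights with a retention fraction that decays
#' geometrically toward `n_target`, a maximum-weight connected subgraph is
#' extracted and scored, and the loop recurses on it. The loop stops when the
#' subnetwork reaches `n_target` nodes, stops shrinking, or no node has
#' positive weight; the iteration with the maximal score is returned as the
#' module.
#'
#' @param g An [mh_graph()].
#' @param seeds Seed values as accepted by [build_seed_vector()].
#' @param n_target Target module size (aggregated node count).
#' @param r Restart probability.
#' @param lambda,delta Crosstalk parameters (default: the graph's).
#' @param norm,k_pen Intra-layer normalization (see [assemble_transition()]).
#' @param adjust An [adjustment_spec()].
#' @param mu Optional biased-walk attribute: named numeric vector by node id.
#' @param noi Optional character vector of nodes of interest; builds `mu` via
#'   [brw_attribute_from_noi()] on the full graph.
#' @param k_scale Decay rate for the `noi`-derived attribute.
#' @param primary_layers Optional named list (by component) of primary layer
#'   ids for aggregation.
#' @param summary_fn Replica-score summary function (default mean).
#' @param decay Geometric decay rate of the retention fraction, in `(0, 1)`.
#' @param tol,max_iter Diffusion controls.
#' @param verbose Print per-iteration progress.
#' @return An object of class `module_result`: `module` (nodes with
#'   component/layer provenance, induced aggregated edges, per-layer
#'   expansion), `iterations` (data frame of per-iteration records),
#'   `best_iteration`, `stopping_reason`, `removal_iteration` (named by
#'   `component::node`; `NA` for nodes never removed), `n_iterations`.
#' @export
amend_run <- function(g, seeds, n_target, r = 0.5, lambda = g$lambda,
                      delta = g$delta, norm = c("degree", "penalized"),
                      k_pen = 0, adjust = adjustment_spec("none"), mu = NULL,
                      noi = NULL, k_scale = 1, primary_layers = NULL,
                      summary_fn = mean, decay = 0.5, tol = 1e-10,
                      max_iter = 1000L, verbose = FALSE) {
  norm <- match.arg(norm)
  stopifnot(inherits(g, "mh_graph"), n_target >= 1, decay > 0, decay < 1)
  full_index <- build_index(g)
  if (!is.null(noi)) {
    mu_full <- brw_attribute_from_noi(g, noi, k_scale, full_index)
    mu_named <- NULL
  } else if (!is.null(mu)) {
    if (is.null(names(mu))) stop("mu must be named by node id")
    mu_full <- NULL
    mu_named <- mu
  } else {
    mu_full <- NULL; mu_named <- NULL
  }
  # aggregated raw seed values on the full network set the scoring baseline
  raw_full <- raw_seed_values(g, seeds, full_index)
  agg_full <- tapply(raw_full,
                     node_key(full_index$table$component,
                              full_index$table$node), mean)
  baseline <- list(mean = mean(agg_full), sd = stats::sd(agg_full))
  seed_by_key <- agg_full

  keep <- lapply(g$components, function(comp)
    unique(unlist(lapply(comp$layers, `[[`, "nodes"))))
  names(keep) <- names(g$components)

  records <- list(); modules <- list()
  removal <- stats::setNames(rep(NA_real_, length(agg_full)), names(agg_full))
  stopping <- "max_iterations"
  it <- 0L
  repeat {
    it <- it + 1L
    sg <- if (it == 1L) g else subgraph_mh(g, keep)
    idx <- build_index(sg)
    mu_sg <- NULL
    if (!is.null(mu_full)) {
      mu_sg <- mu_full[index_of(full_index, idx$table$component,
                                idx$table$layer, idx$table$node)]
    } else if (!is.null(mu_named)) {
      hit <- match(idx$table$node, names(mu_named))
      mu_sg <- ifelse(is.na(hit), 1, mu_named[hit])
    }
    tm <- assemble_transition(sg, idx, lambda = lambda, delta = delta,
                              norm = norm, k_pen = k_pen, mu = mu_sg,
                              adjust = adjust)
    sv <- build_seed_vector(sg, seeds, index = idx)
    dr <- rwr(tm, sv, r = r, tol = tol, max_iter = max_iter)
    p <- dr$p
    if (adjust$method == "sds") {
      s <- stationary_distribution(tm)
      p <- sds_adjust(p, s)
      p[is.na(p)] <- 0
    }
    ag <- aggregate_graph(sg, p, idx, primary_layers = primary_layers,
                          summary_fn = summary_fn)
    n_cur <- igraph::vcount(ag)
    # geometric shrinkage: keep a `decay` fraction per iteration until the
    # target size is reached; a subnetwork already at or below the target is
    # retained whole (single-iteration case)
    f <- if (n_cur <= n_target) 1 - 1e-9 else decay
    w <- shift_scores(igraph::V(ag)$score, f)
    if (isTRUE(attr(w, "degenerate"))) {
      stopping <- "degenerate_scores"
      break
    }
    sel <- mwcs_heuristic(ag, as.numeric(w))
    if (!length(sel)) {
      if (it == 1L)
        stop("no positive-weight node at iteration 1: the seed support is ",
             "too weak or disconnected to start the module search")
      stopping <- "no_positive_weights"
      break
    }
    if (it > 1L && length(sel) >= n_cur) {
      stopping <- "no_shrinkage"
      break
    }
    keys <- igraph::V(ag)$name[sel]
    sc <- score_subnetwork(keys, seed_by_key, ag, baseline = baseline)
    removed <- setdiff(igraph::V(ag)$name, keys)
    removal[removed[is.na(removal[removed])]] <- it
    sub <- igraph::induced_subgraph(ag, sel)
    edf <- igraph::as_data_frame(sub, what = "edges")
    records[[it]] <- data.frame(
      iteration = it, n_nodes = length(sel),
      score = as.numeric(sc),
      experimental = attr(sc, "experimental"),
      topological = attr(sc, "topological"),
      retention_fraction = f, stringsAsFactors = FALSE)
    modules[[it]] <- list(
      nodes = data.frame(node_key = keys,
                         component = igraph::V(ag)$component[sel],
                         node = igraph::V(ag)$node[sel],
                         score = igraph::V(ag)$score[sel],
                         seed = as.numeric(seed_by_key[keys]),
                         stringsAsFactors = FALSE),
      edges = if (nrow(edf)) edf[, c("from", "to", "weight")]
      else data.frame(from = character(), to = character(),
                      weight = numeric()))
    if (verbose)
      message(sprintf("iteration %d: %d -> %d nodes, score %.4f",
                      it, n_cur, length(sel), as.numeric(sc)))
    keep <- split(igraph::V(ag)$node[sel], igraph::V(ag)$component[sel])
    if (length(sel) <= n_target) {
      stopping <- "target_size"
      break
    }
    if (it >= 100L) break
  }
  if (!length(records))
    stop("module search stopped before any module was extracted (",
         stopping, ")")
  iterations <- do.call(rbind, records)
  best <- which.max(iterations$score)
  module <- modules[[best]]
  # per-layer provenance and expansion from the original components
  by_comp <- split(module$nodes$node, module$nodes$component)
  expansion <- lapply(names(by_comp), function(cid)
    expand_module(by_comp[[cid]], g$components[[cid]]))
  names(expansion) <- names(by_comp)
  module$nodes$layers <- vapply(seq_len(nrow(module$nodes)), function(k) {
    cid <- module$nodes$component[k]; v <- module$nodes$node[k]
    lys <- names(g$components[[cid]]$layers)
    paste(lys[vapply(g$components[[cid]]$layers,
                     function(ly) v %in% ly$nodes, logical(1))],
          collapse = ",")
  }, character(1))
  module$layers <- expansion
  structure(list(module = module, iterations = iterations,
                 best_iteration = best, stopping_reason = stopping,
                 removal_iteration = removal, n_iterations = nrow(iterations)),
            class = "module_result")
}

#' @export
print.module_result <- function(x, ...) {
  cat("module_result:", nrow(x$module$nodes), "nodes,",
      nrow(x$module$edges), "edges | best iteration", x$best_iteration,
      "of", x$n_iterations, "| stop:", x$stopping_reason, "\n")
  print(x$iterations, row.names = FALSE)
  invisible(x)
}
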