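# Synthetic multiplex-heterogeneous graphs, planted modules, and seed-value
# generators, so that diffusion, degree-bias adjustment and module search can
# be exercised and benchmarked without any external network.

#' Specify a synthetic multiplex-heterogeneous graph
#'
#' Each component gets `n_layers` layers of `n_nodes` nodes. Layer topology is
#' either scale-free (undirected preferential attachment with `pa_edges` new
#' edges per node and attachment exponent `pa_power`, reproducing the hub
#' structure of interactome graphs) or Erdos-Renyi with density `er_density`.
#' Layers of one component share a fraction `overlap` of their node ids;
#' components are coupled by bipartite edges sampled with density
#' `bipartite_density`.
#'
#' @param n_components Number of components.
#' @param n_layers Layers per component (recycled).
#' @param n_nodes Nodes per layer (recycled per component).
#' @param model `"pa"` (preferential attachment) or `"er"` (recycled).
#' @param pa_edges Edges added per node for `"pa"` layers.
#' @param pa_power Attachment exponent for `"pa"` layers.
#' @param er_density Edge probability for `"er"` layers.
#' @param overlap Fraction of node ids shared by all layers of a component.
#' @param bipartite_density Probability of a bipartite edge between a node
#'   pair of two components.
#' @param lambda,delta Crosstalk parameters stored on the graph.
#' @param seed RNG seed; generation is deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_components = 1L, n_layers = 1L, n_nodes = 100L,
                           model = "pa", pa_edges = 2L, pa_power = 1,
                           er_density = 0.05, overlap = 0.5,
                           bipartite_density = 0.01, lambda = 0.5,
                           delta = 0.5, seed = 1L) {
  stopifnot(n_components >= 1, all(n_layers >= 1), all(n_nodes >= 2),
            all(model %in% c("pa", "er")), overlap >= 0, overlap <= 1,
            bipartite_density >= 0, bipartite_density <= 1,
            er_density >= 0, er_density <= 1)
  structure(list(n_components = as.integer(n_components),
                 n_layers = rep_len(as.integer(n_layers), n_components),
                 n_nodes = rep_len(as.integer(n_nodes), n_components),
                 model = rep_len(model, n_components),
                 pa_edges = as.integer(pa_edges), pa_power = pa_power,
                 er_density = er_density, overlap = overlap,
                 bipartite_density = bipartite_density,
                 lambda = lambda, delta = delta, seed = as.integer(seed)),
            class = "synthetic_spec")
}

with_rng_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic multiplex-heterogeneous graph
#'
#' Deterministic given the spec (including its RNG seed). Node ids are
#' namespaced per component (`c1n0001`, ...); the requested overlap is
#' realized by giving all layers of a component a common block of node ids
#' and each layer its own disjoint remainder.
#'
#' @param spec A [synthetic_spec()].
#' @return An [mh_graph()].
#' @export
generate_graph <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_rng_seed(spec$seed, {
    comps <- list()
    comp_nodes <- list()
    for (ci in seq_len(spec$n_components)) {
      cid <- paste0("c", ci)
      n <- spec$n_nodes[ci]
      nl <- spec$n_layers[ci]
      n_shared <- round(spec$overlap * n)
      if (nl > 1L && n_shared > n)
        stop("overlap exceeds layer size")
      total_ids <- n_shared + nl * (n - n_shared)
      ids <- sprintf("%sn%04d", cid, seq_len(max(total_ids, n)))
      shared <- ids[seq_len(n_shared)]
      cursor <- n_shared
      layers <- list()
      for (li in seq_len(nl)) {
        own <- if (n - n_shared > 0)
          ids[cursor + seq_len(n - n_shared)] else character(0)
        cursor <- cursor + (n - n_shared)
        nodes <- if (nl > 1L) c(shared, own) else ids[seq_len(n)]
        nodes <- sample(nodes)  # random placement in the topology
        ig <- if (spec$model[ci] == "pa") {
          igraph::sample_pa(n, power = spec$pa_power, m = spec$pa_edges,
                            directed = FALSE)
        } else {
          igraph::sample_gnp(n, spec$er_density)
        }
        ed <- igraph::as_edgelist(ig, names = FALSE)
        layers[[li]] <- mh_layer(paste0("L", li),
                                 data.frame(from = nodes[ed[, 1L]],
                                            to = nodes[ed[, 2L]],
                                            weight = 1,
                                            stringsAsFactors = FALSE),
                                 nodes = nodes)
      }
      comps[[cid]] <- mh_component(cid, layers)
      comp_nodes[[cid]] <- unique(unlist(lapply(layers, `[[`, "nodes")))
    }
    bip <- list()
    if (spec$n_components > 1L && spec$bipartite_density > 0) {
      for (a in seq_len(spec$n_components - 1L)) {
        for (b in seq.int(a + 1L, spec$n_components)) {
          na <- comp_nodes[[a]]; nb <- comp_nodes[[b]]
          m <- stats::rbinom(1L, length(na) * length(nb),
                             spec$bipartite_density)
          if (m == 0L) next
          pick <- sample.int(length(na) * length(nb), m)
          ed <- data.frame(from = na[(pick - 1L) %% length(na) + 1L],
                           to = nb[(pick - 1L) %/% length(na) + 1L],
                           weight = 1, stringsAsFactors = FALSE)
          ed <- ed[!duplicated(ed[, 1:2]), , drop = FALSE]
          bip[[length(bip) + 1L]] <-
            list(between = names(comps)[c(a, b)], edges = ed)
        }
      }
    }
    mh_graph(comps, bipartite = bip, lambda = spec$lambda, delta = spec$delta)
  })
}

#' Plant a high-seed connected module in a graph
#'
#' Samples a connected subgraph of the requested size by random-walk growth in
#' one layer, assigns its nodes seed values `|Normal(effect, 1)|` and all
#' other nodes `|Normal(0, 1)|`, and returns the truth labels for recovery
#' scoring. `effect = 0` makes signal and noise indistinguishable.
#'
#' @param g An [mh_graph()].
#' @param size Number of module nodes; must not exceed the host layer.
#' @param effect Mean of the signal seed distribution.
#' @param component,layer Where to plant; defaults to the first layer of the
#'   first component.
#' @param seed RNG seed.
#' @param max_tries Random-walk restarts before giving up.
#' @return List with `truth` (character node ids), `seeds` (nested value
#'   list as accepted by [build_seed_vector()]), `component`.
#' @export
plant_module <- function(g, size, effect, component = NULL, layer = NULL,
                         seed = 1L, max_tries = 50L) {
  stopifnot(inherits(g, "mh_graph"), size >= 1)
  cid <- component %||% names(g$components)[1L]
  comp <- g$components[[cid]]
  lid <- layer %||% names(comp$layers)[1L]
  ly <- comp$layers[[lid]]
  if (size > length(ly$nodes))
    stop("requested module size exceeds the host layer")
  A <- igraph::graph_from_data_frame(ly$edges[, c("from", "to")],
                                     directed = FALSE,
                                     vertices = ly$nodes)
  with_rng_seed(seed, {
    truth <- NULL
    for (try in seq_len(max_tries)) {
      start <- sample(igraph::V(A), 1L)
      walk <- igraph::random_walk(A, start, steps = max(20L * size, 100L))
      picked <- unique(as.integer(walk))
      if (length(picked) >= size) {
        truth <- igraph::V(A)$name[picked[seq_len(size)]]
        break
      }
    }
    if (is.null(truth))
      stop("could not sample a connected subgraph of size ", size,
           " in ", max_tries, " attempts")
    values <- list()
    for (ci in names(g$components)) {
      values[[ci]] <- lapply(g$components[[ci]]$layers, function(lyr) {
        v <- abs(stats::rnorm(length(lyr$nodes), 0, 1))
        names(v) <- lyr$nodes
        hit <- intersect(lyr$nodes, if (ci == cid) truth else character(0))
        if (length(hit)) v[hit] <- abs(stats::rnorm(length(hit), effect, 1))
        v
      })
    }
    list(truth = truth, seeds = values, component = cid)
  })
}

#' Seed values perfectly anticorrelated with degree
#'
#' Assigns the sorted values to nodes in reverse order of replica degree
#' (largest value to the smallest-degree node), realizing a seed-versus-degree
#' antagonism for retention benchmarks.
#'
#' @param g An [mh_graph()].
#' @param values Nonnegative numeric values, one per replica (recycled /
#'   truncated to the replica count); defaults to `|Normal(0, 1)|` draws.
#' @param seed RNG seed used when `values` is `NULL`.
#' @return Named numeric vector by node id covering every replica (per-node
#'   values are averaged over replicas after assignment).
#' @export
anti_degree_seeds <- function(g, values = NULL, seed = 1L) {
  index <- build_index(g)
  blocks <- adjacency_blocks(g, index)
  deg <- Matrix::rowSums(blocks$intra) + Matrix::rowSums(blocks$inter_layer) +
    Matrix::rowSums(blocks$inter_component)
  if (is.null(values))
    values <- with_rng_seed(seed, abs(stats::rnorm(index$n)))
  values <- sort(rep_len(values, index$n))
  out <- numeric(index$n)
  out[order(deg, decreasing = TRUE)] <- values
  tapply(out, index$table$node, mean)[unique(index$table$node)]
}

#' Differential-expression-style seed values
#'
#' Draws node values shaped like `-log10` p-values from a differential
#' expression analysis: a `signal_fraction` of nodes get `|Normal(signal_mean,
#' signal_sd)|` (truly changed features) and the rest get `Exponential(log
#' 10)` values, the exact distribution of `-log10` of a uniform null p-value.
#'
#' @param n Number of values.
#' @param signal_fraction Fraction of signal nodes.
#' @param signal_mean,signal_sd Signal distribution parameters on the
#'   `-log10` p scale.
#' @param seed RNG seed.
#' @return Numeric vector of length `n`.
#' @export
de_seed_values <- function(n, signal_fraction = 0.1, signal_mean = 8,
                           signal_sd = 4, seed = 1L) {
  with_rng_seed(seed, {
    sig <- stats::rbinom(n, 1L, signal_fraction)
    ifelse(sig == 1L, abs(stats::rnorm(n, signal_mean, signal_sd)),
           stats::rexp(n, log(10)))
  })
}

#' Write a synthetic graph in the package's exchange formats
#'
#' Emits per-layer edge-list TSVs, bipartite TSVs, and a ready-to-use YAML
#' config readable by [read_graph()].
#'
#' @param g An [mh_graph()].
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the config path.
#' @export
write_graph_files <- function(g, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- list(components = list(), lambda = g$lambda, delta = g$delta,
              interlayer_weight = g$interlayer_weight,
              eta = as.numeric(g$eta))
  for (cid in names(g$components)) {
    comp <- g$components[[cid]]
    layers <- list()
    for (lid in names(comp$layers)) {
      fn <- paste0(cid, "_", lid, ".tsv")
      ed <- comp$layers[[lid]]$edges
      names(ed) <- c("source", "target", "weight")
      utils::write.table(ed, file.path(out_dir, fn), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      layers[[length(layers) + 1L]] <- list(id = lid, edges = fn)
    }
    cfg$components[[length(cfg$components) + 1L]] <-
      list(id = cid, tau = as.numeric(comp$tau), layers = layers)
  }
  if (length(g$bipartite)) {
    cfg$bipartite <- list()
    for (k in seq_along(g$bipartite)) {
      bp <- g$bipartite[[k]]
      fn <- paste0("bipartite_", bp$between[1L], "_", bp$between[2L], ".tsv")
      ed <- bp$edges
      names(ed)[1:3] <- c("source", "target", "weight")
      utils::write.table(ed, file.path(out_dir, fn), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      cfg$bipartite[[k]] <- list(between = as.list(bp$between), edges = fn)
    }
  }
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(cfg, cfg_path)
  invisible(cfg_path)
}
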