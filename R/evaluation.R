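# Benchmarking procedures: cross-validated node ranking, score-degree
# correlation, and paired biased-walk impact metrics.

#' Read gene sets from a GMT file
#'
#' @param path Path to a GMT file (`name<TAB>description<TAB>members...`).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!requireNamespace("fgsea", quietly = TRUE))
    stop("reading GMT files requires the 'fgsea' package")
  fgsea::gmtPathways(path)
}

#' Cross-validated node-ranking evaluation
#'
#' For each gene set and fold, the members in the training folds become seeds
#' (equal mass, matched by node id in every layer), diffusion is run, replica
#' scores are collapsed per node id (mean), and the ranks of the held-out
#' members among all non-seed nodes are recorded (rank 1 = highest score,
#' ties share the mean rank). Ranks are pooled over sets and folds.
#'
#' @param g An [mh_graph()].
#' @param gene_sets Named list of character vectors of node ids.
#' @param k_folds Number of folds.
#' @param min_size Sets with fewer members present in the graph are skipped
#'   (default `k_folds`).
#' @param r Restart probability.
#' @param fold_seed RNG seed for fold assignment (runs are deterministic given
#'   it).
#' @param ... Passed to [assemble_transition()] (`lambda`, `delta`, `norm`,
#'   `k_pen`, `mu`, `adjust`).
#' @return An object of class `ranking_run`: `ranks` (data frame `set`,
#'   `fold`, `node`, `rank`), `n_ranked` (nodes ranked against), `ecdf`, and
#'   `skipped` set names.
#' @export
kfold_rank_eval <- function(g, gene_sets, k_folds = 5L, min_size = k_folds,
                            r = 0.5, fold_seed = 1L, ...) {
  stopifnot(inherits(g, "mh_graph"), k_folds >= 2L)
  index <- build_index(g)
  all_nodes <- unique(index$table$node)
  tm <- assemble_transition(g, index, ...)
  rows <- list()
  skipped <- character(0)
  with_rng_seed(fold_seed, {
    for (sn in names(gene_sets)) {
      members <- intersect(unique(gene_sets[[sn]]), all_nodes)
      if (length(members) < min_size) {
        skipped <- c(skipped, sn)
        next
      }
      fold <- sample(rep_len(seq_len(k_folds), length(members)))
      for (f in seq_len(k_folds)) {
        train <- members[fold != f]
        test <- members[fold == f]
        if (!length(train) || !length(test)) next
        seeds <- stats::setNames(rep(1, length(train)), train)
        sv <- build_seed_vector(g, seeds, index = index)
        p <- rwr(tm, sv, r = r)$p
        collapsed <- tapply(p, index$table$node, mean)
        nonseed <- setdiff(names(collapsed), train)
        rk <- rank(-collapsed[nonseed], ties.method = "average")
        hit <- intersect(test, nonseed)
        if (length(hit))
          rows[[length(rows) + 1L]] <-
            data.frame(set = sn, fold = f, node = hit,
                       rank = as.numeric(rk[hit]), stringsAsFactors = FALSE)
      }
    }
  })
  ranks <- if (length(rows)) do.call(rbind, rows)
  else data.frame(set = character(), fold = integer(), node = character(),
                  rank = numeric())
  rownames(ranks) <- NULL
  structure(list(ranks = ranks, n_ranked = length(all_nodes),
                 ecdf = if (nrow(ranks)) stats::ecdf(ranks$rank) else NULL,
                 skipped = skipped),
            class = "ranking_run")
}

#' @export
print.ranking_run <- function(x, ...) {
  cat("ranking_run:", nrow(x$ranks), "pooled ranks |",
      length(x$skipped), "sets skipped | median rank =",
      if (nrow(x$ranks)) stats::median(x$ranks$rank) else NA, "\n")
  invisible(x)
}

#' Correlation between diffusion scores and node degree
#'
#' For each seed set, runs diffusion and reports the Pearson correlation of
#' the replica-level diffusion scores with replica degree, plus the mean over
#' sets. Constant scores yield `NA` for that set.
#'
#' @param g An [mh_graph()].
#' @param seed_sets List of seed inputs as accepted by
#'   [build_seed_vector()] (named numeric vectors or nested lists).
#' @param r Restart probability.
#' @param adjust An [adjustment_spec()]; `"sds"` rescales the scores, `"bs"`
#'   and `"in"` adjust the transition matrix.
#' @param ... Passed to [assemble_transition()].
#' @return List with `per_set` correlations and `mean`.
#' @export
score_degree_correlation <- function(g, seed_sets, r = 0.5,
                                     adjust = adjustment_spec("none"), ...) {
  stopifnot(inherits(g, "mh_graph"))
  index <- build_index(g)
  blocks <- adjacency_blocks(g, index)
  deg <- Matrix::rowSums(blocks$intra) + Matrix::rowSums(blocks$inter_layer) +
    Matrix::rowSums(blocks$inter_component)
  tm <- assemble_transition(g, index, adjust = adjust, ...)
  s <- if (adjust$method == "sds") stationary_distribution(tm) else NULL
  per_set <- vapply(seed_sets, function(seeds) {
    sv <- build_seed_vector(g, seeds, index = index)
    p <- rwr(tm, sv, r = r)$p
    if (!is.null(s)) {
      p <- sds_adjust(p, s)
      ok <- !is.na(p)
    } else ok <- rep(TRUE, length(p))
    if (stats::sd(p[ok]) == 0 || stats::sd(deg[ok]) == 0) return(NA_real_)
    stats::cor(p[ok], deg[ok])
  }, numeric(1))
  list(per_set = per_set, mean = mean(per_set, na.rm = TRUE))
}

#' Impact of the biased random walk on module search
#'
#' For each set of nodes of interest (NOI), runs the module search unbiased
#' and with a distance-decay biased-walk attribute centred on the NOI, and
#' reports paired metrics: the mean scaled iteration-of-removal of the NOI
#' (iteration at which a node was filtered out, scaled by the number of
#' iterations plus one; retained nodes count as 1) and the mean full-graph
#' distance from module nodes to the NOI. Positive removal differences and
#' negative distance differences indicate the bias pulls the module toward
#' the NOI.
#'
#' @param g An [mh_graph()].
#' @param seeds Seed values as accepted by [build_seed_vector()].
#' @param noi_sets List of character vectors of node ids.
#' @param n_target Target module size for [amend_run()].
#' @param k_scale Decay rate of the distance-derived attribute.
#' @param ... Passed to [amend_run()].
#' @return Data frame with one row per NOI set: scaled iteration-of-removal
#'   and module-NOI distance under both runs, and their differences
#'   (`biased - unbiased`).
#' @export
brw_impact_eval <- function(g, seeds, noi_sets, n_target, k_scale = 1, ...) {
  stopifnot(inherits(g, "mh_graph"))
  index <- build_index(g)
  all_nodes <- unique(index$table$node)
  for (noi in noi_sets)
    if (!all(noi %in% all_nodes))
      stop("node of interest absent from graph: ",
           paste(setdiff(noi, all_nodes), collapse = ", "))
  ig <- as_igraph_replicas(g, index)
  base <- amend_run(g, seeds, n_target = n_target, ...)
  scaled_removal <- function(m, nodes) {
    denom <- m$n_iterations + 1
    keys <- names(m$removal_iteration)
    node_of <- sub("^.*::", "", keys)
    iter <- m$removal_iteration
    iter[is.na(iter)] <- denom
    mean(vapply(nodes, function(v)
      mean(iter[node_of == v] / denom), numeric(1)))
  }
  module_noi_distance <- function(m, nodes) {
    mod_repl <- which(index$table$node %in% m$module$nodes$node)
    noi_repl <- which(index$table$node %in% nodes)
    d <- igraph::distances(ig, v = mod_repl, to = noi_repl, weights = NA)
    mean(d[is.finite(d)])
  }
  out <- lapply(seq_along(noi_sets), function(k) {
    noi <- noi_sets[[k]]
    biased <- amend_run(g, seeds, n_target = n_target, noi = noi,
                        k_scale = k_scale, ...)
    data.frame(
      noi_set = k,
      removal_unbiased = scaled_removal(base, noi),
      removal_biased = scaled_removal(biased, noi),
      distance_unbiased = module_noi_distance(base, noi),
      distance_biased = module_noi_distance(biased, noi))
  })
  out <- do.call(rbind, out)
  out$removal_diff <- out$removal_biased - out$removal_unbiased
  out$distance_diff <- out$distance_biased - out$distance_unbiased
  out
}

#' Mean ECDF difference between module seed values and degrees
#'
#' For a module node set, computes the empirical cumulative probabilities of
#' the module nodes' seed values and of their degrees, both with respect to
#' the full network, and returns the mean difference (seed ECDF minus degree
#' ECDF). Values near 1 mean the module retains high-seed nodes even when
#' they have low degree.
#'
#' @param module_nodes Character vector of node ids in the module.
#' @param seed_values Named numeric seed values for all nodes.
#' @param degrees Named numeric degrees for all nodes.
#' @return Numeric scalar.
#' @export
ecdf_retention_difference <- function(module_nodes, seed_values, degrees) {
  Fs <- stats::ecdf(seed_values)
  Fd <- stats::ecdf(degrees)
  mean(Fs(seed_values[module_nodes]) - Fd(degrees[module_nodes]))
}
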