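# Seed-vector assembly, the restart-walk fixed point, stationary
# distributions, and the distance-decay biased-walk attribute.

#' Assemble the global seed vector
#'
#' Per-layer raw value maps are normalized independently to sum 1, scaled by
#' the layer weights `tau` and the component weights `eta`, and concatenated in
#' global index order, yielding a stochastic vector. Nodes absent from a value
#' map get seed value 0 (molecules not captured in an assay still participate
#' in diffusion). A layer whose value map is all zero contributes a zero block
#' and its `tau` weight is redistributed proportionally among the component's
#' other layers; if a whole component is zero its `eta` weight is likewise
#' redistributed.
#'
#' @param g An [mh_graph()].
#' @param values Seed values. Either a single named numeric vector (matched by
#'   node id in every layer of every component), or a named list per component
#'   of either a named vector (recycled over that component's layers) or a
#'   named list per layer of named vectors. Values must be nonnegative.
#' @param tau Optional named list (by component id) of layer-weight vectors
#'   overriding the components' `tau`.
#' @param eta Optional component-weight vector overriding the graph's `eta`.
#' @param index Optional pre-built [build_index()].
#' @return An object of class `seed_vector` with fields `p0`, `index`, `tau`,
#'   `eta`.
#' @export
build_seed_vector <- function(g, values, tau = NULL, eta = NULL,
                              index = build_index(g)) {
  stopifnot(inherits(g, "mh_graph"))
  comp_ids <- names(g$components)
  if (is.null(eta)) eta <- g$eta
  check_simplex(eta, length(comp_ids), "eta")
  eta <- stats::setNames(as.numeric(eta), comp_ids)

  layer_values <- function(cid, lid) {
    v <- if (is.numeric(values)) values
    else if (is.list(values)) {
      vc <- values[[cid]]
      if (is.numeric(vc)) vc
      else if (is.list(vc)) vc[[lid]]
      else NULL
    } else NULL
    if (is.null(v)) return(numeric(0))
    if (is.null(names(v))) stop("seed values must be named by node id")
    if (any(v < 0)) stop("seed values must be nonnegative")
    v
  }

  p0 <- numeric(index$n)
  layer_mass <- list()
  for (cid in comp_ids) {
    comp <- g$components[[cid]]
    tw <- if (!is.null(tau[[cid]])) tau[[cid]] else comp$tau
    check_simplex(tw, length(comp$layers),
                  sprintf("tau for component '%s'", cid))
    tw <- stats::setNames(as.numeric(tw), names(comp$layers))
    # per-layer normalized value blocks
    blocks <- list()
    nonzero <- logical(length(comp$layers))
    names(nonzero) <- names(comp$layers)
    for (lid in names(comp$layers)) {
      nodes <- sort(comp$layers[[lid]]$nodes, method = "radix")
      v <- layer_values(cid, lid)
      u <- stats::setNames(numeric(length(nodes)), nodes)
      hit <- intersect(names(v), nodes)
      u[hit] <- v[hit]
      s <- sum(u)
      if (s > 0) {
        u <- u / s
        nonzero[lid] <- TRUE
      }
      blocks[[lid]] <- u
    }
    # redistribute tau of all-zero layers proportionally among the rest
    if (any(nonzero)) {
      tw_eff <- tw * as.numeric(nonzero)
      tw_eff <- tw_eff / sum(tw_eff)
    } else {
      tw_eff <- tw * 0
    }
    comp_total <- 0
    for (lid in names(comp$layers)) {
      nodes <- names(blocks[[lid]])
      gi <- index_of(index, cid, lid, nodes)
      p0[gi] <- tw_eff[lid] * blocks[[lid]]
      comp_total <- comp_total + tw_eff[lid] * sum(blocks[[lid]])
    }
    layer_mass[[cid]] <- comp_total
  }
  # redistribute eta of all-zero components
  comp_nonzero <- vapply(layer_mass, function(x) x > 0, logical(1))
  if (!any(comp_nonzero)) stop("all seed values are zero")
  eta_eff <- eta * as.numeric(comp_nonzero)
  eta_eff <- eta_eff / sum(eta_eff)
  for (cid in comp_ids) {
    rows <- which(index$table$component == cid)
    p0[rows] <- p0[rows] * eta_eff[cid]
  }
  stopifnot(abs(sum(p0) - 1) < 1e-8)
  p0 <- p0 / sum(p0)
  structure(list(p0 = p0, index = index, tau = tau, eta = eta_eff),
            class = "seed_vector")
}

#' Random walk with restart
#'
#' Iterates `p <- (1 - r) * M %*% p + r * p0` from `p = p0` until the L1
#' change drops below `tol`. Mass lost through dangling (all-zero) columns is
#' added back to the restart term every step, so the iterate stays stochastic.
#'
#' @param M A `transition_matrix` from [assemble_transition()], or a plain
#'   column-stochastic sparse matrix.
#' @param p0 A `seed_vector` or a stochastic numeric vector.
#' @param r Restart probability in `(0, 1)`; default 0.5.
#' @param tol L1 convergence tolerance.
#' @param max_iter Iteration cap; non-convergence raises an error carrying the
#'   residual trace in its condition data.
#' @return An object of class `diffusion_result` with fields `p`, `r`,
#'   `iterations`, `residual_trace`, `index` (when available).
#' @export
rwr <- function(M, p0, r = 0.5, tol = 1e-10, max_iter = 1000L) {
  index <- NULL
  if (inherits(M, "transition_matrix")) {
    index <- M$index
    M <- M$M
  }
  if (inherits(p0, "seed_vector")) p0 <- p0$p0
  stopifnot(r > 0, r < 1, length(p0) == ncol(M))
  if (abs(sum(p0) - 1) > 1e-8 || any(p0 < 0))
    stop("p0 must be a stochastic vector")
  p <- p0
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    pn <- as.numeric((1 - r) * (M %*% p)) + r * p0
    deficit <- 1 - sum(pn)
    if (deficit > 1e-15) pn <- pn + deficit * p0
    res <- sum(abs(pn - p))
    trace <- c(trace, res)
    p <- pn
    if (res < tol) {
      out <- structure(list(p = p, r = r, iterations = it,
                            residual_trace = trace, index = index),
                       class = "diffusion_result")
      return(out)
    }
  }
  cond <- structure(class = c("rwr_no_convergence", "error", "condition"),
                    list(message = sprintf(
                      "random walk with restart did not converge in %d iterations (last residual %.3g)",
                      max_iter, trace[length(trace)]),
                      call = sys.call(-1), residual_trace = trace))
  stop(cond)
}

#' @export
print.diffusion_result <- function(x, ...) {
  cat("diffusion_result:", length(x$p), "scores | r =", x$r,
      "| iterations =", x$iterations,
      "| final residual =", format(x$residual_trace[x$iterations]), "\n")
  invisible(x)
}

#' Export diffusion scores as a TSV
#'
#' Writes `component<TAB>layer<TAB>node_id<TAB>score`, one row per replica.
#'
#' @param d A `diffusion_result` carrying an index (from a
#'   `transition_matrix`).
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_scores <- function(d, path) {
  stopifnot(inherits(d, "diffusion_result"), !is.null(d$index))
  tbl <- cbind(d$index$table, score = d$p)
  names(tbl)[names(tbl) == "node"] <- "node_id"
  utils::write.table(tbl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Stationary distribution of a random walk
#'
#' For an unbiased degree-normalized symmetric adjacency the stationary
#' distribution has the closed form `s_j = sum_i a_ij / sum_ik a_ik`
#' (proportional to weighted degree). For an arbitrary column-stochastic
#' transition matrix the principal eigenvector is computed by power iteration
#' on the lazy chain `(M + I) / 2`, which shares the fixed point and is immune
#' to periodicity. If that fails to converge (reducible chains), a damped walk
#' with factor 0.999 is used and a warning is raised.
#'
#' @param x A `transition_matrix`, a column-stochastic matrix, or (with
#'   `method = "closed_form"`) a symmetric nonnegative adjacency matrix.
#' @param method `"auto"` (closed form for symmetric nonnegative input that is
#'   not column-stochastic, else power iteration), `"closed_form"`, or
#'   `"power"`.
#' @param tol,max_iter Power-iteration controls.
#' @return Numeric stationary vector summing to 1.
#' @export
stationary_distribution <- function(x, method = c("auto", "closed_form",
                                                  "power"),
                                    tol = 1e-13, max_iter = 50000L) {
  method <- match.arg(method)
  if (inherits(x, "transition_matrix")) x <- x$M
  if (method == "auto") {
    cs <- Matrix::colSums(x)
    stochastic <- all(abs(cs[cs > 0] - 1) < 1e-9)
    method <- if (!stochastic && Matrix::isSymmetric(x)) "closed_form"
    else "power"
  }
  if (method == "closed_form") {
    cs <- Matrix::colSums(x)
    if (sum(cs) == 0) stop("empty graph has no stationary distribution")
    return(as.numeric(cs / sum(cs)))
  }
  n <- ncol(x)
  s <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    sn <- 0.5 * (as.numeric(x %*% s) + s)
    tot <- sum(sn)
    if (tot <= 0) stop("stationary iteration collapsed to zero")
    sn <- sn / tot
    if (sum(abs(sn - s)) < tol) return(sn)
    s <- sn
  }
  warning("power iteration did not converge; retrying with damping 0.999")
  d <- 0.999
  s <- rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    sn <- d * as.numeric(x %*% s) + (1 - d) / n
    sn <- sn / sum(sn)
    if (sum(abs(sn - s)) < tol * 10) return(sn)
    s <- sn
  }
  s
}

#' Distance-decay biased-walk attribute from nodes of interest
#'
#' Computes `mu_i = exp(-k_scale * d_i)` where `d_i` is the mean unweighted
#' shortest-path distance from replica `i` to the nodes of interest, measured
#' on the full replica graph with all edge classes (intra-layer, inter-layer,
#' bipartite) treated as unit length. For a node of interest, the distance to
#' itself contributes 0. Unreachable replica-NOI pairs contribute the graph
#' diameter plus one.
#'
#' @param g An [mh_graph()].
#' @param noi Character vector of node ids of interest (matched across all
#'   components and layers).
#' @param k_scale Positive decay rate; `k_scale -> 0` recovers the unbiased
#'   walk.
#' @param index Optional pre-built [build_index()].
#' @return Numeric vector `mu` of length `N` in global index order.
#' @export
brw_attribute_from_noi <- function(g, noi, k_scale, index = build_index(g)) {
  stopifnot(length(noi) >= 1L, k_scale >= 0)
  present <- index$table$node %in% noi
  if (!any(present))
    stop("none of the nodes of interest are present in the graph")
  found <- unique(index$table$node[present])
  ig <- as_igraph_replicas(g, index)
  # distance from every replica to the nearest replica of each NOI node id
  d <- igraph::distances(ig, v = which(present), weights = NA)
  noi_of_row <- index$table$node[present]
  dmin <- do.call(rbind, lapply(found, function(v) {
    rows <- which(noi_of_row == v)
    if (length(rows) == 1L) d[rows, , drop = FALSE]
    else matrix(apply(d[rows, , drop = FALSE], 2L, min), nrow = 1L)
  }))
  finite <- dmin[is.finite(dmin)]
  cap <- if (length(finite)) max(finite) + 1 else 1
  dmin[!is.finite(dmin)] <- cap
  dbar <- colMeans(dmin)
  unname(exp(-k_scale * dbar))
}
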