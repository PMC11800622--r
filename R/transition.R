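# Global left-stochastic transition matrix for multiplex-heterogeneous graphs:
# intra-layer, inter-layer and inter-component blocks are column-normalized
# independently, then crosstalk parameters (lambda, delta) partition each
# source column's mass across the three target classes.

#' Column-normalize a nonnegative matrix
#'
#' Divides every nonzero column by its sum, yielding a left-stochastic matrix
#' (`M = A D^-1`). All-zero (dangling) columns are left zero; query them with
#' [dangling_columns()].
#'
#' @param A Nonnegative matrix (dense or `Matrix` sparse).
#' @return A sparse column-stochastic matrix of the same dimension.
#' @export
column_normalize <- function(A) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  if (length(A@x) && min(A@x) < 0)
    stop("adjacency matrix has negative entries")
  cs <- Matrix::colSums(A)
  scale <- ifelse(cs > 0, 1 / cs, 0)
  M <- A %*% Matrix::Diagonal(x = scale)
  dimnames(M) <- dimnames(A)
  M
}

#' Identify dangling (all-zero) columns
#'
#' @param A A matrix.
#' @return Logical vector, `TRUE` where the column sum is zero.
#' @export
dangling_columns <- function(A) {
  Matrix::colSums(A) == 0
}

#' Penalized degree normalization
#'
#' Scales row `i` of the adjacency matrix by `d_i^-k_pen` (with `d_i` the
#' weighted degree of node `i`) before column normalization, so that the
#' transition probability into node `i` from `j` becomes
#' `d_i^-k a_ij / sum_l d_l^-k a_lj`. Larger `k_pen` penalizes transitions
#' into hubs more strongly; `k_pen = 0` recovers plain degree normalization.
#'
#' @param A Nonnegative symmetric adjacency matrix.
#' @param k_pen Penalization factor, `>= 0`.
#' @return Sparse column-stochastic matrix.
#' @export
penalized_normalize <- function(A, k_pen) {
  if (k_pen < 0) stop("k_pen must be nonnegative")
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  deg <- Matrix::rowSums(A)
  scale <- ifelse(deg > 0, deg^(-k_pen), 0)
  column_normalize(Matrix::Diagonal(x = scale) %*% A)
}

#' Reweight adjacency rows by a biased-random-walk attribute
#'
#' Computes `A' = diag(mu) %*% A`; after column normalization the transition
#' probability into node `i` is `mu_i a_ij / sum_l mu_l a_lj`, so large
#' attribute values attract the walker.
#'
#' @param A Nonnegative adjacency matrix.
#' @param mu Nonnegative numeric vector, one value per row (recycled scalar
#'   allowed).
#' @return The reweighted (not yet normalized) sparse matrix.
#' @export
apply_bias <- function(A, mu) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  if (length(mu) == 1L) mu <- rep(mu, nrow(A))
  stopifnot(length(mu) == nrow(A))
  if (any(mu < 0)) stop("bias attribute mu must be nonnegative")
  M <- Matrix::Diagonal(x = mu) %*% A
  dimnames(M) <- dimnames(A)
  M
}

# Reweight rows by mu (and optionally degree penalization) and column
# normalize; columns whose neighborhood has all-zero mu fall back to unbiased
# normalization (the biased transition rate is undefined there and negative
# evidence must not create probability sinks).
reweight_normalize <- function(A, mu = NULL, k_pen = 0) {
  A <- methods::as(methods::as(A, "CsparseMatrix"), "generalMatrix")
  B <- if (k_pen > 0) {
    deg <- Matrix::rowSums(A)
    Matrix::Diagonal(x = ifelse(deg > 0, deg^(-k_pen), 0)) %*% A
  } else A
  if (!is.null(mu)) B <- apply_bias(B, mu)
  dead <- Matrix::colSums(B) == 0 & Matrix::colSums(A) > 0
  if (any(dead)) {
    warning(sum(dead), " column(s) with all-zero biased neighborhood; ",
            "falling back to unbiased normalization there")
    B[, dead] <- A[, dead, drop = FALSE]
  }
  column_normalize(B)
}

# Raw (un-normalized) global adjacency blocks in replica coordinates:
#   intra            - block-diagonal intra-layer adjacency
#   inter_layer      - couplings between replicas of one node id across layers
#   inter_component  - per ordered component pair, bipartite expansions
adjacency_blocks <- function(g, index = build_index(g)) {
  n <- index$n
  tbl <- index$table
  trip_i <- integer(0); trip_j <- integer(0); trip_x <- numeric(0)
  for (cm in g$components) {
    for (ly in cm$layers) {
      nodes <- sort(ly$nodes, method = "radix")
      gi <- index_of(index, cm$component_id, ly$layer_id, nodes)
      ed <- ly$edges
      if (!nrow(ed)) next
      i <- gi[match(ed$from, nodes)]; j <- gi[match(ed$to, nodes)]
      off <- i != j
      trip_i <- c(trip_i, i, j[off]); trip_j <- c(trip_j, j, i[off])
      trip_x <- c(trip_x, ed$weight, ed$weight[off])
    }
  }
  intra <- Matrix::sparseMatrix(i = trip_i, j = trip_j, x = trip_x,
                                dims = c(n, n))

  li <- integer(0); lj <- integer(0); lx <- numeric(0)
  for (cm in g$components) {
    nl <- length(cm$layers)
    if (nl >= 2L) {
      ids <- names(cm$layers)
      for (a in seq_len(nl - 1L)) for (b in seq.int(a + 1L, nl)) {
        shared <- intersect(cm$layers[[a]]$nodes, cm$layers[[b]]$nodes)
        if (!length(shared)) next
        ia <- index_of(index, cm$component_id, ids[a], shared)
        ib <- index_of(index, cm$component_id, ids[b], shared)
        li <- c(li, ia, ib); lj <- c(lj, ib, ia)
        lx <- c(lx, rep(g$interlayer_weight, 2L * length(shared)))
      }
    }
  }
  inter_layer <- Matrix::sparseMatrix(i = li, j = lj, x = lx, dims = c(n, n))

  # per ordered component pair
  pair_blocks <- list()
  for (bp in g$bipartite) {
    ed <- bp$edges
    if (!nrow(ed)) next
    c1 <- bp$between[1L]; c2 <- bp$between[2L]
    r1 <- which(tbl$component == c1); r2 <- which(tbl$component == c2)
    # replicas of each endpoint in every layer of its component
    m1 <- split(r1, tbl$node[r1]); m2 <- split(r2, tbl$node[r2])
    bi <- integer(0); bj <- integer(0); bx <- numeric(0)
    for (k in seq_len(nrow(ed))) {
      ri <- m1[[ed$from[k]]]; rj <- m2[[ed$to[k]]]
      if (is.null(ri) || is.null(rj)) next
      grid <- expand.grid(ri, rj)
      bi <- c(bi, grid[[1L]]); bj <- c(bj, grid[[2L]])
      bx <- c(bx, rep(ed$weight[k], nrow(grid)))
    }
    key <- paste(c1, c2, sep = "\r")
    B <- Matrix::sparseMatrix(i = bi, j = bj, x = bx, dims = c(n, n))
    pair_blocks[[key]] <- if (is.null(pair_blocks[[key]])) B else
      pair_blocks[[key]] + B
  }
  # symmetrize: each unordered pair contributes both directions
  sym <- list()
  for (key in names(pair_blocks)) {
    parts <- strsplit(key, "\r", fixed = TRUE)[[1L]]
    rkey <- paste(parts[2L], parts[1L], sep = "\r")
    sym[[key]] <- (sym[[key]] %||% Matrix::sparseMatrix(i = integer(0),
      j = integer(0), x = numeric(0), dims = c(n, n))) + pair_blocks[[key]]
    sym[[rkey]] <- (sym[[rkey]] %||% Matrix::sparseMatrix(i = integer(0),
      j = integer(0), x = numeric(0), dims = c(n, n))) +
      Matrix::t(pair_blocks[[key]])
  }
  inter_component <- Reduce(`+`, sym,
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(n, n)))
  list(intra = intra, inter_layer = inter_layer,
       inter_component = inter_component, pairs = sym)
}

# Crosstalk mass per source column given which target classes exist.
# A parameter is vacuous (treated as 0) when its target class is absent, so
# its mass flows back to the remaining classes; intra-layer mass of a replica
# with no intra-layer edges is redistributed proportionally to the classes it
# does have. A class whose targets exist but whose configured mass is zero
# stays zero (lambda = delta = 0 keeps the matrix block-diagonal); a replica
# left with no mass at all is dangling.
crosstalk_masses <- function(has_intra, has_layer, has_comp, lambda, delta) {
  dc <- delta * as.numeric(has_comp)
  lam <- lambda * as.numeric(has_layer)
  w_i <- (1 - dc) * (1 - lam)
  w_l <- (1 - dc) * lam
  w_c <- dc
  tot <- w_l + w_c
  lost <- !has_intra & w_i > 0
  scale <- ifelse(lost & tot > 0, 1 + w_i / tot, 1)
  list(intra = w_i * as.numeric(has_intra),
       inter_layer = w_l * scale,
       inter_component = w_c * scale)
}

#' Assemble the global transition matrix
#'
#' Each intra-layer, inter-layer and inter-component adjacency block is
#' column-normalized independently (intra-layer blocks optionally with
#' penalized degree normalization, and all blocks optionally reweighted by a
#' biased-random-walk attribute `mu`). Crosstalk parameters then partition each
#' source column's probability mass: intra-layer `(1-delta)(1-lambda)`,
#' inter-layer `(1-delta)*lambda`, inter-component `delta`, with mass
#' redistributed proportionally to the remaining classes when a class of
#' targets is absent. Inter-component mass is split equally among partner
#' components that have targets for the source column. Replicas with no edges
#' of any class are dangling: their column is all zero and the diffusion engine
#' routes the lost mass to the restart term.
#'
#' @param g An [mh_graph()].
#' @param index Optional pre-built [build_index()].
#' @param lambda,delta Crosstalk overrides; default to the graph's values.
#' @param norm Intra-layer normalization kind, `"degree"` or `"penalized"`.
#' @param k_pen Penalization factor for `norm = "penalized"`.
#' @param mu Optional biased-random-walk attribute: nonnegative numeric vector
#'   of length `N` in global index order (see [brw_attribute_from_noi()]).
#' @param adjust Optional [adjustment_spec()]; methods `"bs"` and `"in"` are
#'   applied to the scoped per-layer normalized blocks before crosstalk
#'   assembly (`"sds"` and `"none"` leave the matrix untouched).
#' @return An object of class `transition_matrix` with fields `M` (sparse
#'   column-stochastic `N x N`), `index`, `dangling`, `class_mass` (3 x N
#'   matrix of per-class column mass) and `params`.
#' @export
assemble_transition <- function(g, index = build_index(g),
                                lambda = g$lambda, delta = g$delta,
                                norm = c("degree", "penalized"), k_pen = 0,
                                mu = NULL, adjust = NULL) {
  norm <- match.arg(norm)
  if (norm == "degree") k_pen <- 0
  if (norm == "penalized" && k_pen < 0) stop("k_pen must be nonnegative")
  stopifnot(lambda >= 0, lambda <= 1, delta >= 0, delta <= 1)
  n <- index$n
  tbl <- index$table
  blocks <- adjacency_blocks(g, index)

  # intra-layer: per-layer reweighted normalization (block-diagonal, so global
  # row degrees equal within-layer degrees)
  intra_norm <- reweight_normalize(blocks$intra, mu = mu, k_pen = k_pen)
  if (!is.null(adjust) && adjust$method %in% c("bs", "in"))
    intra_norm <- adjust_intra_blocks(intra_norm, index, adjust)

  inter_layer_norm <- reweight_normalize(blocks$inter_layer, mu = mu)

  # inter-component: normalize each ordered pair block independently, then
  # split the delta mass equally among partner components with targets
  comp_norm <- Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                    x = numeric(0), dims = c(n, n))
  n_partners <- numeric(n)
  for (key in names(blocks$pairs)) {
    Bn <- reweight_normalize(blocks$pairs[[key]], mu = mu)
    present <- Matrix::colSums(blocks$pairs[[key]]) > 0
    n_partners <- n_partners + as.numeric(present)
    comp_norm <- comp_norm + Bn
  }
  if (any(n_partners > 1)) {
    comp_norm <- comp_norm %*%
      Matrix::Diagonal(x = ifelse(n_partners > 0, 1 / n_partners, 0))
  }

  has_intra <- Matrix::colSums(blocks$intra) > 0
  has_layer <- Matrix::colSums(blocks$inter_layer) > 0
  has_comp <- n_partners > 0
  w <- crosstalk_masses(has_intra, has_layer, has_comp, lambda, delta)

  M <- intra_norm %*% Matrix::Diagonal(x = w$intra) +
    inter_layer_norm %*% Matrix::Diagonal(x = w$inter_layer) +
    comp_norm %*% Matrix::Diagonal(x = w$inter_component)
  M <- Matrix::drop0(methods::as(methods::as(M, "CsparseMatrix"),
                                 "generalMatrix"))
  dangling <- (w$intra + w$inter_layer + w$inter_component) == 0
  class_mass <- rbind(intra = w$intra, inter_layer = w$inter_layer,
                      inter_component = w$inter_component)
  colnames(class_mass) <- NULL
  structure(list(M = M, index = index, dangling = dangling,
                 class_mass = class_mass,
                 params = list(lambda = lambda, delta = delta, norm = norm,
                               k_pen = k_pen,
                               biased = !is.null(mu),
                               adjust = if (!is.null(adjust)) adjust$method
                                        else "none")),
            class = "transition_matrix")
}

# Apply a transition-level degree-bias adjustment (BS or IN) to the scoped
# intra-layer blocks of an already block-normalized intra matrix.
adjust_intra_blocks <- function(intra_norm, index, adjust) {
  tbl <- index$table
  scope <- adjust$scope
  blocks <- unique(tbl[, c("component", "layer")])
  for (r in seq_len(nrow(blocks))) {
    if (!identical(scope, "all")) {
      hit <- any(vapply(scope, function(s)
        s[1L] == blocks$component[r] &&
          (length(s) == 1L || s[2L] == blocks$layer[r]), logical(1)))
      if (!hit) next
    }
    rows <- which(tbl$component == blocks$component[r] &
                    tbl$layer == blocks$layer[r])
    sub <- intra_norm[rows, rows, drop = FALSE]
    if (all(Matrix::colSums(sub) == 0)) next
    sub <- switch(adjust$method,
      bs = bistochastic_scale(sub, tol = adjust$ipf_tol,
                              max_iter = adjust$ipf_max_iter,
                              check_entropy = FALSE),
      "in" = inflate_normalize(sub, gamma = adjust$gamma,
                               rounds = adjust$rounds))
    intra_norm[rows, rows] <- sub
  }
  intra_norm
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat("transition_matrix:", nrow(x$M), "x", ncol(x$M),
      "| nnz =", length(x$M@x),
      "| dangling columns =", sum(x$dangling), "\n")
  cat("  lambda =", x$params$lambda, "| delta =", x$params$delta,
      "| norm =", x$params$norm,
      if (x$params$norm == "penalized") paste("(k_pen =", x$params$k_pen, ")"),
      "| adjust =", x$params$adjust, "\n")
  invisible(x)
}

#' Export a transition matrix for debugging
#'
#' Writes the sparse matrix in Matrix Market format (`transition.mtx`) plus an
#' index TSV mapping global index to `(component, layer, node)`.
#'
#' @param tm A `transition_matrix`.
#' @param out_dir Output directory, created if missing.
#' @return Invisibly, the files written.
#' @export
write_transition <- function(tm, out_dir) {
  stopifnot(inherits(tm, "transition_matrix"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  f_mtx <- file.path(out_dir, "transition.mtx")
  Matrix::writeMM(tm$M, f_mtx)
  f_idx <- file.path(out_dir, "index.tsv")
  tbl <- cbind(index = seq_len(tm$index$n), tm$index$table)
  utils::write.table(tbl, f_idx, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f_mtx, f_idx))
}
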