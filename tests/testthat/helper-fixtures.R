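# Fixtures built in code: a small deterministic multiplex-heterogeneous graph,
# random monoplex graphs, and an exhaustive maximum-weight connected-subgraph
# oracle for graphs small enough to enumerate.

# Two components: "prot" is a 2-layer multiplex (physical + functional edges
# over partially overlapping proteins), "met" a monoplex of metabolites,
# coupled by two bipartite edges.
toy_multihet <- function(lambda = 0.5, delta = 0.5) {
  phys <- mh_layer("phys", data.frame(
    from = c("p1", "p2", "p3"), to = c("p2", "p3", "p4"),
    weight = c(1, 2, 1)))
  func <- mh_layer("func", data.frame(
    from = c("p2", "p3"), to = c("p3", "p5"), weight = c(5, 1)))
  prot <- mh_component("prot", list(phys, func), tau = c(0.6, 0.4))
  met <- mh_component("met", mh_layer("mmi", data.frame(
    from = c("m1", "m2"), to = c("m2", "m3"), weight = 1)))
  mh_graph(list(prot, met),
           bipartite = list(list(between = c("prot", "met"),
                                 edges = data.frame(from = c("p1", "p3"),
                                                    to = c("m1", "m2"),
                                                    weight = 1))),
           eta = c(0.7, 0.3), lambda = lambda, delta = delta)
}

# Connected Erdos-Renyi monoplex wrapped as an mh_graph.
rand_er_mh <- function(n, p = 0.1, seed = 1) {
  set.seed(seed)
  repeat {
    ig <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(ig)) break
  }
  ed <- igraph::as_edgelist(ig, names = FALSE)
  nodes <- sprintf("n%03d", seq_len(n))
  mh_graph(mh_component("c1", mh_layer(
    "L1", data.frame(from = nodes[ed[, 1]], to = nodes[ed[, 2]], weight = 1),
    nodes = nodes)))
}

# Replica degrees (weighted, intra-layer edges only) in global index order.
replica_degrees <- function(g, index = build_index(g)) {
  blocks <- amendr:::adjacency_blocks(g, index)
  Matrix::rowSums(blocks$intra)
}

# Exhaustive maximum-weight connected subgraph by subset enumeration
# (n <= 20); returns the optimal total weight.
mwcs_bruteforce <- function(gr, w) {
  n <- igraph::vcount(gr)
  stopifnot(n <= 20)
  best <- -Inf
  for (mask in seq_len(2^n - 1)) {
    sel <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    tot <- sum(w[sel])
    if (tot <= best) next
    if (length(sel) == 1 ||
        igraph::is_connected(igraph::induced_subgraph(gr, sel)))
      best <- tot
  }
  best
}

# Direct dense evaluation of the biased normalization rate
# mu_i * a_ij / sum_l mu_l * a_lj for cross-checking sparse code paths.
biased_rate_oracle <- function(A, mu) {
  A <- as.matrix(A)
  out <- A * 0
  for (j in seq_len(ncol(A))) {
    denom <- sum(mu * A[, j])
    if (denom > 0) out[, j] <- mu * A[, j] / denom
  }
  out
}
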