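test_that("column normalization is exact and flags dangling columns", {
  P <- Matrix::Matrix(c(0, 1, 1, 0), 2, 2, sparse = TRUE)
  expect_equal(as.matrix(column_normalize(P)), as.matrix(P))  # permutation

  A <- Matrix::sparseMatrix(i = c(1, 2, 3), j = c(1, 1, 1), x = c(2, 6, 2),
                            dims = c(3, 3))
  M <- column_normalize(A)
  expect_equal(as.numeric(M[, 1]), c(0.2, 0.6, 0.2))
  expect_equal(dangling_columns(M), c(FALSE, TRUE, TRUE))
  expect_equal(Matrix::colSums(M)[2:3], c(0, 0), ignore_attr = TRUE)

  expect_error(column_normalize(Matrix::Matrix(c(0, -1, 1, 0), 2, 2)),
               "negative")
})

test_that("penalized degree normalization matches its elementwise form", {
  # star K1,3: hub row 1, leaves 2:4
  A <- Matrix::sparseMatrix(i = c(1, 1, 1, 2, 3, 4), j = c(2, 3, 4, 1, 1, 1),
                            x = 1, dims = c(4, 4))
  M <- penalized_normalize(A, 1)
  expect_equal(as.numeric(M[1, 2:4]), rep(1, 3))   # leaf columns -> hub
  expect_equal(as.numeric(M[2:4, 1]), rep(1 / 3, 3))  # hub column -> leaves

  # k_pen = 0 reduces to plain column normalization
  set.seed(7)
  B <- abs(Matrix::rsparsematrix(15, 15, 0.3))
  B <- B + Matrix::t(B)
  expect_equal(as.matrix(penalized_normalize(B, 0)),
               as.matrix(column_normalize(B)))

  # regular graph: the common degree factor cancels for any k_pen
  ring <- Matrix::sparseMatrix(i = c(1:6, 2:6, 1), j = c(2:6, 1, 1:6),
                               x = 1, dims = c(6, 6))
  for (k in c(0.3, 1, 2.5))
    expect_equal(as.matrix(penalized_normalize(ring, k)),
                 as.matrix(column_normalize(ring)))

  # elementwise oracle d_i^-k a_ij / sum_l d_l^-k a_lj on random graphs
  for (s in 1:5) {
    set.seed(s)
    A <- abs(Matrix::rsparsematrix(12, 12, 0.4))
    A <- A + Matrix::t(A)
    k <- runif(1, 0, 2)
    deg <- Matrix::rowSums(A)
    expected <- biased_rate_oracle(A, ifelse(deg > 0, deg^(-k), 0))
    expect_equal(as.matrix(penalized_normalize(A, k)), expected,
                 tolerance = 1e-12)
  }
  expect_error(penalized_normalize(A, -0.5), "nonnegative")
})

test_that("biased reweighting realizes the attribute-scaled transition rates", {
  # path i - j - k with unit weights; bias on i doubles its pull from j
  A <- Matrix::sparseMatrix(i = c(1, 2, 2, 3), j = c(2, 1, 3, 2), x = 1,
                            dims = c(3, 3))
  M <- column_normalize(apply_bias(A, c(2, 1, 1)))
  expect_equal(as.numeric(M[, 2]), c(2 / 3, 0, 1 / 3))

  # identity bias changes nothing
  expect_equal(as.matrix(column_normalize(apply_bias(A, rep(1, 3)))),
               as.matrix(column_normalize(A)))

  # monotonicity: raising mu_i strictly increases m_ij for every neighbor j
  set.seed(3)
  B <- abs(Matrix::rsparsematrix(10, 10, 0.4)); B <- B + Matrix::t(B)
  mu <- runif(10, 0.5, 2)
  M1 <- column_normalize(apply_bias(B, mu))
  mu2 <- mu; mu2[4] <- mu[4] * 2
  M2 <- column_normalize(apply_bias(B, mu2))
  nb <- which(as.numeric(B[4, ]) > 0)
  expect_true(all(as.numeric(M2[4, nb]) > as.numeric(M1[4, nb])))

  # elementwise oracle on random small graphs
  for (s in 1:5) {
    set.seed(s + 20)
    A <- abs(Matrix::rsparsematrix(sample(5:20, 1), 1, 0.5))
    n <- nrow(A)
    A <- abs(Matrix::rsparsematrix(n, n, 0.45)); A <- A + Matrix::t(A)
    mu <- runif(n, 0, 3)
    got <- as.matrix(amendr:::reweight_normalize(A, mu = mu))
    exp_m <- biased_rate_oracle(A, mu)
    # columns with all-zero biased neighborhoods fall back to unbiased
    dead <- colSums(exp_m) == 0 & Matrix::colSums(A) > 0
    exp_m[, dead] <- as.matrix(column_normalize(A))[, dead]
    expect_equal(got, exp_m, tolerance = 1e-12)
  }
  expect_error(apply_bias(A, rep(-1, nrow(A))), "nonnegative")
})

test_that("single-component single-layer assembly reduces to plain RWR", {
  g <- rand_er_mh(30, 0.15, seed = 5)
  A <- amendr:::adjacency_blocks(g, build_index(g))$intra
  for (par in list(c(0, 0), c(0.5, 0.5), c(1, 0.3), c(0.2, 1))) {
    tm <- assemble_transition(g, lambda = par[1], delta = par[2])
    expect_equal(as.matrix(tm$M), as.matrix(column_normalize(A)),
                 tolerance = 1e-14)
  }
  tmp <- assemble_transition(g, norm = "penalized", k_pen = 0.7)
  expect_equal(as.matrix(tmp$M), as.matrix(penalized_normalize(A, 0.7)),
               tolerance = 1e-14)
})

test_that("zero crosstalk yields a block-diagonal transition matrix", {
  g <- toy_multihet(lambda = 0, delta = 0)
  tm <- assemble_transition(g)
  idx <- tm$index
  blk <- paste(idx$table$component, idx$table$layer)
  tp <- Matrix::summary(tm$M)
  expect_true(all(blk[tp$i] == blk[tp$j]))
  # every column with intra-layer edges is stochastic, isolated-in-layer
  # replicas lose all mass classes (handled as restart by the engine)
  cs <- Matrix::colSums(tm$M)
  expect_true(all(abs(cs[cs > 0] - 1) < 1e-12))
})

test_that("crosstalk mass partitions the column as configured", {
  g <- toy_multihet(lambda = 0.3, delta = 0.2)
  tm <- assemble_transition(g)
  idx <- tm$index
  tbl <- idx$table
  # p3 in phys has intra neighbors, a func replica, and a bipartite partner
  j <- index_of(idx, "prot", "phys", "p3")
  same_layer <- tbl$component == "prot" & tbl$layer == "phys"
  other_layer <- tbl$component == "prot" & tbl$layer == "func"
  other_comp <- tbl$component == "met"
  col <- as.numeric(tm$M[, j])
  expect_equal(sum(col[same_layer]), (1 - 0.2) * (1 - 0.3))
  expect_equal(sum(col[other_layer]), (1 - 0.2) * 0.3)
  expect_equal(sum(col[other_comp]), 0.2)

  # p4 exists only in phys with no bipartite partner: full mass stays intra
  j4 <- index_of(idx, "prot", "phys", "p4")
  col4 <- as.numeric(tm$M[, j4])
  expect_equal(sum(col4[same_layer]), 1)

  # p1 (phys only, bipartite partner m1): lambda mass reassigned
  # proportionally, leaving (1-delta) intra and delta inter-component
  j1 <- index_of(idx, "prot", "phys", "p1")
  col1 <- as.numeric(tm$M[, j1])
  expect_equal(sum(col1[same_layer]), 1 - 0.2)
  expect_equal(sum(col1[other_comp]), 0.2)
})

test_that("per-class column mass is affine in lambda and in delta", {
  g0 <- toy_multihet()
  idx <- build_index(g0)
  tbl <- idx$table
  j <- index_of(idx, "prot", "phys", "p3")  # has all three target classes
  classes <- list(intra = tbl$component == "prot" & tbl$layer == "phys",
                  layer = tbl$component == "prot" & tbl$layer == "func",
                  comp = tbl$component == "met")
  grid <- seq(0, 1, by = 0.1)
  for (vary in c("lambda", "delta")) {
    masses <- sapply(grid, function(v) {
      tm <- if (vary == "lambda") assemble_transition(g0, lambda = v,
                                                      delta = 0.4)
      else assemble_transition(g0, lambda = 0.4, delta = v)
      col <- as.numeric(tm$M[, j])
      vapply(classes, function(cl) sum(col[cl]), numeric(1))
    })
    for (cl in rownames(masses)) {
      y <- masses[cl, ]
      line <- y[1] + (y[11] - y[1]) * grid  # line through the endpoints
      expect_lt(max(abs(y - line)), 1e-12)
    }
  }
})

test_that("transition matrices export to Matrix Market with their index", {
  dir <- withr::local_tempdir()
  tm <- assemble_transition(toy_multihet())
  files <- write_transition(tm, dir)
  expect_true(all(file.exists(files)))
  M2 <- Matrix::readMM(file.path(dir, "transition.mtx"))
  expect_equal(as.matrix(M2), unname(as.matrix(tm$M)), tolerance = 1e-12)
  idx2 <- utils::read.delim(file.path(dir, "index.tsv"))
  expect_equal(nrow(idx2), tm$index$n)
})
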