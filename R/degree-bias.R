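# Degree-bias adjustment: stationary-distribution scaling of scores (SDS),
# bistochastic scaling of the transition matrix (IPF), and
# inflation-normalization (row exponentiation). BS and IN both aim to raise
# the entropy of the stationary distribution, which for degree-normalized
# walks is a direct proxy for node degree.

#' Specify a degree-bias adjustment
#'
#' @param method One of `"none"`, `"sds"` (divide diffusion scores by
#'   stationary probabilities), `"bs"` (bistochastic scaling of the transition
#'   matrix by iterative proportional fitting), `"in"`
#'   (inflation-normalization: row-wise exponentiation followed by column
#'   renormalization).
#' @param scope `"all"`, or a list of `c(component_id)` /
#'   `c(component_id, layer_id)` vectors selecting the intra-layer blocks the
#'   adjustment applies to.
#' @param ipf_tol,ipf_max_iter Iterative-proportional-fitting controls for
#'   `"bs"`.
#' @param gamma Inflation strength for `"in"` (exponents range over
#'   `[1, 1 + gamma]`).
#' @param rounds Number of inflation rounds for `"in"`.
#' @return An object of class `adjustment_spec`.
#' @export
adjustment_spec <- function(method = c("none", "sds", "bs", "in"),
                            scope = "all", ipf_tol = 1e-6,
                            ipf_max_iter = 1000L, gamma = 1, rounds = 1L) {
  method <- match.arg(method)
  if (!identical(scope, "all")) {
    if (is.character(scope)) scope <- list(scope)
    stopifnot(is.list(scope),
              all(vapply(scope, function(s)
                is.character(s) && length(s) %in% 1:2, logical(1))))
  }
  stopifnot(ipf_tol > 0, ipf_max_iter >= 1, gamma >= 0, rounds >= 0)
  structure(list(method = method, scope = scope, ipf_tol = ipf_tol,
                 ipf_max_iter = as.integer(ipf_max_iter), gamma = gamma,
                 rounds = as.integer(rounds)),
            class = "adjustment_spec")
}

#' Stationary-distribution scaling of diffusion scores
#'
#' Divides each diffusion score by the corresponding stationary probability
#' (`p'_i = p_i / s_i`), favoring low-degree nodes. The result is a ranking
#' score and is deliberately not renormalized. Nodes with `s_i = 0` get `NA`
#' with a warning and should be excluded from rankings.
#'
#' @param p A `diffusion_result` or numeric score vector.
#' @param s Stationary distribution (see [stationary_distribution()]).
#' @return Numeric vector of adjusted scores.
#' @export
sds_adjust <- function(p, s) {
  if (inherits(p, "diffusion_result")) p <- p$p
  stopifnot(length(p) == length(s))
  out <- ifelse(s > 0, p / s, NA_real_)
  if (anyNA(out))
    warning(sum(is.na(out)),
            " node(s) have zero stationary probability; scores undefined")
  out
}

#' Bistochastic scaling of a transition matrix
#'
#' Iterative proportional fitting (Sinkhorn-Knopp): rows and columns are
#' alternately rescaled toward unit sums until the maximum deviation of any
#' row or column sum from 1 falls below `tol` or `max_iter` is reached (the
#' achieved deviation is recorded in the `"ipf_deviation"` attribute; matrices
#' with structural zero rows cannot reach exact bistochasticity and return the
#' best effort). Columns are renormalized exactly at the end so the result is
#' a valid transition matrix. An approximately bistochastic matrix has a
#' near-uniform principal eigenvector, i.e. maximal stationary entropy.
#'
#' @param M A `transition_matrix` or column-stochastic sparse matrix.
#' @param tol Target maximum deviation of row/column sums from 1.
#' @param max_iter Iteration cap.
#' @param check_entropy Verify that the stationary entropy did not decrease
#'   (warns on violation).
#' @return Adjusted matrix of the same type as the input.
#' @export
bistochastic_scale <- function(M, tol = 1e-6, max_iter = 1000L,
                               check_entropy = TRUE) {
  tm <- NULL
  if (inherits(M, "transition_matrix")) {
    tm <- M
    M <- M$M
  }
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  if (length(M@x) && min(M@x) < 0) stop("transition matrix must be nonnegative")
  A <- M
  dev <- Inf
  for (it in seq_len(max_iter)) {
    rs <- Matrix::rowSums(A)
    A <- Matrix::Diagonal(x = ifelse(rs > 0, 1 / rs, 0)) %*% A
    cs <- Matrix::colSums(A)
    A <- A %*% Matrix::Diagonal(x = ifelse(cs > 0, 1 / cs, 0))
    rs <- Matrix::rowSums(A); cs <- Matrix::colSums(A)
    dev <- max(abs(c(rs[rs > 0], cs[cs > 0]) - 1))
    if (dev <= tol) break
  }
  out <- column_normalize(A)
  attr(out, "ipf_deviation") <- dev
  if (check_entropy) {
    h0 <- stationary_entropy(M)
    h1 <- stationary_entropy(out)
    if (h1 < h0 - 1e-9)
      warning(sprintf(
        "bistochastic scaling decreased stationary entropy (%.6f -> %.6f)",
        h0, h1))
  }
  if (!is.null(tm)) {
    tm$M <- out
    tm$params$adjust <- "bs"
    return(tm)
  }
  out
}

#' Inflation-normalization of a transition matrix
#'
#' Per round: compute the stationary distribution `s` of the current matrix;
#' assign row `i` the exponent `alpha_i = 1 + gamma * (s_i - min s) /
#' (max s - min s)` (`alpha = 1` everywhere when `s` is constant); raise the
#' entries of row `i` to the power `alpha_i`; renormalize columns. Entries are
#' at most 1, so exponents above 1 shrink them - incoming mass is displaced
#' away from high-stationary-probability (high-degree) rows, raising the
#' stationary entropy. `gamma = 0` or `rounds = 0` is the identity.
#'
#' @param M A `transition_matrix` or column-stochastic sparse matrix.
#' @param gamma Nonnegative inflation strength.
#' @param rounds Number of rounds.
#' @return Adjusted matrix of the same type as the input.
#' @export
inflate_normalize <- function(M, gamma = 1, rounds = 1L) {
  tm <- NULL
  if (inherits(M, "transition_matrix")) {
    tm <- M
    M <- M$M
  }
  stopifnot(gamma >= 0, rounds >= 0)
  M <- methods::as(methods::as(M, "CsparseMatrix"), "generalMatrix")
  if (gamma > 0 && rounds > 0) {
    for (rd in seq_len(rounds)) {
      s <- stationary_distribution(M, method = "power")
      rng <- max(s) - min(s)
      alpha <- if (rng > 0) 1 + gamma * (s - min(s)) / rng
      else rep(1, length(s))
      if (length(M@x)) {
        rows <- M@i + 1L  # dgCMatrix stores 0-based row indices
        M@x <- M@x^alpha[rows]
      }
      M <- column_normalize(M)
    }
  }
  if (!is.null(tm)) {
    tm$M <- M
    tm$params$adjust <- "in"
    return(tm)
  }
  M
}

#' Shannon entropy of the stationary distribution
#'
#' @param M A `transition_matrix` or column-stochastic matrix.
#' @return Entropy in nats.
#' @export
stationary_entropy <- function(M) {
  s <- stationary_distribution(M, method = "power")
  s <- s[s > 0]
  -sum(s * log(s))
}
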