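#' Adaptively learned adjacency matrix for one window
#'
#' Edge weights are produced by a similarity function with a learnable weight
#' vector `omega` applied to element-wise absolute differences of node
#' signals:
#' \deqn{A_{mn} = \frac{\exp(\mathrm{ReLU}(\omega^\top |x_m - x_n|))}
#'                    {\sum_{n'} \exp(\mathrm{ReLU}(\omega^\top |x_m - x_{n'}|))}}
#' The ReLU keeps pre-normalisation scores non-negative and the row-wise
#' softmax makes `A` row-stochastic. The diagonal is included (self-loops:
#' `|x_m - x_m| = 0` contributes `exp(0) = 1` before normalisation). At
#' `omega = 0` the adjacency degenerates to the uniform matrix `1/N` — the
#' trivial solution the joint training loss is designed to move away from.
#'
#' @param segment Numeric matrix `N x L` (one window; rows = ROIs).
#' @param omega Numeric weight vector of length `L`.
#' @return `N x N` row-stochastic matrix with strictly positive entries.
#' @export
#' @examples
#' adaptive_adjacency(matrix(rnorm(8), 4, 2), c(0, 0))  # uniform 1/4
adaptive_adjacency <- function(segment, omega) {
  segment <- as.matrix(segment)
  if (!all(is.finite(segment))) stop("segment contains non-finite values")
  if (length(omega) != ncol(segment)) {
    stop(sprintf("omega has length %d but segment has %d columns",
                 length(omega), ncol(segment)))
  }
  n <- nrow(segment)
  # scores[m, n] = omega' |x_m - x_n|
  d <- pairwise_absdiff(segment)            # (N*N) x L, row-major (m outer)
  s <- pmax(d %*% omega, 0)
  e <- exp(matrix(s, n, n, byrow = TRUE))   # e[m, n]
  e / rowSums(e)
}

# Rows indexed k = (m-1)*N + n (m outer), giving |x_m - x_n| per row.
pairwise_absdiff <- function(segment) {
  n <- nrow(segment)
  m_idx <- rep(seq_len(n), each = n)
  n_idx <- rep(seq_len(n), times = n)
  abs(segment[m_idx, , drop = FALSE] - segment[n_idx, , drop = FALSE])
}

#' Graph-learning regularisation loss
#'
#' \deqn{L = \sum_{m,n} \|x_m - x_n\|_2^2 \, A_{mn} + \lambda \|A\|_F^2}
#' The first term rewards placing weight on edges between nodes with similar
#' signals (smoothness); the Frobenius term encodes the sparsity prior on
#' brain graphs. Minimised on its own this loss collapses to `omega = 0`
#' (uniform adjacency), which is why it enters training only as a regulariser
#' added to the classification loss.
#'
#' @param segment Numeric `N x L` window.
#' @param adjacency `N x N` adjacency for that window.
#' @param lambda_reg Non-negative sparsity weight.
#' @return Non-negative scalar.
#' @export
graph_learning_loss <- function(segment, adjacency, lambda_reg = 1e-3) {
  segment <- as.matrix(segment)
  adjacency <- as.matrix(adjacency)
  n <- nrow(segment)
  if (!identical(dim(adjacency), c(n, n))) {
    stop("adjacency must be N x N for an N-row segment")
  }
  if (lambda_reg < 0) stop("lambda_reg must be non-negative")
  d2 <- pairwise_sqdist(segment)
  sum(d2 * adjacency) + lambda_reg * sum(adjacency^2)
}

# d2[m, n] = ||x_m - x_n||_2^2
pairwise_sqdist <- function(segment) {
  sq <- rowSums(segment^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(segment)
  pmax(d2, 0)
}

#' Graph convolution over a fixed window adjacency
#'
#' Applies `H^{l+1} = act(A H^l W^l)` for each layer, with the same adjacency
#' at every layer of one window. This is the evaluation-mode (deterministic)
#' primitive: batch normalisation and dropout live in the trainable model
#' ([astnet()]), which uses batch statistics and masks shared across a
#' minibatch.
#'
#' @param segment `N x L` input features (`H^0`).
#' @param adjacency `N x N` (row-stochastic in normal use).
#' @param weights List of weight matrices `W^l`, chained dimensions.
#' @param activation Activation applied after each aggregation; `"relu"`
#'   (default) or `"identity"`.
#' @return `N x D_out` node-feature matrix.
#' @export
gcn_forward <- function(segment, adjacency, weights,
                        activation = c("relu", "identity")) {
  activation <- match.arg(activation)
  h <- as.matrix(segment)
  a <- as.matrix(adjacency)
  if (nrow(a) != nrow(h) || ncol(a) != nrow(h)) {
    stop("adjacency must be N x N for an N-row segment")
  }
  for (w in weights) {
    if (ncol(h) != nrow(w)) stop("GCN weight dimensions do not chain")
    h <- a %*% h %*% w
    if (activation == "relu") h <- pmax(h, 0)
  }
  h
}

#' Second-order connectivity matrix
#'
#' `S = H H'` from the final GCN node features; symmetric and positive
#' semidefinite by construction, measuring second-order dependency between
#' ROIs in the learned feature space.
#'
#' @param node_features `N x D` matrix.
#' @return `N x N` symmetric PSD matrix.
#' @export
connectivity_matrix <- function(node_features) {
  h <- as.matrix(node_features)
  if (!all(is.finite(h))) stop("node_features contains non-finite values")
  tcrossprod(h)
}

#' Flatten the strict upper triangle of a symmetric matrix
#'
#' Row-major order: (1,2), (1,3), ..., (1,N), (2,3), ..., (N-1,N); the
#' diagonal is excluded. Length `N(N-1)/2` — 6670 for the 116-parcel AAL
#' atlas.
#'
#' @param mat Square matrix.
#' @return Numeric vector of length `N(N-1)/2`.
#' @seealso [matrix_from_upper()] for the inverse (zero diagonal).
#' @export
vectorize_upper <- function(mat) {
  mat <- as.matrix(mat)
  n <- nrow(mat)
  if (ncol(mat) != n) stop("input must be square")
  mat[upper_index(n)]
}

# Linear indices of the strict upper triangle in row-major pair order.
upper_index <- function(n) {
  ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  ij <- ij[order(ij[, "row"], ij[, "col"]), , drop = FALSE]
  (ij[, "col"] - 1L) * n + ij[, "row"]
}

#' Rebuild a symmetric matrix from its strict upper triangle
#'
#' @param v Vector of length `N(N-1)/2` in the [vectorize_upper()] order.
#' @param n Matrix dimension `N`.
#' @param diag Value placed on the diagonal (default 0).
#' @return `N x N` symmetric matrix.
#' @export
matrix_from_upper <- function(v, n, diag = 0) {
  if (length(v) != n * (n - 1) / 2) stop("length(v) must be N(N-1)/2")
  out <- matrix(0, n, n)
  out[upper_index(n)] <- v
  out <- out + t(out)
  base::diag(out) <- diag
  out
}

#' Pearson functional connectivity of one window
#'
#' Classical static/windowed FC: correlation between the ROI time courses of
#' the window. Constant-signal ROIs yield undefined correlations, which are
#' set to 0 off-diagonal (1 on the diagonal).
#'
#' @param segment `N x L` matrix (rows = ROIs).
#' @return `N x N` correlation matrix.
#' @export
pearson_fc <- function(segment) {
  r <- suppressWarnings(stats::cor(t(segment)))
  r[!is.finite(r)] <- 0
  diag(r) <- 1
  r
}
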