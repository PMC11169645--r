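#' One GRU step
#'
#' Gated recurrent unit update acting on the concatenation `[h_prev, x]`:
#' \deqn{z = \sigma(W_z [h, x] + b_z),\quad r = \sigma(W_r [h, x] + b_r)}
#' \deqn{\tilde h = \tanh(W_h [r \odot h, x] + b_h),\quad
#'       h' = (1 - z) \odot h + z \odot \tilde h}
#' The reset gate `r` controls how much of the previous memory enters the
#' candidate state; the update gate `z` balances forgetting the old state
#' against writing the candidate.
#'
#' @param x_t Input vector at this step.
#' @param h_prev Previous hidden state (length = units).
#' @param params List with matrices `W_z`, `W_r`, `W_h` of shape
#'   `(units + length(x_t)) x units` and bias vectors `b_z`, `b_r`, `b_h`
#'   (biases optional, defaulting to zero).
#' @return New hidden state, length = units.
#' @export
gru_step <- function(x_t, h_prev, params) {
  u <- length(h_prev)
  d <- length(x_t)
  for (nm in c("W_z", "W_r", "W_h")) {
    w <- params[[nm]]
    if (is.null(w) || nrow(w) != u + d || ncol(w) != u) {
      stop(sprintf("%s must be (units + input_dim) x units", nm))
    }
  }
  b_z <- params$b_z %||% numeric(u)
  b_r <- params$b_r %||% numeric(u)
  b_h <- params$b_h %||% numeric(u)
  hx <- c(h_prev, x_t)
  z <- sigmoid(drop(hx %*% params$W_z) + b_z)
  r <- sigmoid(drop(hx %*% params$W_r) + b_r)
  h_tilde <- tanh(drop(c(r * h_prev, x_t) %*% params$W_h) + b_h)
  (1 - z) * h_prev + z * h_tilde
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Encode a window sequence with a stacked bidirectional GRU
#'
#' One GRU scans the sequence start-to-end, a second scans end-to-start; at
#' each layer the per-step outputs of the two directions are concatenated and
#' fed to the next layer. The encoding is the concatenation of the two final
#' hidden states of the top layer (forward direction after step `T`, backward
#' direction after step 1), so the output length is `2 x units` regardless of
#' `T`.
#'
#' @param sequence List of `T >= 1` input vectors (equal length).
#' @param forward_params,backward_params Per-direction parameters: either one
#'   [gru_step()] parameter list (single layer) or a list of `num_layers` of
#'   them. Layer `l > 1` takes the `2 x units`-dim concatenated outputs of
#'   layer `l - 1` as input.
#' @param num_layers Number of stacked layers (default 2).
#' @return Numeric vector of length `2 x units`.
#' @export
bigru_encode <- function(sequence, forward_params, backward_params,
                         num_layers = 2L) {
  if (length(sequence) == 0L) stop("empty sequence")
  if (!is.null(forward_params$W_z)) forward_params <- list(forward_params)
  if (!is.null(backward_params$W_z)) backward_params <- list(backward_params)
  if (length(forward_params) != num_layers ||
      length(backward_params) != num_layers) {
    stop("need one parameter set per layer and direction")
  }
  seq_in <- sequence
  for (l in seq_len(num_layers)) {
    units <- ncol(forward_params[[l]]$W_z)
    t_len <- length(seq_in)
    h_f <- numeric(units)
    h_b <- numeric(units)
    out_f <- vector("list", t_len)
    out_b <- vector("list", t_len)
    for (t in seq_len(t_len)) {
      h_f <- gru_step(seq_in[[t]], h_f, forward_params[[l]])
      out_f[[t]] <- h_f
    }
    for (t in rev(seq_len(t_len))) {
      h_b <- gru_step(seq_in[[t]], h_b, backward_params[[l]])
      out_b[[t]] <- h_b
    }
    seq_in <- lapply(seq_len(t_len), function(t) c(out_f[[t]], out_b[[t]]))
    final <- c(h_f, h_b)
  }
  final
}

#' Embed one flattened connectivity vector through the window MLP
#'
#' The fully connected stack (default widths 1024/256/32 in the trained
#' model) that turns the upper-triangle connectivity vector of one window
#' into its feature `F_t`. ReLU after every layer; the two dropout layers of
#' the trained model sit after layers 1 and 2 and are inactive here
#' (evaluation-mode primitive).
#'
#' @param flat_connectivity Input vector (length `N(N-1)/2` in normal use).
#' @param weights List of layers, each `list(W = matrix, b = vector)` with
#'   chained dimensions.
#' @return Output vector (length = last layer width).
#' @export
window_embed <- function(flat_connectivity, weights) {
  v <- as.numeric(flat_connectivity)
  for (layer in weights) {
    if (length(v) != nrow(layer$W)) stop("MLP weight dimensions do not chain")
    v <- pmax(drop(v %*% layer$W) + layer$b, 0)
  }
  v
}

#' Channel attention over the window sequence
#'
#' Average- and max-pools each window's feature vector down to one scalar,
#' passes both length-`T` descriptors through a shared bottleneck MLP
#' (`T -> max(1, floor(T/ratio)) -> T`, ReLU between, weights shared across
#' the two pooled inputs), sums, and applies a sigmoid to obtain per-window
#' attention weights in (0, 1). The global feature is the attention-weighted
#' sum of the window features.
#'
#' @param features `T x D` matrix of window features (`D` = 32 in the trained
#'   model).
#' @param weights Shared-MLP parameters `list(V1, c1, V2, c2)` with `V1`
#'   `T x h`, `V2` `h x T`; see [init_attention_weights()].
#' @return List with `global_feature` (length `D`) and `weights`
#'   (length `T`, all in (0, 1)).
#' @export
global_attention <- function(features, weights) {
  f <- as.matrix(features)
  t_len <- nrow(f)
  if (t_len == 0L) stop("need at least one window")
  if (nrow(weights$V1) != t_len || ncol(weights$V2) != t_len) {
    stop("attention MLP shaped for a different number of windows")
  }
  pool_avg <- rowMeans(f)
  pool_max <- apply(f, 1L, max)
  shared <- function(d) {
    drop(pmax(drop(d %*% weights$V1) + weights$c1, 0) %*% weights$V2) +
      weights$c2
  }
  w <- sigmoid(shared(pool_avg) + shared(pool_max))
  list(global_feature = drop(crossprod(f, w)), weights = w)
}

#' Initialise shared-MLP weights for [global_attention()]
#'
#' Bottleneck width is `max(1, floor(n_windows / reduction_ratio))`; with the
#' default ratio 3 this stays >= 1 even for the shortest (3-window) series.
#' Uses the current RNG state.
#'
#' @param n_windows Number of windows `T`.
#' @param reduction_ratio Bottleneck reduction ratio (default 3).
#' @param sd Standard deviation of the normal initialisation.
#' @return List `V1`, `c1`, `V2`, `c2`.
#' @export
init_attention_weights <- function(n_windows, reduction_ratio = 3L, sd = 0.1) {
  h <- max(1L, n_windows %/% reduction_ratio)
  list(V1 = matrix(stats::rnorm(n_windows * h, sd = sd), n_windows, h),
       c1 = numeric(h),
       V2 = matrix(stats::rnorm(h * n_windows, sd = sd), h, n_windows),
       c2 = numeric(n_windows))
}
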