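# Brute-force scalar oracles, written independently of the implementation:
# explicit loops over the defining formulas. Used to freeze expected values
# and for randomized equivalence tests.

o_adjacency <- function(segment, omega) {
  n <- nrow(segment)
  a <- matrix(0, n, n)
  for (m in seq_len(n)) {
    for (nn in seq_len(n)) {
      s <- 0
      for (f in seq_len(ncol(segment))) {
        s <- s + omega[f] * abs(segment[m, f] - segment[nn, f])
      }
      a[m, nn] <- exp(max(0, s))
    }
  }
  for (m in seq_len(n)) a[m, ] <- a[m, ] / sum(a[m, ])
  a
}

o_graph_loss <- function(segment, adjacency, lambda) {
  n <- nrow(segment)
  total <- 0
  for (m in seq_len(n)) {
    for (nn in seq_len(n)) {
      d2 <- sum((segment[m, ] - segment[nn, ])^2)
      total <- total + d2 * adjacency[m, nn]
    }
  }
  total + lambda * sum(adjacency^2)
}

o_matmul <- function(a, b) {
  out <- matrix(0, nrow(a), ncol(b))
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(b))) {
      s <- 0
      for (k in seq_len(ncol(a))) s <- s + a[i, k] * b[k, j]
      out[i, j] <- s
    }
  }
  out
}

o_gru_step <- function(x, h, params) {
  u <- length(h)
  hx <- c(h, x)
  z <- r <- numeric(u)
  for (j in seq_len(u)) {
    z[j] <- 1 / (1 + exp(-(sum(hx * params$W_z[, j]) + params$b_z[j])))
    r[j] <- 1 / (1 + exp(-(sum(hx * params$W_r[, j]) + params$b_r[j])))
  }
  rhx <- c(r * h, x)
  ht <- numeric(u)
  for (j in seq_len(u)) {
    ht[j] <- tanh(sum(rhx * params$W_h[, j]) + params$b_h[j])
  }
  (1 - z) * h + z * ht
}

o_mlp <- function(v, weights) {
  for (layer in weights) {
    out <- numeric(ncol(layer$W))
    for (j in seq_along(out)) {
      out[j] <- max(0, sum(v * layer$W[, j]) + layer$b[j])
    }
    v <- out
  }
  v
}

o_attention <- function(features, w) {
  t_len <- nrow(features)
  pa <- pm <- numeric(t_len)
  for (t in seq_len(t_len)) {
    pa[t] <- mean(features[t, ])
    pm[t] <- max(features[t, ])
  }
  shared <- function(d) {
    mid <- pmax(drop(d %*% w$V1) + w$c1, 0)
    drop(mid %*% w$V2) + w$c2
  }
  wt <- 1 / (1 + exp(-(shared(pa) + shared(pm))))
  d_bar <- numeric(ncol(features))
  for (t in seq_len(t_len)) d_bar <- d_bar + wt[t] * features[t, ]
  list(global_feature = d_bar, weights = wt)
}

o_tally <- function(pred, label) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(pred)) {
    if (label[i] == 1L && pred[i] == 1L) tp <- tp + 1L
    if (label[i] == 0L && pred[i] == 0L) tn <- tn + 1L
    if (label[i] == 0L && pred[i] == 1L) fp <- fp + 1L
    if (label[i] == 1L && pred[i] == 0L) fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

random_gru_params <- function(units, d_in, sd = 0.5) {
  list(W_z = matrix(stats::rnorm((units + d_in) * units, sd = sd),
                    units + d_in, units),
       W_r = matrix(stats::rnorm((units + d_in) * units, sd = sd),
                    units + d_in, units),
       W_h = matrix(stats::rnorm((units + d_in) * units, sd = sd),
                    units + d_in, units),
       b_z = stats::rnorm(units, sd = sd),
       b_r = stats::rnorm(units, sd = sd),
       b_h = stats::rnorm(units, sd = sd))
}

# tiny cohort + config used across model tests
tiny_spec <- function(seed = 11, ...) {
  cohort_spec(n_subjects_per_group = 3, n_rois = 5, n_timepoints = 24,
              window_length = 8, n_states = 2,
              community_partition = c(1, 1, 1, 2, 2),
              effect_edges = rbind(c(1, 4)), seed = seed, ...)
}

tiny_config <- function(...) {
  astnet_config(window_length = 8, n_rois = 5, gcn_dims = c(4, 3),
                mlp_dims = c(7, 4), gru_units = 2, gru_layers = 2,
                gru_input_dim = 3, head_dims = c(5, 3, 2), dropout = 0,
                batch_size = 4, seed = 5, ...)
}

# Finite-difference gradient check with a two-epsilon consistency guard:
# coordinates sitting on a ReLU/argmax kink (where the two step sizes
# disagree) are skipped, since the subgradient convention and the FD
# half-slope legitimately differ there.
check_gradients <- function(variant, n_per_param = 6, seed = 1) {
  set.seed(seed)
  coh <- generate_cohort(tiny_spec())
  cfg <- tiny_config()
  m <- build_variant(variant, cfg, n_windows = 3, n_timepoints = 24)
  m$params <- lapply(m$params, function(p) {
    p + stats::rnorm(length(p), sd = 0.05)
  })
  prep <- astnet:::prepare_cohort_data(coh, m$config, m$spec)
  idx <- 1:4
  loss_at <- function(params) {
    astnet:::nn_forward(params, m$config, m$spec, prep, idx,
                        training = TRUE, bn_state = m$bn_state)$total
  }
  fw <- astnet:::nn_forward(m$params, m$config, m$spec, prep, idx,
                            training = TRUE, bn_state = m$bn_state,
                            keep_cache = TRUE)
  gr <- astnet:::nn_backward(m$params, m$config, m$spec, prep, fw)
  worst <- 0
  for (nm in names(gr)) {
    p <- m$params[[nm]]
    for (i in sample(length(p), min(n_per_param, length(p)))) {
      fd_at <- function(eps) {
        pp <- m$params; pp[[nm]][i] <- pp[[nm]][i] + eps
        pm <- m$params; pm[[nm]][i] <- pm[[nm]][i] - eps
        (loss_at(pp) - loss_at(pm)) / (2 * eps)
      }
      fd1 <- fd_at(1e-5)
      fd2 <- fd_at(2e-5)
      if (abs(fd1 - fd2) > 0.01 * max(abs(fd1), 1e-4)) next  # kink
      an <- gr[[nm]][i]
      if (abs(fd1 - an) < 1e-6) next
      worst <- max(worst, abs(fd1 - an) / max(1e-4, abs(fd1), abs(an)))
    }
  }
  worst
}
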