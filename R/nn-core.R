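# Hand-written neural-network core: batched forward with caches, analytic
# backward, Adam. No autodiff framework exists in this R stack, so gradients
# are derived per block and verified against finite differences in the tests.

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

# Parameter set for one model. `spec` comes from the variants factory:
# list(adjacency = "adaptive"|"pearson", use_gcn, use_global, use_local).
init_params <- function(config, n_windows, variant_spec) {
  L <- config$window_length
  n <- config$n_rois
  p_feat <- n * (n - 1L) / 2L
  params <- list()
  if (variant_spec$adjacency == "adaptive") {
    # Normal init with positive mean: scores omega'|x_m - x_n| must start in
    # the responsive range of the row softmax, otherwise the adjacency is
    # indistinguishable from the degenerate uniform solution (omega = 0) and
    # no gradient can differentiate edges. Scaled for signals of unit
    # variance.
    params$omega <- stats::rnorm(L, mean = 0.5, sd = 0.1)
  }
  if (variant_spec$use_gcn) {
    dims <- c(L, config$gcn_dims)
    for (l in seq_along(config$gcn_dims)) {
      params[[paste0("gcn_W", l)]] <- glorot(dims[l], dims[l + 1L])
      if (config$use_batch_norm) {
        params[[paste0("gcn_gamma", l)]] <- rep(1, dims[l + 1L])
        params[[paste0("gcn_beta", l)]] <- rep(0, dims[l + 1L])
      }
    }
  }
  if (variant_spec$use_global) {
    dims <- c(p_feat, config$mlp_dims)
    for (l in seq_along(config$mlp_dims)) {
      params[[paste0("mlp_W", l)]] <- glorot(dims[l], dims[l + 1L])
      params[[paste0("mlp_b", l)]] <- rep(0, dims[l + 1L])
    }
    h_att <- max(1L, n_windows %/% config$attention_ratio)
    params$att_V1 <- glorot(n_windows, h_att)
    params$att_c1 <- rep(0, h_att)
    params$att_V2 <- glorot(h_att, n_windows)
    params$att_c2 <- rep(0, n_windows)
  }
  if (variant_spec$use_local) {
    din <- config$gru_input_dim
    params$proj_W <- glorot(p_feat, din)
    params$proj_b <- rep(0, din)
    u <- config$gru_units
    for (l in seq_len(config$gru_layers)) {
      d_in_l <- if (l == 1L) din else 2L * u
      for (dir in c("f", "b")) {
        for (g in c("Wz", "Wr", "Wh")) {
          params[[sprintf("gru_l%d_%s_%s", l, dir, g)]] <-
            glorot(u + d_in_l, u)
        }
        for (g in c("bz", "br", "bh")) {
          params[[sprintf("gru_l%d_%s_%s", l, dir, g)]] <- rep(0, u)
        }
      }
    }
  }
  d_head_in <- 0L
  if (variant_spec$use_global) {
    d_head_in <- d_head_in + config$mlp_dims[length(config$mlp_dims)]
  }
  if (variant_spec$use_local) d_head_in <- d_head_in + 2L * config$gru_units
  dims <- c(d_head_in, config$head_dims)
  for (l in seq_along(config$head_dims)) {
    params[[paste0("head_W", l)]] <- glorot(dims[l], dims[l + 1L])
    params[[paste0("head_b", l)]] <- rep(0, dims[l + 1L])
  }
  params
}

# Precompute everything that does not depend on parameters: stacked segments,
# pairwise |x_m - x_n| design matrices and squared distances (adaptive
# adjacency), or fixed Pearson-based adjacencies / features.
prepare_subject <- function(data_mat, config, variant_spec, n_windows) {
  L <- config$window_length
  n <- nrow(data_mat)
  segs <- lapply(seq_len(n_windows), function(t) {
    data_mat[, ((t - 1L) * L + 1L):(t * L), drop = FALSE]
  })
  out <- list(G = do.call(rbind, segs))   # (T*N) x L
  if (variant_spec$adjacency == "adaptive") {
    dabs <- do.call(rbind, lapply(segs, pairwise_absdiff))  # (T*N^2) x L
    out$Dabs <- dabs
    out$d2 <- rowSums(dabs^2)
  } else {
    a_list <- lapply(segs, function(g) {
      r <- abs(pearson_fc(g))
      e <- exp(r)
      t(e / rowSums(e))                   # stored transposed (A_k')
    })
    out$A_t <- do.call(cbind, a_list)     # N x (T*N)
    if (!variant_spec$use_gcn) {
      uidx <- upper_index(n)
      out$u <- do.call(rbind, lapply(segs, function(g) pearson_fc(g)[uidx]))
    }
  }
  out
}

prepare_cohort_data <- function(cohort, config, variant_spec) {
  L <- config$window_length
  t_tot <- vapply(cohort$subjects, function(s) ncol(s$data), integer(1))
  if (any(t_tot < L)) stop("series shorter than one window")
  n_windows <- min(t_tot) %/% L
  list(
    subjects = lapply(cohort$subjects, function(s) {
      prepare_subject(s$data, config, variant_spec, n_windows)
    }),
    labels = cohort_labels(cohort),
    n_windows = n_windows
  )
}

bn_eps <- 1e-5

# Forward pass over a minibatch of prepared subjects. Returns loss pieces,
# logits and (optionally) a full cache for the backward pass / diagnostics.
nn_forward <- function(params, config, variant_spec, prep, idx,
                       training = FALSE, bn_state = NULL,
                       keep_cache = FALSE, keep_diagnostics = FALSE) {
  n <- config$n_rois
  t_len <- prep$n_windows
  b <- length(idx)
  m_tot <- b * t_len
  uidx <- upper_index(n)
  p_feat <- n * (n - 1L) / 2L
  keep <- 1 - config$dropout
  cache <- list()
  new_bn <- bn_state

  ## ---- adjacency -------------------------------------------------------
  # Internal layout: a_t is the transposed stack, N rows (target node n) by
  # M*N columns (window k, source node m); column (k-1)*N + m holds row m of
  # A_k. This keeps every reshape a plain as.vector (no aperm copies).
  if (variant_spec$adjacency == "adaptive") {
    dall <- do.call(rbind, lapply(prep$subjects[idx], `[[`, "Dabs"))
    d2all <- unlist(lapply(prep$subjects[idx], `[[`, "d2"), use.names = FALSE)
    score <- drop(dall %*% params$omega)
    relu_mask <- score > 0
    e <- exp(pmax(score, 0))
    emat <- matrix(e, nrow = n)                      # N x (M*N), n fastest
    a_t <- emat / rep(colSums(emat), each = n)
    avec <- as.vector(a_t)
    graph_loss <- (sum(d2all * avec) +
                     config$lambda_reg * sum(avec^2)) / b
    if (keep_cache) {
      cache$dall <- dall; cache$d2all <- d2all
      cache$relu_mask <- relu_mask
    }
  } else {
    a_t <- do.call(cbind, lapply(prep$subjects[idx], `[[`, "A_t"))
    graph_loss <- 0
  }

  ## ---- per-window features --------------------------------------------
  if (variant_spec$use_gcn) {
    h <- do.call(rbind, lapply(prep$subjects[idx], `[[`, "G"))  # (M*N) x L
    n_layers <- length(config$gcn_dims)
    gcn_cache <- vector("list", n_layers)
    for (l in seq_len(n_layers)) {
      w <- params[[paste0("gcn_W", l)]]
      p_lin <- h %*% w
      z <- matrix(0, nrow(p_lin), ncol(p_lin))
      for (k in seq_len(m_tot)) {
        r <- ((k - 1L) * n + 1L):(k * n)
        # column block of a_t is A_k', so crossprod gives A_k %*% P_k
        z[r, ] <- crossprod(a_t[, r, drop = FALSE], p_lin[r, , drop = FALSE])
      }
      if (config$use_batch_norm) {
        key <- paste0("gcn", l)
        if (training) {
          mu <- colMeans(z)
          v <- colMeans(z^2) - mu^2
          if (!is.null(new_bn)) {
            mom <- 0.1
            new_bn[[key]]$mean <- (1 - mom) * new_bn[[key]]$mean + mom * mu
            new_bn[[key]]$var <- (1 - mom) * new_bn[[key]]$var + mom * v
          }
        } else {
          mu <- bn_state[[key]]$mean
          v <- bn_state[[key]]$var
        }
        xhat <- sweep(sweep(z, 2L, mu), 2L, sqrt(v + bn_eps), "/")
        y <- sweep(sweep(xhat, 2L, params[[paste0("gcn_gamma", l)]], "*"),
                   2L, params[[paste0("gcn_beta", l)]], "+")
      } else {
        xhat <- NULL
        y <- z
        mu <- v <- NULL
      }
      act <- pmax(y, 0)
      if (training && config$dropout > 0) {
        mask <- matrix(stats::rbinom(length(act), 1L, keep), nrow(act)) / keep
        act_out <- act * mask
      } else {
        mask <- NULL
        act_out <- act
      }
      gcn_cache[[l]] <- list(h_in = h, p_lin = p_lin, z = z, mu = mu, v = v,
                             xhat = xhat, y = y, mask = mask)
      h <- act_out
    }
    h3 <- h                                          # (M*N) x D
    u_mat <- matrix(0, m_tot, p_feat)
    s_list <- if (keep_cache || keep_diagnostics) vector("list", m_tot)
    h3_blocks <- vector("list", m_tot)
    for (k in seq_len(m_tot)) {
      r <- ((k - 1L) * n + 1L):(k * n)
      hb <- h3[r, , drop = FALSE]
      s <- tcrossprod(hb)
      u_mat[k, ] <- s[uidx]
      h3_blocks[[k]] <- hb
      if (!is.null(s_list)) s_list[[k]] <- s
    }
    if (keep_cache) {
      cache$gcn <- gcn_cache; cache$h3_blocks <- h3_blocks
    }
  } else if (variant_spec$adjacency == "adaptive") {
    # feature = symmetrised learned adjacency, upper triangle
    u_mat <- matrix(0, m_tot, p_feat)
    s_list <- if (keep_diagnostics) vector("list", m_tot)
    for (k in seq_len(m_tot)) {
      r <- ((k - 1L) * n + 1L):(k * n)
      ab <- a_t[, r, drop = FALSE]
      s <- (ab + t(ab)) / 2
      u_mat[k, ] <- s[uidx]
      if (!is.null(s_list)) s_list[[k]] <- s
    }
  } else {
    u_mat <- do.call(rbind, lapply(prep$subjects[idx], `[[`, "u"))
    s_list <- if (keep_diagnostics) {
      lapply(seq_len(m_tot), function(k) matrix_from_upper(u_mat[k, ], n, 1))
    }
  }
  if (keep_cache) cache$u_mat <- u_mat

  ## ---- global branch ---------------------------------------------------
  dbar <- NULL
  att_w <- NULL
  if (variant_spec$use_global) {
    n_mlp <- length(config$mlp_dims)
    mlp_cache <- vector("list", n_mlp)
    x <- u_mat
    for (l in seq_len(n_mlp)) {
      pre <- sweep(x %*% params[[paste0("mlp_W", l)]], 2L,
                   params[[paste0("mlp_b", l)]], "+")
      act <- pmax(pre, 0)
      if (l < n_mlp && training && config$dropout > 0) {
        mask <- matrix(stats::rbinom(length(act), 1L, keep), nrow(act)) / keep
        out <- act * mask
      } else {
        mask <- NULL
        out <- act
      }
      mlp_cache[[l]] <- list(x_in = x, pre = pre, mask = mask)
      x <- out
    }
    f3 <- x                                          # M x 32
    grp <- rep(seq_len(b), each = t_len)
    p_avg <- matrix(rowMeans(f3), b, t_len, byrow = TRUE)
    amax <- max.col(f3, ties.method = "first")
    p_max <- matrix(f3[cbind(seq_len(m_tot), amax)], b, t_len, byrow = TRUE)
    att_shared <- function(d) {
      mid_pre <- sweep(d %*% params$att_V1, 2L, params$att_c1, "+")
      mid <- pmax(mid_pre, 0)
      list(out = sweep(mid %*% params$att_V2, 2L, params$att_c2, "+"),
           mid_pre = mid_pre, mid = mid)
    }
    sa <- att_shared(p_avg)
    sm <- att_shared(p_max)
    att_w <- sigmoid(sa$out + sm$out)                # B x T, in (0,1)
    wvec <- as.vector(t(att_w))
    dbar <- rowsum(f3 * wvec, group = grp, reorder = FALSE)   # B x 32
    if (keep_cache) {
      cache$mlp <- mlp_cache; cache$f3 <- f3; cache$amax <- amax
      cache$p_avg <- p_avg; cache$p_max <- p_max
      cache$sa <- sa; cache$sm <- sm; cache$att_w <- att_w
    }
  }

  ## ---- local branch ----------------------------------------------------
  local_out <- NULL
  if (variant_spec$use_local) {
    x_proj <- sweep(u_mat %*% params$proj_W, 2L, params$proj_b, "+")
    step_rows <- lapply(seq_len(t_len), function(t) {
      (seq_len(b) - 1L) * t_len + t
    })
    seq_in <- lapply(step_rows, function(r) x_proj[r, , drop = FALSE])
    u_units <- config$gru_units
    gru_cache <- vector("list", config$gru_layers)
    for (l in seq_len(config$gru_layers)) {
      fwd <- gru_scan(seq_in, params, l, "f", u_units, reverse = FALSE)
      bwd <- gru_scan(seq_in, params, l, "b", u_units, reverse = TRUE)
      gru_cache[[l]] <- list(fwd = fwd, bwd = bwd, seq_in = seq_in)
      seq_in <- lapply(seq_len(t_len), function(t) {
        cbind(fwd$h[[t]], bwd$h[[t]])
      })
    }
    local_out <- cbind(gru_cache[[config$gru_layers]]$fwd$h[[t_len]],
                       gru_cache[[config$gru_layers]]$bwd$h[[1L]])
    if (keep_cache) {
      cache$x_proj <- x_proj; cache$gru <- gru_cache
      cache$step_rows <- step_rows
    }
  }

  ## ---- head ------------------------------------------------------------
  zc <- cbind(dbar, local_out)
  n_head <- length(config$head_dims)
  head_cache <- vector("list", n_head)
  x <- zc
  for (l in seq_len(n_head)) {
    pre <- sweep(x %*% params[[paste0("head_W", l)]], 2L,
                 params[[paste0("head_b", l)]], "+")
    if (l < n_head) {
      act <- pmax(pre, 0)
      if (training && config$dropout > 0) {
        mask <- matrix(stats::rbinom(length(act), 1L, keep), nrow(act)) / keep
        out <- act * mask
      } else {
        mask <- NULL
        out <- act
      }
    } else {
      mask <- NULL
      out <- pre
    }
    head_cache[[l]] <- list(x_in = x, pre = pre, mask = mask)
    x <- out
  }
  logits <- x                                        # B x 2
  if (keep_cache) {
    cache$head <- head_cache; cache$zc <- zc
    cache$idx <- idx; cache$b <- b; cache$t_len <- t_len
    cache$a_t <- a_t
  }

  labels <- prep$labels[idx]
  lmax <- apply(logits, 1L, max)
  el <- exp(logits - lmax)
  probs <- el / rowSums(el)
  ce <- -mean(log(pmax(probs[cbind(seq_len(b), labels + 1L)], 1e-12)))

  diagnostics <- NULL
  if (keep_diagnostics) {
    diagnostics <- list(
      adjacency = lapply(seq_len(m_tot), function(k) {
        t(a_t[, ((k - 1L) * n + 1L):(k * n), drop = FALSE])
      }),
      connectivity = s_list,
      attention = att_w
    )
  }

  gcoef <- config$graph_coef %||% 1
  list(logits = logits, probs = probs, ce = ce, graph_loss = graph_loss,
       total = ce + gcoef * graph_loss, cache = if (keep_cache) cache,
       bn_state = new_bn, diagnostics = diagnostics)
}

# Scan one GRU direction over a sequence of B x d_in matrices.
gru_scan <- function(seq_in, params, layer, dir, units, reverse) {
  t_len <- length(seq_in)
  b <- nrow(seq_in[[1]])
  pfx <- sprintf("gru_l%d_%s_", layer, dir)
  wz <- params[[paste0(pfx, "Wz")]]; wr <- params[[paste0(pfx, "Wr")]]
  wh <- params[[paste0(pfx, "Wh")]]
  bz <- params[[paste0(pfx, "bz")]]; br <- params[[paste0(pfx, "br")]]
  bh <- params[[paste0(pfx, "bh")]]
  ord <- if (reverse) rev(seq_len(t_len)) else seq_len(t_len)
  h <- matrix(0, b, units)
  h_out <- vector("list", t_len)
  steps <- vector("list", t_len)
  for (t in ord) {
    x <- seq_in[[t]]
    cc <- cbind(h, x)
    z <- sigmoid(sweep(cc %*% wz, 2L, bz, "+"))
    r <- sigmoid(sweep(cc %*% wr, 2L, br, "+"))
    ch <- cbind(r * h, x)
    htld <- tanh(sweep(ch %*% wh, 2L, bh, "+"))
    h_new <- (1 - z) * h + z * htld
    steps[[t]] <- list(h_prev = h, z = z, r = r, htld = htld)
    h <- h_new
    h_out[[t]] <- h_new
  }
  list(h = h_out, steps = steps, ord = ord)
}

# Backward through one GRU direction. d_ext: list of B x units grads on the
# per-step outputs (original t order); returns dX list and parameter grads.
gru_scan_backward <- function(scan, seq_in, params, layer, dir, units,
                              d_ext) {
  t_len <- length(seq_in)
  b <- nrow(seq_in[[1]])
  pfx <- sprintf("gru_l%d_%s_", layer, dir)
  wz <- params[[paste0(pfx, "Wz")]]; wr <- params[[paste0(pfx, "Wr")]]
  wh <- params[[paste0(pfx, "Wh")]]
  g <- list()
  for (nm in c("Wz", "Wr", "Wh")) {
    g[[nm]] <- matrix(0, nrow(params[[paste0(pfx, nm)]]), units)
  }
  for (nm in c("bz", "br", "bh")) g[[nm]] <- rep(0, units)
  d_x <- lapply(seq_len(t_len), function(t) {
    matrix(0, b, ncol(seq_in[[1]]))
  })
  dh_carry <- matrix(0, b, units)
  for (t in rev(scan$ord)) {
    st <- scan$steps[[t]]
    dh <- d_ext[[t]] + dh_carry
    dz <- dh * (st$htld - st$h_prev)
    dhtld <- dh * st$z
    dh_prev <- dh * (1 - st$z)
    da_h <- dhtld * (1 - st$htld^2)
    ch <- cbind(st$r * st$h_prev, seq_in[[t]])
    g$Wh <- g$Wh + crossprod(ch, da_h)
    g$bh <- g$bh + colSums(da_h)
    dch <- da_h %*% t(wh)
    drh <- dch[, seq_len(units), drop = FALSE]
    d_x[[t]] <- d_x[[t]] + dch[, -seq_len(units), drop = FALSE]
    dr <- drh * st$h_prev
    dh_prev <- dh_prev + drh * st$r
    cc <- cbind(st$h_prev, seq_in[[t]])
    da_z <- dz * st$z * (1 - st$z)
    g$Wz <- g$Wz + crossprod(cc, da_z)
    g$bz <- g$bz + colSums(da_z)
    dcc <- da_z %*% t(wz)
    da_r <- dr * st$r * (1 - st$r)
    g$Wr <- g$Wr + crossprod(cc, da_r)
    g$br <- g$br + colSums(da_r)
    dcc <- dcc + da_r %*% t(wr)
    dh_prev <- dh_prev + dcc[, seq_len(units), drop = FALSE]
    d_x[[t]] <- d_x[[t]] + dcc[, -seq_len(units), drop = FALSE]
    dh_carry <- dh_prev
  }
  names(g) <- paste0(pfx, names(g))
  list(d_x = d_x, grads = g)
}

# Full backward pass; fw must come from nn_forward(keep_cache = TRUE,
# training = TRUE). Returns gradient list matching params names.
nn_backward <- function(params, config, variant_spec, prep, fw) {
  cache <- fw$cache
  b <- cache$b
  t_len <- cache$t_len
  n <- config$n_rois
  m_tot <- b * t_len
  uidx <- upper_index(n)
  labels <- prep$labels[cache$idx]
  grads <- list()
  add_grad <- function(nm, val) {
    grads[[nm]] <<- if (is.null(grads[[nm]])) val else grads[[nm]] + val
  }

  ## head
  onehot <- matrix(0, b, 2L)
  onehot[cbind(seq_len(b), labels + 1L)] <- 1
  dx <- (fw$probs - onehot) / b
  n_head <- length(config$head_dims)
  for (l in rev(seq_len(n_head))) {
    hc <- cache$head[[l]]
    if (l < n_head) {
      if (!is.null(hc$mask)) dx <- dx * hc$mask
      dx <- dx * (hc$pre > 0)
    }
    add_grad(paste0("head_W", l), crossprod(hc$x_in, dx))
    add_grad(paste0("head_b", l), colSums(dx))
    dx <- dx %*% t(params[[paste0("head_W", l)]])
  }
  d_zc <- dx
  d32 <- if (variant_spec$use_global) {
    config$mlp_dims[length(config$mlp_dims)]
  } else 0L
  d_u_mat <- matrix(0, m_tot, n * (n - 1L) / 2L)
  grp_k <- rep(seq_len(b), each = t_len)

  ## global branch backward
  if (variant_spec$use_global) {
    d_dbar <- d_zc[, seq_len(d32), drop = FALSE]
    f3 <- cache$f3
    att_w <- cache$att_w
    wvec <- as.vector(t(att_w))
    d_f3 <- d_dbar[grp_k, , drop = FALSE] * wvec
    d_w <- matrix(rowSums(d_dbar[grp_k, , drop = FALSE] * f3),
                  b, t_len, byrow = TRUE)
    dq <- d_w * att_w * (1 - att_w)
    att_back <- function(shared, d_in) {
      add_grad("att_V2", crossprod(shared$mid, dq))
      add_grad("att_c2", colSums(dq))
      d_mid <- (dq %*% t(params$att_V2)) * (shared$mid_pre > 0)
      add_grad("att_V1", crossprod(d_in, d_mid))
      add_grad("att_c1", colSums(d_mid))
      d_mid %*% t(params$att_V1)
    }
    d_pavg <- att_back(cache$sa, cache$p_avg)
    d_pmax <- att_back(cache$sm, cache$p_max)
    nd <- ncol(f3)
    d_f3 <- d_f3 + as.vector(t(d_pavg))[row(f3)] / nd  # avg-pool back
    d_pmax_vec <- as.vector(t(d_pmax))
    d_f3[cbind(seq_len(m_tot), cache$amax)] <-
      d_f3[cbind(seq_len(m_tot), cache$amax)] + d_pmax_vec
    dx <- d_f3
    for (l in rev(seq_along(config$mlp_dims))) {
      mc <- cache$mlp[[l]]
      if (!is.null(mc$mask)) dx <- dx * mc$mask
      dx <- dx * (mc$pre > 0)
      add_grad(paste0("mlp_W", l), crossprod(mc$x_in, dx))
      add_grad(paste0("mlp_b", l), colSums(dx))
      dx <- dx %*% t(params[[paste0("mlp_W", l)]])
    }
    d_u_mat <- d_u_mat + dx
  }

  ## local branch backward
  if (variant_spec$use_local) {
    u_units <- config$gru_units
    d_local <- d_zc[, (d32 + 1L):(d32 + 2L * u_units), drop = FALSE]
    zero <- matrix(0, b, u_units)
    d_ext_f <- lapply(seq_len(t_len), function(t) zero)
    d_ext_b <- lapply(seq_len(t_len), function(t) zero)
    d_ext_f[[t_len]] <- d_local[, seq_len(u_units), drop = FALSE]
    d_ext_b[[1L]] <- d_local[, u_units + seq_len(u_units), drop = FALSE]
    for (l in rev(seq_len(config$gru_layers))) {
      gc_l <- cache$gru[[l]]
      bf <- gru_scan_backward(gc_l$fwd, gc_l$seq_in, params, l, "f",
                              u_units, d_ext_f)
      bb <- gru_scan_backward(gc_l$bwd, gc_l$seq_in, params, l, "b",
                              u_units, d_ext_b)
      for (nm in names(bf$grads)) add_grad(nm, bf$grads[[nm]])
      for (nm in names(bb$grads)) add_grad(nm, bb$grads[[nm]])
      if (l > 1L) {
        d_ext_f <- lapply(seq_len(t_len), function(t) {
          bf$d_x[[t]][, seq_len(u_units), drop = FALSE] +
            bb$d_x[[t]][, seq_len(u_units), drop = FALSE]
        })
        d_ext_b <- lapply(seq_len(t_len), function(t) {
          bf$d_x[[t]][, u_units + seq_len(u_units), drop = FALSE] +
            bb$d_x[[t]][, u_units + seq_len(u_units), drop = FALSE]
        })
      } else {
        d_xproj <- matrix(0, m_tot, config$gru_input_dim)
        for (t in seq_len(t_len)) {
          d_xproj[cache$step_rows[[t]], ] <- bf$d_x[[t]] + bb$d_x[[t]]
        }
        add_grad("proj_W", crossprod(cache$u_mat, d_xproj))
        add_grad("proj_b", colSums(d_xproj))
        d_u_mat <- d_u_mat + d_xproj %*% t(params$proj_W)
      }
    }
  }

  ## feature extractor backward (d_a_t in the transposed N x M*N layout)
  d_a_t <- NULL
  if (variant_spec$use_gcn) {
    d_a_t <- matrix(0, n, m_tot * n)
    d_h3 <- matrix(0, m_tot * n, ncol(cache$h3_blocks[[1]]))
    for (k in seq_len(m_tot)) {
      r <- ((k - 1L) * n + 1L):(k * n)
      ds <- matrix(0, n, n)
      ds[uidx] <- d_u_mat[k, ]
      d_h3[r, ] <- (ds + t(ds)) %*% cache$h3_blocks[[k]]
    }
    dx <- d_h3
    for (l in rev(seq_along(config$gcn_dims))) {
      gc_l <- cache$gcn[[l]]
      if (!is.null(gc_l$mask)) dx <- dx * gc_l$mask
      dx <- dx * (gc_l$y > 0)
      if (config$use_batch_norm) {
        gma <- params[[paste0("gcn_gamma", l)]]
        add_grad(paste0("gcn_gamma", l), colSums(dx * gc_l$xhat))
        add_grad(paste0("gcn_beta", l), colSums(dx))
        dxhat <- sweep(dx, 2L, gma, "*")
        inv_sd <- 1 / sqrt(gc_l$v + bn_eps)
        mh <- colMeans(dxhat)
        mhx <- colMeans(dxhat * gc_l$xhat)
        dz <- sweep(dxhat, 2L, mh) - sweep(gc_l$xhat, 2L, mhx, "*")
        dz <- sweep(dz, 2L, inv_sd, "*")
      } else {
        dz <- dx
      }
      a_t <- cache$a_t
      dp <- matrix(0, nrow(dz), ncol(dz))
      for (k in seq_len(m_tot)) {
        r <- ((k - 1L) * n + 1L):(k * n)
        dzb <- dz[r, , drop = FALSE]
        plb <- gc_l$p_lin[r, , drop = FALSE]
        # dA_k = dZ_k P_k'; transposed layout stores t(dA_k) = P_k dZ_k'
        d_a_t[, r] <- d_a_t[, r] + tcrossprod(plb, dzb)
        dp[r, ] <- a_t[, r, drop = FALSE] %*% dzb
      }
      add_grad(paste0("gcn_W", l), crossprod(gc_l$h_in, dp))
      dx <- dp %*% t(params[[paste0("gcn_W", l)]])
    }
  } else if (variant_spec$adjacency == "adaptive") {
    d_a_t <- matrix(0, n, m_tot * n)
    for (k in seq_len(m_tot)) {
      r <- ((k - 1L) * n + 1L):(k * n)
      ds <- matrix(0, n, n)
      ds[uidx] <- d_u_mat[k, ]
      d_a_t[, r] <- (ds + t(ds)) / 2   # symmetric, so layout-invariant
    }
  }

  ## adjacency backward -> omega
  if (variant_spec$adjacency == "adaptive") {
    a_t <- cache$a_t
    avec <- as.vector(a_t)
    # graph-loss contribution, already in the n-fastest layout
    gcoef <- config$graph_coef %||% 1
    d_avec_gl <- gcoef * (cache$d2all + 2 * config$lambda_reg * avec) / b
    d_a_total <- matrix(d_avec_gl, nrow = n)
    if (!is.null(d_a_t)) d_a_total <- d_a_total + d_a_t
    # softmax rows of A = columns here: dscore = a * (da - <da, a>_col)
    col_dot <- colSums(d_a_total * a_t)
    d_score_t <- a_t * (d_a_total - rep(col_dot, each = n))
    d_score <- as.vector(d_score_t) * cache$relu_mask
    add_grad("omega", drop(crossprod(cache$dall, d_score)))
  }

  grads
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
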