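test_that("forward contract: logit shape, non-negative graph loss, row-stochastic adjacencies", {
  cfg <- tiny_config()
  m <- astnet(cfg, n_windows = 3)
  coh <- generate_cohort(tiny_spec())
  fw <- astnet_forward(m, partition(coh$subjects[[1]], 8))
  expect_length(fw$class_logits, 2L)
  expect_gte(fw$graph_loss, 0)
  expect_length(fw$diagnostics$adjacency, 3L)
  for (a in fw$diagnostics$adjacency) {
    expect_lt(max(abs(rowSums(a) - 1)), 1e-6)
    expect_true(all(a > 0))
  }
  for (s in fw$diagnostics$connectivity) {
    expect_equal(s, t(s), tolerance = 1e-6)
  }
})

test_that("the same architecture code path accepts T = 3 and T = 12 window counts", {
  for (t_len in c(3L, 12L)) {
    cfg <- tiny_config()
    m <- astnet(cfg, n_windows = t_len)
    x <- roi_time_series(matrix(rnorm(5 * 8 * t_len), 5, 8 * t_len), "s", 0L)
    fw <- astnet_forward(m, partition(x, 8))
    expect_length(fw$class_logits, 2L)
    expect_length(fw$diagnostics$attention, t_len)
  }
})

test_that("without the local branch, duplicated windows make the forward permutation-invariant", {
  cfg <- tiny_config()
  m <- build_variant("ASTNet_L", cfg, n_windows = 3)
  seg <- matrix(rnorm(40), 5, 8)
  segs <- list(seg, seg, seg)
  f1 <- astnet_forward(m, segs)
  f2 <- astnet_forward(m, segs[c(2, 3, 1)])
  expect_equal(f1$class_logits, f2$class_logits, tolerance = 1e-12)
})

test_that("total_loss closed forms and oracle equivalence", {
  expect_equal(total_loss(c(50, -50), 0L, 0), 0, tolerance = 1e-12)
  expect_equal(total_loss(c(0, 0), 1L, 0), log(2))
  expect_equal(total_loss(c(0, 0), 0L, 1.5), log(2) + 1.5)
  expect_error(total_loss(c(0, 0), 2L, 0), "label")
  expect_error(total_loss(c(0, 0), 0L, -1), "non-negative")
  set.seed(19)
  for (i in 1:20) {
    z <- rnorm(2, sd = 3)
    lab <- sample(0:1, 1)
    seg <- matrix(rnorm(15), 3, 5)
    a <- adaptive_adjacency(seg, rnorm(5))
    gl <- o_graph_loss(seg, a, 0.2)
    p <- exp(z - max(z)); p <- p / sum(p)
    expect_equal(total_loss(z, lab, graph_learning_loss(seg, a, 0.2)),
                 -log(p[lab + 1]) + gl, tolerance = 1e-8)
  }
})

test_that("variants factory: parameter sets, static widths, unknown names", {
  cfg <- tiny_config()
  full <- astnet(cfg, n_windows = 3)
  no_global <- build_variant("ASTNet_G", cfg, n_windows = 3)
  dropped <- setdiff(names(full$params), names(no_global$params))
  expect_true(all(grepl("^(mlp_|att_)", dropped)))
  expect_length(setdiff(names(no_global$params), names(full$params)), 0L)
  no_local <- build_variant("ASTNet_L", cfg, n_windows = 3)
  expect_true(all(grepl("^(gru_|proj_)",
                        setdiff(names(full$params), names(no_local$params)))))
  # MLP_s on a 116-ROI static FC: first layer input width N(N-1)/2 = 6670
  cfg116 <- astnet_config(n_rois = 116, seed = 2)
  mlp_s <- build_variant("MLP_s", cfg116, n_timepoints = 231)
  expect_identical(nrow(mlp_s$params$mlp_W1), 6670L)
  expect_identical(mlp_s$config$window_length, 231L)
  expect_error(build_variant("bogus", cfg, n_windows = 3), "ASTNet_G")
})

test_that("analytic gradients match finite differences for representative variants", {
  expect_lt(check_gradients("ASTNet", seed = 1), 2e-3)
  expect_lt(check_gradients("AGL_d", seed = 2), 2e-3)
  expect_lt(check_gradients("BiGRU", seed = 3), 2e-3)
  expect_lt(check_gradients("MLP_s", seed = 4), 2e-3)
})

test_that("omega receives gradient and moves after one optimizer step", {
  cfg <- tiny_config()
  m <- astnet(cfg, n_windows = 3)
  coh <- generate_cohort(tiny_spec())
  before <- m$params$omega
  fit <- astnet_train(m, coh, epochs = 1)
  expect_false(isTRUE(all.equal(before, fit$model$params$omega)))
})

test_that("evaluation-mode forward is deterministic", {
  cfg <- tiny_config()
  m <- astnet(cfg, n_windows = 3)
  coh <- generate_cohort(tiny_spec())
  segs <- partition(coh$subjects[[2]], 8)
  f1 <- astnet_forward(m, segs)
  f2 <- astnet_forward(m, segs)
  expect_identical(f1$class_logits, f2$class_logits)
})

test_that("training loss decreases over the first 20 epochs on a separable cohort", {
  spec <- cohort_spec(n_subjects_per_group = 10, n_rois = 8,
                      n_timepoints = 60, window_length = 20, n_states = 1,
                      community_partition = rep(1:2, each = 4),
                      effect_edges = cbind(1:4, 5:8), effect_size = 0.6,
                      affected_states = 1, seed = 41)
  coh <- generate_cohort(spec)
  cfg <- astnet_config(window_length = 20, n_rois = 8,
                       mlp_dims = c(64, 32, 16), head_dims = c(16, 8, 2),
                       batch_size = 5, seed = 6)
  m <- build_variant("MLP_d", cfg, n_windows = 3)
  fit <- astnet_train(m, coh, epochs = 20)
  h <- fit$history
  expect_lt(mean(tail(h$total_loss, 3)), mean(head(h$total_loss, 3)))
})

test_that("batched engine equals the composition of the public primitives", {
  set.seed(3)
  spec <- cohort_spec(n_subjects_per_group = 2, n_rois = 6,
                      n_timepoints = 30, window_length = 10, n_states = 1,
                      community_partition = rep(1:2, each = 3),
                      effect_edges = rbind(c(1, 4)), seed = 21)
  coh <- generate_cohort(spec)
  cfg <- astnet_config(window_length = 10, n_rois = 6, gcn_dims = c(5, 4, 3),
                       mlp_dims = c(9, 6, 4), gru_units = 2, gru_layers = 2,
                       gru_input_dim = 5, head_dims = c(6, 4, 2),
                       dropout = 0, use_batch_norm = FALSE, seed = 13)
  m <- astnet(cfg, n_windows = 3)
  segs <- partition(coh$subjects[[1]], 10)
  fw <- astnet_forward(m, segs)
  p <- m$params
  u_list <- lapply(segs$segments, function(g) {
    a <- adaptive_adjacency(g, p$omega)
    h <- gcn_forward(g, a, list(p$gcn_W1, p$gcn_W2, p$gcn_W3), "relu")
    vectorize_upper(connectivity_matrix(h))
  })
  u <- do.call(rbind, u_list)
  mlpw <- lapply(1:3, function(l) {
    list(W = p[[paste0("mlp_W", l)]], b = p[[paste0("mlp_b", l)]])
  })
  f3 <- t(apply(u, 1, window_embed, weights = mlpw))
  att <- global_attention(f3, list(V1 = p$att_V1, c1 = p$att_c1,
                                   V2 = p$att_V2, c2 = p$att_c2))
  gp <- function(l, d) {
    list(W_z = p[[sprintf("gru_l%d_%s_Wz", l, d)]],
         W_r = p[[sprintf("gru_l%d_%s_Wr", l, d)]],
         W_h = p[[sprintf("gru_l%d_%s_Wh", l, d)]],
         b_z = p[[sprintf("gru_l%d_%s_bz", l, d)]],
         b_r = p[[sprintf("gru_l%d_%s_br", l, d)]],
         b_h = p[[sprintf("gru_l%d_%s_bh", l, d)]])
  }
  xseq <- lapply(1:3, function(t) drop(u[t, ] %*% p$proj_W) + p$proj_b)
  loc <- bigru_encode(xseq, list(gp(1, "f"), gp(2, "f")),
                      list(gp(1, "b"), gp(2, "b")), num_layers = 2)
  z <- c(att$global_feature, loc)
  for (l in 1:3) {
    z <- drop(z %*% p[[paste0("head_W", l)]]) + p[[paste0("head_b", l)]]
    if (l < 3) z <- pmax(z, 0)
  }
  expect_equal(fw$class_logits, z, tolerance = 1e-10)
  expect_equal(as.vector(fw$diagnostics$attention), att$weights,
               tolerance = 1e-10)
  gl <- sum(vapply(segs$segments, function(g) {
    graph_learning_loss(g, adaptive_adjacency(g, p$omega), cfg$lambda_reg)
  }, numeric(1)))
  expect_equal(fw$graph_loss, gl, tolerance = 1e-10)
})

test_that("model checkpoints save and load with a JSON sidecar", {
  cfg <- tiny_config()
  m <- build_variant("MLP_d", cfg, n_windows = 3)
  coh <- generate_cohort(tiny_spec())
  fit <- astnet_train(m, coh, epochs = 2)
  path <- withr::local_tempfile(fileext = ".rds")
  astnet_save(fit, path)
  back <- astnet_load(path)
  expect_equal(back$model$params, fit$model$params)
  side <- readLines(paste0(path, ".json"))
  expect_match(side, '"variant": "MLP_d"')
})
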