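test_that("omega = 0 and identical node features give the exact uniform adjacency", {
  seg <- matrix(rnorm(8), 4, 2)
  expect_equal(adaptive_adjacency(seg, c(0, 0)),
               matrix(0.25, 4, 4), tolerance = 0)
  same <- matrix(rep(rnorm(3), each = 5), 5, 3)  # all rows identical
  expect_equal(adaptive_adjacency(same, rnorm(3)),
               matrix(0.2, 5, 5), tolerance = 1e-15)
})

test_that("the 3-node instance matches the scalar oracle values", {
  seg <- rbind(c(1, 0), c(0, 0), c(2, 2))
  a <- adaptive_adjacency(seg, c(1, 1))
  frozen <- rbind(
    c(0.0420100661340660, 0.1141951993845945, 0.8437947344813395),
    c(0.0466126225779739, 0.0171478255455204, 0.9362395518765056),
    c(0.2653879287722419, 0.7213991842739685, 0.0132128869537894))
  expect_equal(a, frozen, tolerance = 1e-8)
  expect_equal(a, o_adjacency(seg, c(1, 1)), tolerance = 1e-12)
  expect_equal(graph_learning_loss(seg, a, 0.5), 20.0662451986097,
               tolerance = 1e-8)
})

test_that("adjacency is row-stochastic, positive, and matches the oracle on random inputs", {
  set.seed(7)
  for (i in 1:100) {
    n <- sample(3:8, 1)
    L <- sample(2:10, 1)
    seg <- matrix(rnorm(n * L, sd = runif(1, 0.5, 3)), n, L)
    omega <- rnorm(L)
    a <- adaptive_adjacency(seg, omega)
    expect_true(all(a > 0))
    expect_lt(max(abs(rowSums(a) - 1)), 1e-6)
    expect_equal(a, o_adjacency(seg, omega), tolerance = 1e-8)
  }
})

test_that("omega / segment dimension mismatch errors", {
  expect_error(adaptive_adjacency(matrix(rnorm(6), 3, 2), c(1, 1, 1)),
               "length")
})

test_that("graph-learning loss trivial cases and oracle equivalence", {
  same <- matrix(rep(rnorm(4), each = 4), 4, 4)
  a_any <- adaptive_adjacency(same, rnorm(4))
  expect_equal(graph_learning_loss(same, a_any, 0), 0)
  # identical features, lambda = 1, uniform A: ||A||_F^2 = N^2 / N^2 = 1
  expect_equal(graph_learning_loss(same, matrix(0.25, 4, 4), 1), 1)
  expect_error(graph_learning_loss(same, a_any, -0.1), "non-negative")
  set.seed(8)
  for (i in 1:100) {
    n <- sample(3:7, 1)
    seg <- matrix(rnorm(n * 5), n, 5)
    a <- adaptive_adjacency(seg, rnorm(5))
    lam <- runif(1, 0, 2)
    expect_equal(graph_learning_loss(seg, a, lam),
                 o_graph_loss(seg, a, lam), tolerance = 1e-8)
  }
})

test_that("scaling all pairwise distances up strictly increases the smoothness term", {
  set.seed(9)
  seg <- matrix(rnorm(5 * 6), 5, 6)
  a <- adaptive_adjacency(seg, rnorm(6))
  l1 <- graph_learning_loss(seg, a, 0)
  l2 <- graph_learning_loss(2 * seg, a, 0)  # distances x2, d^2 x4, A fixed
  expect_gt(l2, l1)
  expect_equal(l2, 4 * l1, tolerance = 1e-10)
})

test_that("finite-difference gradient of the joint omega chain matches the analytic form", {
  # d/d omega of [graph_learning_loss(seg, A(omega), lambda)]: softmax +
  # ReLU chain rule, written out independently of the training engine
  set.seed(10)
  seg <- matrix(rnorm(4 * 5), 4, 5)
  omega <- rnorm(5, mean = 0.3)
  lam <- 0.01
  n <- nrow(seg)
  a <- adaptive_adjacency(seg, omega)
  d2 <- as.matrix(dist(seg))^2
  d_a <- d2 + 2 * lam * a
  row_dot <- rowSums(d_a * a)
  d_score <- a * (d_a - row_dot)
  an <- numeric(5)
  for (m in 1:n) for (nn in 1:n) {
    s <- sum(omega * abs(seg[m, ] - seg[nn, ]))
    if (s > 0) an <- an + d_score[m, nn] * abs(seg[m, ] - seg[nn, ])
  }
  fd <- numeric(5)
  for (f in 1:5) {
    op <- omega; op[f] <- op[f] + 1e-6
    om <- omega; om[f] <- om[f] - 1e-6
    fd[f] <- (graph_learning_loss(seg, adaptive_adjacency(seg, op), lam) -
                graph_learning_loss(seg, adaptive_adjacency(seg, om), lam)) /
      2e-6
  }
  expect_equal(an, fd, tolerance = 1e-4)
})

test_that("gcn_forward fixed points and averaging behaviour", {
  x <- matrix(rnorm(12), 4, 3)
  # A = I, W = I, identity activation: output equals input
  expect_equal(gcn_forward(x, diag(4), list(diag(3)), "identity"), x)
  # uniform A: every row becomes the column-mean row
  out <- gcn_forward(x, matrix(0.25, 4, 4), list(diag(3)), "identity")
  expect_equal(out, matrix(colMeans(x), 4, 3, byrow = TRUE),
               tolerance = 1e-12)
})

test_that("gcn_forward matches the brute-force matmul oracle in eval mode", {
  set.seed(11)
  for (i in 1:20) {
    x <- matrix(rnorm(12), 4, 3)
    a <- adaptive_adjacency(x, rnorm(3))
    w <- matrix(rnorm(6), 3, 2)
    expect_equal(gcn_forward(x, a, list(w), "relu"),
                 pmax(o_matmul(o_matmul(a, x), w), 0), tolerance = 1e-6)
  }
  expect_error(gcn_forward(x, a, list(matrix(0, 5, 2))), "chain")
  expect_error(gcn_forward(x, diag(3), list(w)), "N x N")
})

test_that("connectivity matrix is H H', symmetric and PSD", {
  q <- qr.Q(qr(matrix(rnorm(25), 5, 5)))[, 1:3]  # orthonormal rows? cols
  h_ortho <- t(q)  # 3 x 5 with orthonormal rows
  expect_equal(connectivity_matrix(h_ortho), diag(3), tolerance = 1e-12)
  expect_equal(connectivity_matrix(matrix(0, 4, 2)), matrix(0, 4, 4))
  set.seed(12)
  for (i in 1:100) {
    h <- matrix(rnorm(15), 5, 3)
    s <- connectivity_matrix(h)
    oracle <- matrix(0, 5, 5)
    for (m in 1:5) for (nn in 1:5) oracle[m, nn] <- sum(h[m, ] * h[nn, ])
    expect_equal(s, oracle, tolerance = 1e-8)
    expect_equal(s, t(s))
    expect_gt(min(eigen(s, symmetric = TRUE, only.values = TRUE)$values),
              -1e-10)
  }
})

test_that("vectorize_upper follows row-major strict-upper order and round-trips", {
  s <- rbind(c(1, 2, 3), c(2, 4, 5), c(3, 5, 6))
  expect_equal(vectorize_upper(s), c(2, 3, 5))
  expect_length(vectorize_upper(diag(116)), 6670L)
  expect_length(vectorize_upper(matrix(1, 2, 2)), 1L)
  expect_error(vectorize_upper(matrix(0, 2, 3)), "square")
  set.seed(13)
  m <- connectivity_matrix(matrix(rnorm(24), 6, 4))
  v <- vectorize_upper(m)
  back <- matrix_from_upper(v, 6)
  off <- m; diag(off) <- 0
  expect_identical(back, off)
})
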