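make_featured_graph <- function(n, seed, scheme = "knn", k = 4) {
  ch <- gen_chain(n, seed = seed)
  attach_features(build_graph(ch$coords, scheme, k = k),
                  residue_onehot(ch$seq))
}

test_that("outputs are invariant to rotations, translations, reflections", {
  g <- make_featured_graph(18, seed = 1)
  cfg <- mpnn_config(layers = 2, hidden = 8, head = "regress", seed = 4)
  params <- plmgraph:::mpnn_init(cfg, ncol(g$node_feats))
  out0 <- mpnn_forward(g, cfg, params)
  set.seed(99)
  for (i in 1:10) {
    gt <- g
    gt$coords <- rigid_transform(g$coords, reflect = i %% 2 == 0)
    expect_equal(mpnn_forward(gt, cfg, params), out0, tolerance = 1e-5)
  }
})

test_that("permuting nodes permutes outputs identically", {
  g <- make_featured_graph(15, seed = 2)
  cfg <- mpnn_config(layers = 1, hidden = 8, head = "regress", seed = 7)
  params <- plmgraph:::mpnn_init(cfg, ncol(g$node_feats))
  out0 <- mpnn_forward(g, cfg, params)
  set.seed(5)
  for (i in 1:5) {
    p <- sample(nrow(g$coords))
    gp <- g
    gp$coords <- g$coords[p, ]
    gp$node_feats <- g$node_feats[p, ]
    inv <- order(p)
    gp$edges <- matrix(as.integer(inv[g$edges]), ncol = 2,
                       dimnames = dimnames(g$edges))
    outp <- mpnn_forward(gp, cfg, params)
    expect_equal(outp[inv[seq_len(nrow(out0))], , drop = FALSE], out0,
                 tolerance = 1e-10)
  }
})

test_that("a 1-layer network reproduces the hand-computed message sum", {
  # 3-node path, nodes at 0, 3, 7 on the x axis, scalar feature per node
  coords <- cbind(c(0, 3, 7), 0, 0)
  g <- build_graph(coords, "rball", cutoff = 5)   # edges 1<->2, 2<->3
  g <- attach_features(g, matrix(c(1, 2, 4), 3, 1))
  cfg <- mpnn_config(layers = 1, hidden = 1, aggregation = "mean",
                     head = "regress", head_skip = FALSE,
                     rbf_centers = 1, rbf_max = 10)
  params <- list(W_self1 = matrix(0.5, 1, 1),
                 W_msg1 = matrix(c(1, 2), 2, 1),   # weight on h_src, rbf
                 b1 = 0.1,
                 W_out = matrix(3, 1, 1), b_out = -0.2)
  out <- mpnn_forward(g, cfg, params)

  rbf <- function(d) exp(-d^2 / (2 * 10^2))
  # node 1: one in-edge from 2 (d=3); node 2: from 1 (d=3) and 3 (d=4);
  # node 3: one in-edge from 2 (d=4)
  m <- c(1 * 2 + 2 * rbf(3),
         (1 * 1 + 2 * rbf(3) + 1 * 4 + 2 * rbf(4)) / 2,
         1 * 2 + 2 * rbf(4))
  h1 <- pmax(0.5 * c(1, 2, 4) + m + 0.1, 0)
  expect_equal(as.numeric(out), 3 * h1 - 0.2, tolerance = 1e-12)
})

test_that("training reaches a learnable constant and is reproducible", {
  gs <- lapply(1:6, make_featured_graph, n = 12)
  labs <- lapply(gs, function(g) rep(2.5, nrow(g$coords)))
  cfg <- mpnn_config(head = "regress", hidden = 8, epochs = 60, seed = 3)
  fit <- mpnn(gs[1:4], labs[1:4], cfg, gs[5:6], labs[5:6])
  expect_lt(fit$report$eval_metric, 0.2)
  expect_equal(fit$report$metric_name, "rmse")
  fit2 <- mpnn(gs[1:4], labs[1:4], cfg, gs[5:6], labs[5:6])
  expect_identical(fit$params, fit2$params)
  expect_identical(fit$report, fit2$report)
})

test_that("a linear function of node features is recovered", {
  gs <- lapply(1:8, make_featured_graph, n = 15)
  w <- seq(-1, 1, length.out = 21)
  labs <- lapply(gs, function(g) as.numeric(g$node_feats %*% w) * 3 + 1)
  cfg <- mpnn_config(layers = 2, head = "regress", hidden = 16,
                     epochs = 150, seed = 6)
  fit <- mpnn(gs[1:6], labs[1:6], cfg, gs[7:8], labs[7:8])
  expect_lt(fit$report$eval_metric, 0.3)
})

test_that("classification masks classes beyond each chain's length", {
  gs <- lapply(1:4, make_featured_graph, n = 6)
  labs <- lapply(gs, function(g) seq_len(nrow(g$coords)))
  cfg <- mpnn_config(head = "classify", classes = 10, hidden = 8,
                     epochs = 5, seed = 1)
  fit <- mpnn(gs, labs, cfg)
  pred <- predict(fit, gs)
  expect_true(all(unlist(pred) <= 6))
})

test_that("divergent training fails loudly with the offending epoch", {
  gs <- lapply(1:2, make_featured_graph, n = 8)
  set.seed(2)
  labs <- lapply(gs, function(g) rnorm(nrow(g$coords)))
  cfg <- mpnn_config(head = "regress", hidden = 4, epochs = 10,
                     lr = 1e200, seed = 1)
  expect_error(mpnn(gs, labs, cfg), "diverged.*epoch")
})

test_that("shape mismatches between features and parameters are caught", {
  g <- make_featured_graph(8, seed = 1)
  cfg <- mpnn_config(head = "regress", hidden = 4, seed = 1)
  params <- plmgraph:::mpnn_init(cfg, 5)
  expect_error(mpnn_forward(g, cfg, params), "width")
})
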