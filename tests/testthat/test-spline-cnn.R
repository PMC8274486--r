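test_that("degree-1 spline basis matches the open uniform formula", {
  b <- spline_basis(0, 5)
  expect_equal(b$indices[1, 1], 0); expect_equal(b$weights[1, 1], 1)
  b <- spline_basis(1, 5)
  expect_equal(b$indices[1, 1], 4); expect_equal(b$weights[1, 1], 1)
  expect_equal(sum(b$weights[1, ]), 1)
  b <- spline_basis(0.1, 5)
  expect_equal(as.vector(b$indices), c(0, 1), ignore_attr = TRUE)
  expect_equal(as.vector(b$weights), c(0.6, 0.4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_warning(spline_basis(1.2, 5), "clipped")
})

test_that("spline convolution equals the brute-force dense oracle", {
  g <- random_graph(seed = 42)
  k <- 5
  gp <- prepare_graph(g, k)
  set.seed(7)
  ker <- list(W = matrix(rnorm(3 * 2 * k^3, sd = 0.3), 6, k^3),
              root = matrix(rnorm(6, sd = 0.3), 3, 2),
              bias = rnorm(2))
  out <- spline_conv(gp, g$node_features, ker)
  bf <- brute_spline_conv(g, g$node_features, ker, k)
  expect_lt(max(abs(out - bf)), 1e-6)
})

test_that("equal kernel matrices reduce to mean aggregation (partition of unity)", {
  for (seed in c(1, 2, 3)) {
    g <- random_graph(seed = seed)
    gp <- prepare_graph(g, 5)
    set.seed(seed + 100)
    Wm <- matrix(rnorm(6), 3, 2)
    ker <- list(W = matrix(rep(as.vector(Wm), 125), 6, 125),
                root = matrix(rnorm(6), 3, 2), bias = rnorm(2))
    out <- spline_conv(gp, g$node_features, ker)
    ref <- g$node_features %*% ker$root +
      matrix(ker$bias, g$n_nodes, 2, byrow = TRUE)
    for (v in seq_len(g$n_nodes)) {
      nb <- g$edges[g$edges[, 2] == v, 1]
      ref[v, ] <- ref[v, ] + colMeans(g$node_features[nb, , drop = FALSE] %*% Wm)
    }
    expect_equal(out, ref, tolerance = 1e-12)
  }
})

test_that("an isolated node sees only root weight and bias", {
  g <- random_graph()
  g$n_nodes <- 6L
  g$node_features <- rbind(g$node_features, c(1, -1, 2))
  gp <- prepare_graph(g, 5)
  ker <- list(W = matrix(rnorm(6 * 125), 6, 125),
              root = matrix(rnorm(6), 3, 2), bias = c(0.3, -0.2))
  out <- spline_conv(gp, g$node_features, ker)
  expect_equal(out[6, ], as.vector(g$node_features[6, ] %*% ker$root) +
                 ker$bias, tolerance = 1e-12)
})

test_that("canonical architecture reproduces the published parameter count", {
  m <- build_geometric_model(geo_config())
  expect_equal(count_parameters(m), 1686097)
})

test_that("analytic gradients match finite differences on a small graph", {
  g <- random_graph(seed = 12)
  g$node_features <- cbind(rnorm(5), matrix(rnorm(15), 5, 3))
  gp <- prepare_graph(g, 5)
  cfg <- geo_config(local_widths = c(4, 4), global_dim = 6, lift_widths = 6,
                    head_widths = 5, dropout = 0)
  model <- build_geometric_model(cfg, seed = 3)
  set.seed(20)
  target <- rnorm(5)
  fw <- ecapnet:::geo_forward(model, gp)
  ls <- ecapnet:::nn_loss(fw$pred, target, "l1")
  gr <- ecapnet:::geo_backward(model, gp, fw, ls$grad)
  lossfun <- function(params) {
    model$params <- params
    mean(abs(ecapnet:::geo_forward(model, gp)$pred - target))
  }
  eps <- 1e-6
  for (spec in list(c("conv", 1, "W"), c("conv", 2, "root"),
                    c("lift", 1, "W"), c("head", 1, "W"), c("head", 2, "b"))) {
    a <- spec[1]; b <- as.integer(spec[2]); c <- spec[3]
    p <- model$params
    for (idx in unique(pmin(c(1L, 3L), length(p[[a]][[b]][[c]])))) {
      base <- p[[a]][[b]][[c]][idx]
      pp <- p; pp[[a]][[b]][[c]][idx] <- base + eps
      pm <- p; pm[[a]][[b]][[c]][idx] <- base - eps
      num <- (lossfun(pp) - lossfun(pm)) / (2 * eps)
      expect_equal(gr[[a]][[b]][[c]][idx], num, tolerance = 1e-4)
    }
  }
})

test_that("predictions are equivariant under vertex relabeling and translation", {
  mesh <- sample_shape(seed = 4)
  cfg <- geo_config(local_widths = c(4, 4, 4), global_dim = 8,
                    lift_widths = 8, head_widths = 6, dropout = 0)
  model <- build_geometric_model(cfg, seed = 5)
  curv <- vertex_curvature(mesh, "mean")
  feats <- cbind(curv, vertex_normals(mesh))
  g <- mesh_to_graph(mesh, feats)
  pred <- predict_geometric(model, prepare_graph(g, 5))
  # translation invariance (all inputs are translation invariant)
  mesh2 <- mesh
  mesh2$vertices <- mesh$vertices +
    matrix(c(10, -5, 3), nrow(mesh$vertices), 3, byrow = TRUE)
  g2 <- mesh_to_graph(mesh2, feats)
  pred2 <- predict_geometric(model, prepare_graph(g2, 5))
  expect_equal(pred2, pred, tolerance = 1e-6)
  # relabeling equivariance
  V <- nrow(mesh$vertices)
  set.seed(6)
  perm <- sample.int(V)
  mesh3 <- mesh
  mesh3$vertices[perm, ] <- mesh$vertices
  mesh3$faces <- matrix(perm[mesh$faces], ncol = 3)
  mesh3$ostium_ring <- perm[mesh$ostium_ring]
  feats3 <- feats; feats3[perm, ] <- feats
  g3 <- mesh_to_graph(mesh3, feats3)
  pred3 <- predict_geometric(model, prepare_graph(g3, 5))
  expect_equal(pred3[perm], pred, tolerance = 1e-6)
})

test_that("vertex features are power-transformed, standardized unit-normal channels", {
  d <- cached_dataset(4, seed = 6)
  meshes <- lapply(d$cases, `[[`, "mesh")
  pf <- preprocess_vertex_features(meshes[1:3])
  expect_equal(ncol(pf$features[[1]]), 4)
  pool <- unlist(lapply(pf$features, function(f) f[, 1]))
  expect_lt(abs(mean(pool)), 1e-6)
  expect_lt(abs(sd(pool) - 1), 1e-2)
  nrm <- sqrt(rowSums(pf$features[[2]][, 2:4]^2))
  expect_equal(nrm, rep(1, length(nrm)), tolerance = 1e-9)
  # record reused verbatim on an unseen mesh
  f4 <- apply_vertex_features(meshes[[4]], pf$record)
  expect_equal(ncol(f4), 4)
  expect_false(isTRUE(all.equal(mean(f4[, 1]), 0, tolerance = 1e-8)))
})

test_that("the geometric surrogate memorizes two meshes and is seed-deterministic", {
  d <- cached_dataset(4, seed = 8)
  cfg <- geo_config(local_widths = c(8, 8), global_dim = 16, lift_widths = 16,
                    head_widths = 16, epochs = 60, lr = 0.01, dropout = 0)
  pf <- preprocess_vertex_features(lapply(d$cases[1:2], `[[`, "mesh"))
  cases <- Map(function(cs, f) {
    g <- cs$graph; g$node_features <- f
    list(graph = prepare_graph(g, 5), target = cs$ecap)
  }, d$cases[1:2], pf$features)
  m <- build_geometric_model(cfg, seed = 1)
  m1 <- train_geometric(m, cases, seed = 1)
  preds <- lapply(cases, function(cs) predict_geometric(m1, cs$graph))
  rng <- diff(range(unlist(lapply(d$cases[1:2], `[[`, "ecap"))))
  expect_lt(mae(preds, lapply(d$cases[1:2], `[[`, "ecap")) / rng, 0.05)
  m2 <- train_geometric(build_geometric_model(cfg, seed = 1), cases, seed = 1)
  expect_identical(m1$history, m2$history)
})
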