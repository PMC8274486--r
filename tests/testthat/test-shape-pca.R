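test_that("rank-1 shape family yields a single mode along the line", {
  set.seed(5)
  base <- rnorm(30); dir <- rnorm(30); dir <- dir / sqrt(sum(dir^2))
  X <- t(sapply(seq(-2, 2, length.out = 9), function(t) base + t * dir))
  sm <- suppressWarnings(fit_shape_model(X, M = 5))
  expect_equal(sm$M, 1)
  expect_gt(abs(sum(sm$components[1, ] * dir)), 1 - 1e-8)
})

test_that("eigenpairs match a dense covariance eigendecomposition oracle", {
  set.seed(6)
  X <- matrix(rnorm(5 * 36), 5, 36)
  sm <- fit_shape_model(X, M = 4)
  C <- stats::cov(X)
  ev <- eigen(C, symmetric = TRUE)
  expect_equal(sm$eigenvalues, ev$values[1:4], tolerance = 1e-9)
  for (i in 1:4)
    expect_gt(abs(sum(sm$components[i, ] * ev$vectors[, i])), 1 - 1e-8)
})

test_that("component count caps at n - 1 with a warning", {
  set.seed(7)
  X <- matrix(rnorm(10 * 60), 10, 60)
  expect_warning(sm <- fit_shape_model(X, M = 32), "capped")
  expect_equal(sm$M, 9)
})

test_that("projection and reconstruction satisfy the printed identities", {
  set.seed(8)
  X <- matrix(rnorm(8 * 30), 8, 30)
  sm <- fit_shape_model(X, M = 7)
  expect_equal(project_shape(sm$mean_shape, sm), rep(0, 7))
  y1 <- sm$mean_shape + sm$eigenvalues[1] * sm$components[1, ]
  a <- project_shape(y1, sm)
  expect_equal(a, c(1, rep(0, 6)), tolerance = 1e-9)
  expect_equal(reconstruct_shape(rep(0, 7), sm), sm$mean_shape)
  # training shapes are in-span at full rank: exact roundtrip
  for (i in c(1, 5)) {
    rec <- reconstruct_shape(project_shape(X[i, ], sm), sm)
    expect_equal(rec, X[i, ], tolerance = 1e-8, ignore_attr = TRUE)
  }
  # sqrt scaling is self-consistent too
  a2 <- project_shape(X[2, ], sm, scaling = "sqrt")
  expect_equal(reconstruct_shape(a2, sm, scaling = "sqrt"), X[2, ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("explained variance is non-decreasing and reaches 1 at full rank", {
  set.seed(9)
  X <- matrix(rnorm(6 * 24), 6, 24)
  sm <- fit_shape_model(X, M = 5)
  ev <- explained_variance(sm)
  expect_true(all(diff(ev) >= 0))
  expect_equal(ev[length(ev)], 1)
})

test_that("corresponded meshes are accepted and topology mismatches rejected", {
  d1 <- cached_dataset(4, seed = 2)
  meshes <- lapply(d1$cases, `[[`, "mesh")
  sm <- fit_shape_model(meshes, M = 3)
  expect_equal(sm$M, 3)
  expect_identical(sm$template_faces, meshes[[1]]$faces)
  rec <- reconstruct_shape(project_shape(meshes[[2]], sm), sm)
  expect_s3_class(rec, "surface_mesh")
  expect_equal(rec$vertices, meshes[[2]]$vertices, tolerance = 1e-6,
               ignore_attr = TRUE)
  bad <- meshes
  bad[[2]] <- icosphere(1)
  expect_error(fit_shape_model(bad, M = 2), "topology")
})

test_that("dense regressor parameter counts are architecture-determined", {
  expect_equal(count_parameters(build_fcn(fcn_config())), 7846178)
  expect_equal(count_parameters(build_fcn(fcn_config(1, c(1), 1))), 4)
  expect_equal(count_parameters(build_fcn(fcn_config(2, c(3), 1))), 13)
  expect_error(fcn_config(hidden = integer(0)), "non-empty")
})

test_that("the regressor memorizes two samples and trains deterministically", {
  cfg <- fcn_config(input_dim = 4, hidden = c(16, 32), output_dim = 20,
                    epochs = 150, lr = 0.01, loss = "l2", dropout = 0)
  set.seed(11)
  X <- matrix(rnorm(8), 2, 4)
  Y <- matrix(rnorm(40), 2, 20)
  m <- build_fcn(cfg, seed = 1)
  m1 <- train_fcn(m, X, Y, seed = 1)
  final_l1 <- mean(abs(predict_fcn(m1, X) - Y))
  expect_lt(final_l1, 1e-2)
  expect_lte(m1$history$train_loss[m1$best_epoch],
             m1$history$train_loss[1])
  m2 <- train_fcn(build_fcn(cfg, seed = 1), X, Y, seed = 1)
  expect_identical(m1$history, m2$history)
})

test_that("prediction output shapes follow the configuration", {
  cfg <- fcn_config(input_dim = 3, hidden = c(8), output_dim = 12,
                    dropout = 0, epochs = 2)
  m <- build_fcn(cfg, seed = 2)
  expect_length(predict_fcn(m, c(1, 2, 3)), 12)
  expect_equal(dim(predict_fcn(m, matrix(1, 5, 3))), c(5, 12))
  expect_error(predict_fcn(m, c(1, 2)), "coefficients")
  # zero weights: constant bias output
  m$layers <- lapply(m$layers, function(l) list(W = l$W * 0, b = l$b * 0 + 0.5))
  expect_equal(predict_fcn(m, c(0, 0, 0)), rep(0.5, 12))
})
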