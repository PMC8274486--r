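test_that("heat-method distance matches analytic values on disc and sphere", {
  dm <- disc_mesh()
  d <- geodesic_distance(dm, 1)
  expect_equal(d[1], 0)
  rr <- sqrt(rowSums(dm$vertices^2))
  sel <- rr > 0.1
  expect_lt(max(abs(d[sel] - rr[sel]) / rr[sel]), 0.02)

  sp <- icosphere(3)
  np <- which.max(sp$vertices[, 3])
  d <- geodesic_distance(sp, np)
  expect_equal(d[np], 0)
  anti <- which.min(sp$vertices[, 3])
  expect_lt(abs(d[anti] - pi) / pi, 0.05)
  eq <- which(abs(sp$vertices[, 3]) < 0.05)
  expect_lt(max(abs(d[eq] - pi / 2) / (pi / 2)), 0.05)
})

test_that("apex vertex is the distance argmax with low-index tie-breaking", {
  cm <- cylinder_mesh(10, 12)
  d <- geodesic_distance(cm, cm$ostium_ring)
  expect_equal(apex_vertex(d), nrow(cm$vertices))  # the cap vertex
  expect_equal(apex_vertex(c(1, 5, 5, 2)), 2L)
})

test_that("isolines on a cylinder are circles at the inset levels", {
  cm <- cylinder_mesh(40, 56, h = 1, r = 1)
  dz <- cm$vertices[, 3]
  iso <- extract_isolines(cm, dz, 2)
  expect_equal(attr(iso, "levels") / max(dz), c(0.25, 0.75), tolerance = 1e-12)
  for (L in iso) {
    p <- L$points
    len <- sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), ])^2)))
    if (L$level < 1) expect_lt(abs(len - 2 * pi) / (2 * pi), 0.01)
    # every point interpolates its level exactly
    expect_lt(max(abs(sqrt(p[, 1]^2 + p[, 2]^2) *
                        0 + p[, 3] - L$level)), 1e-9)
  }
  expect_error(extract_isolines(cm, dz, 1), "R must be")
})

test_that("angular parameterization anchors at the landmark and is rigid-invariant", {
  th <- 2 * pi * (0:35) / 36
  circle <- cbind(cos(th), sin(th), 0)
  par <- angular_parameterize(circle, c(1, 0, 0), c(0, 0, 1))
  expect_equal(par$theta[1], 0)
  q <- which.min(abs(th - pi / 2))
  expect_equal(par$theta[q], pi / 2, tolerance = 1e-9)
  expect_true(all(diff(par$theta[par$order]) > 0 |
                    abs(diff(par$theta[par$order]) + 2 * pi) < 1e-9))
  Rm <- rotation_matrix()
  par2 <- angular_parameterize(circle %*% t(Rm), as.vector(Rm %*% c(1, 0, 0)),
                               as.vector(Rm %*% c(0, 0, 1)))
  expect_equal(par2$theta, par$theta, tolerance = 1e-9)
  expect_error(angular_parameterize(circle[1:2, ], c(1, 0, 0), c(0, 0, 1)),
               "at least 3")
})

test_that("flat map samples the cylinder rows at the analytic radius", {
  cm <- cylinder_mesh(40, 56)
  dz <- cm$vertices[, 3]
  fl <- build_flat_map(cm, dz, 1L, R = 16, A = 32)
  expect_equal(dim(fl$channels), c(16, 32, 3))
  for (r in c(1, 8)) {   # rows below the cap
    rad <- sqrt(fl$channels[r, , 1]^2 + fl$channels[r, , 2]^2)
    expect_lt(max(abs(rad - 1)), 0.01)
  }
  bsum <- apply(fl$corr_bary, c(1, 2), sum)
  expect_lt(max(abs(bsum - 1)), 1e-12)
  expect_true(all(fl$corr_bary >= 0))
  expect_true(all(diff(fl$d_levels) > 0))
})

test_that("bull's-eye rasterization masks the unit disc and pads outside", {
  cm <- cylinder_mesh(20, 32)
  fl <- build_flat_map(cm, cm$vertices[, 3], 1L, R = 8, A = 16)
  be <- to_bullseye(fl, S = 128, pad_value = -7)
  expect_true(all(be$image[, , 1][!be$mask] == -7))
  expect_lt(abs(mean(be$mask) - pi / 4) / (pi / 4), 0.02)
  # constant grid stays constant inside the mask
  be2 <- to_bullseye(fl, S = 32, values = array(3.5, c(8, 16, 1)))
  expect_true(all(abs(be2$image[, , 1][be2$mask] - 3.5) < 1e-12))
  # mask is symmetric under 90-degree rotation
  rot90 <- t(be$mask)[, nrow(be$mask):1]
  expect_identical(rot90, be$mask, ignore_attr = TRUE)
})

test_that("unflatten transports grid fields back within tolerance", {
  cm <- cylinder_mesh(40, 56)
  dz <- cm$vertices[, 3]
  fl <- build_flat_map(cm, dz, 1L, R = 32, A = 48)
  const <- matrix(2.25, 32, 48)
  expect_equal(unflatten(cm, fl, const), rep(2.25, nrow(cm$vertices)),
               tolerance = 1e-12)
  gv <- sample_to_grid(fl, cm, dz)
  rec <- unflatten(cm, fl, gv)
  expect_lt(mean(abs(rec - dz)) / diff(range(dz)), 0.01)
})

test_that("transport error decreases with grid resolution", {
  mesh <- sample_shape(seed = 11)
  d <- geodesic_distance(mesh, mesh$ostium_ring)
  err <- sapply(c(32, 128), function(R) {
    fl <- build_flat_map(mesh, d, mesh$landmark, R = R, A = R)
    gv <- sample_to_grid(fl, mesh, d)
    mean(abs(unflatten(mesh, fl, gv) - d)) / max(d)
  })
  expect_lt(err[2], err[1])
  expect_lt(err[2], 0.02)
})

test_that("flattening is invariant under rigid motion of mesh and landmark", {
  mesh <- sample_shape(seed = 2)
  d <- geodesic_distance(mesh, mesh$ostium_ring)
  fl <- build_flat_map(mesh, d, mesh$landmark, R = 8, A = 12)
  Rm <- rotation_matrix(c(0, 1, 1), 1.1)
  mesh2 <- rigid_transform(mesh, Rm, c(-4, 2, 9))
  d2 <- geodesic_distance(mesh2, mesh2$ostium_ring)
  fl2 <- build_flat_map(mesh2, d2, mesh2$landmark, R = 8, A = 12)
  expect_equal(fl2$corr_face, fl$corr_face)
  expect_equal(fl2$corr_bary, fl$corr_bary, tolerance = 1e-6)
  expect_equal(to_bullseye(fl2, 32)$mask, to_bullseye(fl, 32)$mask)
})
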