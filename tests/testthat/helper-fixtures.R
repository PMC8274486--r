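# Programmatic mesh fixtures shared across the suite.

# icosphere by subdividing an icosahedron; all vertices on the sphere
icosphere <- function(subdiv = 3, radius = 1) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (s in seq_len(subdiv)) {
    nv <- v; key <- new.env()
    mid <- function(i, j) {
      k <- paste(min(i, j), max(i, j))
      if (!is.null(key[[k]])) return(key[[k]])
      p <- v[i, ] + v[j, ]; p <- p / sqrt(sum(p^2))
      nv <<- rbind(nv, p); key[[k]] <- nrow(nv); nrow(nv)
    }
    nf <- matrix(0L, 0, 3)
    for (t in seq_len(nrow(f))) {
      a <- f[t, 1]; b <- f[t, 2]; c <- f[t, 3]
      ab <- mid(a, b); bc <- mid(b, c); ca <- mid(c, a)
      nf <- rbind(nf, c(a, ab, ca), c(b, bc, ab), c(c, ca, bc), c(ab, bc, ca))
    }
    v <- nv; f <- nf
  }
  surface_mesh(v * radius, f)
}

# structured planar disc: center vertex + concentric rings, z = 0
disc_mesh <- function(nr = 18, nc = 56, radius = 1) {
  v <- matrix(0, 1, 3)
  for (r in seq_len(nr)) {
    rad <- radius * r / nr
    th <- 2 * pi * (seq_len(nc) - 1) / nc
    v <- rbind(v, cbind(rad * cos(th), rad * sin(th), 0))
  }
  j <- seq_len(nc); jn <- c(2:nc, 1)
  f <- cbind(1L, 1 + j, 1 + jn)
  for (r in 2:nr) {
    b0 <- 1 + (r - 2) * nc; b1 <- 1 + (r - 1) * nc
    f <- rbind(f, cbind(b0 + j, b1 + j, b0 + jn), cbind(b0 + jn, b1 + j, b1 + jn))
  }
  surface_mesh(v, f)
}

# open cylinder with a cone cap at the top; ostium ring at the bottom
cylinder_mesh <- function(nz = 30, nc = 48, h = 1, r = 1) {
  s <- rep(seq(0, 1, length.out = nz + 1), each = nc)
  th <- rep(2 * pi * (seq_len(nc) - 1) / nc, nz + 1)
  v <- cbind(r * cos(th), r * sin(th), s * h)
  f <- matrix(0L, 0, 3); j <- seq_len(nc); jn <- c(2:nc, 1)
  for (i in seq_len(nz)) {
    b0 <- (i - 1) * nc; b1 <- i * nc
    f <- rbind(f, cbind(b0 + j, b0 + jn, b1 + j), cbind(b0 + jn, b1 + jn, b1 + j))
  }
  v <- rbind(v, c(0, 0, h * 1.05))
  apex <- (nz + 1) * nc + 1
  top <- nz * nc
  f <- rbind(f, cbind(top + j, top + jn, apex))
  surface_mesh(v, f, ostium_ring = seq_len(nc), landmark = 1L)
}

# flat rectangular grid in the z = 0 plane, counter-clockwise from +z
planar_grid <- function(nx = 6, ny = 6) {
  v <- as.matrix(expand.grid(x = seq(0, 1, length.out = nx),
                             y = seq(0, 1, length.out = ny)))
  v <- cbind(v, 0)
  id <- function(i, j) (j - 1) * nx + i
  f <- matrix(0L, 0, 3)
  for (j in seq_len(ny - 1)) for (i in seq_len(nx - 1)) {
    f <- rbind(f, c(id(i, j), id(i + 1, j), id(i, j + 1)),
               c(id(i + 1, j), id(i + 1, j + 1), id(i, j + 1)))
  }
  surface_mesh(v, f)
}

rotation_matrix <- function(axis = c(1, 2, 1), angle = 0.7) {
  a <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3,
              byrow = TRUE)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * K %*% K
}

rigid_transform <- function(mesh, Rm = rotation_matrix(), tr = c(3, -2, 5)) {
  m2 <- mesh
  m2$vertices <- mesh$vertices %*% t(Rm) +
    matrix(tr, nrow(mesh$vertices), 3, byrow = TRUE)
  m2
}

# constant-step WSS series helper: phases as rows of a K x 3 matrix, one vertex
step_series <- function(vals, period = 1, V = 1) {
  K <- nrow(vals)
  times <- (seq_len(K) - 1) / K * period
  arr <- array(0, c(K, V, 3))
  for (k in seq_len(K)) arr[k, , ] <- matrix(vals[k, ], V, 3, byrow = TRUE)
  wss_series(times, arr, period)
}

# small random 5-node graph with pseudo-coordinates, for spline-conv oracles
random_graph <- function(seed = 42, V = 5, feat_ch = 3) {
  set.seed(seed)
  und <- rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 5), c(1, 5), c(2, 4))
  edges <- rbind(und, und[, 2:1])
  pseudo <- matrix(stats::runif(nrow(edges) * 3), ncol = 3)
  structure(list(n_nodes = V, edges = edges, pseudo_coords = pseudo,
                 node_features = matrix(stats::rnorm(V * feat_ch), V, feat_ch)),
            class = "mesh_graph")
}

# dense brute-force spline convolution over all k^3 basis products
brute_spline_conv <- function(graph, features, kernel, k) {
  basis1d <- function(u, k) {
    p <- u * (k - 1); i0 <- min(floor(p), k - 1); fr <- p - i0
    b <- numeric(k); b[i0 + 1] <- 1 - fr
    if (i0 + 2 <= k) b[i0 + 2] <- b[i0 + 2] + fr
    if (i0 + 1 == k) b[k] <- 1
    b
  }
  F <- features
  V <- graph$n_nodes
  in_ch <- ncol(F); out_ch <- ncol(kernel$root)
  out <- F %*% kernel$root + matrix(kernel$bias, V, out_ch, byrow = TRUE)
  deg <- tabulate(graph$edges[, 2], V)
  for (e in seq_len(nrow(graph$edges))) {
    i <- graph$edges[e, 1]; j <- graph$edges[e, 2]
    b1 <- basis1d(graph$pseudo_coords[e, 1], k)
    b2 <- basis1d(graph$pseudo_coords[e, 2], k)
    b3 <- basis1d(graph$pseudo_coords[e, 3], k)
    for (p3 in 1:k) for (p2 in 1:k) for (p1 in 1:k) {
      w <- b1[p1] * b2[p2] * b3[p3]
      if (w == 0) next
      pidx <- (p1 - 1) + k * (p2 - 1) + k * k * (p3 - 1) + 1
      Wp <- matrix(kernel$W[, pidx], in_ch, out_ch)
      out[j, ] <- out[j, ] + w / deg[j] * (F[i, ] %*% Wp)
    }
  }
  out
}

# small deterministic synthetic dataset cached across tests in one session
cached_dataset <- local({
  store <- new.env()
  function(n, seed = 1, cohort = "synthetic-like") {
    key <- paste(n, seed, cohort, sep = "_")
    if (is.null(store[[key]]))
      store[[key]] <- make_dataset(n, seed = seed, cohort = cohort)
    store[[key]]
  }
})
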