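# Heat-method geodesic distance on triangle meshes: integrate heat for a
# short time t from the source set, normalize the gradient field, and solve
# a Poisson problem for the distance potential.

#' Heat-method geodesic distance
#'
#' Solves (M + t S) u = delta_source with t = (mean edge length)^2, forms the
#' per-face unit vector field X = -grad(u)/|grad(u)|, and solves the Poisson
#' problem S phi = div(X), shifting so the minimum over the source set is 0.
#' On meshes with an open boundary the short-time heat solve averages the
#' Neumann and Dirichlet solutions, the standard stabilization for boundary
#' sources.
#'
#' @param mesh a \code{surface_mesh}.
#' @param source integer vector of source vertex indices (non-empty).
#' @param t_multiplier multiple of the squared mean edge length used as
#'   diffusion time (default 1).
#' @return numeric vector of per-vertex geodesic distances (>= 0, exactly 0
#'   on the source set).
#' @export
geodesic_distance <- function(mesh, source, t_multiplier = 1) {
  source <- as.integer(source)
  if (!length(source)) stop("source set is empty")
  V <- nrow(mesh$vertices)
  if (any(source < 1L) || any(source > V)) stop("source indices out of range")
  ops <- build_operators(mesh)
  S <- ops$stiffness
  M <- Matrix::Diagonal(x = ops$mass)
  he <- half_edges(mesh)
  elen <- sqrt(rowSums((mesh$vertices[he[, 1], , drop = FALSE] -
                        mesh$vertices[he[, 2], , drop = FALSE])^2))
  t <- t_multiplier * mean(elen)^2
  delta <- numeric(V); delta[source] <- 1
  A <- M + t * S
  u <- as.vector(Matrix::solve(A, delta))
  bnd <- boundary_vertices(mesh)
  if (length(bnd) && length(setdiff(bnd, source))) {
    # Dirichlet u = 0 on non-source boundary, then average with Neumann
    fixed <- setdiff(bnd, source)
    free <- setdiff(seq_len(V), fixed)
    ud <- numeric(V)
    ud[free] <- as.vector(Matrix::solve(A[free, free], delta[free]))
    u <- 0.5 * (u + ud)
  }
  if (!all(is.finite(u))) stop("heat solve failed (non-finite solution)")
  # per-face gradient of u, normalized
  f <- mesh$faces; v <- mesh$vertices
  n <- face_cross(mesh)           # 2*area*normal
  a2 <- sqrt(rowSums(n^2))        # 2*area
  nn <- n / a2
  gr <- matrix(0, nrow(f), 3)
  for (c in 1:3) {
    i <- f[, c]; j <- f[, (c %% 3) + 1]; k <- f[, ((c + 1) %% 3) + 1]
    # grad u = sum_i u_i (N x e_i) / (2A), e_i the edge opposite corner i
    e <- v[k, , drop = FALSE] - v[j, , drop = FALSE]
    cr <- cbind(nn[, 2] * e[, 3] - nn[, 3] * e[, 2],
                nn[, 3] * e[, 1] - nn[, 1] * e[, 3],
                nn[, 1] * e[, 2] - nn[, 2] * e[, 1])
    gr <- gr + u[i] * cr / a2
  }
  gn <- sqrt(rowSums(gr^2))
  gn[gn == 0] <- 1
  X <- -gr / gn
  # integrated divergence at vertices: for each face and each corner i,
  # 0.5 * (cot(theta_jk_at_k) * e_ij . X + cot(theta_at_j) * e_ik . X)
  div <- numeric(V)
  cot_of <- function(p, q, r) {
    u1 <- v[q, , drop = FALSE] - v[p, , drop = FALSE]
    u2 <- v[r, , drop = FALSE] - v[p, , drop = FALSE]
    d <- rowSums(u1 * u2)
    cr <- cbind(u1[, 2] * u2[, 3] - u1[, 3] * u2[, 2],
                u1[, 3] * u2[, 1] - u1[, 1] * u2[, 3],
                u1[, 1] * u2[, 2] - u1[, 2] * u2[, 1])
    d / sqrt(rowSums(cr^2))
  }
  for (c in 1:3) {
    i <- f[, c]; j <- f[, (c %% 3) + 1]; k <- f[, ((c + 1) %% 3) + 1]
    e1 <- v[j, , drop = FALSE] - v[i, , drop = FALSE]
    e2 <- v[k, , drop = FALSE] - v[i, , drop = FALSE]
    cot1 <- cot_of(k, i, j)   # angle at k, opposite edge i->j
    cot2 <- cot_of(j, i, k)   # angle at j, opposite edge i->k
    contrib <- 0.5 * (cot1 * rowSums(e1 * X) + cot2 * rowSums(e2 * X))
    div <- div + scatter_add(contrib, i, V)
  }
  # Poisson solve; S is singular (constant nullspace), regularize lightly
  # with the positive semi-definite stiffness convention, Laplace = -S
  reg <- 1e-10 * mean(Matrix::diag(S))
  phi <- as.vector(Matrix::solve(S + reg * Matrix::Diagonal(V), -div))
  d <- phi - min(phi[source])
  d[source] <- 0
  d <- pmax(d, 0)
  if (!all(is.finite(d)))
    stop("Poisson solve failed; vertices unreachable from source: ",
         paste(which(!is.finite(d))[1:5], collapse = ", "))
  d
}

#' Apex vertex of a distance field
#'
#' @param dist numeric per-vertex distance field.
#' @return index of the vertex with the largest distance; ties broken by the
#'   lowest index.
#' @export
apex_vertex <- function(dist) which.max(dist)
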