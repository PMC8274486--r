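# Mesh data model and differential-geometry primitives.
#
# A surface_mesh is a triangulated, connected, orientable, manifold surface
# with at most one boundary loop (the LAA ostium). Vertices are in mm.
# Indices are 1-based inside R; all file interfaces use 0-based indices.

#' Construct a triangle surface mesh
#'
#' @param vertices numeric matrix (V x 3) of vertex positions, mm.
#' @param faces integer matrix (F x 3) of 1-based vertex indices per triangle.
#' @param fields named list of per-vertex arrays (vectors of length V or
#'   matrices with V rows).
#' @param ostium_ring optional ordered integer vector of vertex indices along
#'   the open boundary ring.
#' @param landmark optional single vertex index marking the circumflex-artery
#'   reference point.
#' @param validate logical; run full topology validation (default TRUE).
#'
#' @return an object of class \code{surface_mesh}.
#' @export
surface_mesh <- function(vertices, faces, fields = list(),
                         ostium_ring = NULL, landmark = NULL,
                         validate = TRUE) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  dimnames(vertices) <- NULL
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  dimnames(faces) <- NULL
  if (ncol(vertices) != 3L) stop("vertices must be a V x 3 matrix")
  if (ncol(faces) != 3L) stop("faces must be an F x 3 matrix of triangles")
  mesh <- structure(
    list(vertices = vertices, faces = faces, fields = fields,
         ostium_ring = if (!is.null(ostium_ring)) as.integer(ostium_ring),
         landmark = if (!is.null(landmark)) as.integer(landmark)),
    class = "surface_mesh")
  if (validate) validate_mesh(mesh)
  mesh
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  if (length(x$fields))
    cat("  fields:", paste(names(x$fields), collapse = ", "), "\n")
  if (!is.null(x$ostium_ring))
    cat(sprintf("  ostium ring: %d vertices\n", length(x$ostium_ring)))
  if (!is.null(x$landmark))
    cat(sprintf("  landmark vertex: %d\n", x$landmark))
  invisible(x)
}

#' Validate surface mesh invariants
#'
#' Checks index ranges, face non-degeneracy, edge-manifoldness, orientability,
#' connectivity and the at-most-one-boundary-loop condition.
#'
#' @param mesh a \code{surface_mesh}.
#' @return invisibly TRUE; stops with a descriptive error otherwise.
#' @export
validate_mesh <- function(mesh) {
  V <- nrow(mesh$vertices); F <- nrow(mesh$faces); f <- mesh$faces
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex coordinates")
  if (any(f < 1L) || any(f > V)) stop("face indices out of range [1, V]")
  degen <- f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]
  if (any(degen))
    stop("degenerate faces (repeated vertex): ", paste(which(degen)[1:min(5, sum(degen))], collapse = ", "))
  a <- face_areas(mesh)
  if (any(a <= 0))
    stop("zero-area faces: ", paste(which(a <= 0)[1:min(5, sum(a <= 0))], collapse = ", "))
  he <- half_edges(mesh)
  key <- edge_key(he[, 1], he[, 2])
  cnt <- table(key)
  if (any(cnt > 2L)) {
    bad <- names(cnt)[cnt > 2L]
    stop("non-manifold edges (shared by >2 faces): ", paste(utils::head(bad, 5), collapse = "; "))
  }
  # orientability: for edges shared by two faces, the two directed half-edges
  # must run in opposite directions
  dkey <- paste(he[, 1], he[, 2], sep = ">")
  if (anyDuplicated(dkey))
    stop("inconsistent face orientation (repeated directed half-edge)")
  # connectivity over vertices used by faces
  comp <- vertex_components(V, he)
  used <- sort(unique(as.vector(f)))
  if (length(unique(comp[used])) > 1L) stop("mesh is not connected")
  # boundary loops
  loops <- boundary_loops(mesh)
  if (length(loops) > 1L)
    stop(sprintf("mesh has %d boundary loops; at most one is supported", length(loops)))
  if (!is.null(mesh$ostium_ring)) {
    if (any(mesh$ostium_ring < 1L) || any(mesh$ostium_ring > V))
      stop("ostium_ring indices out of range")
  }
  if (!is.null(mesh$landmark) &&
      (mesh$landmark < 1L || mesh$landmark > V))
    stop("landmark index out of range")
  invisible(TRUE)
}

edge_key <- function(i, j) paste(pmin(i, j), pmax(i, j), sep = "-")

# sum vals into n bins indexed by idx (dense result, zeros where no entry)
scatter_add <- function(vals, idx, n) {
  tmp <- rowsum(vals, idx)
  out <- numeric(n)
  out[as.integer(rownames(tmp))] <- tmp
  out
}

# directed half-edges (3F x 2), one row per face edge in face winding order
half_edges <- function(mesh) {
  f <- mesh$faces
  cbind(c(f[, 1], f[, 2], f[, 3]), c(f[, 2], f[, 3], f[, 1]))
}

vertex_components <- function(V, he) {
  # union-find over undirected edges
  parent <- seq_len(V)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (r in seq_len(nrow(he))) {
    a <- find(he[r, 1]); b <- find(he[r, 2])
    if (a != b) parent[a] <- b
  }
  vapply(seq_len(V), find, integer(1))
}

#' Boundary loops of a mesh
#'
#' @param mesh a \code{surface_mesh}.
#' @return list of integer vectors, each an ordered closed loop of vertex
#'   indices along a boundary (empty list for closed surfaces).
#' @export
boundary_loops <- function(mesh) {
  he <- half_edges(mesh)
  key <- edge_key(he[, 1], he[, 2])
  cnt <- table(key)
  bkey <- names(cnt)[cnt == 1L]
  if (!length(bkey)) return(list())
  bhe <- he[key %in% bkey, , drop = FALSE]
  # boundary half-edges occur once; traverse successor map j -> next half-edge
  nxt <- split(bhe[, 2], bhe[, 1])
  loops <- list(); visited <- character(0)
  starts <- bhe[, 1]
  for (s in starts) {
    if (as.character(s) %in% visited) next
    loop <- integer(0); v <- s
    repeat {
      loop <- c(loop, v); visited <- c(visited, as.character(v))
      nv <- nxt[[as.character(v)]]
      if (is.null(nv)) break
      v <- nv[1]
      if (v == s) break
    }
    loops[[length(loops) + 1L]] <- loop
  }
  loops
}

face_cross <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Face areas
#' @param mesh a \code{surface_mesh}.
#' @return numeric vector of triangle areas.
#' @export
face_areas <- function(mesh) {
  cr <- face_cross(mesh)
  0.5 * sqrt(rowSums(cr^2))
}

#' Unit face normals
#' @param mesh a \code{surface_mesh}.
#' @return F x 3 matrix of unit normals following face winding.
#' @export
face_normals <- function(mesh) {
  cr <- face_cross(mesh)
  n <- sqrt(rowSums(cr^2))
  cr / n
}

#' Area-weighted vertex normals
#'
#' Per-vertex unit normal computed as the area-weighted average of incident
#' face normals; outward for positively oriented closed surfaces.
#'
#' @param mesh a \code{surface_mesh}.
#' @return V x 3 matrix of unit normals.
#' @export
vertex_normals <- function(mesh) {
  V <- nrow(mesh$vertices)
  cr <- face_cross(mesh)  # length = 2 * area, direction = face normal
  idx <- as.vector(mesh$faces)
  acc <- matrix(0, V, 3)
  for (k in 1:3) acc[, k] <- scatter_add(rep(cr[, k], 3), idx, V)
  nrm <- sqrt(rowSums(acc^2))
  star <- tabulate(idx, nbins = V)
  if (any(star > 0 & nrm <= .Machine$double.eps))
    stop("zero-area vertex star at vertex ",
         which(star > 0 & nrm <= .Machine$double.eps)[1])
  if (any(star == 0))
    stop("isolated vertex (no incident face): ", which(star == 0)[1])
  acc / nrm
}

#' Cotangent stiffness and lumped mass operators
#'
#' Builds the positive semi-definite cotangent Laplacian (stiffness) with
#' weights w_ij = (cot a_ij + cot b_ij) / 2 and the barycentric lumped mass
#' matrix (one third of incident face area per vertex).
#'
#' @param mesh a \code{surface_mesh}.
#' @return list with sparse symmetric \code{stiffness} (V x V) and numeric
#'   \code{mass} (diagonal entries, V).
#' @export
build_operators <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces; V <- nrow(v)
  a <- face_areas(mesh)
  if (any(a <= 0)) stop("degenerate (zero-area) triangle at face ", which(a <= 0)[1])
  i1 <- f[, 1]; i2 <- f[, 2]; i3 <- f[, 3]
  cot_at <- function(p, q, r) {
    # cotangent of angle at p in triangle (p,q,r)
    u <- v[q, , drop = FALSE] - v[p, , drop = FALSE]
    w <- v[r, , drop = FALSE] - v[p, , drop = FALSE]
    d <- rowSums(u * w)
    cr <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                u[, 3] * w[, 1] - u[, 1] * w[, 3],
                u[, 1] * w[, 2] - u[, 2] * w[, 1])
    d / sqrt(rowSums(cr^2))
  }
  c1 <- cot_at(i1, i2, i3)  # angle at v1, opposite edge (v2,v3)
  c2 <- cot_at(i2, i3, i1)  # opposite edge (v3,v1)
  c3 <- cot_at(i3, i1, i2)  # opposite edge (v1,v2)
  ii <- c(i2, i3, i1); jj <- c(i3, i1, i2); ww <- 0.5 * c(c1, c2, c3)
  S <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(-ww, -ww),
                            dims = c(V, V))
  diag(S) <- 0
  diag(S) <- -Matrix::rowSums(S)
  mass <- scatter_add(rep(a / 3, 3), as.vector(f), V)
  list(stiffness = S, mass = mass)
}

#' Vertex indices on the boundary
#' @param mesh a \code{surface_mesh}.
#' @return integer vector of boundary vertex indices (empty if closed).
#' @export
boundary_vertices <- function(mesh) {
  loops <- boundary_loops(mesh)
  if (!length(loops)) integer(0) else sort(unique(unlist(loops)))
}

# vertex -> neighbor adjacency list from undirected edges
vertex_adjacency <- function(mesh) {
  he <- half_edges(mesh)
  V <- nrow(mesh$vertices)
  adj <- split(he[, 2], factor(he[, 1], levels = seq_len(V)))
  lapply(adj, function(x) sort(unique(x)))
}

#' Per-vertex curvature
#'
#' Mean curvature is computed from the cotangent Laplacian applied to the
#' coordinates: H = |S x| / (2 m) per vertex, signed by the direction of the
#' mean-curvature vector relative to the outward normal (positive for a
#' sphere with outward normals). Gaussian curvature is the angle defect over
#' the lumped vertex area. Boundary vertices, where the cotangent formula is
#' undefined, are assigned the value of their nearest interior neighbor.
#'
#' @param mesh a \code{surface_mesh}.
#' @param kind one of \code{"mean"} or \code{"gaussian"}.
#' @return numeric vector of per-vertex curvature (1/mm for mean, 1/mm^2 for
#'   gaussian).
#' @export
vertex_curvature <- function(mesh, kind = c("mean", "gaussian")) {
  kind <- match.arg(kind)
  V <- nrow(mesh$vertices)
  ops <- build_operators(mesh)
  nrm <- vertex_normals(mesh)
  if (kind == "mean") {
    hv <- as.matrix(ops$stiffness %*% mesh$vertices) / (2 * ops$mass)
    h <- sqrt(rowSums(hv^2))
    sgn <- sign(rowSums(hv * nrm))
    sgn[sgn == 0] <- 1
    val <- sgn * h
  } else {
    f <- mesh$faces
    ang_at <- function(p, q, r) {
      u <- mesh$vertices[q, , drop = FALSE] - mesh$vertices[p, , drop = FALSE]
      w <- mesh$vertices[r, , drop = FALSE] - mesh$vertices[p, , drop = FALSE]
      cosang <- rowSums(u * w) / (sqrt(rowSums(u^2)) * sqrt(rowSums(w^2)))
      acos(pmin(1, pmax(-1, cosang)))
    }
    angs <- c(ang_at(f[, 1], f[, 2], f[, 3]),
              ang_at(f[, 2], f[, 3], f[, 1]),
              ang_at(f[, 3], f[, 1], f[, 2]))
    asum <- scatter_add(angs, as.vector(f), V)
    bnd0 <- boundary_vertices(mesh)
    defect <- 2 * pi - asum
    defect[bnd0] <- pi - asum[bnd0]
    val <- defect / ops$mass
  }
  bnd <- boundary_vertices(mesh)
  if (length(bnd)) {
    interior <- setdiff(seq_len(V), bnd)
    if (!length(interior)) stop("mesh has no interior vertices")
    # nearest interior vertex by Euclidean distance (boundary ring is thin,
    # so this matches the nearest-interior-neighbor rule)
    iv <- mesh$vertices[interior, , drop = FALSE]
    for (b in bnd) {
      d2 <- rowSums((iv - matrix(mesh$vertices[b, ], length(interior), 3,
                                 byrow = TRUE))^2)
      val[b] <- val[interior[which.min(d2)]]
    }
  }
  val
}

#' Convert a mesh to an attributed graph with edge pseudo-coordinates
#'
#' Every undirected mesh edge yields two directed edges. Pseudo-coordinates
#' for edge i -> j are (p_j - p_i) / (2 s) + 0.5 componentwise, where s is
#' the largest absolute per-axis coordinate difference over all edges of the
#' graph, so that u(i->j) + u(j->i) = (1,1,1) and all values lie in [0,1].
#'
#' @param mesh a \code{surface_mesh}.
#' @param features optional numeric matrix (V x C) of node features.
#' @return object of class \code{mesh_graph} with \code{n_nodes},
#'   \code{edges} (E x 2, 1-based, both directions), \code{pseudo_coords}
#'   (E x 3 in [0,1]) and \code{node_features}.
#' @export
mesh_to_graph <- function(mesh, features = NULL) {
  if (!all(is.finite(mesh$vertices))) stop("non-finite vertex positions")
  he <- half_edges(mesh)
  key <- edge_key(he[, 1], he[, 2])
  und <- he[!duplicated(key), , drop = FALSE]
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  dp <- mesh$vertices[edges[, 2], , drop = FALSE] -
    mesh$vertices[edges[, 1], , drop = FALSE]
  s <- max(abs(dp))
  if (s <= 0) stop("all edge vectors are zero")
  pseudo <- dp / (2 * s) + 0.5
  if (!is.null(features)) {
    features <- as.matrix(features)
    if (nrow(features) != nrow(mesh$vertices))
      stop("feature rows must align with vertices")
  }
  structure(list(n_nodes = nrow(mesh$vertices),
                 edges = edges, pseudo_coords = pseudo,
                 node_features = features),
            class = "mesh_graph")
}

#' @export
print.mesh_graph <- function(x, ...) {
  cat(sprintf("mesh_graph: %d nodes, %d directed edges", x$n_nodes,
              nrow(x$edges)))
  if (!is.null(x$node_features))
    cat(sprintf(", %d feature channels", ncol(x$node_features)))
  cat("\n")
  invisible(x)
}
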