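# Surface flattening for image-based surrogates: geodesic-depth isolines,
# centroid-pivot angular parameterization anchored at the circumflex-artery
# landmark, (depth x angle) grid sampling with mesh correspondence, bull's-eye
# rasterization, and transport of grid fields back onto the mesh.

#' Extract closed isolines of a vertex scalar field
#'
#' Marching-triangles extraction at \code{R} levels placed at
#' (r - 0.5)/R of the field maximum, r = 1..R (endpoints inset by half a
#' level). Crossing points are linearly interpolated along mesh edges. When
#' a level yields several closed loops (lobed shapes), the loop of greatest
#' arc length is kept and the event is recorded in the result's
#' \code{multi_loop} attribute.
#'
#' @param mesh a \code{surface_mesh}.
#' @param dist numeric per-vertex field (non-constant).
#' @param R number of levels (>= 2).
#' @return list of length R; each element has \code{points} (n x 3),
#'   \code{faces} (n, face id of the segment leaving each point),
#'   \code{level} (absolute field level).
#' @export
extract_isolines <- function(mesh, dist, R) {
  if (R < 2) stop("R must be >= 2")
  dmax <- max(dist)
  if (diff(range(dist)) <= 0) stop("distance field is constant")
  levels <- (seq_len(R) - 0.5) / R * dmax
  out <- vector("list", R)
  multi <- logical(R)
  for (r in seq_len(R)) {
    loops <- isoline_loops(mesh, dist, levels[r])
    if (!length(loops))
      stop("no isoline crossing at level ", signif(levels[r], 6))
    if (length(loops) > 1L) {
      multi[r] <- TRUE
      lens <- vapply(loops, function(L) {
        p <- L$points
        sum(sqrt(rowSums((p - p[c(2:nrow(p), 1), , drop = FALSE])^2)))
      }, numeric(1))
      loops <- loops[which.max(lens)]
    }
    out[[r]] <- c(loops[[1]], list(level = levels[r]))
  }
  attr(out, "levels") <- levels
  attr(out, "multi_loop") <- multi
  out
}

# all closed loops of the level set dist == level
isoline_loops <- function(mesh, dist, level) {
  f <- mesh$faces; v <- mesh$vertices
  d <- dist - level
  # crossing edges per face: sign change across each face edge
  cross_pt <- function(i, j) {
    t <- d[i] / (d[i] - d[j])
    v[i, ] + t * (v[j, ] - v[i, ])
  }
  # collect segments: face -> (edge_key_a, edge_key_b)
  segs_from <- character(0); segs_to <- character(0); seg_face <- integer(0)
  pts <- list()
  for (k in seq_len(nrow(f))) {
    tri <- f[k, ]
    dd <- d[tri]
    cr <- which(c(dd[1] * dd[2] < 0, dd[2] * dd[3] < 0, dd[3] * dd[1] < 0))
    if (length(cr) != 2) next
    e <- list(c(tri[1], tri[2]), c(tri[2], tri[3]), c(tri[3], tri[1]))
    keys <- vapply(cr, function(c1) edge_key(e[[c1]][1], e[[c1]][2]), character(1))
    for (c1 in cr) {
      key <- edge_key(e[[c1]][1], e[[c1]][2])
      if (is.null(pts[[key]])) pts[[key]] <- cross_pt(e[[c1]][1], e[[c1]][2])
    }
    segs_from <- c(segs_from, keys[1]); segs_to <- c(segs_to, keys[2])
    seg_face <- c(seg_face, k)
  }
  if (!length(segs_from)) return(list())
  # chain segments into loops: adjacency over edge keys
  nseg <- length(segs_from)
  used <- logical(nseg)
  adj <- split(seq_len(nseg), segs_from)
  adj2 <- split(seq_len(nseg), segs_to)
  loops <- list()
  for (s0 in seq_len(nseg)) {
    if (used[s0]) next
    keys_path <- segs_from[s0]
    faces_path <- integer(0)
    cur_key <- segs_from[s0]
    repeat {
      cand <- c(adj[[cur_key]], adj2[[cur_key]])
      cand <- cand[!used[cand]]
      if (!length(cand)) break
      s <- cand[1]; used[s] <- TRUE
      nxt <- if (segs_from[s] == cur_key) segs_to[s] else segs_from[s]
      faces_path <- c(faces_path, seg_face[s])
      if (nxt == keys_path[1]) break
      keys_path <- c(keys_path, nxt)
      cur_key <- nxt
    }
    if (length(keys_path) >= 3) {
      p <- do.call(rbind, pts[keys_path])
      loops[[length(loops) + 1L]] <- list(points = unname(p),
                                          faces = faces_path)
    }
  }
  loops
}

#' Angular parameterization of a closed polyline
#'
#' Points are projected onto the plane through the polyline centroid
#' orthogonal to \code{axis}; angles are measured counter-clockwise about
#' the axis and rotated so the point nearest \code{landmark_pos} has angle 0.
#'
#' @param points n x 3 matrix of closed-polyline points (n >= 3).
#' @param landmark_pos 3-vector; the reference (0 degree) position.
#' @param axis 3-vector normal of the projection plane (nonzero).
#' @return list with \code{theta} (angles in [0, 2pi) per point, zero at the
#'   point nearest the landmark), \code{centroid}, \code{axis} (unit),
#'   \code{ref} (unit in-plane direction of angle 0), and \code{order}
#'   (permutation making the traversal angle-increasing).
#' @export
angular_parameterize <- function(points, landmark_pos, axis) {
  n <- nrow(points)
  if (n < 3) stop("polyline needs at least 3 points")
  nrm <- sqrt(sum(axis^2))
  if (nrm <= 0) stop("axis must be nonzero")
  axis <- axis / nrm
  centroid <- colMeans(points)
  rel <- sweep(points, 2, centroid)
  # in-plane components
  proj <- rel - outer(as.vector(rel %*% axis), axis)
  rad <- sqrt(rowSums(proj^2))
  if (any(rad <= 1e-12))
    stop("polyline point coincides with the centroid after projection")
  near <- which.min(colSums((t(points) - landmark_pos)^2))
  ref <- proj[near, ]; ref <- ref / sqrt(sum(ref^2))
  w <- c(axis[2] * ref[3] - axis[3] * ref[2],
         axis[3] * ref[1] - axis[1] * ref[3],
         axis[1] * ref[2] - axis[2] * ref[1])
  theta <- atan2(proj %*% w, proj %*% ref) %% (2 * pi)
  theta <- as.vector(theta)
  theta[near] <- 0
  # winding direction along the stored traversal
  dtheta <- diff(c(theta, theta[1]))
  wind <- sum(((dtheta + pi) %% (2 * pi)) - pi)
  order_idx <- seq_len(n)
  if (wind < 0) order_idx <- rev(order_idx)
  list(theta = theta, centroid = centroid, axis = axis, ref = ref,
       order = order_idx)
}

#' Build a flattened (depth x angle) map of a mesh
#'
#' For each of R geodesic-depth isolines and A uniformly spaced angles, the
#' isoline point at that angle is sampled (linear interpolation in angle
#' along the loop) and recorded with its xyz position and mesh
#' correspondence (face id + barycentric weights). Row order is increasing
#' distance from the ostium.
#'
#' @param mesh a \code{surface_mesh}.
#' @param dist per-vertex geodesic distance from the ostium.
#' @param landmark vertex index used as the 0-degree reference.
#' @param R number of isolines (>= 2).
#' @param A number of angular samples (>= 4).
#' @return object of class \code{flat_map}.
#' @export
build_flat_map <- function(mesh, dist, landmark, R = 128, A = 128) {
  if (A < 4) stop("A must be >= 4")
  if (landmark < 1 || landmark > nrow(mesh$vertices))
    stop("landmark vertex out of range")
  iso <- extract_isolines(mesh, dist, R)
  dmax <- max(dist)
  apex_pos <- mesh$vertices[apex_vertex(dist), ]
  lm_pos <- mesh$vertices[landmark, ]
  theta_grid <- 2 * pi * (seq_len(A) - 1) / A
  channels <- array(NA_real_, c(R, A, 3))
  corr_face <- matrix(NA_integer_, R, A)
  corr_bary <- array(NA_real_, c(R, A, 3))
  row_centroid <- matrix(0, R, 3)
  row_axis <- matrix(0, R, 3)
  row_ref <- matrix(0, R, 3)
  for (r in seq_len(R)) {
    loop <- iso[[r]]
    p <- loop$points; nf <- loop$faces
    centroid <- colMeans(p)
    axis <- colMeans(face_gradient_dirs(mesh, dist, unique(nf)))
    if (sum(axis^2) <= 1e-24) axis <- apex_pos - centroid
    if (sum(axis * (apex_pos - centroid)) < 0) axis <- -axis
    par <- angular_parameterize(p, lm_pos, axis)
    ord <- par$order
    th <- par$theta[ord]; pp <- p[ord, , drop = FALSE]
    # faces of segments follow the traversal; segment leaving point i in the
    # original order sits between original points i and i+1
    n <- nrow(p)
    seg_face_orig <- loop$faces  # segment i connects point i to i+1 (cyclic)
    if (identical(ord, rev(seq_len(n)))) {
      # reversed traversal: segment leaving new point i is original segment i-1
      seg_face <- rev(c(seg_face_orig[n], seg_face_orig[-n]))
    } else seg_face <- seg_face_orig
    # rotate so angles start at the minimum (0 at the landmark point)
    start <- which.min(th)
    idx <- c(start:n, if (start > 1) 1:(start - 1))
    th <- th[idx]; pp <- pp[idx, , drop = FALSE]; seg_face <- seg_face[idx]
    th_un <- unwrap_angles(th)
    row_centroid[r, ] <- par$centroid
    row_axis[r, ] <- par$axis
    row_ref[r, ] <- par$ref
    for (a in seq_len(A)) {
      tg <- theta_grid[a]
      # locate in cyclic sequence th_un (increasing, th_un[1] = 0)
      j <- findInterval(tg, th_un)
      if (j >= 1 && j < n) {
        t0 <- th_un[j]; t1 <- th_un[j + 1]
        w1 <- if (t1 > t0) (tg - t0) / (t1 - t0) else 0
        pa <- (1 - w1) * pp[j, ] + w1 * pp[j + 1, ]
        fc <- seg_face[j]
      } else {
        # between last point and the first (wrap)
        t0 <- th_un[n]; t1 <- th_un[1] + 2 * pi
        w1 <- if (t1 > t0) (tg - t0) / (t1 - t0) else 0
        pa <- (1 - w1) * pp[n, ] + w1 * pp[1, ]
        fc <- seg_face[n]
      }
      channels[r, a, ] <- pa
      corr_face[r, a] <- fc
      corr_bary[r, a, ] <- barycentric_weights(mesh, fc, pa)
    }
  }
  structure(list(grid_shape = c(R, A), channels = channels,
                 corr_face = corr_face, corr_bary = corr_bary,
                 d_levels = attr(iso, "levels") / dmax,
                 theta = theta_grid,
                 row_centroid = row_centroid, row_axis = row_axis,
                 row_ref = row_ref,
                 d_max = dmax, vertex_dist = dist,
                 multi_loop = attr(iso, "multi_loop"),
                 angle_convention = "counter-clockwise about apex-pointing axis"),
            class = "flat_map")
}

# unit directions of the per-face gradient of dist, restricted to faces
face_gradient_dirs <- function(mesh, dist, faces_idx) {
  f <- mesh$faces[faces_idx, , drop = FALSE]
  v <- mesh$vertices
  n <- face_cross(mesh)[faces_idx, , drop = FALSE]
  a2 <- sqrt(rowSums(n^2)); nn <- n / a2
  gr <- matrix(0, nrow(f), 3)
  for (c in 1:3) {
    i <- f[, c]; j <- f[, (c %% 3) + 1]; k <- f[, ((c + 1) %% 3) + 1]
    e <- v[k, , drop = FALSE] - v[j, , drop = FALSE]
    cr <- cbind(nn[, 2] * e[, 3] - nn[, 3] * e[, 2],
                nn[, 3] * e[, 1] - nn[, 1] * e[, 3],
                nn[, 1] * e[, 2] - nn[, 2] * e[, 1])
    gr <- gr + dist[i] * cr / a2
  }
  gn <- sqrt(rowSums(gr^2)); gn[gn == 0] <- 1
  gr / gn
}

unwrap_angles <- function(th) {
  # th starts at its minimum (0); make the cyclic sequence non-decreasing
  out <- th
  for (i in 2:length(out))
    while (out[i] < out[i - 1]) out[i] <- out[i] + 2 * pi
  out - out[1]
}

barycentric_weights <- function(mesh, face, p) {
  tri <- mesh$vertices[mesh$faces[face, ], , drop = FALSE]
  e1 <- tri[2, ] - tri[1, ]; e2 <- tri[3, ] - tri[1, ]
  rp <- p - tri[1, ]
  d11 <- sum(e1 * e1); d12 <- sum(e1 * e2); d22 <- sum(e2 * e2)
  r1 <- sum(rp * e1); r2 <- sum(rp * e2)
  det <- d11 * d22 - d12^2
  w2 <- (d22 * r1 - d12 * r2) / det
  w3 <- (d11 * r2 - d12 * r1) / det
  w <- c(1 - w2 - w3, w2, w3)
  w <- pmax(w, 0)
  w / sum(w)
}

#' Rasterize flattened grid channels as a bull's-eye image
#'
#' The apex (innermost isoline, largest geodesic depth) maps to the disc
#' center and the ostium to the rim. Bilinear interpolation in (depth,
#' angle) with angular wraparound; pixels outside the unit disc are set to
#' \code{pad_value}.
#'
#' @param flat a \code{flat_map}.
#' @param S raster side length (>= 16).
#' @param values numeric array (R x A) or (R x A x C) of grid channels;
#'   defaults to the xyz channels of \code{flat}.
#' @param pad_value scalar used outside the disc mask (default 0).
#' @return object of class \code{bullseye} with \code{image} (S x S x C),
#'   \code{mask} (S x S logical) and \code{pad_value}.
#' @export
to_bullseye <- function(flat, S = 128, values = flat$channels, pad_value = 0) {
  if (S < 16) stop("S must be >= 16")
  if (length(dim(values)) == 2) dim(values) <- c(dim(values), 1)
  R <- dim(values)[1]; A <- dim(values)[2]; C <- dim(values)[3]
  ctr <- (S + 1) / 2
  xs <- (seq_len(S) - ctr) / (S / 2)
  X <- matrix(xs, S, S, byrow = TRUE)   # column coordinate
  Y <- matrix(xs, S, S)                 # row coordinate
  rho <- sqrt(X^2 + Y^2)
  thet <- atan2(Y, X) %% (2 * pi)
  mask <- rho <= 1
  img <- array(pad_value, c(S, S, C))
  dn <- 1 - rho   # normalized geodesic depth: apex (dn=1) at the center
  rpos <- pmin(pmax(as.vector(dn) * R + 0.5, 1), R)
  r0 <- floor(rpos); r1 <- pmin(r0 + 1, R); tr <- rpos - r0
  cpos <- as.vector(thet) / (2 * pi) * A + 1
  c0 <- floor(cpos); tc <- cpos - c0
  c0w <- ((c0 - 1) %% A) + 1; c1w <- (c0 %% A) + 1
  for (ch in seq_len(C)) {
    v <- values[, , ch]
    val <- (1 - tr) * ((1 - tc) * v[cbind(r0, c0w)] + tc * v[cbind(r0, c1w)]) +
      tr * ((1 - tc) * v[cbind(r1, c0w)] + tc * v[cbind(r1, c1w)])
    plane <- matrix(pad_value, S, S)
    plane[mask] <- val[mask]
    img[, , ch] <- plane
  }
  structure(list(image = img, mask = mask, pad_value = pad_value),
            class = "bullseye")
}

#' Transport grid values back onto the mesh
#'
#' Each vertex receives the grid value at its (normalized geodesic depth,
#' angle) coordinate by bilinear interpolation (angle wraps; depth clamps to
#' the covered range).
#'
#' @param mesh a \code{surface_mesh}.
#' @param flat a \code{flat_map} built on this mesh.
#' @param grid_values numeric matrix (R x A) of per-cell scalars.
#' @return numeric per-vertex field with no non-finite entries.
#' @export
unflatten <- function(mesh, flat, grid_values) {
  R <- flat$grid_shape[1]; A <- flat$grid_shape[2]
  if (!all(dim(grid_values) == c(R, A)))
    stop("grid_values must be R x A")
  V <- nrow(mesh$vertices)
  dn <- flat$vertex_dist / flat$d_max
  rpos <- pmin(pmax(dn * R + 0.5, 1), R)
  r0 <- floor(rpos); r1 <- pmin(r0 + 1, R); tr <- rpos - r0
  out <- numeric(V)
  # per-vertex angle in each bracketing row's frame
  ang_in_row <- function(r, pts) {
    rel <- sweep(pts, 2, flat$row_centroid[r, ])
    ax <- flat$row_axis[r, ]; ref <- flat$row_ref[r, ]
    w <- c(ax[2] * ref[3] - ax[3] * ref[2],
           ax[3] * ref[1] - ax[1] * ref[3],
           ax[1] * ref[2] - ax[2] * ref[1])
    proj <- rel - outer(as.vector(rel %*% ax), ax)
    as.vector(atan2(proj %*% w, proj %*% ref)) %% (2 * pi)
  }
  sample_row <- function(r, th) {
    cpos <- th / (2 * pi) * A + 1
    c0 <- floor(cpos); tc <- cpos - c0
    c0w <- ((c0 - 1) %% A) + 1; c1w <- (c0 %% A) + 1
    (1 - tc) * grid_values[cbind(r, c0w)] + tc * grid_values[cbind(r, c1w)]
  }
  pts <- mesh$vertices
  th0 <- ang_in_row_vec(flat, r0, pts)
  th1 <- ang_in_row_vec(flat, r1, pts)
  v0 <- sample_row(r0, th0)
  v1 <- sample_row(r1, th1)
  out <- (1 - tr) * v0 + tr * v1
  if (!all(is.finite(out))) stop("non-finite transported values")
  out
}

# vectorized per-vertex angle where each vertex may use a different row
ang_in_row_vec <- function(flat, rows, pts) {
  th <- numeric(nrow(pts))
  for (r in unique(rows)) {
    sel <- rows == r
    rel <- sweep(pts[sel, , drop = FALSE], 2, flat$row_centroid[r, ])
    ax <- flat$row_axis[r, ]; ref <- flat$row_ref[r, ]
    w <- c(ax[2] * ref[3] - ax[3] * ref[2],
           ax[3] * ref[1] - ax[1] * ref[3],
           ax[1] * ref[2] - ax[2] * ref[1])
    proj <- rel - outer(as.vector(rel %*% ax), ax)
    th[sel] <- as.vector(atan2(proj %*% w, proj %*% ref)) %% (2 * pi)
  }
  th
}

#' Sample a per-vertex field onto the flattened grid
#'
#' Evaluates a vertex field at each grid cell through the stored face and
#' barycentric correspondence.
#'
#' @param flat a \code{flat_map}.
#' @param mesh the source \code{surface_mesh}.
#' @param field numeric per-vertex field.
#' @return numeric matrix (R x A).
#' @export
sample_to_grid <- function(flat, mesh, field) {
  R <- flat$grid_shape[1]; A <- flat$grid_shape[2]
  out <- matrix(0, R, A)
  fv <- mesh$faces
  for (r in seq_len(R)) {
    fc <- flat$corr_face[r, ]
    b <- flat$corr_bary[r, , ]
    tri <- fv[fc, , drop = FALSE]
    out[r, ] <- b[, 1] * field[tri[, 1]] + b[, 2] * field[tri[, 2]] +
      b[, 3] * field[tri[, 3]]
  }
  out
}
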