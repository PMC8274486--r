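# Synthetic LAA generator: corresponded lobed-tube anatomies with an ostium
# boundary ring and a circumflex-like landmark, a closed-form
# geometry-determined hemodynamic oracle (TAWSS*, OSI*, ECAP*), and an
# exactly invertible two-phase WSS series so the whole index pipeline can be
# exercised without CFD.
#
# All samples deform a fixed tube template (shared topology), so the set is
# in vertex correspondence by construction and directly usable by the PCA
# shape model.

#' Shape-sampling specification
#'
#' The template is a tapering tube of length \code{length_mm} open at the
#' ostium (radius \code{r_ostium}) and capped at the apex. Samples apply a
#' smooth random centerline bend, a smooth radius-profile modulation, and
#' outward Gaussian lobes; lobed, "cauliflower"-like morphologies carry
#' higher stasis in the oracle.
#'
#' @param n_axial axial rings between ostium and apex (default 20).
#' @param n_circ circumferential vertices per ring (default 14).
#' @param length_mm tube length, mm (default 30).
#' @param r_ostium ostium radius, mm (default 10).
#' @param taper fraction of the ostium radius lost at the apex (default
#'   0.65; the appendage narrows toward the apex).
#' @param bend_sd standard deviations (mm) of the two bending harmonics
#'   (default c(4, 2)).
#' @param radius_sd standard deviation of the relative radius-profile
#'   modulation (default 0.08).
#' @param lobe_count inclusive range of lobe counts (default c(1, 3)).
#' @param lobe_amp range of relative lobe amplitudes (default c(0.2, 0.5)).
#' @param lobe_width_s range of axial lobe widths, in axial fraction
#'   (default c(0.08, 0.18)).
#' @param lobe_width_theta range of angular lobe widths, rad (default
#'   c(0.4, 0.9)).
#' @param scale_range global isotropic scale range (default c(0.85, 1.15)).
#' @return a list of class \code{shape_spec}.
#' @export
shape_spec <- function(n_axial = 20, n_circ = 14, length_mm = 30,
                       r_ostium = 10, taper = 0.65, bend_sd = c(4, 2),
                       radius_sd = 0.08, lobe_count = c(1, 3),
                       lobe_amp = c(0.2, 0.5), lobe_width_s = c(0.08, 0.18),
                       lobe_width_theta = c(0.4, 0.9),
                       scale_range = c(0.85, 1.15)) {
  structure(list(n_axial = n_axial, n_circ = n_circ, length_mm = length_mm,
                 r_ostium = r_ostium, taper = taper, bend_sd = bend_sd,
                 radius_sd = radius_sd, lobe_count = lobe_count,
                 lobe_amp = lobe_amp, lobe_width_s = lobe_width_s,
                 lobe_width_theta = lobe_width_theta,
                 scale_range = scale_range),
            class = "shape_spec")
}

#' Hemodynamic-oracle specification
#'
#' With normalized geodesic depth d in [0, 1] from the ostium and lobe
#' indicator b (sum of the generator's lobe kernels), the oracle sets
#' OSI* = osi_max clip(d^gamma (1 + c2 b), 0, 1),
#' TAWSS* = tawss_base (1 - 0.9 d) + c0 and ECAP* = OSI*/TAWSS*: shear
#' decays and oscillation grows with depth, and lobes (stasis pockets)
#' amplify oscillation, giving the positively skewed, depth-increasing ECAP
#' structure seen in appendage simulations.
#'
#' @param c0 baseline TAWSS offset, Pa (default 0.05).
#' @param c1 depth gain of OSI (fixed at osi_max; kept for clarity).
#' @param gamma depth exponent of OSI (default 2).
#' @param c2 lobe gain (default 4).
#' @param osi_max peak oscillatory index, <= 0.5 (default 0.5).
#' @param tawss_base ostium-level TAWSS, Pa (default 1).
#' @param noise_sd standard deviation of smooth multiplicative log-noise on
#'   ECAP (default 0 = deterministic oracle).
#' @return a list of class \code{oracle_spec}.
#' @export
oracle_spec <- function(c0 = 0.05, c1 = NULL, gamma = 2, c2 = 4,
                        osi_max = 0.5, tawss_base = 1, noise_sd = 0) {
  if (osi_max > 0.5) stop("osi_max must be <= 0.5")
  structure(list(c0 = c0, gamma = gamma, c2 = c2, osi_max = osi_max,
                 tawss_base = tawss_base, noise_sd = noise_sd),
            class = "oracle_spec")
}

# template (s, theta) coordinates shared by all samples
template_coords <- function(spec) {
  s <- rep(seq(0, 1, length.out = spec$n_axial + 1), each = spec$n_circ)
  th <- rep(2 * pi * (seq_len(spec$n_circ) - 1) / spec$n_circ,
            spec$n_axial + 1)
  list(s = s, theta = th)
}

template_faces <- function(spec) {
  nc <- spec$n_circ; na <- spec$n_axial
  f <- matrix(0L, 0, 3)
  for (i in seq_len(na)) {
    base0 <- (i - 1) * nc
    base1 <- i * nc
    j <- seq_len(nc); jn <- c(2:nc, 1)
    # outward orientation for counter-clockwise theta and outward radius
    f <- rbind(f,
               cbind(base0 + j, base0 + jn, base1 + j),
               cbind(base0 + jn, base1 + jn, base1 + j))
  }
  apex <- (na + 1) * nc + 1
  top <- na * nc
  j <- seq_len(nc); jn <- c(2:nc, 1)
  f <- rbind(f, cbind(top + j, top + jn, apex))
  f
}

#' Sample a synthetic LAA surface
#'
#' Deterministic per seed; all samples share the template topology (faces
#' are bit-identical across draws), have the open ostium ring as their only
#' boundary, and carry the lobe-kernel field \code{lobe} used by the
#' hemodynamic oracle.
#'
#' @param spec a \code{shape_spec}.
#' @param seed integer seed.
#' @return a \code{surface_mesh} with \code{ostium_ring}, \code{landmark}
#'   and a \code{lobe} field.
#' @export
sample_shape <- function(spec = shape_spec(), seed = 1) {
  faces <- template_faces(spec)
  for (attempt in 1:10) {
    set.seed(seed + (attempt - 1) * 1000003L)
    mesh <- try(sample_shape_once(spec, faces), silent = TRUE)
    if (!inherits(mesh, "try-error")) return(mesh)
  }
  stop("failed to sample a valid shape after 10 attempts: ",
       attr(mesh, "condition")$message)
}

sample_shape_once <- function(spec, faces) {
  tc <- template_coords(spec)
  nc <- spec$n_circ
  # centerline bend (lateral offsets, two harmonics per axis)
  bx <- stats::rnorm(2, sd = spec$bend_sd)
  by <- stats::rnorm(2, sd = spec$bend_sd)
  cl_x <- function(s) bx[1] * sin(pi * s) + bx[2] * sin(2 * pi * s)
  cl_y <- function(s) by[1] * sin(pi * s) + by[2] * sin(2 * pi * s)
  # radius profile: monotone taper plus smooth modulation
  rmod <- stats::rnorm(2, sd = spec$radius_sd)
  rprof <- function(s) {
    base <- spec$r_ostium * (1 - spec$taper * s^1.3)
    mod <- 1 + rmod[1] * sin(pi * s) + rmod[2] * sin(2 * pi * s)
    pmax(base * pmax(mod, 0.3), 0.08 * spec$r_ostium)
  }
  # lobes
  G <- sample(spec$lobe_count[1]:spec$lobe_count[2], 1)
  lobes <- NULL
  if (G > 0)
    lobes <- data.frame(
      s = stats::runif(G, 0.3, 0.9),
      theta = stats::runif(G, 0, 2 * pi),
      amp = stats::runif(G, spec$lobe_amp[1], spec$lobe_amp[2]),
      ws = stats::runif(G, spec$lobe_width_s[1], spec$lobe_width_s[2]),
      wt = stats::runif(G, spec$lobe_width_theta[1], spec$lobe_width_theta[2]))
  scale <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
  lobe_kernel <- function(s, th) {
    if (is.null(lobes)) return(numeric(length(s)))
    out <- numeric(length(s))
    for (g in seq_len(nrow(lobes))) {
      dth <- abs(((th - lobes$theta[g] + pi) %% (2 * pi)) - pi)
      out <- out + lobes$amp[g] *
        exp(-0.5 * ((s - lobes$s[g])^2 / lobes$ws[g]^2 +
                    dth^2 / lobes$wt[g]^2))
    }
    out
  }
  b <- lobe_kernel(tc$s, tc$theta)
  rho <- rprof(tc$s) * (1 + b)
  xs <- cl_x(tc$s) + rho * cos(tc$theta)
  ys <- cl_y(tc$s) + rho * sin(tc$theta)
  zs <- tc$s * spec$length_mm
  apex_b <- mean(lobe_kernel(rep(1, nc),
                             2 * pi * (seq_len(nc) - 1) / nc))
  apex <- c(cl_x(1), cl_y(1), spec$length_mm + 0.6 * rprof(1))
  verts <- scale * rbind(cbind(xs, ys, zs), apex)
  mesh <- surface_mesh(verts, faces,
                       fields = list(lobe = c(b, apex_b)),
                       ostium_ring = seq_len(nc),
                       landmark = 1L)
  mesh
}

#' Closed-form hemodynamic oracle fields
#'
#' @param mesh a \code{surface_mesh} from \code{\link{sample_shape}} (needs
#'   \code{ostium_ring} and the \code{lobe} field).
#' @param spec an \code{oracle_spec}.
#' @param seed seed for the optional smooth noise.
#' @return list with \code{tawss}, \code{osi}, \code{ecap}, \code{depth}
#'   per-vertex fields.
#' @export
oracle_fields <- function(mesh, spec = oracle_spec(), seed = 1) {
  if (is.null(mesh$ostium_ring)) stop("mesh lacks an ostium ring")
  b <- mesh$fields$lobe
  if (is.null(b)) stop("mesh lacks the generator's lobe field")
  d <- geodesic_distance(mesh, mesh$ostium_ring)
  delta <- d / max(d)
  osi_star <- spec$osi_max * pmin(pmax(delta^spec$gamma * (1 + spec$c2 * b), 0), 1)
  tawss_star <- spec$tawss_base * (1 - 0.9 * delta) + spec$c0
  ecap_star <- osi_star / tawss_star
  if (spec$noise_sd > 0) {
    set.seed(seed)
    # smooth multiplicative noise: low-order harmonics in depth
    co <- stats::rnorm(3, sd = spec$noise_sd)
    eps <- co[1] * sin(pi * delta) + co[2] * cos(pi * delta) +
      co[3] * sin(2 * pi * delta)
    ecap_star <- ecap_star * exp(eps)
    osi_star <- pmin(ecap_star * tawss_star, 0.5)
    ecap_star <- osi_star / tawss_star
  }
  list(tawss = tawss_star, osi = osi_star, ecap = ecap_star, depth = delta)
}

#' Exactly invertible two-phase WSS series for oracle targets
#'
#' Builds a per-vertex step series along a fixed unit direction with
#' magnitude a forward for the first half-cycle and b backward for the
#' second, where a = 2 TAWSS* (1 - OSI*) and b = 2 TAWSS* OSI*, so the
#' left-sample quadrature recovers (TAWSS*, OSI*, ECAP*) exactly.
#'
#' @param mesh a \code{surface_mesh} (vertex count only).
#' @param targets list with \code{tawss} (> 0) and \code{osi} (<= 0.5).
#' @param period cycle duration, s (default 1).
#' @param n_per_phase samples per half-cycle (default 1).
#' @param direction fixed unit 3-vector (default x).
#' @return a \code{wss_series}.
#' @export
synth_wss <- function(mesh, targets, period = 1, n_per_phase = 1,
                      direction = c(1, 0, 0)) {
  tw <- targets$tawss; os <- targets$osi
  if (any(os > 0.5 + 1e-12)) stop("oracle OSI exceeds 0.5")
  if (any(tw < 0)) stop("oracle TAWSS must be nonnegative")
  V <- nrow(mesh$vertices)
  direction <- direction / sqrt(sum(direction^2))
  a <- 2 * tw * (1 - os)
  b <- 2 * tw * os
  K <- 2 * n_per_phase
  times <- (seq_len(K) - 1) / K * period
  vals <- array(0, c(K, V, 3))
  for (k in seq_len(K)) {
    mag <- if (k <= n_per_phase) a else -b
    vals[k, , ] <- outer(mag, direction)
  }
  wss_series(times, vals, period)
}

#' Generate a corresponded synthetic dataset with oracle targets
#'
#' @param n number of cases (>= 2).
#' @param shape a \code{shape_spec}; the presets \code{"synthetic-like"}
#'   (default; lobe-rich) and \code{"real-like"} (fewer, weaker lobes) are
#'   selected via \code{cohort}.
#' @param oracle an \code{oracle_spec}.
#' @param seed integer seed; case i uses seed + i.
#' @param cohort \code{"synthetic-like"}, \code{"real-like"} or
#'   \code{"custom"} (use \code{shape} as given).
#' @return object of class \code{laa_dataset}: per-case meshes, oracle
#'   fields, curvature/normals, raw graphs, and the stacked PCA coordinate
#'   matrix.
#' @export
make_dataset <- function(n, shape = shape_spec(), oracle = oracle_spec(),
                         seed = 1, cohort = c("synthetic-like", "real-like",
                                              "custom")) {
  cohort <- match.arg(cohort)
  if (n < 2) stop("n must be >= 2")
  if (cohort == "real-like")
    shape <- utils::modifyList(shape, list(lobe_count = c(0, 1),
                                           lobe_amp = c(0.05, 0.25)))
  cases <- vector("list", n)
  for (i in seq_len(n)) {
    mesh <- sample_shape(shape, seed = seed + i)
    orc <- oracle_fields(mesh, oracle, seed = seed + i)
    mesh$fields$TAWSS <- orc$tawss
    mesh$fields$OSI <- orc$osi
    mesh$fields$ECAP <- orc$ecap
    cases[[i]] <- list(
      id = sprintf("case_%03d", i),
      mesh = mesh,
      ecap = orc$ecap, tawss = orc$tawss, osi = orc$osi,
      depth = orc$depth,
      curvature = vertex_curvature(mesh, "mean"),
      normals = vertex_normals(mesh),
      graph = mesh_to_graph(mesh))
  }
  X <- t(vapply(cases, function(cs) as.vector(t(cs$mesh$vertices)),
                numeric(3 * nrow(cases[[1]]$mesh$vertices))))
  structure(list(cases = cases, coords = X,
                 template_faces = cases[[1]]$mesh$faces,
                 shape_spec = shape, oracle_spec = oracle,
                 seed = seed, cohort = cohort),
            class = "laa_dataset")
}

#' @export
print.laa_dataset <- function(x, ...) {
  cat(sprintf("laa_dataset: %d %s cases, %d vertices each\n",
              length(x$cases), x$cohort,
              nrow(x$cases[[1]]$mesh$vertices)))
  invisible(x)
}
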