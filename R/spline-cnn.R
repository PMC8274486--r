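# Spline-kernel graph convolutional surrogate: local feature module of
# consecutive spline convolutions over edge pseudo-coordinates, a shared
# dense lift whose per-graph max-pool yields a global feature vector, and a
# per-vertex regression head over the concatenated local+global features.
# Degree-1 open uniform B-spline basis, tensor-product over the three
# pseudo-coordinate dimensions.

#' Degree-1 B-spline basis on [0, 1]
#'
#' Open uniform basis with k knots: position p = u (k - 1); the contributing
#' knots are floor(p) and floor(p) + 1 with weights (1 - frac(p), frac(p)).
#' At u = 1 the single index k - 1 carries weight 1. Values outside [0, 1]
#' are clipped (the clip count is returned as an attribute).
#'
#' @param u numeric values in [0, 1].
#' @param k kernel size (knots per dimension, >= 2).
#' @return list with \code{indices} (n x 2, 0-based) and \code{weights}
#'   (n x 2, rows sum to 1); attribute \code{clipped} counts out-of-range
#'   inputs.
#' @export
spline_basis <- function(u, k) {
  if (k < 2) stop("kernel size must be >= 2")
  clipped <- sum(u < 0 | u > 1)
  if (clipped > 0) {
    warning(clipped, " pseudo-coordinate value(s) outside [0,1] clipped")
    u <- pmin(1, pmax(0, u))
  }
  p <- u * (k - 1)
  i0 <- pmin(floor(p), k - 1)
  fr <- p - i0
  i1 <- pmin(i0 + 1, k - 1)
  out <- list(indices = unname(cbind(i0, i1)),
              weights = unname(cbind(1 - fr, fr)))
  attr(out, "clipped") <- clipped
  out
}

# tensor-product basis for all edges: 8 active products at degree 1
graph_spline_basis <- function(pseudo, k) {
  E <- nrow(pseudo)
  b <- lapply(1:3, function(d) spline_basis(pseudo[, d], k))
  bidx <- matrix(0L, E, 8)
  bw <- matrix(0, E, 8)
  m <- 1
  for (c3 in 1:2) for (c2 in 1:2) for (c1 in 1:2) {
    bidx[, m] <- b[[1]]$indices[, c1] + k * b[[2]]$indices[, c2] +
      k * k * b[[3]]$indices[, c3]
    bw[, m] <- b[[1]]$weights[, c1] * b[[2]]$weights[, c2] *
      b[[3]]$weights[, c3]
    m <- m + 1
  }
  list(bidx = bidx, bw = bw)
}

#' Prepare a mesh graph for spline convolution
#'
#' Precomputes the per-edge tensor-product basis and the in-degree
#' normalization used by the mean-aggregating convolution.
#'
#' @param graph a \code{mesh_graph} (see \code{\link{mesh_to_graph}}).
#' @param k kernel size per pseudo-coordinate dimension (default 5).
#' @return list with 0-based edge arrays, basis indices/weights, inverse
#'   in-degrees and the node features.
#' @export
prepare_graph <- function(graph, k = 5) {
  basis <- graph_spline_basis(graph$pseudo_coords, k)
  tgt <- graph$edges[, 2]
  deg <- tabulate(tgt, nbins = graph$n_nodes)
  invdeg <- ifelse(deg > 0, 1 / deg, 0)
  list(n_nodes = graph$n_nodes,
       src = as.integer(graph$edges[, 1] - 1L),
       tgt = as.integer(tgt - 1L),
       bidx = basis$bidx, bw = basis$bw, invdeg = invdeg,
       features = graph$node_features, k = k)
}

#' Spline convolution over a prepared graph
#'
#' Mean aggregation over in-neighbors of the basis-weighted linear maps,
#' plus a root (self) weight and bias.
#'
#' @param gp a prepared graph (\code{\link{prepare_graph}}).
#' @param features V x in feature matrix.
#' @param kernel list with \code{W} ((in*out) x k^3 kernel matrices,
#'   column-major per basis index), \code{root} (in x out), \code{bias}
#'   (out).
#' @return V x out output features.
#' @export
spline_conv <- function(gp, features, kernel) {
  spline_conv_fwd(features, gp$src, gp$tgt, gp$bidx, gp$bw, gp$invdeg,
                  kernel$W, kernel$root, kernel$bias)
}

#' Configuration of the geometric surrogate network
#'
#' Defaults reproduce the published architecture: twelve spline-convolution
#' layers with sequentially increasing widths, a dense lift of the
#' concatenated local features to a 1,024-dimensional max-pooled global
#' vector, and a per-vertex regression head over the local+global
#' concatenation; 1,686,097 trainable parameters with four input channels.
#'
#' @param local_widths output width of each spline-conv layer.
#' @param global_dim width of the max-pooled global feature vector.
#' @param lift_widths widths of dense layers between the local concatenation
#'   and the global vector (the final entry must equal \code{global_dim}).
#' @param head_widths hidden widths of the per-vertex regression head.
#' @param in_channels input feature channels (curvature + unit normal = 4).
#' @param kernel_size B-spline kernel size per dimension (default 5).
#' @param activation \code{"elu"} (default) or \code{"relu"}.
#' @param dropout dropout rate on head hidden layers (default 0.1).
#' @param lr Adam learning rate (default 0.001).
#' @param batch_size graphs per optimization step (default 16).
#' @param epochs training epochs (default 300).
#' @param loss \code{"l1"}, \code{"l2"} or \code{"smooth_l1"}.
#' @param target_transform \code{"none"} or \code{"log1p"} applied to ECAP
#'   targets during training (inverted at prediction).
#' @return a list of class \code{geo_config}.
#' @export
geo_config <- function(local_widths = c(16, 16, 16, 16, 16, 16, 16, 16, 16,
                                        32, 32, 128),
                       global_dim = 1024,
                       lift_widths = global_dim,
                       head_widths = c(256, 64),
                       in_channels = 4, kernel_size = 5,
                       activation = "elu", dropout = 0.1, lr = 0.001,
                       batch_size = 16, epochs = 300, loss = "l1",
                       target_transform = "none") {
  if (any(local_widths < 1)) stop("widths must be >= 1")
  if (utils::tail(lift_widths, 1) != global_dim)
    stop("last lift width must equal global_dim")
  structure(list(local_widths = local_widths, global_dim = global_dim,
                 lift_widths = lift_widths, head_widths = head_widths,
                 in_channels = in_channels, kernel_size = kernel_size,
                 activation = activation, dropout = dropout, lr = lr,
                 batch_size = batch_size, epochs = epochs, loss = loss,
                 target_transform = target_transform),
            class = "geo_config")
}

new_spline_kernel <- function(in_ch, out_ch, k) {
  K <- k^3
  # neighbor and root paths each see fan-in in_ch; the 8 active basis
  # products sum to 1, so scale like a dense layer
  list(W = matrix(stats::rnorm(in_ch * out_ch * K, sd = sqrt(1 / in_ch)),
                  in_ch * out_ch, K),
       root = matrix(stats::rnorm(in_ch * out_ch, sd = sqrt(1 / in_ch)),
                     in_ch, out_ch),
       bias = numeric(out_ch))
}

#' Build the geometric surrogate model
#'
#' @param config a \code{geo_config}.
#' @param seed RNG seed for weight initialization.
#' @return object of class \code{geo_model}.
#' @export
build_geometric_model <- function(config = geo_config(), seed = 1) {
  set.seed(seed)
  k <- config$kernel_size
  widths <- config$local_widths
  conv <- vector("list", length(widths))
  in_ch <- config$in_channels
  for (l in seq_along(widths)) {
    conv[[l]] <- new_spline_kernel(in_ch, widths[l], k)
    in_ch <- widths[l]
  }
  C <- sum(widths)
  lift <- nn_init_dense(c(C, config$lift_widths))
  head <- nn_init_dense(c(C + config$global_dim, config$head_widths, 1))
  structure(list(params = list(conv = conv, lift = lift, head = head),
                 config = config),
            class = "geo_model")
}

#' @export
count_parameters.geo_model <- function(model, ...) {
  count_params_list(model$params)
}

#' @export
print.geo_model <- function(x, ...) {
  cat(sprintf(
    "geo_model: %d spline-conv layers (%s), global dim %d | %s parameters\n",
    length(x$config$local_widths),
    paste(x$config$local_widths, collapse = ","),
    x$config$global_dim,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# forward pass; returns prediction and cache for backward
geo_forward <- function(model, gp, training = FALSE) {
  cfg <- model$config
  act <- cfg$activation
  conv <- model$params$conv
  L <- length(conv)
  h <- gp$features
  zs <- vector("list", L); hs <- vector("list", L)
  for (l in seq_len(L)) {
    z <- spline_conv_fwd(h, gp$src, gp$tgt, gp$bidx, gp$bw, gp$invdeg,
                         conv[[l]]$W, conv[[l]]$root, conv[[l]]$bias)
    zs[[l]] <- z
    h <- nn_act(z, act)
    hs[[l]] <- h
  }
  Hc <- do.call(cbind, hs)
  lift_cache <- nn_dense_forward_act_all(model$params$lift, Hc, act)
  aJ <- lift_cache$h[[length(lift_cache$h)]]
  amax <- max.col(t(aJ), ties.method = "first")  # argmax vertex per channel
  g <- aJ[cbind(amax, seq_len(ncol(aJ)))]
  U <- cbind(Hc, matrix(g, nrow(Hc), length(g), byrow = TRUE))
  head_cache <- nn_dense_forward(model$params$head, U, act,
                                 cfg$dropout, training = training)
  pred <- as.vector(head_cache$h[[length(head_cache$h)]])
  list(pred = pred, zs = zs, hs = hs, Hc = Hc, lift_cache = lift_cache,
       amax = amax, head_cache = head_cache, U = U)
}

# dense forward where every layer (incl. the last) gets the activation
nn_dense_forward_act_all <- function(layers, X, activation) {
  L <- length(layers)
  cache <- list(h = vector("list", L + 1), z = vector("list", L))
  cache$h[[1]] <- X
  h <- X
  for (l in seq_len(L)) {
    z <- sweep(h %*% layers[[l]]$W, 2, layers[[l]]$b, "+")
    cache$z[[l]] <- z
    h <- nn_act(z, activation)
    cache$h[[l + 1]] <- h
  }
  cache
}

nn_dense_backward_act_all <- function(layers, cache, gout, activation) {
  L <- length(layers)
  grads <- vector("list", L)
  g <- gout
  for (l in rev(seq_len(L))) {
    y <- cache$h[[l + 1]]
    g <- g * nn_act_grad(cache$z[[l]], y, activation)
    grads[[l]] <- list(W = crossprod(cache$h[[l]], g), b = colSums(g))
    if (l > 1) g <- tcrossprod(g, layers[[l]]$W)
  }
  list(grads = grads,
       ginput = if (L >= 1) tcrossprod(g, layers[[1]]$W) else gout)
}

geo_backward <- function(model, gp, fw, gpred) {
  cfg <- model$config
  act <- cfg$activation
  conv <- model$params$conv
  L <- length(conv)
  widths <- cfg$local_widths
  gout <- matrix(gpred, ncol = 1)
  hb <- nn_dense_backward(model$params$head, fw$head_cache, gout, act,
                          cfg$dropout)
  C <- sum(widths)
  gU <- hb$ginput
  gHc <- gU[, seq_len(C), drop = FALSE]
  gg <- colSums(gU[, C + seq_len(cfg$global_dim), drop = FALSE])
  # max-pool routes each global channel's gradient to its argmax vertex
  gaJ <- matrix(0, gp$n_nodes, cfg$global_dim)
  gaJ[cbind(fw$amax, seq_len(cfg$global_dim))] <- gg
  lb <- nn_dense_backward_act_all(model$params$lift, fw$lift_cache, gaJ, act)
  gHc <- gHc + lb$ginput
  # split concat gradient and run conv layers backwards
  offs <- c(0, cumsum(widths))
  gconv <- vector("list", L)
  gh_next <- NULL   # gradient wrt h_l accumulated from layer l+1
  for (l in rev(seq_len(L))) {
    gh <- gHc[, (offs[l] + 1):offs[l + 1], drop = FALSE]
    if (!is.null(gh_next)) gh <- gh + gh_next
    gz <- gh * nn_act_grad(fw$zs[[l]], fw$hs[[l]], act)
    hin <- if (l == 1) gp$features else fw$hs[[l - 1]]
    bw <- spline_conv_bwd(hin, gp$src, gp$tgt, gp$bidx, gp$bw, gp$invdeg,
                          conv[[l]]$W, conv[[l]]$root, gz)
    gconv[[l]] <- list(W = bw$gW, root = bw$groot, bias = bw$gbias)
    gh_next <- if (l > 1) bw$gF
  }
  list(conv = gconv, lift = lb$grads, head = hb$grads)
}

#' Per-vertex input features for the geometric surrogate
#'
#' Channel 1 is the power-transformed (Yeo-Johnson, lambda fitted on the
#' pooled training vertices) and z-scored mean curvature; channels 2-4 are
#' the unit vertex normals. The fitted transform record is reused verbatim
#' on test meshes.
#'
#' @param meshes list of \code{surface_mesh} training meshes.
#' @return list with \code{features} (per-mesh V x 4 matrices) and
#'   \code{record} (lambda, mean, sd) for reuse via
#'   \code{\link{apply_vertex_features}}.
#' @export
preprocess_vertex_features <- function(meshes) {
  curv <- lapply(meshes, vertex_curvature, kind = "mean")
  pool <- unlist(curv)
  if (stats::sd(pool) == 0) stop("constant curvature across training pool")
  lambda <- fit_yeo_johnson(pool)
  tpool <- yeo_johnson(pool, lambda)
  record <- list(lambda = lambda, mean = mean(tpool), sd = stats::sd(tpool))
  feats <- Map(function(m, cv) {
    tc <- (yeo_johnson(cv, lambda) - record$mean) / record$sd
    cbind(tc, vertex_normals(m))
  }, meshes, curv)
  list(features = feats, record = record)
}

#' Apply a stored feature transform to a mesh
#' @param mesh a \code{surface_mesh}.
#' @param record transform record from
#'   \code{\link{preprocess_vertex_features}}.
#' @return V x 4 feature matrix.
#' @export
apply_vertex_features <- function(mesh, record) {
  cv <- vertex_curvature(mesh, kind = "mean")
  tc <- (yeo_johnson(cv, record$lambda) - record$mean) / record$sd
  cbind(tc, vertex_normals(mesh))
}

# Yeo-Johnson power transform and profile-likelihood lambda fit
yeo_johnson <- function(x, lambda) {
  pos <- x >= 0
  out <- numeric(length(x))
  if (abs(lambda) > 1e-10) {
    out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  } else out[pos] <- log1p(x[pos])
  if (abs(lambda - 2) > 1e-10) {
    out[!pos] <- -((1 - x[!pos])^(2 - lambda) - 1) / (2 - lambda)
  } else out[!pos] <- -log1p(-x[!pos])
  out
}

fit_yeo_johnson <- function(x, interval = c(-3, 5)) {
  n <- length(x)
  loglik <- function(lambda) {
    z <- yeo_johnson(x, lambda)
    s2 <- stats::var(z) * (n - 1) / n
    -0.5 * n * log(s2) + (lambda - 1) * sum(sign(x) * log1p(abs(x)))
  }
  stats::optimize(loglik, interval, maximum = TRUE)$maximum
}

#' Train the geometric surrogate
#'
#' Minibatched Adam on the configured loss over (graph, target) pairs, with
#' best-validation checkpoint selection. Deterministic per seed.
#'
#' @param model a \code{geo_model}.
#' @param train list of cases, each \code{list(graph = prepared graph,
#'   target = per-vertex ECAP)}.
#' @param val validation cases in the same form (defaults to \code{train}).
#' @param seed RNG seed (default 1).
#' @param verbose print per-epoch losses.
#' @return the trained model with \code{history} and \code{best_epoch}.
#' @export
train_geometric <- function(model, train, val = train, seed = 1,
                            verbose = FALSE) {
  if (length(train) < 2) stop("need at least 2 training graphs")
  cfg <- model$config
  set.seed(seed)
  tt <- cfg$target_transform
  tr_y <- lapply(train, function(cs) transform_target(cs$target, tt))
  va_y <- lapply(val, function(cs) transform_target(cs$target, tt))
  opt <- adam_new(model$params, lr = cfg$lr)
  params <- model$params
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  n <- length(train)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      model$params <- params
      gacc <- NULL
      bl <- 0
      for (i in bt) {
        fw <- geo_forward(model, train[[i]]$graph, training = TRUE)
        ls <- nn_loss(fw$pred, tr_y[[i]], cfg$loss)
        if (!is.finite(ls$value))
          stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
        bl <- bl + ls$value
        gr <- geo_backward(model, train[[i]]$graph, fw, ls$grad)
        gacc <- if (is.null(gacc)) gr else add_grads(gacc, gr)
      }
      gacc <- scale_grads(gacc, 1 / length(bt))
      st <- adam_step(opt, params, gacc)
      opt <- st$state; params <- st$params
      ep_loss <- ep_loss + bl
    }
    ep_loss <- ep_loss / n
    model$params <- params
    vl <- mean(vapply(seq_along(val), function(i) {
      fw <- geo_forward(model, val[[i]]$graph, training = FALSE)
      nn_loss(fw$pred, va_y[[i]], cfg$loss)$value
    }, numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %d train %.5f val %.5f", ep,
                                 ep_loss, vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

add_grads <- function(a, b) {
  rec <- function(x, y) {
    if (is.list(x)) Map(rec, x, y) else x + y
  }
  rec(a, b)
}

scale_grads <- function(a, s) {
  rapply(a, function(x) x * s, how = "replace")
}

#' Predict a per-vertex ECAP field on a mesh
#'
#' @param model a trained \code{geo_model}.
#' @param mesh a \code{surface_mesh}, or a prepared graph from
#'   \code{\link{prepare_graph}} (with features set).
#' @param record feature transform record (required when a mesh is given).
#' @return numeric per-vertex prediction on the original ECAP scale.
#' @export
predict_geometric <- function(model, mesh, record = NULL) {
  gp <- if (inherits(mesh, "surface_mesh")) {
    if (is.null(record)) stop("feature transform record required for a mesh")
    feats <- apply_vertex_features(mesh, record)
    prepare_graph(mesh_to_graph(mesh, feats), k = model$config$kernel_size)
  } else mesh
  fw <- geo_forward(model, gp, training = FALSE)
  out <- inverse_transform_target(fw$pred, model$config$target_transform)
  if (!all(is.finite(out))) stop("non-finite prediction")
  out
}
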