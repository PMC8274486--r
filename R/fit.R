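# Modelling front-end: one fitting function over the three surrogate
# families, returning a classed fit object with predict/print/summary/plot
# methods. Geometry-side preprocessing (feature transforms, shape model,
# flattening) is fitted on the training cases only and stored in the fit.

#' Fit an ECAP surrogate model
#'
#' Trains one of the surrogate families on the cases of an
#' \code{laa_dataset}:
#' \describe{
#'   \item{geometric}{spline-kernel graph network on curvature+normal
#'     features with edge pseudo-coordinates (operates on meshes of any
#'     vertex count).}
#'   \item{pca_fcn}{truncated-PCA shape coefficients fed to a dense
#'     regressor predicting ECAP on the corresponded template.}
#'   \item{unet_bullseye / unet_cartesian}{encoder-decoder image regressor
#'     over flattened maps (xyz channels in, ECAP out), masked loss for the
#'     bull's-eye representation.}
#' }
#'
#' @param data an \code{laa_dataset} (see \code{\link{make_dataset}}).
#' @param arch surrogate family.
#' @param train_ids indices of training cases.
#' @param val_ids indices of validation cases for checkpoint selection
#'   (default: the training cases).
#' @param config named list of family-specific settings; recognized
#'   entries: \code{geo} (a \code{geo_config}), \code{fcn} (an
#'   \code{fcn_config}), \code{unet} (a \code{unet_config}), \code{M}
#'   (PCA components, default 32), \code{grid} (flattening resolution,
#'   default 32).
#' @param seed RNG seed for initialization and training.
#' @return an object of class \code{c("ecap_fit_<arch>", "ecap_fit")}.
#' @export
fit_ecap_surrogate <- function(data, arch = c("geometric", "pca_fcn",
                                              "unet_bullseye",
                                              "unet_cartesian"),
                               train_ids, val_ids = NULL, config = list(),
                               seed = 1) {
  arch <- match.arg(arch)
  if (is.null(val_ids)) val_ids <- train_ids
  fit <- switch(arch,
                geometric = fit_geometric_arch(data, train_ids, val_ids,
                                               config, seed),
                pca_fcn = fit_pca_fcn_arch(data, train_ids, val_ids, config,
                                           seed),
                unet_bullseye = fit_unet_arch(data, train_ids, val_ids,
                                              config, seed, bullseye = TRUE),
                unet_cartesian = fit_unet_arch(data, train_ids, val_ids,
                                               config, seed,
                                               bullseye = FALSE))
  fit$arch <- arch
  fit$train_ids <- train_ids
  fit$val_ids <- val_ids
  fit$seed <- seed
  class(fit) <- c(paste0("ecap_fit_", sub("_.*", "", arch)), "ecap_fit")
  fit
}

fit_geometric_arch <- function(data, train_ids, val_ids, config, seed) {
  cfg <- config$geo %||% geo_config()
  # pooled feature transform fitted on training meshes only
  pool <- unlist(lapply(data$cases[train_ids], `[[`, "curvature"))
  lambda <- fit_yeo_johnson(pool)
  tpool <- yeo_johnson(pool, lambda)
  record <- list(lambda = lambda, mean = mean(tpool), sd = stats::sd(tpool))
  case_graph <- function(cs) {
    tc <- (yeo_johnson(cs$curvature, record$lambda) - record$mean) / record$sd
    g <- cs$graph
    g$node_features <- cbind(tc, cs$normals)
    list(graph = prepare_graph(g, k = cfg$kernel_size), target = cs$ecap)
  }
  train <- lapply(data$cases[train_ids], case_graph)
  val <- lapply(data$cases[val_ids], case_graph)
  model <- build_geometric_model(cfg, seed = seed)
  model <- train_geometric(model, train, val, seed = seed)
  list(model = model, feature_record = record, history = model$history)
}

fit_pca_fcn_arch <- function(data, train_ids, val_ids, config, seed) {
  M <- config$M %||% 32
  shapes <- data$coords[train_ids, , drop = FALSE]
  sm <- fit_shape_model(shapes, M, template_faces = data$template_faces)
  alph <- function(ids) t(vapply(ids, function(i)
    project_shape(data$coords[i, ], sm), numeric(sm$M)))
  targets <- function(ids) t(vapply(ids, function(i) data$cases[[i]]$ecap,
                                    numeric(length(data$cases[[1]]$ecap))))
  Vout <- length(data$cases[[1]]$ecap)
  fcfg <- config$fcn %||% fcn_config(input_dim = sm$M, output_dim = Vout)
  fcfg$input_dim <- sm$M; fcfg$output_dim <- Vout
  model <- build_fcn(fcfg, seed = seed)
  model <- train_fcn(model, alph(train_ids), targets(train_ids),
                     alph(val_ids), targets(val_ids), seed = seed)
  list(model = model, shape_model = sm, history = model$history)
}

#' Attach flattened representations to a dataset
#'
#' Computes, per case, the heat-method geodesic depth from the ostium, the
#' (depth x angle) flat map with xyz channels, and the ECAP target grid.
#' Required before fitting the image surrogates.
#'
#' @param data an \code{laa_dataset}.
#' @param R,A flattening resolution (default 32 x 32).
#' @return the dataset with \code{flat} and \code{target_grid} per case.
#' @export
add_flat_maps <- function(data, R = 32, A = 32) {
  for (i in seq_along(data$cases)) {
    cs <- data$cases[[i]]
    d <- geodesic_distance(cs$mesh, cs$mesh$ostium_ring)
    fl <- build_flat_map(cs$mesh, d, cs$mesh$landmark, R = R, A = A)
    data$cases[[i]]$flat <- fl
    data$cases[[i]]$target_grid <- sample_to_grid(fl, cs$mesh, cs$ecap)
  }
  data$flat_resolution <- c(R, A)
  data
}

fit_unet_arch <- function(data, train_ids, val_ids, config, seed, bullseye) {
  if (is.null(data$cases[[train_ids[1]]]$flat))
    stop("dataset lacks flat maps; run add_flat_maps() first")
  R <- data$flat_resolution[1]; A <- data$flat_resolution[2]
  S <- config$S %||% R
  ucfg <- config$unet %||% unet_config(depth = max(1, log2(S) - 1),
                                       base_channels = 8)
  if (S %% 2^ucfg$depth != 0)
    stop("raster side ", S, " not divisible by 2^depth = ", 2^ucfg$depth)
  case_rep <- function(cs) {
    if (bullseye) {
      be <- to_bullseye(cs$flat, S = S)
      tg <- to_bullseye(cs$flat, S = S,
                        values = array(cs$target_grid, c(R, A, 1)))
      list(image = be$image, target = tg$image[, , 1], mask = be$mask)
    } else {
      list(image = cs$flat$channels, target = cs$target_grid,
           mask = matrix(TRUE, R, A))
    }
  }
  reps <- lapply(data$cases, case_rep)
  std <- standardize_inputs(lapply(reps[train_ids], `[[`, "image"),
                            lapply(reps[train_ids], `[[`, "mask"))
  prep <- function(ids) lapply(ids, function(i) {
    r <- reps[[i]]
    r$image <- apply_standardize(r$image, std$record)
    r
  })
  model <- build_unet(ucfg, seed = seed,
                      input_size = if (bullseye) S else R)
  model <- train_unet(model, prep(train_ids), prep(val_ids), seed = seed)
  list(model = model, standardize_record = std$record, bullseye = bullseye,
       raster_size = S, history = model$history)
}

#' Predict per-vertex ECAP fields from a fitted surrogate
#'
#' @param object an \code{ecap_fit}.
#' @param newdata an \code{laa_dataset} (with flat maps for the image
#'   surrogates).
#' @param ids case indices to predict (default: all).
#' @param ... unused.
#' @return list of per-vertex prediction vectors on the ECAP scale.
#' @export
predict.ecap_fit <- function(object, newdata, ids = NULL, ...) {
  ids <- ids %||% seq_along(newdata$cases)
  switch(object$arch,
         geometric = lapply(newdata$cases[ids], function(cs) {
           tc <- (yeo_johnson(cs$curvature, object$feature_record$lambda) -
                    object$feature_record$mean) / object$feature_record$sd
           g <- cs$graph
           g$node_features <- cbind(tc, cs$normals)
           gp <- prepare_graph(g, k = object$model$config$kernel_size)
           predict_geometric(object$model, gp)
         }),
         pca_fcn = lapply(ids, function(i) {
           a <- project_shape(newdata$coords[i, ], object$shape_model)
           as.vector(predict_fcn(object$model, a))
         }),
         unet_bullseye = ,
         unet_cartesian = lapply(newdata$cases[ids], function(cs) {
           predict_unet_case(object, cs)
         }))
}

predict_unet_case <- function(object, cs) {
  fl <- cs$flat
  if (is.null(fl)) stop("case lacks a flat map; run add_flat_maps() first")
  R <- fl$grid_shape[1]; A <- fl$grid_shape[2]
  if (object$bullseye) {
    be <- to_bullseye(fl, S = object$raster_size)
    img <- apply_standardize(be$image, object$standardize_record)
    out <- predict_unet(object$model, img)
    grid <- bullseye_to_grid(out, R, A)
  } else {
    img <- apply_standardize(fl$channels, object$standardize_record)
    grid <- predict_unet(object$model, img)
  }
  unflatten(cs$mesh, fl, grid)
}

#' Sample a bull's-eye image back onto the (depth x angle) grid
#'
#' Inverse of the \code{\link{to_bullseye}} rasterization: each grid cell is
#' read off the image at its polar position by bilinear interpolation.
#'
#' @param image S x S matrix.
#' @param R,A grid resolution.
#' @return R x A matrix.
#' @export
bullseye_to_grid <- function(image, R, A) {
  S <- nrow(image)
  ctr <- (S + 1) / 2
  out <- matrix(0, R, A)
  for (r in seq_len(R)) {
    rho <- 1 - (r - 0.5) / R
    th <- 2 * pi * (seq_len(A) - 1) / A
    x <- rho * cos(th); y <- rho * sin(th)
    ci <- x * S / 2 + ctr   # column position
    ri <- y * S / 2 + ctr   # row position
    c0 <- pmin(pmax(floor(ci), 1), S - 1); tc <- ci - c0
    r0 <- pmin(pmax(floor(ri), 1), S - 1); tr <- ri - r0
    out[r, ] <- (1 - tr) * ((1 - tc) * image[cbind(r0, c0)] +
                              tc * image[cbind(r0, c0 + 1)]) +
      tr * ((1 - tc) * image[cbind(r0 + 1, c0)] +
              tc * image[cbind(r0 + 1, c0 + 1)])
  }
  out
}

#' @export
print.ecap_fit <- function(x, ...) {
  cat(sprintf("ecap_fit (%s): trained on %d cases, best epoch %d\n",
              x$arch, length(x$train_ids), x$model$best_epoch))
  cat(sprintf("  parameters: %s\n",
              format(count_parameters(x$model), big.mark = ",")))
  invisible(x)
}

#' @export
summary.ecap_fit <- function(object, ...) {
  h <- object$history
  cat(sprintf("ECAP surrogate fit: architecture %s\n", object$arch))
  cat(sprintf("  training cases: %d, validation cases: %d\n",
              length(object$train_ids), length(object$val_ids)))
  cat(sprintf("  trainable parameters: %s\n",
              format(count_parameters(object$model), big.mark = ",")))
  cat(sprintf("  epochs: %d, best validation loss %.5f at epoch %d\n",
              nrow(h), min(h$val_loss), object$model$best_epoch))
  invisible(object)
}

#' Plot training history of a fitted surrogate
#' @param x an \code{ecap_fit}.
#' @param ... passed to \code{matplot}.
#' @export
plot.ecap_fit <- function(x, ...) {
  h <- x$history
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("steelblue", "firebrick"),
                    xlab = "epoch", ylab = "loss", ...)
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}

#' Plot a bull's-eye map
#' @param be a \code{bullseye} object (or S x S matrix).
#' @param channel channel to draw for multi-channel images.
#' @param ... passed to \code{image}.
#' @export
plot_bullseye <- function(be, channel = 1, ...) {
  img <- if (inherits(be, "bullseye")) be$image[, , channel] else be
  graphics::image(t(img)[, nrow(img):1], asp = 1, axes = FALSE,
                  col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE), ...)
  invisible(be)
}
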