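# Encoder-decoder image regressor over flattened LAA maps: stride-2
# convolution blocks (3x3 kernels, per-image channel normalization, ReLU)
# with a mirrored nearest-neighbor-upsampling decoder, skip concatenations,
# a linear final convolution, and a masked L1 loss that ignores padded
# pixels. Channel widths double per block from base_channels, capped at
# max_channels.

#' Configuration of the encoder-decoder image surrogate
#'
#' @param depth encoder block count (default 7; a raster of side S requires
#'   S divisible by 2^depth).
#' @param base_channels width of the first block (default 32).
#' @param max_channels cap on channel doubling (default 512).
#' @param in_channels input channels (xyz coordinates = 3).
#' @param out_channels output channels (ECAP = 1).
#' @param lr Adam learning rate (default 5e-4).
#' @param epochs training epochs (default 300).
#' @param batch_size images per optimization step (default 8).
#' @param loss \code{"l1"} (default), \code{"l2"} or \code{"smooth_l1"}.
#' @param dropout dropout rate on decoder features (default 0.1).
#' @param circular_pad_angle treat the second image axis as periodic
#'   (Cartesian depth-angle maps); default FALSE.
#' @return a list of class \code{unet_config}.
#' @export
unet_config <- function(depth = 7, base_channels = 32, max_channels = 512,
                        in_channels = 3, out_channels = 1, lr = 5e-4,
                        epochs = 300, batch_size = 8, loss = "l1",
                        dropout = 0.1, circular_pad_angle = FALSE) {
  structure(list(depth = depth, base_channels = base_channels,
                 max_channels = max_channels, in_channels = in_channels,
                 out_channels = out_channels, lr = lr, epochs = epochs,
                 batch_size = batch_size, loss = loss, dropout = dropout,
                 circular_pad_angle = circular_pad_angle),
            class = "unet_config")
}

unet_channels <- function(config) {
  pmin(config$base_channels * 2^(seq_len(config$depth) - 1),
       config$max_channels)
}

new_conv <- function(cin, cout, kh = 3, kw = 3) {
  list(K = matrix(stats::rnorm(kh * kw * cin * cout,
                               sd = sqrt(2 / (kh * kw * cin))),
                  kh * kw * cin, cout),
       bias = numeric(cout),
       gamma = rep(1, cout), beta = numeric(cout))
}

#' Build the encoder-decoder surrogate
#'
#' @param config a \code{unet_config}.
#' @param seed RNG seed for initialization.
#' @param input_size raster side length the model will be applied to; used
#'   to check divisibility by 2^depth (default 128).
#' @return object of class \code{unet_model}.
#' @export
build_unet <- function(config = unet_config(), seed = 1, input_size = 128) {
  if (input_size %% 2^config$depth != 0)
    stop("raster side ", input_size, " must be divisible by 2^depth = ",
         2^config$depth)
  set.seed(seed)
  ch <- unet_channels(config)
  enc <- vector("list", config$depth)
  cin <- config$in_channels
  for (i in seq_len(config$depth)) {
    enc[[i]] <- new_conv(cin, ch[i])
    cin <- ch[i]
  }
  dec <- vector("list", config$depth)
  # dec[[i]] consumes upsampled deeper features + the skip at level i-1
  for (i in rev(seq_len(config$depth))) {
    up_ch <- if (i == config$depth) ch[i] else ch[i]
    skip_ch <- if (i == 1) config$in_channels else ch[i - 1]
    out_ch <- if (i == 1) config$base_channels else ch[i - 1]
    dec[[i]] <- new_conv(ch[i] + skip_ch, out_ch)
  }
  final <- new_conv(config$base_channels, config$out_channels)
  final$gamma <- NULL; final$beta <- NULL
  structure(list(params = list(enc = enc, dec = dec, final = final),
                 config = config),
            class = "unet_model")
}

#' @export
count_parameters.unet_model <- function(model, ...) {
  count_params_list(model$params)
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf("unet_model: depth %d, base %d channels | %s parameters\n",
              x$config$depth, x$config$base_channels,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

# per-image channel normalization (batch statistics at batch size one)
inorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  C <- dim(x)[3]
  mu <- apply(x, 3, mean)
  va <- apply(x, 3, function(s) mean((s - mean(s))^2))
  xhat <- x
  for (c in seq_len(C)) xhat[, , c] <- (x[, , c] - mu[c]) / sqrt(va[c] + eps)
  y <- xhat
  for (c in seq_len(C)) y[, , c] <- gamma[c] * xhat[, , c] + beta[c]
  list(y = y, xhat = xhat, mu = mu, va = va, eps = eps)
}

inorm_bwd <- function(cache, gamma, gy) {
  C <- dim(gy)[3]
  n <- prod(dim(gy)[1:2])
  gx <- gy
  ggamma <- numeric(C); gbeta <- numeric(C)
  for (c in seq_len(C)) {
    xh <- cache$xhat[, , c]
    g <- gy[, , c]
    ggamma[c] <- sum(g * xh)
    gbeta[c] <- sum(g)
    gxh <- g * gamma[c]
    iv <- 1 / sqrt(cache$va[c] + cache$eps)
    gx[, , c] <- iv * (gxh - mean(gxh) - xh * mean(gxh * xh))
  }
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

upsample2 <- function(x) {
  H <- dim(x)[1]; W <- dim(x)[2]; C <- dim(x)[3]
  idx_r <- rep(seq_len(H), each = 2)
  idx_c <- rep(seq_len(W), each = 2)
  x[idx_r, idx_c, , drop = FALSE]
}

downsample2_sum <- function(g) {
  H <- dim(g)[1] / 2; W <- dim(g)[2] / 2; C <- dim(g)[3]
  out <- array(0, c(H, W, C))
  for (c in seq_len(C)) {
    m <- g[, , c]
    out[, , c] <- m[seq(1, 2 * H, 2), seq(1, 2 * W, 2)] +
      m[seq(2, 2 * H, 2), seq(1, 2 * W, 2)] +
      m[seq(1, 2 * H, 2), seq(2, 2 * W, 2)] +
      m[seq(2, 2 * H, 2), seq(2, 2 * W, 2)]
  }
  out
}

relu3 <- function(x) { x[x < 0] <- 0; x }

unet_forward <- function(model, X, training = FALSE) {
  cfg <- model$config
  p <- model$params
  D <- cfg$depth
  hs <- vector("list", D + 1)  # hs[[1]] = input, hs[[i+1]] = encoder level i
  caches <- list(enc = vector("list", D), dec = vector("list", D))
  hs[[1]] <- X
  h <- X
  for (i in seq_len(D)) {
    z <- conv2d_fwd(h, p$enc[[i]]$K, p$enc[[i]]$bias, 3, 3, 2, 1)
    no <- inorm_fwd(z, p$enc[[i]]$gamma, p$enc[[i]]$beta)
    h <- relu3(no$y)
    caches$enc[[i]] <- list(x = hs[[i]], z = z, norm = no, h = h)
    hs[[i + 1]] <- h
  }
  d <- h
  for (i in rev(seq_len(D))) {
    up <- upsample2(d)
    skip <- hs[[i]]
    u <- abind3(up, skip)
    z <- conv2d_fwd(u, p$dec[[i]]$K, p$dec[[i]]$bias, 3, 3, 1, 1)
    no <- inorm_fwd(z, p$dec[[i]]$gamma, p$dec[[i]]$beta)
    h2 <- relu3(no$y)
    mask <- NULL
    if (training && cfg$dropout > 0) {
      mask <- array(stats::runif(length(h2)) >= cfg$dropout, dim(h2)) /
        (1 - cfg$dropout)
      h2 <- h2 * mask
    }
    caches$dec[[i]] <- list(u = u, z = z, norm = no, h = h2, din = d,
                            mask = mask, up_ch = dim(up)[3])
    d <- h2
  }
  z <- conv2d_fwd(d, p$final$K, p$final$bias, 3, 3, 1, 1)
  caches$final <- list(x = d, z = z)
  list(pred = z, caches = caches)
}

abind3 <- function(a, b) {
  out <- array(0, c(dim(a)[1], dim(a)[2], dim(a)[3] + dim(b)[3]))
  out[, , seq_len(dim(a)[3])] <- a
  out[, , dim(a)[3] + seq_len(dim(b)[3])] <- b
  out
}

unet_backward <- function(model, fw, gpred) {
  p <- model$params
  D <- model$config$depth
  caches <- fw$caches
  grads <- list(enc = vector("list", D), dec = vector("list", D))
  bwf <- conv2d_bwd(caches$final$x, p$final$K, gpred, 3, 3, 1, 1)
  grads$final <- list(K = bwf$gK, bias = bwf$gbias)
  gd <- bwf$gX                    # grad wrt dec[[1]] output
  gskip <- vector("list", D + 1)  # grad flowing into encoder outputs hs[[i]]
  # decoder levels shallow -> deep; each level's input is the next level's
  # output, so gd carries straight through the loop
  for (i in seq_len(D)) {
    cc <- caches$dec[[i]]
    if (!is.null(cc$mask)) gd <- gd * cc$mask
    gy <- gd; gy[cc$norm$y <= 0] <- 0
    nb <- inorm_bwd(cc$norm, p$dec[[i]]$gamma, gy)
    bw <- conv2d_bwd(cc$u, p$dec[[i]]$K, nb$gx, 3, 3, 1, 1)
    grads$dec[[i]] <- list(K = bw$gK, bias = bw$gbias,
                           gamma = nb$ggamma, beta = nb$gbeta)
    up_ch <- cc$up_ch
    gup <- bw$gX[, , seq_len(up_ch), drop = FALSE]
    gskip[[i]] <- bw$gX[, , up_ch + seq_len(dim(bw$gX)[3] - up_ch),
                        drop = FALSE]
    gd <- downsample2_sum(gup)
  }
  genc_out <- gd                  # grad wrt bottom features hs[[D+1]]
  for (i in rev(seq_len(D))) {
    cc <- caches$enc[[i]]
    g <- genc_out
    if (!is.null(gskip[[i + 1]])) g <- g + gskip[[i + 1]]
    gy <- g; gy[cc$norm$y <= 0] <- 0
    nb <- inorm_bwd(cc$norm, p$enc[[i]]$gamma, gy)
    bw <- conv2d_bwd(cc$x, p$enc[[i]]$K, nb$gx, 3, 3, 2, 1)
    grads$enc[[i]] <- list(K = bw$gK, bias = bw$gbias,
                           gamma = nb$ggamma, beta = nb$gbeta)
    genc_out <- bw$gX
  }
  grads
}

#' Masked L1 loss
#'
#' Mean absolute error over mask-true pixels only; padded regions do not
#' contribute to the loss or its gradient.
#'
#' @param pred,target numeric arrays of equal shape (H x W or H x W x C).
#' @param mask logical H x W matrix with at least one TRUE pixel.
#' @return scalar loss with gradient array attached as attribute
#'   \code{"grad"}.
#' @export
masked_l1 <- function(pred, target, mask) {
  if (!isTRUE(all(dim(pred) == dim(target))))
    stop("pred and target shapes differ")
  if (!any(mask)) stop("mask has no TRUE pixels")
  m <- if (length(dim(pred)) == 3)
    array(rep(mask, dim(pred)[3]), dim(pred)) else mask
  d <- (pred - target) * m
  n <- sum(m)
  val <- sum(abs(d)) / n
  attr(val, "grad") <- sign(d) / n
  val
}

#' Standardize image stacks for training
#'
#' Per-channel z-scoring with statistics computed over the mask-true pixels
#' of the training set only; the returned record is reused verbatim on test
#' data via \code{\link{apply_standardize}}.
#'
#' @param images list of H x W x C arrays.
#' @param masks list of H x W logical matrices (default: all-true).
#' @return list with standardized \code{images} and the transform
#'   \code{record} (per-channel mean and sd).
#' @export
standardize_inputs <- function(images, masks = NULL) {
  C <- dim(images[[1]])[3]
  if (is.null(masks))
    masks <- lapply(images, function(im) matrix(TRUE, dim(im)[1], dim(im)[2]))
  mu <- numeric(C); sdv <- numeric(C)
  for (c in seq_len(C)) {
    vals <- unlist(Map(function(im, mk) im[, , c][mk], images, masks))
    mu[c] <- mean(vals); sdv[c] <- stats::sd(vals)
    if (sdv[c] == 0) stop("zero variance in channel ", c)
  }
  record <- list(mean = mu, sd = sdv)
  list(images = lapply(images, apply_standardize, record = record),
       record = record)
}

#' Apply a stored standardization record to an image
#' @param image H x W x C array.
#' @param record transform record from \code{\link{standardize_inputs}}.
#' @return standardized array.
#' @export
apply_standardize <- function(image, record) {
  for (c in seq_len(dim(image)[3]))
    image[, , c] <- (image[, , c] - record$mean[c]) / record$sd[c]
  image
}

#' Train the encoder-decoder surrogate
#'
#' Minibatched Adam on the masked loss, best-validation checkpoint
#' selection; deterministic per seed. Inputs are expected standardized
#' (\code{\link{standardize_inputs}}).
#'
#' @param model a \code{unet_model}.
#' @param train list of cases \code{list(image, target, mask)}; target is
#'   H x W (single output channel).
#' @param val validation cases (defaults to \code{train}).
#' @param seed RNG seed.
#' @param verbose print per-epoch losses.
#' @return trained model with \code{history} and \code{best_epoch}.
#' @export
train_unet <- function(model, train, val = train, seed = 1, verbose = FALSE) {
  if (length(train) < 2) stop("need at least 2 training images")
  cfg <- model$config
  set.seed(seed)
  opt <- adam_new(model$params, lr = cfg$lr)
  params <- model$params
  best <- list(loss = Inf, params = params, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  n <- length(train)
  case_loss <- function(m, cs, training) {
    fw <- unet_forward(m, cs$image, training = training)
    pred <- fw$pred[, , 1]
    ls <- masked_l1(pred, cs$target, cs$mask)
    list(fw = fw, value = as.numeric(ls), grad = attr(ls, "grad"))
  }
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    ep_loss <- 0
    for (bt in batches) {
      model$params <- params
      gacc <- NULL
      for (i in bt) {
        cl <- case_loss(model, train[[i]], TRUE)
        if (!is.finite(cl$value))
          stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
        ep_loss <- ep_loss + cl$value
        gpred <- array(cl$grad, c(dim(cl$grad)[1], dim(cl$grad)[2], 1))
        gr <- unet_backward(model, cl$fw, gpred)
        gacc <- if (is.null(gacc)) gr else add_grads(gacc, gr)
      }
      gacc <- scale_grads(gacc, 1 / length(bt))
      st <- adam_step(opt, params, gacc)
      opt <- st$state; params <- st$params
    }
    ep_loss <- ep_loss / n
    model$params <- params
    vl <- mean(vapply(val, function(cs) case_loss(model, cs, FALSE)$value,
                      numeric(1)))
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = vl))
    if (verbose) message(sprintf("epoch %d train %.5f val %.5f",
                                 ep, ep_loss, vl))
    if (vl < best$loss) best <- list(loss = vl, params = params, epoch = ep)
  }
  model$params <- best$params
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Predict an output image
#' @param model a trained \code{unet_model}.
#' @param image standardized H x W x C input array.
#' @return H x W prediction matrix.
#' @export
predict_unet <- function(model, image) {
  unet_forward(model, image, training = FALSE)$pred[, , 1]
}
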