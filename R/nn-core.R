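# Minimal dense neural-network engine: He-initialized linear layers,
# ReLU/ELU activations, inverted dropout, L1/L2/smooth-L1 losses and Adam.
# All randomness flows through R's RNG so training is deterministic per seed.

nn_init_dense <- function(dims) {
  # dims: vector of layer sizes, input first
  layers <- vector("list", length(dims) - 1)
  for (l in seq_along(layers)) {
    fan_in <- dims[l]
    layers[[l]] <- list(
      W = matrix(stats::rnorm(fan_in * dims[l + 1], sd = sqrt(2 / fan_in)),
                 fan_in, dims[l + 1]),
      b = numeric(dims[l + 1]))
  }
  layers
}

nn_act <- function(x, kind) {
  switch(kind,
         relu = pmax(x, 0),
         elu = ifelse(x > 0, x, expm1(x)),
         identity = x,
         stop("unknown activation: ", kind))
}

nn_act_grad <- function(x, y, kind) {
  # derivative wrt pre-activation x (y = act(x))
  switch(kind,
         relu = (x > 0) * 1,
         elu = ifelse(x > 0, 1, y + 1),
         identity = array(1, dim(x)),
         stop("unknown activation: ", kind))
}

# forward through dense layers; hidden layers get activation + dropout,
# output layer is linear
nn_dense_forward <- function(layers, X, activation, dropout = 0,
                             training = FALSE) {
  L <- length(layers)
  cache <- list(h = vector("list", L + 1), z = vector("list", L),
                mask = vector("list", L))
  cache$h[[1]] <- X
  h <- X
  for (l in seq_len(L)) {
    z <- h %*% layers[[l]]$W
    z <- sweep(z, 2, layers[[l]]$b, "+")
    cache$z[[l]] <- z
    if (l < L) {
      h <- nn_act(z, activation)
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(h)) >= dropout, nrow(h), ncol(h)) /
          (1 - dropout)
        h <- h * mask
        cache$mask[[l]] <- mask
      }
    } else h <- z
    cache$h[[l + 1]] <- h
  }
  cache
}

nn_dense_backward <- function(layers, cache, gout, activation, dropout = 0) {
  L <- length(layers)
  grads <- vector("list", L)
  g <- gout
  for (l in rev(seq_len(L))) {
    if (l < L) {
      if (!is.null(cache$mask[[l]])) g <- g * cache$mask[[l]]
      hpre <- nn_act(cache$z[[l]], activation)
      g <- g * nn_act_grad(cache$z[[l]], hpre, activation)
    }
    grads[[l]] <- list(W = crossprod(cache$h[[l]], g), b = colSums(g))
    if (l > 1) g <- tcrossprod(g, layers[[l]]$W)
  }
  list(grads = grads, ginput = if (L >= 1) tcrossprod(g, layers[[1]]$W))
}

nn_loss <- function(pred, target, kind = "l1") {
  d <- pred - target
  switch(kind,
         l1 = list(value = mean(abs(d)), grad = sign(d) / length(d)),
         l2 = list(value = mean(d^2), grad = 2 * d / length(d)),
         smooth_l1 = {
           a <- abs(d)
           v <- ifelse(a < 1, 0.5 * d^2, a - 0.5)
           g <- ifelse(a < 1, d, sign(d))
           list(value = mean(v), grad = g / length(d))
         },
         stop("unknown loss: ", kind))
}

# ---- Adam over arbitrary nested parameter lists ---------------------------

adam_new <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  zeros <- rapply(params, function(p) p * 0, how = "replace")
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
       m = zeros, v = zeros, t = 0L)
}

adam_step <- function(state, params, grads) {
  state$t <- state$t + 1L
  b1 <- state$beta1; b2 <- state$beta2
  corr1 <- 1 - b1^state$t; corr2 <- 1 - b2^state$t
  walk <- function(p, g, m, v) {
    m <- b1 * m + (1 - b1) * g
    v <- b2 * v + (1 - b2) * g^2
    p <- p - state$lr * (m / corr1) / (sqrt(v / corr2) + state$eps)
    list(p = p, m = m, v = v)
  }
  rec <- function(p, g, m, v) {
    if (is.list(p)) {
      out <- list(p = p, m = m, v = v)
      for (nm in seq_along(p)) {
        r <- rec(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out$p[[nm]] <- r$p; out$m[[nm]] <- r$m; out$v[[nm]] <- r$v
      }
      out
    } else walk(p, g, m, v)
  }
  r <- rec(params, grads, state$m, state$v)
  state$m <- r$m; state$v <- r$v
  list(state = state, params = r$p)
}

count_params_list <- function(params) {
  sum(rapply(params, length, how = "unlist"))
}
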