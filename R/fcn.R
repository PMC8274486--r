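# Fully connected regressor from PCA shape coefficients to per-vertex ECAP
# on the registration template. Five hidden layers of sequentially
# increasing width by default; the default configuration has exactly
# 7,846,178 trainable parameters for a 2,466-vertex template.

#' Configuration for the shape-coefficient dense regressor
#'
#' @param input_dim number of shape coefficients (default 32).
#' @param hidden hidden-layer widths (default c(128, 256, 512, 1024, 2048)).
#' @param output_dim template vertex count (default 2466).
#' @param activation \code{"relu"} (default) or \code{"elu"}.
#' @param dropout dropout rate in [0, 1) (default 0.1).
#' @param lr Adam learning rate (default 0.01).
#' @param epochs training epochs (default 150).
#' @param loss \code{"l1"} (default), \code{"l2"} or \code{"smooth_l1"}.
#' @return a list of class \code{fcn_config}.
#' @export
fcn_config <- function(input_dim = 32, hidden = c(128, 256, 512, 1024, 2048),
                       output_dim = 2466, activation = "relu", dropout = 0.1,
                       lr = 0.01, epochs = 150, loss = "l1") {
  if (!length(hidden)) stop("hidden width list must be non-empty")
  if (any(c(input_dim, hidden, output_dim) < 1)) stop("all widths must be >= 1")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(input_dim = input_dim, hidden = hidden,
                 output_dim = output_dim, activation = activation,
                 dropout = dropout, lr = lr, epochs = epochs, loss = loss),
            class = "fcn_config")
}

#' Build the dense shape-to-ECAP regressor
#'
#' @param config an \code{fcn_config}.
#' @param seed RNG seed for weight initialization (default 1).
#' @return object of class \code{fcn_model}.
#' @export
build_fcn <- function(config = fcn_config(), seed = 1) {
  set.seed(seed)
  dims <- c(config$input_dim, config$hidden, config$output_dim)
  structure(list(layers = nn_init_dense(dims), config = config),
            class = "fcn_model")
}

#' Count trainable parameters
#' @param model a model object.
#' @param ... unused.
#' @return integer parameter count.
#' @export
count_parameters <- function(model, ...) UseMethod("count_parameters")

#' @export
count_parameters.fcn_model <- function(model, ...) {
  count_params_list(model$layers)
}

#' @export
print.fcn_model <- function(x, ...) {
  cat(sprintf("fcn_model: %s -> %d | %s parameters\n",
              paste(c(x$config$input_dim, x$config$hidden), collapse = " -> "),
              x$config$output_dim,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Train the dense regressor
#'
#' Full-batch Adam with the configured loss; the parameter state with the
#' best validation loss across epochs is returned. Deterministic per seed.
#'
#' @param model an \code{fcn_model}.
#' @param train_x,train_y training inputs (n x input_dim) and targets
#'   (n x output_dim).
#' @param val_x,val_y validation pairs used for checkpoint selection.
#' @param seed RNG seed controlling dropout (default 1).
#' @return the trained model with a \code{history} data frame
#'   (epoch, train_loss, val_loss) and \code{best_epoch} attached.
#' @export
train_fcn <- function(model, train_x, train_y, val_x = train_x,
                      val_y = train_y, seed = 1) {
  train_x <- as.matrix(train_x); train_y <- as.matrix(train_y)
  val_x <- as.matrix(val_x); val_y <- as.matrix(val_y)
  if (nrow(train_x) < 2) stop("need at least 2 training pairs")
  cfg <- model$config
  set.seed(seed)
  opt <- adam_new(model$layers, lr = cfg$lr)
  best <- list(loss = Inf, layers = model$layers, epoch = 0L)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     val_loss = numeric(0))
  layers <- model$layers
  for (ep in seq_len(cfg$epochs)) {
    cache <- nn_dense_forward(layers, train_x, cfg$activation, cfg$dropout,
                              training = TRUE)
    pred <- cache$h[[length(cache$h)]]
    ls <- nn_loss(pred, train_y, cfg$loss)
    if (!is.finite(ls$value))
      stop("NaN/Inf loss at epoch ", ep, "; lower the learning rate")
    bk <- nn_dense_backward(layers, cache, ls$grad, cfg$activation, cfg$dropout)
    st <- adam_step(opt, layers, bk$grads)
    opt <- st$state; layers <- st$params
    vcache <- nn_dense_forward(layers, val_x, cfg$activation, 0, training = FALSE)
    vl <- nn_loss(vcache$h[[length(vcache$h)]], val_y, cfg$loss)$value
    hist <- rbind(hist, data.frame(epoch = ep, train_loss = ls$value,
                                   val_loss = vl))
    if (vl < best$loss) best <- list(loss = vl, layers = layers, epoch = ep)
  }
  model$layers <- best$layers
  model$history <- hist
  model$best_epoch <- best$epoch
  model
}

#' Predict per-vertex values from shape coefficients
#'
#' @param model a trained \code{fcn_model}.
#' @param alphas coefficient vector or matrix (B x input_dim).
#' @return numeric vector (output_dim) or matrix (B x output_dim).
#' @export
predict_fcn <- function(model, alphas) {
  single <- is.null(dim(alphas))
  X <- if (single) matrix(alphas, 1) else as.matrix(alphas)
  if (ncol(X) != model$config$input_dim)
    stop("expected ", model$config$input_dim, " shape coefficients, got ",
         ncol(X))
  cache <- nn_dense_forward(model$layers, X, model$config$activation, 0,
                            training = FALSE)
  out <- cache$h[[length(cache$h)]]
  if (single) as.vector(out) else out
}
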