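# Truncated-PCA statistical shape model over corresponded meshes.
#
# Shapes are encoded as flattened (3V) coordinate vectors. With mean shape
# Xbar, orthonormal eigenvector rows W_i and eigenvalues lambda_i of the
# sample covariance, a shape is synthesized as
#   X = Xbar + sum_i alpha_i lambda_i W_i
# and projected as
#   alpha_i = W_i . (Y - Xbar) / lambda_i ,
# the eigenvalue (not square-root) scaling. A `scaling = "sqrt"` switch uses
# sqrt(lambda_i) instead; the roundtrip is self-consistent either way.

#' Fit a truncated-PCA shape model
#'
#' @param shapes list of corresponded \code{surface_mesh} objects (shared
#'   vertex count and faces), or a numeric matrix (n x 3V) of flattened
#'   coordinates.
#' @param M number of principal components to retain; capped at
#'   min(M, n - 1, 3V) with a warning when capped.
#' @param template_faces faces matrix when \code{shapes} is a matrix.
#' @return object of class \code{shape_model} with \code{mean_shape} (3V),
#'   \code{components} (M x 3V, orthonormal rows), \code{eigenvalues}
#'   (non-increasing, > 0), \code{M}, \code{template_faces}.
#' @export
fit_shape_model <- function(shapes, M, template_faces = NULL) {
  if (is.list(shapes) && inherits(shapes[[1]], "surface_mesh")) {
    faces0 <- shapes[[1]]$faces
    V0 <- nrow(shapes[[1]]$vertices)
    for (s in seq_along(shapes)) {
      if (nrow(shapes[[s]]$vertices) != V0 ||
          !identical(shapes[[s]]$faces, faces0))
        stop("inconsistent topology at sample ", s,
             "; all shapes must share vertex count and faces")
    }
    X <- t(vapply(shapes, function(m) as.vector(t(m$vertices)),
                  numeric(3 * V0)))
    template_faces <- faces0
  } else {
    X <- as.matrix(shapes)
  }
  n <- nrow(X)
  if (n < 2) stop("need at least 2 shapes")
  mean_shape <- colMeans(X)
  Xc <- sweep(X, 2, mean_shape)
  sv <- svd(Xc, nu = 0)
  lam <- sv$d^2 / (n - 1)
  keep <- lam > max(lam) * 1e-12
  lam <- lam[keep]
  W <- t(sv$v[, keep, drop = FALSE])
  cap <- min(n - 1, ncol(X), length(lam))
  Mreq <- M
  M <- min(M, cap)
  if (M < Mreq)
    warning(sprintf("requested %d components; capped at %d (n = %d samples)",
                    Mreq, M, n))
  structure(list(mean_shape = mean_shape,
                 components = W[seq_len(M), , drop = FALSE],
                 eigenvalues = lam[seq_len(M)],
                 M = M, template_faces = template_faces),
            class = "shape_model")
}

#' @export
print.shape_model <- function(x, ...) {
  cat(sprintf("shape_model: %d components over %d coordinates\n",
              x$M, length(x$mean_shape)))
  cat("  eigenvalues:", paste(signif(utils::head(x$eigenvalues, 5), 4),
                              collapse = ", "),
      if (x$M > 5) "..." else "", "\n")
  invisible(x)
}

shape_to_vec <- function(shape) {
  if (inherits(shape, "surface_mesh")) as.vector(t(shape$vertices))
  else as.numeric(shape)
}

#' Project a corresponded shape onto the model
#'
#' @param shape a corresponded \code{surface_mesh} or flattened coordinate
#'   vector matching the template.
#' @param model a \code{shape_model}.
#' @param scaling \code{"eigenvalue"} (default; divide by lambda_i) or
#'   \code{"sqrt"} (divide by sqrt(lambda_i)).
#' @return numeric vector of M shape coefficients alpha.
#' @export
project_shape <- function(shape, model, scaling = c("eigenvalue", "sqrt")) {
  scaling <- match.arg(scaling)
  y <- shape_to_vec(shape)
  if (length(y) != length(model$mean_shape))
    stop("shape does not match template topology")
  sc <- if (scaling == "eigenvalue") model$eigenvalues else sqrt(model$eigenvalues)
  as.vector(model$components %*% (y - model$mean_shape)) / sc
}

#' Reconstruct a shape from model coefficients
#'
#' @param alphas numeric coefficient vector (length <= M).
#' @param model a \code{shape_model}.
#' @param scaling as in \code{\link{project_shape}}.
#' @return a \code{surface_mesh} when template faces are available, else the
#'   flattened coordinate vector.
#' @export
reconstruct_shape <- function(alphas, model, scaling = c("eigenvalue", "sqrt")) {
  scaling <- match.arg(scaling)
  if (length(alphas) > model$M) stop("more coefficients than components")
  sc <- if (scaling == "eigenvalue") model$eigenvalues else sqrt(model$eigenvalues)
  k <- length(alphas)
  x <- model$mean_shape +
    as.vector(crossprod(model$components[seq_len(k), , drop = FALSE],
                        alphas * sc[seq_len(k)]))
  if (is.null(model$template_faces)) return(x)
  surface_mesh(matrix(x, ncol = 3, byrow = TRUE), model$template_faces,
               validate = FALSE)
}

#' Explained-variance ratio of the leading components
#' @param model a \code{shape_model}.
#' @param total_variance total variance of the training set (defaults to the
#'   sum of the model's eigenvalues, i.e. the retained spectrum).
#' @return cumulative fraction of variance per component count.
#' @export
explained_variance <- function(model, total_variance = sum(model$eigenvalues)) {
  cumsum(model$eigenvalues) / total_variance
}
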