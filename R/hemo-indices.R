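# Wall-shear-stress indices: TAWSS, OSI and the endothelial cell activation
# potential ECAP = OSI / TAWSS, computed from a per-vertex WSS vector time
# series over one cardiac cycle, plus the target transforms applied to ECAP
# maps before surrogate training.

#' Construct a wall-shear-stress time series
#'
#' @param times strictly increasing sample times, s (length K >= 1).
#' @param values numeric array (K x V x 3) of per-vertex WSS vectors, Pa.
#' @param period cycle duration T, s.
#' @return object of class \code{wss_series}.
#' @export
wss_series <- function(times, values, period) {
  times <- as.numeric(times)
  if (length(dim(values)) != 3 || dim(values)[3] != 3)
    stop("values must be a K x V x 3 array")
  if (length(times) != dim(values)[1])
    stop("times length must match first dimension of values")
  if (length(times) > 1 && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (!all(is.finite(values))) stop("non-finite WSS values")
  dt <- series_dt(times, period)
  if (any(dt <= 0)) stop("non-positive sample duration; check times vs period")
  if (abs(sum(dt) - period) > 1e-9 * period)
    stop("sample durations do not sum to the period")
  structure(list(times = times, values = values, period = period),
            class = "wss_series")
}

# left-sample durations: dt_k = t_{k+1} - t_k, last = T - t_K + t_1
series_dt <- function(times, period) {
  K <- length(times)
  if (K == 1) return(period)
  c(diff(times), period - times[K] + times[1])
}

#' Time-averaged mean vector and mean magnitude of a WSS series
#'
#' Piecewise-constant (left-sample) quadrature, exact for step-function
#' series: each sample holds from its own time to the next (cyclically).
#'
#' @param series a \code{wss_series}.
#' @return list with \code{mean_vector} (V x 3) and \code{mean_magnitude}
#'   (length V).
#' @export
integrate_series <- function(series) {
  dt <- series_dt(series$times, series$period)
  K <- dim(series$values)[1]; V <- dim(series$values)[2]
  w <- dt / series$period
  mv <- matrix(0, V, 3)
  mm <- numeric(V)
  for (k in seq_len(K)) {
    tau <- series$values[k, , , drop = FALSE]
    dim(tau) <- c(V, 3)
    mv <- mv + w[k] * tau
    mm <- mm + w[k] * sqrt(rowSums(tau^2))
  }
  list(mean_vector = mv, mean_magnitude = mm)
}

#' Time-averaged wall shear stress
#' @param series a \code{wss_series}.
#' @return numeric vector (V) of TAWSS values, Pa.
#' @export
tawss <- function(series) integrate_series(series)$mean_magnitude

#' Oscillatory shear index
#'
#' OSI = 0.5 (1 - |mean vector| / mean magnitude), clipped to [0, 0.5];
#' defined as 0 where the series is identically zero.
#'
#' @param series a \code{wss_series}.
#' @return numeric vector (V) of OSI values in [0, 0.5].
#' @export
osi <- function(series) {
  m <- integrate_series(series)
  num <- sqrt(rowSums(m$mean_vector^2))
  out <- ifelse(m$mean_magnitude > 0,
                0.5 * (1 - num / m$mean_magnitude), 0)
  pmin(0.5, pmax(0, out))
}

#' Endothelial cell activation potential
#'
#' ECAP = OSI / TAWSS per vertex, with the denominator floored at \code{eps}
#' so vanishing shear yields a large finite value rather than infinity.
#'
#' @param tawss numeric vector of TAWSS values (>= 0), Pa.
#' @param osi numeric vector of OSI values in [0, 0.5].
#' @param eps denominator floor (default 1e-8).
#' @return numeric vector of ECAP values, 1/Pa.
#' @export
ecap <- function(tawss, osi, eps = 1e-8) {
  if (length(tawss) != length(osi)) stop("tawss and osi lengths differ")
  if (any(tawss < 0)) stop("negative TAWSS")
  if (any(osi < -1e-12) || any(osi > 0.5 + 1e-12)) stop("OSI outside [0, 0.5]")
  osi / pmax(tawss, eps)
}

#' Compute all hemodynamic index fields from a WSS series
#'
#' @param series a \code{wss_series}.
#' @param eps ECAP denominator floor.
#' @return list with \code{tawss}, \code{osi}, \code{ecap} vertex fields.
#' @export
hemo_fields <- function(series, eps = 1e-8) {
  m <- integrate_series(series)
  tw <- m$mean_magnitude
  num <- sqrt(rowSums(m$mean_vector^2))
  os <- pmin(0.5, pmax(0, ifelse(tw > 0, 0.5 * (1 - num / tw), 0)))
  list(tawss = tw, osi = os, ecap = os / pmax(tw, eps))
}

#' Forward target transform for surrogate training
#'
#' \code{log1p} maps x to log(1 + x), admitting exact zeros; used for
#' heavily right-skewed ECAP distributions.
#'
#' @param field numeric vector (nonnegative for \code{log1p}).
#' @param mode \code{"none"} or \code{"log1p"}.
#' @return transformed field.
#' @export
transform_target <- function(field, mode = c("none", "log1p")) {
  mode <- match.arg(mode)
  if (mode == "none") return(field)
  if (any(field < 0)) stop("log1p transform requires nonnegative input")
  log1p(field)
}

#' Inverse of \code{transform_target}
#' @param field transformed field.
#' @param mode \code{"none"} or \code{"log1p"}.
#' @return field on the original scale.
#' @export
inverse_transform_target <- function(field, mode = c("none", "log1p")) {
  mode <- match.arg(mode)
  if (mode == "none") field else expm1(field)
}
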