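#' Tuning parameters for Huber M-estimation
#'
#' @param k positive tuning constant of the Huber loss: residuals within
#'   `k` robust standard deviations are treated quadratically, larger ones
#'   linearly. The default 1.345 gives 95% efficiency at the Gaussian model.
#' @param max_iter maximum number of IRLS iterations.
#' @param tol relative convergence tolerance on the coefficients:
#'   iteration stops when `max_j |b_new - b_old| / max(1, |b_old|) < tol`.
#' @param scale_floor if the robust residual scale falls to or below this
#'   value the data are treated as noise-free: the current least-squares
#'   solution is returned with unit weights.
#' @return a list of class `huber_config`.
#' @export
huber_config <- function(k = 1.345, max_iter = 50L, tol = 1e-6,
                         scale_floor = 0) {
  stopifnot(is.numeric(k), length(k) == 1L, is.finite(k), k > 0,
            is.numeric(max_iter), length(max_iter) == 1L, max_iter >= 1,
            is.numeric(tol), length(tol) == 1L, tol > 0,
            is.numeric(scale_floor), length(scale_floor) == 1L,
            scale_floor >= 0)
  structure(list(k = k, max_iter = as.integer(max_iter), tol = tol,
                 scale_floor = scale_floor),
            class = "huber_config")
}

as_huber_config <- function(config) {
  if (inherits(config, "huber_config")) return(config)
  do.call(huber_config, as.list(config))
}

#' Huber loss
#'
#' Quadratic (`x^2/2`) for `|x| <= k`, linear (`k|x| - k^2/2`) beyond; the two
#' branches meet continuously at `|x| = k`.
#'
#' @param x numeric vector of residuals.
#' @param k positive knot.
#' @return non-negative numeric vector of losses.
#' @export
#' @examples
#' huber_loss(c(0, 1.345, 2), k = 1.345)
huber_loss <- function(x, k = 1.345) {
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a single positive finite number", call. = FALSE)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("x must be finite numeric", call. = FALSE)
  ax <- abs(x)
  ifelse(ax <= k, x^2 / 2, k * ax - k^2 / 2)
}

#' IRLS weight implied by the Huber loss
#'
#' Observations with `|residual| <= k * scale` get weight 1; beyond the bound
#' the weight decays as `k * scale / |residual|`, capping each observation's
#' influence.
#'
#' @param residual numeric vector of residuals.
#' @param scale positive robust residual scale.
#' @param k positive tuning constant.
#' @return weights in (0, 1].
#' @export
huber_weight <- function(residual, scale, k = 1.345) {
  if (!is.numeric(scale) || length(scale) != 1L || !is.finite(scale) ||
      scale <= 0)
    stop("scale must be a single positive number", call. = FALSE)
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0)
    stop("k must be a single positive finite number", call. = FALSE)
  bound <- k * scale
  pmin(1, bound / abs(residual))
}

#' Robust residual scale from the median absolute deviation
#'
#' `median(|x - center|) / 0.6745`, the MAD rescaled to be consistent for the
#' Gaussian standard deviation. The default centers at the median; the IRLS
#' solver centers at zero because the no-intercept mixing model forces
#' residuals through zero.
#'
#' @param residuals numeric vector, length >= 1.
#' @param center center of the deviations; `NULL` (default) uses the median.
#' @return non-negative scale estimate; 0 for a constant vector (under median
#'   centering).
#' @export
mad_scale <- function(residuals, center = NULL) {
  if (length(residuals) == 0L || !is.numeric(residuals))
    stop("residuals must be a non-empty numeric vector", call. = FALSE)
  if (any(!is.finite(residuals)))
    stop("residuals must be finite", call. = FALSE)
  if (is.null(center)) center <- stats::median(residuals)
  stats::median(abs(residuals - center)) / 0.6745
}

#' Huber M-estimation of a no-intercept linear model by IRLS
#'
#' Minimizes `sum_i f(y_i - x_i' beta)` with the Huber loss `f`, by
#' iteratively reweighted least squares: initialize at the ordinary
#' least-squares solution, then alternate between re-estimating the residual
#' scale (zero-centered MAD), computing Huber weights, and solving the
#' weighted least-squares problem, until the coefficients stabilize. No
#' intercept is ever added: under the mixing model the bulk signal is a pure
#' weighted sum of cell type profiles.
#'
#' @param y numeric response vector (one gene's bulk expression over samples).
#' @param X numeric design matrix, observations x predictors (samples x cell
#'   types), full column rank.
#' @param config a [huber_config()].
#' @return a list of class `huber_fit`: `coefficients`, `weights` (final IRLS
#'   weights, one per observation, in (0, 1]), `scale`, `n_iterations`,
#'   `converged`.
#' @export
#' @examples
#' set.seed(1)
#' X <- cbind(a = runif(30), b = runif(30))
#' y <- X %*% c(2, 3) + rnorm(30, sd = 0.1)
#' fit_huber(y, X)$coefficients
fit_huber <- function(y, X, config = huber_config()) {
  config <- as_huber_config(config)
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(!is.finite(y)) || any(!is.finite(X)))
    stop("y and X must be finite", call. = FALSE)
  if (nrow(X) != length(y))
    stop("nrow(X) must equal length(y)", call. = FALSE)
  if (ncol(X) < 1L)
    stop("X needs at least one predictor", call. = FALSE)
  if (nrow(X) < ncol(X))
    stop("underdetermined system: ", nrow(X), " observations for ",
         ncol(X), " predictors", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[seq(qx$rank + 1L, ncol(X))]]
    if (is.null(dep)) dep <- qx$pivot[seq(qx$rank + 1L, ncol(X))]
    stop("design matrix is rank deficient; collinear predictor(s): ",
         paste(dep, collapse = ", "), call. = FALSE)
  }
  fit <- .huber_irls_cpp(y, X, config$k, config$max_iter, config$tol,
                         config$scale_floor)
  fit$coefficients <- as.numeric(fit$coefficients)
  names(fit$coefficients) <- colnames(X)
  fit$weights <- as.numeric(fit$weights)
  structure(fit, class = "huber_fit")
}

#' @export
print.huber_fit <- function(x, ...) {
  cat("Huber M-estimation fit (no intercept)\n")
  cat("  coefficients:", format(x$coefficients, digits = 6), "\n")
  cat("  scale:", format(x$scale, digits = 6),
      " iterations:", x$n_iterations,
      " converged:", x$converged, "\n")
  invisible(x)
}
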