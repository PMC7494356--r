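# Efficient-coding threshold predictions: in the sampling-limited regime,
# detection thresholds are predicted to be inversely proportional to the
# standard deviation of natural texture statistics along the probed
# direction ("variance is salience").

#' Fit a multivariate Gaussian to texture vectors
#'
#' @param vectors Numeric matrix (samples x embedded coordinates), e.g. the
#'   `vectors` element of [run_pipeline()] after masking blurred patches.
#' @param ridge Optional nonnegative ridge added to the covariance diagonal.
#' @return A `gaussian_texture_model`: list with `mean`, `cov`, `n`, `ridge`.
#' @export
fit_gaussian <- function(vectors, ridge = 0) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 2L) stop("need at least 2 vectors")
  if (ridge < 0) stop("`ridge` must be nonnegative")
  S <- stats::cov(vectors)
  if (ridge > 0) {
    S <- S + diag(ridge, ncol(S))
    message("fit_gaussian: ridge ", ridge, " added to covariance diagonal")
  }
  structure(list(mean = colMeans(vectors), cov = S, n = nrow(vectors),
                 ridge = ridge),
            class = "gaussian_texture_model")
}

#' @export
print.gaussian_texture_model <- function(x, ...) {
  cat("gaussian_texture_model: ", length(x$mean), " coordinates, fit to ",
      x$n, " vectors\n", sep = "")
  invisible(x)
}

#' Predicted detection threshold along a texture direction
#'
#' Returns `(u' S u)^(-eta/2)` for the direction's unit vector `u` in the
#' flattened coordinate embedding — with `eta = 1`, the reciprocal of the
#' standard deviation along the direction, in the same contrast units as the
#' plane geometry. Predictions are unscaled: a single overall factor is fit
#' to measurements with [fit_scale()].
#'
#' @param model A `gaussian_texture_model`.
#' @param direction A `plane_direction` (or a unit numeric vector).
#' @param eta Power-law exponent (default 1; `eta = 0` makes all predictions
#'   equal, i.e. independent of the data).
#' @return Positive predicted threshold (unscaled).
#' @export
predict_threshold <- function(model, direction, eta = 1) {
  u <- if (inherits(direction, "plane_direction")) direction_vector(direction)
       else as.numeric(direction)
  nu <- sqrt(sum(u^2))
  if (nu == 0) stop("direction vector must be nonzero")
  u <- u / nu
  if (length(u) != length(model$mean))
    stop("direction dimension ", length(u), " does not match model dimension ",
         length(model$mean))
  v <- drop(t(u) %*% model$cov %*% u)
  if (v <= 1e-14)
    stop("zero variance along direction: predicted threshold is infinite")
  v^(-eta / 2)
}

#' Predicted thresholds for a set of directions
#'
#' @param model A `gaussian_texture_model`.
#' @param directions List of `plane_direction`s.
#' @param eta Power-law exponent.
#' @return Numeric vector of unscaled predicted thresholds.
#' @export
predict_thresholds <- function(model, directions, eta = 1) {
  vapply(directions, function(d) predict_threshold(model, d, eta), numeric(1))
}

#' Fit the overall scale aligning predictions to measurements
#'
#' Minimizes `mean(((log(x_i) - log(scale * y_i)) / eps_i)^2)` over the
#' single multiplier `scale`, where `x` are measurements, `y` predictions and
#' `eps` log-space measurement uncertainties. Closed form:
#' `scale = exp(sum(w * (log x - log y)) / sum(w))` with `w = 1/eps^2`.
#'
#' @param predicted,measured Positive numeric vectors of equal length.
#' @param log_errors Positive log-space uncertainties (default: equal
#'   weights).
#' @return The scalar scale factor.
#' @export
fit_scale <- function(predicted, measured, log_errors = NULL) {
  if (length(predicted) != length(measured)) stop("length mismatch")
  if (any(predicted <= 0) || any(measured <= 0))
    stop("thresholds must be positive")
  if (is.null(log_errors)) log_errors <- rep(1, length(predicted))
  if (any(log_errors <= 0)) stop("`log_errors` must be positive")
  w <- 1 / log_errors^2
  exp(sum(w * (log(measured) - log(predicted))) / sum(w))
}

#' Fit the power-law exponent relating variance to threshold
#'
#' Weighted least squares of `log(measured)` on `-log(predicted_std)` with an
#' intercept: `log(threshold) = log(scale) - eta * log(sd)`. Returns the
#' point estimate of `eta` and the intercept-derived scale.
#'
#' @param predicted_std Positive standard deviations along each direction.
#' @param measured Positive measured thresholds.
#' @param log_errors Optional log-space uncertainties (weights `1/eps^2`).
#' @return List with `eta`, `scale`, and the weighted-least-squares `fit`.
#' @export
fit_eta <- function(predicted_std, measured, log_errors = NULL) {
  n <- length(predicted_std)
  if (n < 3L) stop("need at least 3 points to fit eta")
  if (length(measured) != n) stop("length mismatch")
  if (any(predicted_std <= 0) || any(measured <= 0)) stop("inputs must be positive")
  if (stats::sd(log(predicted_std)) < 1e-12)
    stop("degenerate regressor: predicted standard deviations are constant")
  if (is.null(log_errors)) log_errors <- rep(1, n)
  w <- 1 / log_errors^2
  x <- -log(predicted_std); y <- log(measured)
  fit <- stats::lm(y ~ x, weights = w)
  list(eta = unname(stats::coef(fit)[2]), scale = exp(unname(stats::coef(fit)[1])),
       fit = fit)
}
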