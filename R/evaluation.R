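# Agreement statistics between predicted and measured thresholds.

#' Log errors between two sets of thresholds
#'
#' `log(y) - log(x)`, elementwise; for small mismatches this approximates the
#' relative error (a value of 0.13 is roughly a 13% relative error).
#'
#' @param x,y Positive numeric vectors of equal length.
#' @return Numeric vector of log differences.
#' @export
log_errors <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (any(x <= 0) || any(y <= 0)) stop("thresholds must be positive")
  log(y) - log(x)
}

#' Median absolute log error
#'
#' The headline mismatch statistic: the median of `|log y - log x|`.
#' Symmetric in its arguments. For an even number of pairs the usual median
#' convention (mean of the two central values) applies.
#'
#' @inheritParams log_errors
#' @export
median_abs_log_error <- function(x, y) {
  stats::median(abs(log_errors(x, y)))
}

#' Permutation test for prediction-measurement agreement
#'
#' Tests the null hypothesis that measured thresholds are unrelated to the
#' texture direction in which they were measured: measured values are
#' shuffled across direction labels (globally, or within each plane for the
#' ellipse-aware variant), the median absolute log error against the
#' predictions is recomputed for each shuffle, and the p-value is the
#' fraction of null statistics at or below the observed one, computed as
#' `(1 + #{null <= observed}) / (1 + n_perm)` so it is never exactly zero.
#'
#' @param predicted,measured Positive numeric vectors (>= 3 pairs).
#' @param n_perm Number of permutations (>= 100; default 10000).
#' @param mode `"global"` shuffles across all directions; `"within_plane"`
#'   shuffles only within the plane labels given in `plane`.
#' @param plane Plane labels (required for `mode = "within_plane"`).
#' @param seed Integer seed.
#' @return List with `p`, `observed`, `null_range` (2.5 and 97.5 percentiles
#'   of the null distribution), and `n_perm`.
#' @export
permutation_test <- function(predicted, measured, n_perm = 10000L,
                             mode = c("global", "within_plane"), plane = NULL,
                             seed = 1L) {
  mode <- match.arg(mode)
  if (length(predicted) != length(measured)) stop("length mismatch")
  if (length(predicted) < 3L) stop("need at least 3 pairs")
  if (n_perm < 100L) stop("need at least 100 permutations")
  if (mode == "within_plane") {
    if (is.null(plane) || length(plane) != length(measured))
      stop("`plane` labels required for within-plane permutation")
    groups <- split(seq_along(measured), plane)
  }
  obs <- median_abs_log_error(predicted, measured)
  null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    perm <- if (mode == "global") sample(measured)
    else {
      out <- measured
      for (g in groups) out[g] <- measured[sample(g)]
      out
    }
    median_abs_log_error(predicted, perm)
  }, numeric(1)))
  list(p = (1 + sum(null <= obs)) / (1 + n_perm), observed = obs,
       null_range = unname(stats::quantile(null, c(0.025, 0.975))),
       n_perm = as.integer(n_perm))
}

#' Fit an origin-centered ellipse to threshold points in a plane
#'
#' Least-squares fit of the conic `a x^2 + b x y + c y^2 = 1` (the center is
#' the plane origin, where predictions are centered by construction). Errors
#' if the best-fitting conic is not an ellipse or the points are degenerate
#' (e.g. collinear through the origin).
#'
#' @param points Two-column matrix of (x, y) coordinates, or a list with
#'   `angle` and `threshold` (polar form).
#' @return List with `coef` (a, b, c), `residual` (RMS of the conic
#'   equation), and `axes` (semi-axis lengths).
#' @export
fit_threshold_ellipse <- function(points) {
  if (is.list(points) && !is.null(points$angle))
    points <- cbind(points$threshold * cos(points$angle),
                    points$threshold * sin(points$angle))
  points <- as.matrix(points)
  if (nrow(points) < 3L) stop("need at least 3 points")
  M <- cbind(points[, 1]^2, points[, 1] * points[, 2], points[, 2]^2)
  qr_ <- qr(M)
  if (qr_$rank < 3L) stop("degenerate point configuration (collinear points)")
  cf <- qr.coef(qr_, rep(1, nrow(points)))
  if (cf[2]^2 - 4 * cf[1] * cf[3] >= 0 || cf[1] <= 0)
    stop("best-fitting conic is not an ellipse")
  Q <- matrix(c(cf[1], cf[2] / 2, cf[2] / 2, cf[3]), 2, 2)
  ev <- eigen(Q, symmetric = TRUE)$values
  list(coef = stats::setNames(as.numeric(cf), c("a", "b", "c")),
       residual = sqrt(mean((M %*% cf - 1)^2)),
       axes = 1 / sqrt(sort(ev)))
}

#' Summarize prediction-measurement agreement
#'
#' Convenience wrapper computing the scaled predictions, overall and
#' per-subset median absolute log errors, and the permutation test.
#'
#' @param predicted Unscaled predicted thresholds.
#' @param measured Measured thresholds.
#' @param log_err Log-space measurement uncertainties (for the scale fit).
#' @param subset Optional factor (e.g. simple vs mixed plane) for a
#'   per-subset breakdown of median log errors.
#' @param n_perm,seed Permutation-test controls.
#' @return List with `scale`, `scaled_predictions`, `median_abs_log_error`,
#'   `per_subset` (median signed log prediction error by subset), and `perm`
#'   (the permutation test result).
#' @export
evaluate_predictions <- function(predicted, measured, log_err = NULL,
                                 subset = NULL, n_perm = 10000L, seed = 1L) {
  sc <- fit_scale(predicted, measured, log_err)
  yhat <- sc * predicted
  out <- list(scale = sc, scaled_predictions = yhat,
              median_abs_log_error = median_abs_log_error(measured, yhat))
  if (!is.null(subset)) {
    out$per_subset <- tapply(log(yhat) - log(measured), subset, stats::median)
  }
  out$perm <- permutation_test(yhat, measured, n_perm = n_perm, seed = seed)
  out
}
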