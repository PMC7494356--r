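# Four-alternative forced-choice psychometrics: Weibull fits, bootstrap
# uncertainties, and cross-subject averaging.

#' Weibull psychometric function for 4AFC
#'
#' `fc(c) = 0.25 + 0.75 * (1 - 2^(-(c/lambda)^k))`: chance 0.25 at zero
#' contrast, ceiling 1 at high contrast, and exactly 0.625 — halfway between
#' chance and ceiling — at `c = lambda`, so the scale parameter is the
#' threshold. The base-2 parameterization pins that identity; the guess rate
#' is fixed at 0.25 and the lapse rate at 0.
#'
#' @param contrast Nonnegative texture contrast(s).
#' @param lambda Scale (threshold) parameter, > 0.
#' @param k Shape parameter, > 0.
#' @return Fraction correct in [0.25, 1].
#' @export
weibull_fc <- function(contrast, lambda, k) {
  stopifnot(lambda > 0, k > 0)
  0.25 + 0.75 * (1 - 2^(-(contrast / lambda)^k))
}

#' Bundle 4AFC trial counts for one direction
#'
#' @param contrasts Positive texture contrasts tested.
#' @param n_trials,n_correct Trial and correct counts per contrast.
#' @param direction Optional `plane_direction` label.
#' @param subject Optional subject label.
#' @return A `trial_block`.
#' @export
trial_block <- function(contrasts, n_trials, n_correct, direction = NULL,
                        subject = NA_character_) {
  stopifnot(length(contrasts) == length(n_trials),
            length(contrasts) == length(n_correct))
  if (any(contrasts <= 0)) stop("contrasts must be positive")
  if (any(n_correct < 0) || any(n_correct > n_trials))
    stop("need 0 <= n_correct <= n_trials")
  structure(list(contrasts = as.numeric(contrasts),
                 n_trials = as.integer(n_trials),
                 n_correct = as.integer(n_correct),
                 direction = direction, subject = subject),
            class = "trial_block")
}

weibull_negll <- function(par, contrasts, n_trials, n_correct) {
  lambda <- exp(par[1]); k <- exp(par[2])
  p <- weibull_fc(contrasts, lambda, k)
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(n_correct * log(p) + (n_trials - n_correct) * log(1 - p))
}

fit_weibull_mle <- function(contrasts, n_trials, n_correct, start = NULL) {
  starts <- if (!is.null(start)) list(start) else {
    fc <- n_correct / n_trials
    # start lambda near the contrast whose performance is closest to 0.625
    l0 <- contrasts[which.min(abs(fc - 0.625))]
    lapply(c(1, 2, 4), function(k0) c(log(l0), log(k0)))
  }
  best <- NULL
  for (s in starts) {
    o <- try(stats::optim(s, weibull_negll,
                          contrasts = contrasts, n_trials = n_trials,
                          n_correct = n_correct, method = "Nelder-Mead",
                          control = list(maxit = 500)), silent = TRUE)
    if (inherits(o, "try-error")) next
    if (is.null(best) || o$value < best$value) best <- o
  }
  if (is.null(best)) stop("Weibull fit failed to converge")
  best
}

#' Maximum-likelihood Weibull threshold for a trial block
#'
#' Binomial maximum likelihood over (log lambda, log k); the threshold is the
#' scale parameter lambda (the 0.625 fraction-correct point). A bootstrap
#' (trials resampled within each contrast, fit repeated) provides the
#' log-space uncertainty (half the central 68% range of log lambda) and a 95%
#' interval. Thresholds beyond the tested contrast range are returned as-is
#' and flagged `extrapolated`; near-chance data that push the threshold far
#' above the tested range are flagged `unbounded` (a low-sensitivity
#' direction).
#'
#' @param block A `trial_block` with at least 2 distinct contrasts.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A `weibull_fit`: list with `lambda`, `k`, `threshold`, `log_se`,
#'   `ci` (95% bootstrap interval for the threshold), `extrapolated`,
#'   `unbounded`.
#' @export
fit_threshold <- function(block, n_boot = 1000L, seed = 1L) {
  if (length(unique(block$contrasts)) < 2L)
    stop("need at least 2 distinct contrasts")
  o <- fit_weibull_mle(block$contrasts, block$n_trials, block$n_correct)
  lambda <- exp(o$par[1]); k <- exp(o$par[2])
  unbounded <- lambda > 100 * max(block$contrasts)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      nc <- stats::rbinom(length(block$contrasts), block$n_trials,
                          block$n_correct / block$n_trials)
      ob <- try(fit_weibull_mle(block$contrasts, block$n_trials, nc,
                                start = o$par),
                silent = TRUE)
      if (inherits(ob, "try-error")) NA_real_ else exp(ob$par[1])
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  log_se <- unname(diff(stats::quantile(log(boot), c(0.16, 0.84))) / 2)
  ci <- unname(stats::quantile(boot, c(0.025, 0.975)))
  structure(list(lambda = unname(lambda), k = unname(k),
                 threshold = unname(lambda), log_se = log_se, ci = ci,
                 extrapolated = lambda < min(block$contrasts) ||
                   lambda > max(block$contrasts),
                 unbounded = unbounded, n_boot = length(boot)),
            class = "weibull_fit")
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("weibull_fit: threshold ", format(x$threshold, digits = 4),
      " (log SE ", format(x$log_se, digits = 3), "), k = ",
      format(x$k, digits = 3), sep = "")
  if (x$unbounded) cat(" [unbounded]")
  else if (x$extrapolated) cat(" [extrapolated]")
  cat("\n")
  invisible(x)
}

#' Align subjects by per-subject sensitivity multipliers
#'
#' Models each subject's log thresholds as a shared consensus plus a
#' per-subject offset (a multiplicative sensitivity factor), fit by
#' alternating means to minimize squared log deviations. Multipliers are
#' normalized to geometric mean 1; the consensus is the per-direction
#' geometric mean of the rescaled thresholds. Also reports the fraction of
#' cross-subject log-variance explained by the consensus-plus-multipliers
#' model.
#'
#' @param thresholds Numeric matrix, subjects x directions (NA for missing);
#'   a single subject may be given as a vector.
#' @param max_iter,tol Alternating-means iteration controls.
#' @return List with `consensus` (length = directions), `multipliers` (length
#'   = subjects), `variance_explained`.
#' @export
align_subjects <- function(thresholds, max_iter = 100L, tol = 1e-12) {
  if (is.vector(thresholds)) thresholds <- matrix(thresholds, nrow = 1)
  if (any(thresholds <= 0, na.rm = TRUE)) stop("thresholds must be positive")
  lt <- log(thresholds)
  obs <- is.finite(lt)
  if (any(colSums(obs) == 0)) stop("directions with no data")
  # subjects must be connected through shared directions
  ns <- nrow(lt)
  if (ns > 1) {
    adj <- (obs %*% t(obs)) > 0
    reach <- adj[1, ]
    for (i in seq_len(ns)) reach <- reach | (reach %*% adj) > 0
    if (!all(reach))
      stop("disjoint direction coverage: subjects cannot be aligned")
  }
  m <- rep(0, ns)
  cons <- colMeans(lt - m, na.rm = TRUE)
  last <- Inf
  for (it in seq_len(max_iter)) {
    cons <- colMeans(lt - m, na.rm = TRUE)
    m <- rowMeans(sweep(lt, 2, cons, `-`), na.rm = TRUE)
    m <- m - mean(m)
    objective <- mean((lt - outer(m, cons, `+`))^2, na.rm = TRUE)
    if (abs(last - objective) < tol) break
    last <- objective
  }
  fitted <- outer(m, cons, `+`)
  sst <- sum((lt - mean(lt, na.rm = TRUE))^2, na.rm = TRUE)
  sse <- sum((lt - fitted)^2, na.rm = TRUE)
  list(consensus = exp(cons), multipliers = exp(m),
       variance_explained = if (sst > 0) 1 - sse / sst else 1)
}

#' Combine per-subject log-space error bars
#'
#' Root-mean-square of the log-space errors, exponentiated.
#'
#' @param per_subject_log_errors Numeric vector of log-space error bars.
#' @return Combined multiplicative error bar.
#' @export
combine_errorbars <- function(per_subject_log_errors) {
  exp(sqrt(mean(per_subject_log_errors^2)))
}
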