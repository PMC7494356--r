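# Synthetic fixtures: images with natural-scene-like statistics (1/f^2-type
# power spectra, lognormal intensities, optional blur) and simulated 4AFC
# observers. These stand in for an external natural-image database and real
# subjects so the full analysis chain runs self-contained; they are labeled
# synthetic throughout and do not attempt photorealism.

#' Specification for a synthetic image ensemble
#'
#' Defaults emulate broad statistical properties of natural scenes: a
#' power-law (approximately 1/f^2) spatial power spectrum, lognormal light
#' intensities, and a fraction of out-of-focus images. A mild horizontal
#' anisotropy is planted so that second-order texture statistics differ
#' across orientations and downstream threshold predictions are non-trivial.
#'
#' @param n_images Number of images.
#' @param size Image side length in pixels.
#' @param spectral_exponent Power-spectrum exponent: power ~ 1/f^exponent
#'   (default 2; 0 gives white noise).
#' @param log_mean,log_sd Mean and standard deviation of log intensity.
#' @param blur_fraction Fraction of images that are Gaussian-blurred.
#' @param blur_sigma Blur standard deviation in pixels.
#' @param anisotropy Median horizontal-correlation strengthening factor (> 1
#'   attenuates high horizontal frequencies; 1 = isotropic).
#' @param anisotropy_sd Log-scale standard deviation of the per-image
#'   anisotropy. Scene-to-scene heterogeneity is what survives ensemble
#'   whitening and creates direction-dependent variance in texture space, so
#'   this (together with `exponent_sd`) controls how strongly predicted
#'   thresholds differ across planes.
#' @param exponent_sd Standard deviation of the per-image spectral exponent.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_images = 24L, size = 256L, spectral_exponent = 2,
                         log_mean = 4.6, log_sd = 0.5, blur_fraction = 0.25,
                         blur_sigma = 3, anisotropy = 1.5, anisotropy_sd = 0.4,
                         exponent_sd = 0.3) {
  stopifnot(n_images >= 1, size >= 8, spectral_exponent >= 0, log_sd > 0,
            blur_fraction >= 0, blur_fraction <= 1, blur_sigma > 0,
            anisotropy > 0, anisotropy_sd >= 0, exponent_sd >= 0)
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 spectral_exponent = spectral_exponent, log_mean = log_mean,
                 log_sd = log_sd, blur_fraction = blur_fraction,
                 blur_sigma = blur_sigma, anisotropy = anisotropy,
                 anisotropy_sd = anisotropy_sd, exponent_sd = exponent_sd),
            class = "fixture_spec")
}

fourier_freqs <- function(n) {
  f <- c(0:(n %/% 2), -((n - (n %/% 2 + 1)):1)) / n
  f[seq_len(n)]
}

# Stationary Gaussian random field with power ~ f_eff^(-exponent), unit
# variance; anisotropy > 1 suppresses high column (horizontal) frequencies.
power_law_field <- function(n, exponent, anisotropy = 1) {
  fr <- fourier_freqs(n); fc <- fourier_freqs(n)
  f2 <- outer(fr^2, (anisotropy * fc)^2, `+`)
  amp <- f2^(-exponent / 4)
  amp[1, 1] <- 0
  z <- matrix(stats::rnorm(n * n), n, n)
  x <- Re(stats::fft(stats::fft(z) * amp, inverse = TRUE)) / (n * n)
  (x - mean(x)) / stats::sd(x)
}

gaussian_blur <- function(img, sigma) {
  n1 <- nrow(img); n2 <- ncol(img)
  h <- exp(-2 * pi^2 * sigma^2 * outer(fourier_freqs(n1)^2, fourier_freqs(n2)^2, `+`))
  Re(stats::fft(stats::fft(img) * h, inverse = TRUE)) / (n1 * n2)
}

#' Generate a synthetic image ensemble with ground-truth blur labels
#'
#' Each image is the exponential of a power-law-correlated Gaussian field
#' (hence lognormal intensities with approximately 1/f^exponent power
#' spectrum in log space); a seeded random subset is Gaussian-blurred and
#' labeled as such. The spectral exponent and horizontal anisotropy of each
#' image are drawn around the ensemble medians, emulating scene-to-scene
#' variation: the shared spectrum is later removed by whitening, and it is
#' these per-image deviations that give the texture-space distribution its
#' direction-dependent variance.
#'
#' @param spec A [fixture_spec()].
#' @param seed Integer seed.
#' @return List with `images` (list of intensity matrices) and `blurred`
#'   (logical ground-truth labels).
#' @export
generate_images <- function(spec = fixture_spec(), seed = 1L) {
  with_seed(seed, {
    n_blur <- round(spec$blur_fraction * spec$n_images)
    blurred <- logical(spec$n_images)
    blurred[sample.int(spec$n_images, n_blur)] <- TRUE
    images <- lapply(seq_len(spec$n_images), function(i) {
      expo <- max(0, spec$spectral_exponent + stats::rnorm(1, 0, spec$exponent_sd))
      anis <- spec$anisotropy * exp(stats::rnorm(1, 0, spec$anisotropy_sd))
      fld <- power_law_field(spec$size, expo, anis)
      img <- exp(spec$log_mean + spec$log_sd * fld)
      if (blurred[i]) img <- gaussian_blur(img, spec$blur_sigma)
      pmax(img, .Machine$double.eps)
    })
    list(images = images, blurred = blurred)
  })
}

#' Simulate 4AFC observer data for a set of directions
#'
#' Draws binomial trial outcomes from a Weibull observer with the given true
#' thresholds. Each direction is tested at `n_contrasts` contrasts spread
#' multiplicatively around its true threshold, with `n_trials` trials in
#' total per direction (the experimental design behind the fitted
#' psychometric functions).
#'
#' @param true_thresholds Positive vector of true thresholds (one per
#'   direction).
#' @param k Weibull shape of the simulated observer (default 2).
#' @param n_trials Total trials per direction (default 360).
#' @param n_contrasts Number of contrast levels per direction (default 3).
#' @param contrast_spread Multiplicative spread of tested contrasts around
#'   the true threshold (default 1.6: contrasts from threshold/1.6 to
#'   threshold*1.6).
#' @param directions Optional list of `plane_direction` labels.
#' @param subject Subject label recorded on each block.
#' @param seed Integer seed.
#' @return List of `trial_block`s with the ground truth stored in
#'   `attr(, "true_thresholds")`.
#' @export
generate_observer_data <- function(true_thresholds, k = 2, n_trials = 360L,
                                   n_contrasts = 3L, contrast_spread = 1.6,
                                   directions = NULL, subject = "synthetic",
                                   seed = 1L) {
  stopifnot(all(true_thresholds > 0), k > 0, n_contrasts >= 2,
            contrast_spread > 1)
  per <- n_trials %/% n_contrasts
  blocks <- with_seed(seed, lapply(seq_along(true_thresholds), function(i) {
    lam <- true_thresholds[i]
    contrasts <- lam * contrast_spread^seq(-1, 1, length.out = n_contrasts)
    p <- weibull_fc(contrasts, lam, k)
    nc <- stats::rbinom(n_contrasts, per, p)
    trial_block(contrasts, rep(per, n_contrasts), nc,
                direction = if (is.null(directions)) NULL else directions[[i]],
                subject = subject)
  }))
  attr(blocks, "true_thresholds") <- true_thresholds
  attr(blocks, "k") <- k
  blocks
}

#' Standard direction sets for simple and mixed second-order planes
#'
#' Twelve evenly spaced directions (30 degree steps) in each requested
#' plane, mirroring the experimental sampling of texture planes.
#'
#' @param planes List of plane descriptors: either a single group (simple
#'   plane) or `list(group_a, h_a, group_b, h_b)` (mixed plane).
#' @param n_directions Directions per plane (default 12).
#' @param G Number of gray levels.
#' @return List of `plane_direction`s with a `plane` label attribute.
#' @export
plane_directions <- function(planes, n_directions = 12L, G = 3L) {
  angles <- 2 * pi * (seq_len(n_directions) - 1) / n_directions
  out <- list(); labels <- character(0)
  for (pl in planes) {
    if (inherits(pl, "texture_group") || is.character(pl)) {
      g <- if (is.character(pl)) texture_group(pl, G) else pl
      for (a in angles) out[[length(out) + 1L]] <- plane_direction(g, angle = a)
      labels <- c(labels, rep(g$name, n_directions))
    } else {
      ga <- if (is.character(pl[[1]])) texture_group(pl[[1]], G) else pl[[1]]
      gb <- if (is.character(pl[[3]])) texture_group(pl[[3]], G) else pl[[3]]
      for (a in angles)
        out[[length(out) + 1L]] <- plane_direction(ga, angle = a,
                                                   h_a = pl[[2]], group_b = gb,
                                                   h_b = pl[[4]], G = G)
      labels <- c(labels,
                  rep(paste0(ga$name, "[", pl[[2]], "];", gb$name, "[", pl[[4]], "]"),
                      n_directions))
    }
  }
  attr(out, "plane") <- labels
  out
}
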