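# Natural-image preprocessing: log luminance -> downsample -> patchify ->
# spectral whitening -> rank ternarization -> texture analysis -> blur
# rejection.

#' Pipeline configuration
#'
#' @param N Downsampling factor (images are averaged over N x N pixel
#'   blocks). Default 2.
#' @param R Patch size in checks after downsampling. Default 32.
#' @param G Number of gray levels for ternarization. Default 3.
#' @param input_is_log Set to `TRUE` when images already encode log
#'   luminance.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(N = 2L, R = 32L, G = 3L, input_is_log = FALSE) {
  N <- stopifnot_scalar_int(N, "N", min = 1)
  R <- stopifnot_scalar_int(R, "R", min = 2)
  G <- stopifnot_scalar_int(G, "G", min = 2)
  structure(list(N = N, R = R, G = G, input_is_log = isTRUE(input_is_log)),
            class = "pipeline_config")
}

#' Elementwise log-luminance transform
#'
#' @param image Numeric matrix of luminances (strictly positive unless
#'   already log-encoded).
#' @param input_is_log If `TRUE` the image is returned unchanged.
#' @return Numeric matrix of log luminances.
#' @export
log_transform <- function(image, input_is_log = FALSE) {
  if (input_is_log) return(image)
  bad <- sum(image <= 0)
  if (bad > 0)
    stop("log transform: ", bad, " nonpositive intensity value(s)")
  log(image)
}

#' Downsample an image by block averaging
#'
#' Each output pixel is the mean of an `N x N` block; trailing partial blocks
#' are discarded.
#'
#' @param image Numeric matrix.
#' @param N Block size (>= 1).
#' @export
downsample <- function(image, N) {
  N <- stopifnot_scalar_int(N, "N", min = 1)
  if (N == 1L) return(image)
  nr <- nrow(image) %/% N; nc <- ncol(image) %/% N
  if (nr < 1L || nc < 1L) stop("image smaller than one ", N, "x", N, " block")
  m <- image[seq_len(nr * N), seq_len(nc * N), drop = FALSE]
  # average over columns then rows of each block
  m <- t(rowsum(t(m), rep(seq_len(nc), each = N))) / N
  rowsum(m, rep(seq_len(nr), each = N)) / N
}

#' Split an image into non-overlapping square patches
#'
#' @param image Numeric matrix.
#' @param R Patch side length.
#' @return List with elements `patches` (list of R x R matrices) and `grid`
#'   (data frame of 1-based patch-grid positions, row-major order). Images
#'   smaller than `R` yield zero patches.
#' @export
patchify <- function(image, R) {
  R <- stopifnot_scalar_int(R, "R", min = 2)
  nr <- nrow(image) %/% R; nc <- ncol(image) %/% R
  if (nr < 1L || nc < 1L)
    return(list(patches = list(), grid = data.frame(row = integer(), col = integer())))
  grid <- expand.grid(col = seq_len(nc), row = seq_len(nr))[, 2:1]
  patches <- lapply(seq_len(nrow(grid)), function(i) {
    r <- grid$row[i]; c <- grid$col[i]
    image[(r - 1L) * R + seq_len(R), (c - 1L) * R + seq_len(R), drop = FALSE]
  })
  list(patches = patches, grid = grid)
}

#' Build the ensemble whitening filter
#'
#' The filter is the reciprocal square root of the ensemble-average power
#' spectrum (magnitude-squared 2D Fourier transform) of the patches; applying
#' it flattens the average pairwise correlation spectrum of the ensemble. The
#' zero-frequency gain is set to 0, which removes each patch's mean — the
#' subsequent rank ternarization is insensitive to the mean, and this keeps
#' the filter from being dominated by luminance variance.
#'
#' @param patches List of equal-size numeric matrices.
#' @return Numeric matrix of per-frequency filter gains.
#' @export
build_whitening_filter <- function(patches) {
  if (length(patches) == 0) stop("no patches")
  dims <- dim(patches[[1]])
  pw <- matrix(0, dims[1], dims[2])
  for (p in patches) {
    if (!all(dim(p) == dims)) stop("patches must share a common size")
    pw <- pw + Mod(stats::fft(p))^2
  }
  pw <- pw / length(patches)
  dc <- pw[1, 1]
  pw[1, 1] <- 1
  if (any(pw <= 0))
    stop("degenerate ensemble: zero power in ", sum(pw <= 0), " frequency bin(s)")
  f <- 1 / sqrt(pw)
  f[1, 1] <- 0
  f
}

#' Apply a whitening filter to a patch
#'
#' @param patch Numeric matrix.
#' @param filter Filter from [build_whitening_filter()] (same size).
#' @return Filtered patch (real part of the inverse transform).
#' @export
whiten <- function(patch, filter) {
  if (!all(dim(patch) == dim(filter))) stop("patch/filter size mismatch")
  Re(stats::fft(stats::fft(patch) * filter, inverse = TRUE)) / length(patch)
}

#' Ternarize a patch by rank (histogram equalization)
#'
#' Pixels are ranked within the patch; the lowest third becomes level 0
#' (black), the middle third level 1 (gray), the top third level 2 (white) —
#' generally `G` equal quantile bins. Level counts differ by at most 1. Ties
#' are broken by a seeded pseudorandom permutation so the result is
#' deterministic and unbiased across levels.
#'
#' @param patch Numeric matrix with at least `G` pixels.
#' @param G Number of gray levels.
#' @param seed Seed for the tie-breaking permutation.
#' @return A `gray_patch`.
#' @export
ternarize <- function(patch, G = 3L, seed = 1L) {
  n <- length(patch)
  if (n < G) stop("patch has fewer pixels than gray levels")
  tie <- with_seed(seed, sample.int(n))
  rk <- integer(n)
  rk[order(as.vector(patch), tie)] <- seq_len(n)
  bounds <- round(seq_len(G - 1) * n / G)
  lev <- rowSums(outer(rk, bounds, `>`))
  gray_patch(matrix(lev, nrow(patch), ncol(patch)), G = G)
}

#' Laplacian sharpness of a raw image region
#'
#' The region is normalized so its median luminance is 1, convolved with the
#' 3x3 Laplacian kernel (cross of 1s around -4), and the median absolute
#' response over interior pixels is returned. Computed on raw luminances
#' before any other preprocessing; invariant to overall intensity scaling.
#'
#' @param raw_patch Numeric matrix (>= 3x3) of raw luminances.
#' @return Nonnegative sharpness score.
#' @export
sharpness <- function(raw_patch) {
  if (nrow(raw_patch) < 3L || ncol(raw_patch) < 3L)
    stop("sharpness needs at least a 3x3 region")
  med <- stats::median(raw_patch)
  if (med <= 0) stop("median luminance must be positive")
  m <- raw_patch / med
  nr <- nrow(m); nc <- ncol(m)
  lap <- m[1:(nr - 2), 2:(nc - 1)] + m[3:nr, 2:(nc - 1)] +
    m[2:(nr - 1), 1:(nc - 2)] + m[2:(nr - 1), 3:nc] -
    4 * m[2:(nr - 1), 2:(nc - 1)]
  stats::median(abs(lap))
}

# Log density of rows of x under N(mu, S) with ridge escalation if the
# Cholesky factorization fails.
ldmvnorm <- function(x, mu, S) {
  d <- ncol(x)
  ridge <- 0
  repeat {
    ch <- try(chol(S + diag(ridge, d)), silent = TRUE)
    if (!inherits(ch, "try-error")) break
    ridge <- if (ridge == 0) 1e-10 * mean(diag(S)) else ridge * 10
    if (!is.finite(ridge) || ridge > mean(diag(S))) stop("singular covariance")
  }
  xc <- sweep(x, 2, mu)
  z <- backsolve(ch, t(xc), transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(ch))) - 0.5 * colSums(z^2)
}

# Two-component full-covariance Gaussian mixture EM: k-means initialization
# with multiple seeded restarts, unshared covariances, fixed diagonal ridge
# (relative to the mean coordinate variance) so near-degenerate coordinates
# (e.g. the first-order histogram pinned by ternarization) stay harmless.
gmm2_em <- function(x, seed = 1L, ridge_rel = 1e-6, max_iter = 200L,
                    tol = 1e-8, n_start = 10L) {
  n <- nrow(x); d <- ncol(x)
  ridge <- ridge_rel * mean(apply(x, 2, stats::var))
  if (!is.finite(ridge) || ridge <= 0) ridge <- 1e-12
  km <- with_seed(seed, stats::kmeans(x, centers = 2, nstart = n_start))
  z <- matrix(0, n, 2); z[cbind(seq_len(n), km$cluster)] <- 1
  ll_old <- -Inf
  for (it in seq_len(max_iter)) {
    nk <- pmax(colSums(z), 1e-8)
    pi_k <- nk / n
    lp <- matrix(0, n, 2)
    for (k in 1:2) {
      mu <- colSums(z[, k] * x) / nk[k]
      xc <- sweep(x, 2, mu)
      S <- crossprod(xc * z[, k], xc) / nk[k] + diag(ridge, d)
      lp[, k] <- log(pi_k[k]) + ldmvnorm(x, mu, S)
    }
    m <- apply(lp, 1, max)
    lse <- m + log(rowSums(exp(lp - m)))
    z <- exp(lp - lse)
    ll <- sum(lse)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
    ll_old <- ll
  }
  list(responsibilities = z, classification = max.col(z), loglik = ll)
}

#' Separate sharp from blurred patches with a two-component Gaussian mixture
#'
#' Fits a two-component Gaussian mixture with unshared full covariances to
#' the texture vectors (in the flattened coordinate embedding), assigns each
#' patch to its maximum-responsibility component, and keeps the component
#' whose members have the higher median sharpness (ties broken toward the
#' larger component). The mixture is fit by EM with seeded k-means
#' initialization (10 restarts) and a small diagonal ridge on the
#' covariances, so coordinates pinned by the preprocessing (the first-order
#' histogram) do not destabilize the fit.
#'
#' @param vectors Numeric matrix (patches x embedded coordinates).
#' @param sharpness Numeric vector of per-patch sharpness scores.
#' @param seed Integer seed for the k-means initialization.
#' @return Logical mask (`TRUE` = keep) with attributes `classification` and
#'   `fraction_kept`.
#' @export
remove_blurred <- function(vectors, sharpness, seed = 1L) {
  if (nrow(vectors) < 2L) stop("need at least 2 patches")
  if (length(sharpness) != nrow(vectors))
    stop("`sharpness` must have one entry per patch")
  if (any(!is.finite(vectors))) stop("texture vectors must be finite")
  fit <- gmm2_em(vectors, seed = seed)
  cls <- fit$classification
  med <- vapply(1:2, function(k) stats::median(sharpness[cls == k]), numeric(1))
  keep_comp <- if (med[1] == med[2]) which.max(tabulate(cls, 2)) else which.max(med)
  mask <- cls == keep_comp
  message("blur rejection: keeping ", sum(mask), "/", length(mask),
          " patches (sharp component median sharpness ",
          format(max(med), digits = 3), " vs ", format(min(med), digits = 3), ")")
  structure(mask, classification = cls, fraction_kept = mean(mask))
}

#' Run the full image-to-texture-statistics pipeline
#'
#' Composition: log transform -> downsample by N -> split into R x R patches
#' -> whiten with the ensemble filter -> ternarize -> texture analysis ->
#' Gaussian-mixture blur rejection. Sharpness is computed on each patch's raw
#' (pre-log, pre-downsampling) pixel region. Stage counts are reported via
#' `message()`.
#'
#' @param images List of numeric luminance matrices.
#' @param config A [pipeline_config()].
#' @param seed Integer seed (ternarization tie-breaks).
#' @return List with `records` (data frame: image, row, col, sharpness,
#'   in_focus), `vectors` (matrix of embedded texture coordinates, one row
#'   per patch), `probs` (matrix of raw per-group probabilities),
#'   `patches` (list of ternarized `gray_patch`es), `filter` (whitening
#'   filter), and `mask` (the blur-rejection mask).
#' @export
run_pipeline <- function(images, config = pipeline_config(), seed = 1L) {
  empty <- list(records = data.frame(), vectors = NULL, probs = NULL,
                patches = list(), filter = NULL, mask = logical())
  if (length(images) == 0) return(empty)
  N <- config$N; R <- config$R; G <- config$G
  all_patches <- list(); rec <- list(); sharp <- numeric(0)
  for (i in seq_along(images)) {
    img <- images[[i]]
    lg <- log_transform(img, config$input_is_log)
    dn <- downsample(lg, N)
    pp <- patchify(dn, R)
    if (length(pp$patches) == 0) {
      message("image ", i, ": smaller than one ", R, "x", R, " patch; skipped")
      next
    }
    for (j in seq_along(pp$patches)) {
      r <- pp$grid$row[j]; c <- pp$grid$col[j]
      raw <- images[[i]][(r - 1L) * R * N + seq_len(R * N),
                         (c - 1L) * R * N + seq_len(R * N), drop = FALSE]
      sh <- sharpness(if (config$input_is_log) exp(raw) else raw)
      all_patches[[length(all_patches) + 1L]] <- pp$patches[[j]]
      sharp <- c(sharp, sh)
      rec[[length(rec) + 1L]] <- data.frame(image = i, row = r, col = c)
    }
  }
  message("pipeline: ", length(all_patches), " patches from ",
          length(images), " images")
  if (length(all_patches) == 0) return(empty)
  filt <- build_whitening_filter(all_patches)
  tern <- vector("list", length(all_patches))
  vecs <- matrix(NA_real_, length(all_patches), (G - 1) * length(enumerate_groups(G)))
  pmat <- matrix(NA_real_, length(all_patches), G * length(enumerate_groups(G)))
  seeds <- with_seed(seed, sample.int(.Machine$integer.max %/% 4L,
                                      length(all_patches)))
  for (j in seq_along(all_patches)) {
    wt <- whiten(all_patches[[j]], filt)
    tp <- ternarize(wt, G = G, seed = seeds[j])
    tv <- analyze(tp)
    tern[[j]] <- tp
    vecs[j, ] <- embed_coords(tv)
    pmat[j, ] <- as.numeric(tv)
  }
  colnames(vecs) <- names(embed_coords(analyze(tern[[1]])))
  mask <- remove_blurred(vecs, sharp, seed = seed)
  records <- do.call(rbind, rec)
  records$sharpness <- sharp
  records$in_focus <- as.logical(mask)
  list(records = records, vectors = vecs, probs = pmat, patches = tern,
       filter = filt, mask = mask)
}
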