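# Translation-invariant coordinate system for 2x2 textures with G gray levels.
#
# Conventions (fixed; all downstream code depends on them):
#   * Glider positions are row-major within the 2x2 block:
#       A1 = top-left, A2 = top-right, A3 = bottom-left, A4 = bottom-right,
#     i.e. offsets (0,0), (0,1), (1,0), (1,1) in (row, col) form.
#   * A texture group is a nonzero coefficient vector s = (s1,s2,s3,s4) over
#     these positions, taken modulo G, canonicalized by (a) translating its
#     support so that it touches row 1 and column 1 of the glider and
#     (b) choosing the lexicographically smallest unit multiple (for prime G
#     this makes the first nonzero coefficient equal to 1).
#   * Group ordering: by correlation order (number of nonzero coefficients),
#     then by support (sorted positions, lexicographically), then by
#     coefficient vector. For G = 3 this puts the single first-order group
#     first, then the eight second-order groups (horizontal, vertical, main
#     diagonal, anti-diagonal; sum before difference), then the sixteen
#     third-order and eight fourth-order groups.
#   * A texture vector lists, for each group in this order, the G
#     probabilities p_h = Pr[ s1*A1 + ... + s4*A4 = h (mod G) ], h = 0..G-1.

GLIDER_ROW <- c(1L, 1L, 2L, 2L)
GLIDER_COL <- c(1L, 2L, 1L, 2L)

.space_cache <- new.env(parent = emptyenv())

#' Construct a gray-level patch
#'
#' A gray patch is an integer matrix whose entries are gray levels in
#' `0..G-1`. It is the object that texture analysis and synthesis act on.
#'
#' @param values Integer matrix (at least 2x2) with entries in `0..G-1`.
#' @param G Number of gray levels (default 3: black, gray, white).
#' @return An object of class `gray_patch`: the integer matrix with a `G`
#'   attribute.
#' @examples
#' p <- gray_patch(matrix(c(0, 1, 2, 0), 2, 2))
#' analyze(p, boundary = "periodic")
#' @export
gray_patch <- function(values, G = 3L) {
  G <- stopifnot_scalar_int(G, "G", min = 2)
  values <- as.matrix(values)
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("a gray patch must be at least 2x2")
  if (any(is.na(values)) || any(values != round(values)))
    stop("gray levels must be integers")
  if (any(values < 0L) || any(values >= G))
    stop("gray levels must lie in 0..G-1 (G = ", G, ")")
  storage.mode(values) <- "integer"
  structure(values, G = G, class = "gray_patch")
}

patch_G <- function(patch) {
  g <- attr(patch, "G")
  if (is.null(g)) 3L else as.integer(g)
}

#' @export
print.gray_patch <- function(x, ...) {
  cat("gray_patch: ", nrow(x), "x", ncol(x), ", G = ", patch_G(x), "\n", sep = "")
  print(unclass(x)[seq_len(min(8L, nrow(x))), seq_len(min(8L, ncol(x))), drop = FALSE])
  invisible(x)
}

greek_letter <- function(order) {
  switch(order, "γ", "β", "θ", "α")
}

coeff_symbol <- function(k, G) {
  if (k == 0L) "0"
  else if (k == 1L) "+"
  else if (G > 2L && k == G - 1L) "-"
  else as.character(k)
}

group_name <- function(coeffs, G) {
  sym <- vapply(coeffs, coeff_symbol, character(1), G = G)
  last <- max(which(coeffs != 0L))
  paste0(greek_letter(sum(coeffs != 0L)), paste(sym[seq_len(last)], collapse = ""))
}

new_texture_group <- function(coeffs, G) {
  support <- which(coeffs != 0L)
  structure(list(
    coeffs = as.integer(coeffs),
    G = as.integer(G),
    order = length(support),
    support = support,
    name = group_name(coeffs, G),
    id = paste0(paste(LETTERS[support], collapse = ""), "_",
                paste(coeffs[support], collapse = "_"))
  ), class = "texture_group")
}

#' @export
print.texture_group <- function(x, ...) {
  cat("texture_group ", x$name, " (", x$id, "): coeffs (",
      paste(x$coeffs, collapse = ","), ") mod ", x$G, "\n", sep = "")
  invisible(x)
}

all_coeff_vectors <- function(G) {
  as.matrix(expand.grid(s4 = 0:(G - 1), s3 = 0:(G - 1),
                        s2 = 0:(G - 1), s1 = 0:(G - 1)))[, 4:1, drop = FALSE]
}

lex_key <- function(s, G) sum(s * G^(3:0))

# Translate a coefficient vector's support so it touches row 1 and column 1.
translate_coeffs <- function(s) {
  supp <- which(s != 0L)
  dr <- min(GLIDER_ROW[supp]) - 1L
  dc <- min(GLIDER_COL[supp]) - 1L
  if (dr == 0L && dc == 0L) return(as.integer(s))
  out <- integer(4)
  for (p in supp) {
    q <- which(GLIDER_ROW == GLIDER_ROW[p] - dr & GLIDER_COL == GLIDER_COL[p] - dc)
    out[q] <- s[p]
  }
  out
}

#' Enumerate canonical texture groups
#'
#' Lists the canonical texture groups (coefficient vectors over the 2x2
#' glider, up to translation of their support and multiplication by a unit
#' modulo `G`). For `G = 3` there are 33 groups: 1 first-order, 8
#' second-order, 16 third-order, and 8 fourth-order; each contributes `G - 1`
#' independent coordinates, for a 66-dimensional texture space.
#'
#' @param G Number of gray levels (>= 2).
#' @param order Optional correlation order in 1..4; `NULL` returns all orders.
#' @return List of `texture_group` objects in the package's fixed ordering.
#' @examples
#' length(enumerate_groups(3, order = 2)) # 8 pairwise groups
#' space_dimension(3)                     # 66
#' @export
enumerate_groups <- function(G = 3L, order = NULL) {
  G <- stopifnot_scalar_int(G, "G", min = 2)
  key <- as.character(G)
  if (is.null(.space_cache[[key]])) {
    S <- all_coeff_vectors(G)
    S <- S[rowSums(S != 0) > 0, , drop = FALSE]
    units <- mod_units(G)
    keep <- logical(nrow(S))
    ord <- integer(nrow(S)); skey <- numeric(nrow(S)); ckey <- numeric(nrow(S))
    for (i in seq_len(nrow(S))) {
      s <- as.integer(S[i, ])
      supp <- which(s != 0L)
      if (min(GLIDER_ROW[supp]) != 1L || min(GLIDER_COL[supp]) != 1L) next
      orbit_keys <- vapply(units, function(u) lex_key((u * s) %% G, G), numeric(1))
      if (lex_key(s, G) > min(orbit_keys)) next
      keep[i] <- TRUE
      ord[i] <- length(supp)
      skey[i] <- sum(supp * 5^(4 - seq_along(supp)))
      ckey[i] <- lex_key(s, G)
    }
    idx <- which(keep)
    idx <- idx[order(ord[idx], skey[idx], ckey[idx])]
    .space_cache[[key]] <- lapply(idx, function(i) new_texture_group(S[i, ], G))
  }
  groups <- .space_cache[[key]]
  if (!is.null(order)) {
    order <- stopifnot_scalar_int(order, "order", min = 1)
    groups <- Filter(function(g) g$order == order, groups)
  }
  groups
}

#' Dimension of the texture coordinate space
#'
#' Each canonical group contributes `G - 1` independent probabilities (its G
#' probabilities sum to one), so the dimension is `(G - 1) *` the number of
#' canonical groups: 66 for `G = 3`, 10 for `G = 2`.
#'
#' @inheritParams enumerate_groups
#' @return Integer dimension.
#' @export
space_dimension <- function(G = 3L, order = NULL) {
  as.integer(G - 1L) * length(enumerate_groups(G, order))
}

group_index <- function(group, G = group$G) {
  groups <- enumerate_groups(G)
  ids <- vapply(groups, `[[`, character(1), "id")
  i <- match(group$id, ids)
  if (is.na(i)) stop("group ", group$id, " is not canonical for G = ", G)
  i
}

#' Look up a canonical texture group by name or id
#'
#' @param name Group name (e.g. `"β++"`) or positional id (e.g. `"AB_1_1"`).
#' @param G Number of gray levels.
#' @return A `texture_group`.
#' @export
texture_group <- function(name, G = 3L) {
  groups <- enumerate_groups(G)
  ids <- vapply(groups, `[[`, character(1), "id")
  nms <- vapply(groups, `[[`, character(1), "name")
  i <- match(name, ids)
  if (is.na(i)) i <- match(name, nms)
  if (is.na(i)) stop("unknown texture group: ", name)
  groups[[i]]
}

new_texture_vector <- function(probs, groups, G, counts = NULL, placements = NULL) {
  nms <- unlist(lapply(groups, function(g) paste0(g$name, "[", 0:(G - 1), "]")))
  structure(as.numeric(probs), names = nms, G = G,
            group_ids = vapply(groups, `[[`, character(1), "id"),
            counts = counts, placements = placements,
            class = "texture_vector")
}

tv_groups <- function(v) {
  G <- attr(v, "G")
  lapply(attr(v, "group_ids"), texture_group, G = G)
}

#' Extract one group's probabilities from a texture vector
#'
#' @param v A `texture_vector`.
#' @param group A `texture_group` (or name/id string).
#' @return Numeric vector of G probabilities (h = 0..G-1).
#' @export
tv_probs <- function(v, group) {
  G <- attr(v, "G")
  if (is.character(group)) group <- texture_group(group, G)
  i <- match(group$id, attr(v, "group_ids"))
  if (is.na(i)) stop("group ", group$id, " not present in texture vector")
  v[(i - 1L) * G + seq_len(G)]
}

#' @export
print.texture_vector <- function(x, ...) {
  G <- attr(x, "G")
  cat("texture_vector: ", length(x) / G, " groups x G = ", G, "\n", sep = "")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# Placement anchors and per-group modular sums, vectorized over the patch.
group_sums <- function(patch, group, boundary) {
  nr <- nrow(patch); nc <- ncol(patch); G <- patch_G(patch)
  supp <- group$support
  dr <- GLIDER_ROW[supp] - 1L; dc <- GLIDER_COL[supp] - 1L
  if (boundary == "valid") {
    nra <- nr - max(dr); nca <- nc - max(dc)
    if (nra < 1L || nca < 1L)
      stop("patch too small for group ", group$name, " (needs at least ",
           max(dr) + 1L, "x", max(dc) + 1L, ")")
    acc <- matrix(0L, nra, nca)
    for (k in seq_along(supp))
      acc <- acc + group$coeffs[supp[k]] *
        patch[dr[k] + seq_len(nra), dc[k] + seq_len(nca), drop = FALSE]
  } else {
    acc <- matrix(0L, nr, nc)
    for (k in seq_along(supp)) {
      ri <- ((seq_len(nr) - 1L + dr[k]) %% nr) + 1L
      ci <- ((seq_len(nc) - 1L + dc[k]) %% nc) + 1L
      acc <- acc + group$coeffs[supp[k]] * patch[ri, ci, drop = FALSE]
    }
  }
  acc %% G
}

#' Texture coordinates of a patch
#'
#' Glides the minimal shape containing each group's support over the patch and
#' counts the fraction of placements where the modular combination
#' `s1*A1 + s2*A2 + s3*A3 + s4*A4 (mod G)` equals each value `h`. Counts are
#' integer-exact; each group's probabilities sum to one exactly.
#'
#' @param patch A `gray_patch` (or integer matrix; `G` then taken from
#'   `attr(patch, "G")` or 3).
#' @param groups List of `texture_group`s (default: all canonical groups).
#' @param boundary `"valid"` glides only fully contained placements (the
#'   default used for image analysis); `"periodic"` wraps around, which makes
#'   the counts exactly translation invariant.
#' @return A `texture_vector`.
#' @export
analyze <- function(patch, groups = NULL, boundary = c("valid", "periodic")) {
  boundary <- match.arg(boundary)
  G <- patch_G(patch)
  if (is.null(groups)) groups <- enumerate_groups(G)
  if (inherits(groups, "texture_group")) groups <- list(groups)
  counts <- matrix(0L, length(groups), G)
  placements <- integer(length(groups))
  for (i in seq_along(groups)) {
    h <- group_sums(patch, groups[[i]], boundary)
    counts[i, ] <- tabulate(h + 1L, nbins = G)
    placements[i] <- length(h)
  }
  probs <- counts / placements
  new_texture_vector(as.vector(t(probs)), groups, G,
                     counts = as.vector(t(counts)), placements = placements)
}

# -- Block configuration probabilities and the DFT link to coordinates -------

# Configuration index convention: index = 1 + a1 + G*a2 + G^2*a3 + G^3*a4,
# with (a1, a2, a3, a4) the gray levels at glider positions A1..A4.
block_configs <- function(G) {
  as.matrix(expand.grid(a1 = 0:(G - 1), a2 = 0:(G - 1),
                        a3 = 0:(G - 1), a4 = 0:(G - 1)))
}

#' Distribution of 2x2 block configurations in a patch
#'
#' @inheritParams analyze
#' @return Numeric vector of length `G^4` of configuration probabilities (with
#'   integer counts in `attr(, "counts")`).
#' @export
block_probabilities <- function(patch, boundary = c("valid", "periodic")) {
  boundary <- match.arg(boundary)
  G <- patch_G(patch)
  nr <- nrow(patch); nc <- ncol(patch)
  if (boundary == "valid") {
    if (nr < 2L || nc < 2L) stop("patch too small for a 2x2 glider")
    sub <- function(dr, dc) patch[dr + seq_len(nr - 1L), dc + seq_len(nc - 1L)]
  } else {
    sub <- function(dr, dc) {
      patch[((seq_len(nr) - 1L + dr) %% nr) + 1L,
            ((seq_len(nc) - 1L + dc) %% nc) + 1L]
    }
  }
  idx <- sub(0L, 0L) + G * sub(0L, 1L) + G^2 * sub(1L, 0L) + G^3 * sub(1L, 1L)
  counts <- tabulate(idx + 1L, nbins = G^4)
  structure(counts / sum(counts), counts = counts, G = G)
}

#' Marginalize block probabilities to texture coordinates
#'
#' For each group, sums the block distribution over the event
#' `s . a = h (mod G)`. For periodic-boundary block probabilities this equals
#' [analyze()] exactly (same integer counts).
#'
#' @param P Block probability vector from [block_probabilities()] (or any
#'   normalized length-`G^4` vector; pass `G` if no attribute is set).
#' @param G Number of gray levels.
#' @param groups List of groups (default all canonical).
#' @return A `texture_vector`.
#' @export
coords_from_block_probs <- function(P, G = attr(P, "G") %||% 3L, groups = NULL) {
  if (length(P) != G^4) stop("`P` must have length G^4")
  if (is.null(groups)) groups <- enumerate_groups(G)
  cfg <- block_configs(G)
  counts <- attr(P, "counts")
  src <- if (is.null(counts)) as.numeric(P) else as.numeric(counts)
  tot <- sum(src)
  sums <- matrix(0, length(groups), G)
  for (i in seq_along(groups)) {
    h <- as.integer(cfg %*% groups[[i]]$coeffs) %% G
    for (k in 0:(G - 1)) sums[i, k + 1L] <- sum(src[h == k])
  }
  new_texture_vector(as.vector(t(sums / tot)), groups, G,
                     counts = if (is.null(counts)) NULL else as.vector(t(sums)),
                     placements = rep(tot, length(groups)))
}

# For every nonzero coefficient vector s, the canonical group it reduces to
# and the unit u with s (translated) = u * canonical.
canon_lookup <- function(G) {
  key <- paste0("lookup", G)
  if (!is.null(.space_cache[[key]])) return(.space_cache[[key]])
  groups <- enumerate_groups(G)
  keys <- vapply(groups, function(g) lex_key(g$coeffs, G), numeric(1))
  S <- all_coeff_vectors(G)
  units <- mod_units(G)
  tab <- matrix(NA_integer_, nrow(S), 2,
                dimnames = list(NULL, c("group", "unit")))
  for (i in seq_len(nrow(S))) {
    s <- as.integer(S[i, ])
    if (all(s == 0L)) next
    st <- translate_coeffs(s)
    for (u in units) {
      cand <- (mod_inv(u, G) * st) %% G
      j <- match(lex_key(cand, G), keys)
      if (!is.na(j)) { tab[i, ] <- c(j, u); break }
    }
  }
  .space_cache[[key]] <- tab
  tab
}

#' Reconstruct block probabilities from texture coordinates
#'
#' Inverts [coords_from_block_probs()] through a discrete Fourier transform
#' over the group `Z_G^4` of configurations: the character sum of each
#' coefficient vector is read off the corresponding canonical group's
#' probabilities (every nonzero vector is a unit multiple of a translated
#' canonical group), and the inverse transform yields the unique
#' translation-invariant block distribution with those coordinates.
#'
#' @param v A `texture_vector` covering all canonical groups.
#' @param tol Infeasibility tolerance: reconstructed probabilities below
#'   `-tol` raise an error; values in `[-tol, 0)` are clipped to 0.
#' @return Numeric vector of `G^4` block probabilities.
#' @export
block_probs_from_coords <- function(v, tol = 1e-9) {
  G <- attr(v, "G")
  groups <- enumerate_groups(G)
  if (length(v) != length(groups) * G)
    stop("`v` must cover all ", length(groups), " canonical groups")
  pm <- matrix(as.numeric(v), nrow = G) # G x n_groups
  lookup <- canon_lookup(G)
  S <- all_coeff_vectors(G)
  om <- exp(2i * pi / G)
  phat <- complex(length(S[, 1]))
  for (i in seq_len(nrow(S))) {
    if (is.na(lookup[i, "group"])) { phat[i] <- 1 + 0i; next } # s = 0
    u <- lookup[i, "unit"]; j <- lookup[i, "group"]
    phat[i] <- sum(pm[, j] * om^((u * (0:(G - 1))) %% G))
  }
  cfg <- block_configs(G)
  dot <- (S %*% t(cfg)) %% G   # G^4 x G^4
  P <- Re(as.vector(t(om^(-dot)) %*% phat)) / G^4
  if (min(P) < -tol)
    stop("infeasible texture coordinates: reconstructed block probability ",
         format(min(P)), " < ", -tol)
  P <- pmax(P, 0)
  structure(P / sum(P), G = G)
}

# -- Plane geometry -----------------------------------------------------------

#' Simplex vertex coordinates for one texture group
#'
#' Unit vectors `v_h` in `R^(G-1)`, one per probability axis, with
#' `sum(v_h) = 0` and pairwise dot products `-1/(G-1)`. A group's
#' probabilities embed as `w = sum_h p_h v_h`; conversely
#' `p_h = 1/G + (G-1)/G * (w . v_h)`. The origin (all probabilities `1/G`)
#' maps to `w = 0` and a vertex (one probability equal to 1) to `|w| = 1`, so
#' texture contrast is the Euclidean norm of `w`. For `G = 3` the vertices are
#' at angles 90 (h = 0), -30 (h = 1) and 210 degrees (h = 2).
#'
#' @param G Number of gray levels.
#' @return `(G-1) x G` matrix whose columns are the vertex vectors.
#' @export
simplex_vertices <- function(G = 3L) {
  if (G == 2L) return(matrix(c(1, -1), 1, 2))
  if (G == 3L) {
    ang <- c(pi / 2, -pi / 6, pi + pi / 6)
    return(rbind(cos(ang), sin(ang)))
  }
  K <- (G / (G - 1)) * (diag(G) - 1 / G)
  e <- eigen(K, symmetric = TRUE)
  t(e$vectors[, seq_len(G - 1)] %*% diag(sqrt(e$values[seq_len(G - 1)])))
}

#' Flatten a texture vector into the isometric coordinate embedding
#'
#' Concatenates the per-group simplex embeddings (`G - 1` numbers per group;
#' 66 for `G = 3`). In this embedding every plane direction is a unit vector
#' and texture contrast is Euclidean distance from the origin, so covariance
#' and threshold computations can use the ordinary inner product.
#'
#' @param v A `texture_vector`.
#' @return Numeric vector of length `(G-1) * n_groups`.
#' @export
embed_coords <- function(v) {
  G <- attr(v, "G")
  V <- simplex_vertices(G)
  pm <- matrix(as.numeric(v), nrow = G)
  w <- V %*% pm
  ids <- attr(v, "group_ids")
  nms <- as.vector(vapply(seq_along(ids), function(i)
    paste0(ids[i], ".w", seq_len(G - 1)), character(G - 1)))
  stats::setNames(as.vector(w), nms)
}

#' Define a direction in a simple or mixed texture plane
#'
#' A simple plane varies the probabilities of a single group; the angle is
#' measured in that group's simplex embedding (see [simplex_vertices()]: for
#' `G = 3`, 90 degrees points at the `p0` vertex). A mixed plane pairs one
#' probability axis from each of two distinct groups; angle 0 points along the
#' first axis, 90 degrees along the second, and an axis coordinate of 1
#' corresponds to full saturation (that probability equal to 1).
#'
#' @param group_a First group (object, name, or id).
#' @param angle Angle in radians within the plane.
#' @param h_a For mixed planes, the probability axis of `group_a` (0..G-1).
#' @param group_b,h_b Second group and axis for mixed planes.
#' @param G Number of gray levels.
#' @return A `plane_direction` object.
#' @export
plane_direction <- function(group_a, angle = 0, h_a = NULL, group_b = NULL,
                            h_b = NULL, G = 3L) {
  if (is.character(group_a)) group_a <- texture_group(group_a, G)
  G <- group_a$G
  if (is.null(group_b)) {
    structure(list(type = "simple", group_a = group_a, angle = angle, G = G),
              class = "plane_direction")
  } else {
    if (is.character(group_b)) group_b <- texture_group(group_b, G)
    if (is.null(h_a) || is.null(h_b))
      stop("mixed planes need `h_a` and `h_b`")
    if (identical(group_a$id, group_b$id))
      stop("mixed planes pair two distinct groups")
    structure(list(type = "mixed", group_a = group_a, h_a = as.integer(h_a),
                   group_b = group_b, h_b = as.integer(h_b),
                   angle = angle, G = G),
              class = "plane_direction")
  }
}

#' @export
print.plane_direction <- function(x, ...) {
  if (x$type == "simple")
    cat("plane_direction: simple plane ", x$group_a$name,
        ", angle ", format(x$angle), " rad\n", sep = "")
  else
    cat("plane_direction: mixed plane (", x$group_a$name, "[", x$h_a, "], ",
        x$group_b$name, "[", x$h_b, "]), angle ", format(x$angle),
        " rad\n", sep = "")
  invisible(x)
}

#' Texture vector at a given contrast along a plane direction
#'
#' Displaces the origin (all probabilities `1/G`) by `contrast` along the
#' direction; groups not named by the plane stay at the origin. Feasibility
#' (probabilities in `[0, 1]`) is not enforced here: psychometric fits may
#' legitimately extrapolate beyond the simplex, and synthesis performs its own
#' feasibility check.
#'
#' @param direction A `plane_direction`.
#' @param contrast Nonnegative distance from the origin (1 = full saturation).
#' @return A `texture_vector` of target probabilities.
#' @export
plane_point <- function(direction, contrast) {
  if (contrast < 0) stop("`contrast` must be >= 0")
  G <- direction$G
  groups <- enumerate_groups(G)
  pm <- matrix(1 / G, G, length(groups))
  V <- simplex_vertices(G)
  if (direction$type == "simple") {
    w <- numeric(nrow(V))
    w[seq_len(min(2L, nrow(V)))] <-
      (contrast * c(cos(direction$angle), sin(direction$angle)))[seq_len(min(2L, nrow(V)))]
    i <- group_index(direction$group_a)
    pm[, i] <- 1 / G + (G - 1) / G * as.vector(crossprod(V, w))
  } else {
    ca <- contrast * cos(direction$angle)
    cb <- contrast * sin(direction$angle)
    ia <- group_index(direction$group_a); ib <- group_index(direction$group_b)
    pm[, ia] <- (1 - (1 / G + (G - 1) / G * ca)) / (G - 1)
    pm[direction$h_a + 1L, ia] <- 1 / G + (G - 1) / G * ca
    pm[, ib] <- (1 - (1 / G + (G - 1) / G * cb)) / (G - 1)
    pm[direction$h_b + 1L, ib] <- 1 / G + (G - 1) / G * cb
  }
  new_texture_vector(pm[], groups, G)
}

#' Unit vector of a plane direction in the flattened embedding
#'
#' @param direction A `plane_direction`.
#' @return Numeric unit vector of length `(G-1) * n_groups` such that
#'   `embed_coords(plane_point(direction, c))` equals `c` times this vector.
#' @export
direction_vector <- function(direction) {
  G <- direction$G
  groups <- enumerate_groups(G)
  V <- simplex_vertices(G)
  d <- nrow(V)
  out <- numeric(d * length(groups))
  if (direction$type == "simple") {
    i <- group_index(direction$group_a)
    w <- numeric(d)
    w[seq_len(min(2L, d))] <-
      c(cos(direction$angle), sin(direction$angle))[seq_len(min(2L, d))]
    out[(i - 1L) * d + seq_len(d)] <- w
  } else {
    ia <- group_index(direction$group_a); ib <- group_index(direction$group_b)
    out[(ia - 1L) * d + seq_len(d)] <- cos(direction$angle) * V[, direction$h_a + 1L]
    out[(ib - 1L) * d + seq_len(d)] <- sin(direction$angle) * V[, direction$h_b + 1L]
  }
  out
}
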