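# Dihedral (D4) and gray-level symmetries and their action on texture
# coordinates.
#
# A symmetry transformation has a geometric part (one of the eight symmetries
# of the square; the six named after common usage are identity, lrFlip,
# udFlip, rot90, rot180, rot270, with transpose/antiTranspose completing the
# group under composition — rotations are clockwise) and a gray-level part,
# an affine map v -> a*v + b (mod G) with a invertible. For G = 3 the affine
# maps realize every permutation of the three gray levels; exch(B,W) is
# v -> 2v + 2, exch(B,G) is v -> 2v + 1, exch(G,W) is v -> 2v.
#
# Induced action on coordinates: for a target canonical group s, the glider
# statistic of the transformed patch pulls back to the statistic of
# s'(q) = s(gmap(q)) on the original patch, and the modular value maps as
# h -> a*h + b*sum(s). After re-canonicalizing s' (translation plus a unit
# factor u), this gives an exact permutation of (group, h) entries.

GEOMETRIES <- list(
  identity      = c(1L, 2L, 3L, 4L),
  lrFlip        = c(2L, 1L, 4L, 3L),
  udFlip        = c(3L, 4L, 1L, 2L),
  rot90         = c(2L, 4L, 1L, 3L),
  rot180        = c(4L, 3L, 2L, 1L),
  rot270        = c(3L, 1L, 4L, 2L),
  transpose     = c(1L, 3L, 2L, 4L),
  antiTranspose = c(4L, 2L, 3L, 1L)
)

geom_patch_fun <- function(geometry) {
  switch(geometry,
    identity      = function(m) m,
    lrFlip        = function(m) m[, ncol(m):1, drop = FALSE],
    udFlip        = function(m) m[nrow(m):1, , drop = FALSE],
    rot90         = function(m) t(m[nrow(m):1, , drop = FALSE]),
    rot180        = function(m) m[nrow(m):1, ncol(m):1, drop = FALSE],
    rot270        = function(m) t(m)[ncol(m):1, , drop = FALSE],
    transpose     = function(m) t(m),
    antiTranspose = function(m) t(m)[ncol(m):1, nrow(m):1, drop = FALSE]
  )
}

geom_from_perm <- function(perm) {
  for (nm in names(GEOMETRIES))
    if (identical(GEOMETRIES[[nm]], as.integer(perm))) return(nm)
  stop("permutation does not correspond to a square symmetry")
}

#' Construct a symmetry transformation
#'
#' @param geometry One of `"identity"`, `"lrFlip"`, `"udFlip"`, `"rot90"`,
#'   `"rot180"`, `"rot270"` (rotations clockwise), `"transpose"`,
#'   `"antiTranspose"`.
#' @param a,b Gray-level affine map `v -> a*v + b (mod G)`; `a` must be a
#'   unit modulo `G`.
#' @param G Number of gray levels.
#' @return A `symmetry_transformation`.
#' @seealso [gray_exchange()] for the named level swaps.
#' @export
symmetry_transformation <- function(geometry = "identity", a = 1L, b = 0L, G = 3L) {
  geometry <- match.arg(geometry, names(GEOMETRIES))
  a <- as.integer(a %% G); b <- as.integer(b %% G)
  mod_inv(a, G) # errors if not a unit
  structure(list(geometry = geometry, a = a, b = b, G = as.integer(G)),
            class = "symmetry_transformation")
}

#' Named gray-level exchange for three levels
#'
#' `exch(B,W)` exchanges black and white, `exch(B,G)` black and gray,
#' `exch(G,W)` gray and white; `cycle(BGW)` maps black to gray to white to
#' black. These are the affine maps mod 3 combined with the identity
#' geometry.
#'
#' @param which One of `"exch(B,W)"`, `"exch(B,G)"`, `"exch(G,W)"`,
#'   `"cycle(BGW)"`, `"cycle(BWG)"`.
#' @return A `symmetry_transformation` with identity geometry.
#' @export
gray_exchange <- function(which = "exch(B,W)") {
  ab <- switch(which,
    "exch(B,W)"  = c(2L, 2L),
    "exch(B,G)"  = c(2L, 1L),
    "exch(G,W)"  = c(2L, 0L),
    "cycle(BGW)" = c(1L, 1L),
    "cycle(BWG)" = c(1L, 2L),
    stop("unknown gray-level transformation: ", which))
  symmetry_transformation("identity", ab[1], ab[2], G = 3L)
}

#' @export
print.symmetry_transformation <- function(x, ...) {
  cat("symmetry_transformation: geometry ", x$geometry,
      ", value map v -> ", x$a, "*v + ", x$b, " (mod ", x$G, ")\n", sep = "")
  invisible(x)
}

#' Compose two symmetry transformations
#'
#' Returns the transformation equivalent to applying `t1` first, then `t2`.
#'
#' @param t2,t1 `symmetry_transformation`s with equal `G`.
#' @export
compose_transforms <- function(t2, t1) {
  stopifnot(t1$G == t2$G)
  # patches: t2(t1(P)); positions compose accordingly
  p1 <- GEOMETRIES[[t1$geometry]]; p2 <- GEOMETRIES[[t2$geometry]]
  perm <- p2[p1]
  symmetry_transformation(geom_from_perm(perm),
                          (t2$a * t1$a) %% t1$G,
                          (t2$a * t1$b + t2$b) %% t1$G, t1$G)
}

#' Invert a symmetry transformation
#' @param t A `symmetry_transformation`.
#' @export
invert_transform <- function(t) {
  perm <- order(GEOMETRIES[[t$geometry]])
  ainv <- mod_inv(t$a, t$G)
  symmetry_transformation(geom_from_perm(perm), ainv,
                          (-ainv * t$b) %% t$G, t$G)
}

#' Apply a symmetry transformation to a patch
#'
#' Applies the geometric transform to the grid, then the gray-level map to
#' each check.
#'
#' @param t A `symmetry_transformation`.
#' @param patch A `gray_patch`.
#' @return The transformed `gray_patch`.
#' @export
apply_to_patch <- function(t, patch) {
  G <- patch_G(patch)
  stopifnot(G == t$G)
  m <- geom_patch_fun(t$geometry)(unclass(patch))
  gray_patch((t$a * m + t$b) %% G, G = G)
}

# For a target canonical group s (as seen in the transformed patch), the
# source canonical group on the original patch plus the map h_source -> h.
coeff_row_index <- function(s, G) {
  # row of all_coeff_vectors(G) holding s (s4 varies fastest)
  1L + s[4] + G * s[3] + G^2 * s[2] + G^3 * s[1]
}

pullback_group <- function(t, group) {
  G <- t$G
  gmap <- GEOMETRIES[[t$geometry]]
  s <- group$coeffs
  sprime <- translate_coeffs(s[gmap])
  lookup <- canon_lookup(G)
  i <- coeff_row_index(sprime, G)
  src <- lookup[i, "group"]; u <- lookup[i, "unit"]
  sigma <- sum(s) %% G
  hmap <- ((t$a * u * (0:(G - 1)) + t$b * sigma) %% G) + 1L
  list(source = enumerate_groups(G)[[src]], h_from_source = hmap)
}

#' Image of a texture group under a symmetry transformation
#'
#' Returns the canonical group that `group`'s statistics occupy after the
#' patch transformation, together with the induced map of modular values:
#' entry `h + 1` of `h_map` gives the value (0-based) that `h` is sent to.
#'
#' @param t A `symmetry_transformation`.
#' @param group A `texture_group`.
#' @return `list(group = <texture_group>, h_map = <integer vector>)`.
#' @export
transform_group <- function(t, group) {
  # Pull `group` back through the inverse transformation: with T' = t^{-1},
  # p_{P, group}(pb$h_from_source[k]) = p_{t(P), pb$source}(k), so pb$source
  # is the image group and h_from_source inverts the value map.
  pb <- pullback_group(invert_transform(t), group)
  hmap <- integer(t$G)
  hmap[pb$h_from_source] <- 0:(t$G - 1)
  list(group = pb$source, h_map = hmap)
}

#' Action of a symmetry transformation on texture coordinates
#'
#' Permutes groups and modular values so that, exactly and for every patch,
#' `transform_coordinates(t, analyze(p, boundary = "periodic"))` equals
#' `analyze(apply_to_patch(t, p), boundary = "periodic")`.
#'
#' @param t A `symmetry_transformation`.
#' @param v A `texture_vector` over all canonical groups.
#' @return The transformed `texture_vector`.
#' @export
transform_coordinates <- function(t, v) {
  G <- attr(v, "G")
  stopifnot(G == t$G)
  groups <- enumerate_groups(G)
  if (length(v) != G * length(groups))
    stop("`v` must cover all canonical groups")
  pm <- matrix(as.numeric(v), nrow = G)
  out <- matrix(NA_real_, G, length(groups))
  for (i in seq_along(groups)) {
    pb <- pullback_group(t, groups[[i]])
    j <- group_index(pb$source)
    out[pb$h_from_source, i] <- pm[, j]
  }
  new_texture_vector(as.vector(out), groups, G)
}

#' Image of a plane direction under a symmetry transformation
#'
#' @param t A `symmetry_transformation`.
#' @param direction A `plane_direction`.
#' @return The transformed `plane_direction` (canonicalized so that, for
#'   mixed planes, the group with the smaller canonical index is the first
#'   axis).
#' @export
transform_direction <- function(t, direction) {
  G <- direction$G
  V <- simplex_vertices(G)
  if (direction$type == "simple") {
    tg <- transform_group(t, direction$group_a)
    m <- tg$h_map
    M <- ((G - 1) / G) * Reduce(`+`, lapply(0:(G - 1), function(h)
      V[, m[h + 1L] + 1L] %*% t(V[, h + 1L])))
    w <- M %*% c(cos(direction$angle), sin(direction$angle))[seq_len(nrow(V))]
    plane_direction(tg$group, angle = atan2(w[2], w[1]), G = G)
  } else {
    ta <- transform_group(t, direction$group_a)
    tb <- transform_group(t, direction$group_b)
    ha <- ta$h_map[direction$h_a + 1L]
    hb <- tb$h_map[direction$h_b + 1L]
    ia <- group_index(ta$group); ib <- group_index(tb$group)
    if (ia <= ib)
      plane_direction(ta$group, angle = direction$angle, h_a = ha,
                      group_b = tb$group, h_b = hb, G = G)
    else
      plane_direction(tb$group, angle = pi / 2 - direction$angle, h_a = hb,
                      group_b = ta$group, h_b = ha, G = G)
  }
}

#' Canonical identifier of a plane direction
#'
#' Used to pair directions when computing threshold changes; angles are
#' reduced modulo 2*pi and rounded.
#'
#' @param direction A `plane_direction`.
#' @param digits Rounding digits for the angle.
#' @export
direction_key <- function(direction, digits = 6) {
  ang <- direction$angle %% (2 * pi)
  ang <- round(ang, digits) %% round(2 * pi, digits)
  if (direction$type == "simple")
    paste0("S|", direction$group_a$id, "|", format(ang, nsmall = digits))
  else
    paste0("M|", direction$group_a$id, "[", direction$h_a, "]|",
           direction$group_b$id, "[", direction$h_b, "]|",
           format(ang, nsmall = digits))
}

#' A measured or predicted threshold in one texture direction
#'
#' @param direction A `plane_direction`.
#' @param threshold Positive threshold in contrast units.
#' @param log_err Optional log-space uncertainty.
#' @param subject Optional subject label.
#' @export
threshold_record <- function(direction, threshold, log_err = NA_real_,
                             subject = NA_character_) {
  stopifnot(threshold > 0)
  structure(list(direction = direction, threshold = threshold,
                 log_err = log_err, subject = subject),
            class = "threshold_record")
}

#' Change in log thresholds under a symmetry transformation
#'
#' Maps each record's direction through `t` and pairs it with the record
#' available at the transformed direction. Directions on which `t` acts
#' trivially, and directions whose image carries no record, are excluded and
#' counted.
#'
#' @param t A `symmetry_transformation`.
#' @param records List of `threshold_record`s.
#' @return `list(log_diffs, n_trivial, n_unmatched)`, where `log_diffs[i]` is
#'   `log(threshold at transformed direction) - log(threshold at original)`.
#' @export
threshold_change <- function(t, records) {
  keys <- vapply(records, function(r) direction_key(r$direction), character(1))
  thr <- vapply(records, `[[`, numeric(1), "threshold")
  diffs <- numeric(0); n_triv <- 0L; n_unm <- 0L
  for (r in records) {
    k0 <- direction_key(r$direction)
    k1 <- direction_key(transform_direction(t, r$direction))
    if (k1 == k0) { n_triv <- n_triv + 1L; next }
    j <- match(k1, keys)
    if (is.na(j)) { n_unm <- n_unm + 1L; next }
    diffs <- c(diffs, log(thr[j]) - log(r$threshold))
  }
  list(log_diffs = diffs, n_trivial = n_triv, n_unmatched = n_unm)
}
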