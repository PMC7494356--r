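# Maximum-entropy texture synthesis.
#
# Single-group textures are generated exactly: cells are visited in raster
# order (processed as anti-diagonal wavefronts so the inner loop is
# vectorized); the first cells that cannot complete a glider placement are
# drawn i.i.d. uniform, and every later cell is solved from an independent
# draw h ~ probs of the group's modular statistic, so the constrained group's
# empirical distribution is an unbiased i.i.d. sample of `probs` and all
# remaining structure is maximally random.
#
# Mixed-plane textures (one probability axis pinned in each of two groups)
# are generated by the same sequential scheme with the local conditional
# taken proportional to the product of per-group weight factors. The product
# rule is exact when either group sits at its unbiased value and acquires an
# O(saturation^2) bias otherwise, so the weights are calibrated: a few probe
# patches are synthesized and the weights reweighted multiplicatively until
# the realized coordinates match the requested ones. Saturations that the
# conditional construction cannot reach (zero-probability cells, or
# calibration failing to converge) raise an infeasibility error; such
# unreachable combinations genuinely exist near the boundary of the space.

# Raster-last support offset: the cell of the glider support that is filled
# last in raster order; every other support cell is then up/left of it.
raster_last <- function(support) {
  r <- GLIDER_ROW[support]; c <- GLIDER_COL[support]
  o <- order(r, c)
  support[o[length(o)]]
}

make_constraint <- function(group, w) {
  supp <- group$support
  q <- raster_last(supp)
  list(coeffs = group$coeffs, support = supp, q = q,
       qr = GLIDER_ROW[q] - 1L, qc = GLIDER_COL[q] - 1L,
       maxdr = max(GLIDER_ROW[supp]) - 1L, maxdc = max(GLIDER_COL[supp]) - 1L,
       sq_inv = NULL, w = as.numeric(w), group = group)
}

# Sequential conditional fill. constraints: list from make_constraint().
# Draws consume the current RNG stream; wrap calls in with_seed().
synth_fill <- function(constraints, nr, nc, G) {
  A <- matrix(NA_integer_, nr, nc)
  cellr <- as.vector(row(A)); cellc <- as.vector(col(A))
  wave <- 2L * cellr + cellc
  for (w in sort(unique(wave))) {
    idx <- which(wave == w)
    r <- cellr[idx]; c <- cellc[idx]
    W <- matrix(1, length(idx), G)
    active <- rep(FALSE, length(idx))
    for (cn in constraints) {
      ar <- r - cn$qr; ac <- c - cn$qc
      ok <- ar >= 1L & ac >= 1L & (ar + cn$maxdr) <= nr & (ac + cn$maxdc) <= nc
      if (!any(ok)) next
      active <- active | ok
      partial <- integer(sum(ok))
      for (p in setdiff(cn$support, cn$q)) {
        rr <- ar[ok] + GLIDER_ROW[p] - 1L
        cc <- ac[ok] + GLIDER_COL[p] - 1L
        partial <- partial + cn$coeffs[p] * A[cbind(rr, cc)]
      }
      sq <- cn$coeffs[cn$q]
      for (v in 0:(G - 1)) {
        h <- (partial + sq * v) %% G
        W[which(ok), v + 1L] <- W[which(ok), v + 1L] * cn$w[h + 1L]
      }
    }
    tot <- rowSums(W)
    if (any(active & tot <= 0))
      stop("infeasible texture target: the sequential construction reached a ",
           "cell with no admissible gray level (requested saturation is not ",
           "achievable)")
    vals <- integer(length(idx))
    if (any(!active)) vals[!active] <- sample.int(G, sum(!active), replace = TRUE) - 1L
    if (any(active)) {
      Wa <- W[active, , drop = FALSE] / tot[active]
      u <- stats::runif(nrow(Wa))
      cum <- Wa
      if (G > 1) for (k in 2:G) cum[, k] <- cum[, k] + cum[, k - 1L]
      vals[active] <- rowSums(cum < u)
    }
    A[cbind(r, c)] <- vals
  }
  gray_patch(A, G = G)
}

check_probs <- function(probs, G, what = "probs") {
  if (length(probs) != G || any(is.na(probs)) || any(probs < -1e-12) ||
      abs(sum(probs) - 1) > 1e-8)
    stop("`", what, "` must be ", G,
         " nonnegative probabilities summing to 1")
  pmax(as.numeric(probs), 0)
}

#' Synthesize a maximum-entropy texture with one constrained group
#'
#' Generates a patch whose modular statistic in `group` is an i.i.d. sample
#' from `probs` (so the analyzed coordinates of the constrained group
#' converge to `probs` with no bias beyond edge seeding), while all other
#' groups remain at their unbiased values `1/G`. Any point of the probability
#' simplex is achievable for a single group. Deterministic given `seed`.
#'
#' @param group A `texture_group` (or name/id).
#' @param probs G probabilities for the group's modular values h = 0..G-1.
#' @param size Patch size: scalar or `c(nrow, ncol)`.
#' @param seed Integer seed.
#' @return A `gray_patch`.
#' @examples
#' p <- synthesize_single_group("AB_1_2", c(0, 0, 1), size = 16, seed = 1)
#' tv_probs(analyze(p), "AB_1_2") # exactly (0, 0, 1)
#' @export
synthesize_single_group <- function(group, probs, size, seed = 1L) {
  if (is.character(group)) group <- texture_group(group)
  G <- group$G
  probs <- check_probs(probs, G)
  size <- rep(as.integer(size), length.out = 2L)
  if (any(size < 2L)) stop("`size` must be at least 2x2")
  with_seed(seed, synth_fill(list(make_constraint(group, probs)),
                             size[1], size[2], G))
}

#' Synthesize a maximum-entropy texture constrained in two groups
#'
#' Pins one probability axis in each of two distinct groups (a "mixed plane"
#' target): `Pr[statistic of group_a = h_a] = value_a` with the group's
#' remaining probability split evenly, and likewise for `group_b`. The
#' sequential conditional construction is calibrated on probe patches so the
#' realized coordinates match the target; combinations that are too saturated
#' to coexist raise an infeasibility error echoing the attempted target.
#'
#' @param group_a,group_b Distinct `texture_group`s (or names/ids).
#' @param h_a,h_b Constrained modular value per group (0..G-1).
#' @param value_a,value_b Target probabilities for those values.
#' @param size Patch size: scalar or `c(nrow, ncol)`.
#' @param seed Integer seed.
#' @param calibrate Number of probe-and-reweight iterations (default 5).
#' @param probe_size Probe patch size used during calibration.
#' @param tol Maximum allowed deviation of realized from requested axis
#'   probabilities after calibration before declaring the target infeasible.
#' @return A `gray_patch`.
#' @export
synthesize_mixed <- function(group_a, h_a, value_a, group_b, h_b, value_b,
                             size, seed = 1L, calibrate = 5L,
                             probe_size = 128L, tol = 0.05) {
  if (is.character(group_a)) group_a <- texture_group(group_a)
  if (is.character(group_b)) group_b <- texture_group(group_b)
  if (identical(group_a$id, group_b$id))
    stop("mixed synthesis needs two distinct groups")
  G <- group_a$G
  axis_probs <- function(h, value) {
    if (value < 0 || value > 1)
      stop("axis probabilities must lie in [0, 1]")
    p <- rep((1 - value) / (G - 1), G); p[h + 1L] <- value; p
  }
  ta <- axis_probs(h_a, value_a); tb <- axis_probs(h_b, value_b)
  size <- rep(as.integer(size), length.out = 2L)
  with_seed(seed, {
    wa <- ta; wb <- tb
    for (it in seq_len(calibrate)) {
      probe <- synth_fill(list(make_constraint(group_a, wa),
                               make_constraint(group_b, wb)),
                          probe_size, probe_size, G)
      pa <- tv_probs(analyze(probe, list(group_a)), group_a)
      pb <- tv_probs(analyze(probe, list(group_b)), group_b)
      wa <- wa * (ta / pmax(pa, 1e-4))
      wb <- wb * (tb / pmax(pb, 1e-4))
      wa <- pmax(wa, 0) / sum(pmax(wa, 0))
      wb <- pmax(wb, 0) / sum(pmax(wb, 0))
    }
    if (calibrate > 0) {
      probe <- synth_fill(list(make_constraint(group_a, wa),
                               make_constraint(group_b, wb)),
                          probe_size, probe_size, G)
      pa <- tv_probs(analyze(probe, list(group_a)), group_a)
      pb <- tv_probs(analyze(probe, list(group_b)), group_b)
      err <- max(abs(pa[h_a + 1L] - value_a), abs(pb[h_b + 1L] - value_b))
      if (err > tol)
        stop("infeasible mixed texture target (", group_a$name, "[", h_a,
             "] = ", value_a, ", ", group_b$name, "[", h_b, "] = ", value_b,
             "): calibrated construction deviates by ", format(err, digits = 3))
    }
    synth_fill(list(make_constraint(group_a, wa), make_constraint(group_b, wb)),
               size[1], size[2], G)
  })
}

#' Specify a texture for stimulus generation
#'
#' @param group,probs Single-group target: group plus its G probabilities.
#' @param group_a,h_a,value_a,group_b,h_b,value_b Mixed target (see
#'   [synthesize_mixed()]).
#' @return A `texture_spec` (either `"single"` or `"mixed"`); `texture_spec()`
#'   with no arguments gives the unbiased i.i.d. texture.
#' @export
texture_spec <- function(group = NULL, probs = NULL, group_a = NULL, h_a = NULL,
                         value_a = NULL, group_b = NULL, h_b = NULL,
                         value_b = NULL) {
  if (!is.null(group)) {
    if (is.character(group)) group <- texture_group(group)
    structure(list(type = "single", group = group,
                   probs = check_probs(probs, group$G)), class = "texture_spec")
  } else if (!is.null(group_a)) {
    if (is.character(group_a)) group_a <- texture_group(group_a)
    if (is.character(group_b)) group_b <- texture_group(group_b)
    structure(list(type = "mixed", group_a = group_a, h_a = h_a,
                   value_a = value_a, group_b = group_b, h_b = h_b,
                   value_b = value_b), class = "texture_spec")
  } else {
    structure(list(type = "iid"), class = "texture_spec")
  }
}

#' Synthesize a patch from a texture specification
#'
#' @param spec A `texture_spec`.
#' @param size Patch size: scalar or `c(nrow, ncol)`.
#' @param seed Integer seed.
#' @param G Gray levels (used for the `"iid"` spec).
#' @return A `gray_patch`.
#' @export
synthesize <- function(spec, size, seed = 1L, G = 3L) {
  size <- rep(as.integer(size), length.out = 2L)
  switch(spec$type,
    iid = with_seed(seed, gray_patch(
      matrix(sample.int(G, size[1] * size[2], replace = TRUE) - 1L,
             size[1], size[2]), G = G)),
    single = synthesize_single_group(spec$group, spec$probs, size, seed),
    mixed = synthesize_mixed(spec$group_a, spec$h_a, spec$value_a,
                             spec$group_b, spec$h_b, spec$value_b,
                             size, seed))
}

#' Render a four-alternative forced-choice stimulus array
#'
#' A 64x64-check array containing a 16x64 (or 64x16) target strip at an
#' 8-check margin from the named side. One region is filled with the
#' structured texture, the other with the unbiased i.i.d. texture; which one
#' is structured follows `structured_target`. With the defaults and
#' `side = "top"`, the strip occupies rows 9-24 (1-based).
#'
#' @param texture A `texture_spec` for the structured region.
#' @param side One of `"left"`, `"right"`, `"top"`, `"bottom"`.
#' @param structured_target If `TRUE` the strip is structured and the
#'   background i.i.d.; if `FALSE` the reverse.
#' @param seed Integer seed.
#' @param size Array side length (default 64).
#' @param strip Strip thickness (default 16).
#' @param margin Margin between strip and array edge (default 8).
#' @return A `gray_patch` with attributes `side`, `structured_target`,
#'   `strip_rows`, `strip_cols`.
#' @export
make_stimulus <- function(texture, side = c("left", "right", "top", "bottom"),
                          structured_target = TRUE, seed = 1L,
                          size = 64L, strip = 16L, margin = 8L) {
  side <- match.arg(side)
  G <- if (texture$type == "single") texture$group$G
       else if (texture$type == "mixed") texture$group_a$G else 3L
  rows <- cols <- seq_len(size)
  if (side == "top")    rows <- margin + seq_len(strip)
  if (side == "bottom") rows <- size - margin - strip + seq_len(strip)
  if (side == "left")   cols <- margin + seq_len(strip)
  if (side == "right")  cols <- size - margin - strip + seq_len(strip)
  arr <- with_seed(seed, {
    s1 <- sample.int(.Machine$integer.max / 2L, 2L)
    if (structured_target) {
      bg <- synthesize(texture_spec(), c(size, size), seed = s1[1], G = G)
      tg <- synthesize(texture, c(length(rows), length(cols)), seed = s1[2], G = G)
      bg[rows, cols] <- tg
      bg
    } else {
      bg <- synthesize(texture, c(size, size), seed = s1[1], G = G)
      tg <- synthesize(texture_spec(), c(length(rows), length(cols)),
                       seed = s1[2], G = G)
      bg[rows, cols] <- tg
      bg
    }
  })
  structure(gray_patch(arr, G = G), side = side,
            structured_target = structured_target,
            strip_rows = rows, strip_cols = cols)
}
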