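# Maximum-entropy synthesis: exactness of single-group constraints,
# round-trip recovery, entropy of unconstrained statistics, determinism.

test_that("point-mass constraints are satisfied exactly", {
  # horizontal difference locked to h = 2: 'mini-gradients'
  p <- synthesize_single_group("AB_1_2", c(0, 0, 1), size = 16, seed = 1)
  expect_equal(unname(tv_probs(analyze(p), "AB_1_2")), c(0, 0, 1))
  # horizontal sum locked to h = 0: every horizontal neighbor pair sums to 0
  p2 <- synthesize_single_group("AB_1_1", c(1, 0, 0), size = 16, seed = 2)
  sums <- (unclass(p2)[, -16] + unclass(p2)[, -1]) %% 3
  expect_true(all(sums == 0))
})

test_that("synthesis is deterministic given the seed", {
  a <- synthesize_single_group("BC_1_1", c(0.5, 0.3, 0.2), size = 32, seed = 9)
  b <- synthesize_single_group("BC_1_1", c(0.5, 0.3, 0.2), size = 32, seed = 9)
  expect_identical(a, b)
  c_ <- synthesize_single_group("BC_1_1", c(0.5, 0.3, 0.2), size = 32, seed = 10)
  expect_false(identical(a, c_))
})

test_that("unconstrained textures look i.i.d. uniform", {
  p <- synthesize_single_group("AB_1_1", c(1, 1, 1) / 3, size = 128, seed = 3)
  v <- analyze(p)
  expect_lt(max(abs(as.numeric(v) - 1 / 3)), 0.05)
  expect_lt(max(abs(tabulate(unclass(p) + 1L, 3) / 128^2 - 1 / 3)), 0.02)
})

test_that("analyzed coordinates recover the target across groups and targets", {
  targets <- list(c(0.6, 0.25, 0.15), c(0.2, 0.2, 0.6), c(0.45, 0.45, 0.1))
  for (g in enumerate_groups(3, 2)[c(1, 4, 6, 7)]) {
    for (tgt in targets) {
      est <- rowMeans(vapply(1:5, function(s)
        unname(tv_probs(analyze(synthesize_single_group(g, tgt, 64, seed = s)), g)),
        numeric(3)))
      n_eff <- 5 * 64 * 63
      se <- sqrt(tgt * (1 - tgt) / n_eff)
      expect_true(all(abs(est - tgt) < pmax(4 * se, 1e-12)),
                  label = paste("round trip", g$id))
    }
  }
})

test_that("a vacuous constraint reproduces the i.i.d. ensemble distribution", {
  # count distribution of a second group's coordinate over many 4x4 periodic
  # patches: constrained-at-origin ensemble vs truly i.i.d. ensemble. This
  # catches any spurious structure introduced by the sequential construction
  # (e.g. biased seeding) when the constraint carries no information.
  n <- 1500
  counts_of <- function(gen) {
    vapply(seq_len(n), function(s) {
      p <- gen(s)
      attr(analyze(p, list(texture_group("AC_1_1")), boundary = "periodic"),
           "counts")[1]
    }, numeric(1))
  }
  con <- counts_of(function(s)
    synthesize_single_group("AB_1_1", c(1, 1, 1) / 3, size = 4, seed = s))
  iid <- counts_of(function(s)
    synthesize(texture_spec(), size = 4, seed = s + n))
  # two-sample chi-square over pooled count bins, alpha = 0.01
  bins <- c(0:6, Inf)
  oc <- table(cut(con, bins, right = FALSE))
  oi <- table(cut(iid, bins, right = FALSE))
  keep <- (oc + oi) >= 10
  suppressWarnings(
    tst <- stats::chisq.test(rbind(oc[keep], oi[keep])))
  expect_gt(tst$p.value, 0.01)
})

test_that("unconstrained non-harmonic coordinates stay centered at 1/G", {
  # under a saturated horizontal constraint, the placements of other groups
  # are no longer independent (their joint distribution legitimately differs
  # from i.i.d.), but maximum entropy keeps their mean at 1/G
  con <- vapply(1:300, function(s) {
    p <- synthesize_single_group("AB_1_1", c(0.6, 0.2, 0.2), size = 8, seed = s)
    unname(tv_probs(analyze(p, boundary = "periodic"), "AC_1_1"))
  }, numeric(3))
  se <- apply(con, 1, stats::sd) / sqrt(ncol(con))
  expect_true(all(abs(rowMeans(con) - 1 / 3) < 4 * se + 1e-9))
})

test_that("mixed-plane synthesis hits both constrained axes", {
  res <- vapply(1:6, function(s) {
    p <- synthesize_mixed("AB_1_1", 0, 0.6, "AB_1_2", 1, 1 / 3, 64, seed = s)
    c(tv_probs(analyze(p), "AB_1_1")[1], tv_probs(analyze(p), "AB_1_2")[2])
  }, numeric(2))
  expect_lt(abs(mean(res[1, ]) - 0.6), 0.02)
  expect_lt(abs(mean(res[2, ]) - 1 / 3), 0.02)
  # different orientations
  res2 <- vapply(1:6, function(s) {
    p <- synthesize_mixed("AB_1_1", 0, 0.55, "AC_1_1", 0, 0.5, 64, seed = s)
    c(tv_probs(analyze(p), "AB_1_1")[1], tv_probs(analyze(p), "AC_1_1")[1])
  }, numeric(2))
  expect_lt(abs(mean(res2[1, ]) - 0.55), 0.025)
  expect_lt(abs(mean(res2[2, ]) - 0.5), 0.025)
  # both constraints at the origin: i.i.d.-like
  p0 <- synthesize_mixed("AB_1_1", 0, 1 / 3, "AC_1_1", 0, 1 / 3, 96, seed = 1)
  expect_lt(max(abs(as.numeric(analyze(p0)) - 1 / 3)), 0.06)
})

test_that("unreachable saturation combinations raise an infeasibility error", {
  expect_error(
    synthesize_mixed("AB_1_1", 0, 1, "AB_1_2", 1, 1, 32, seed = 1),
    "infeasible")
  expect_error(synthesize_single_group("AB_1_1", c(0.5, 0.2, 0.2), 16),
               "sum")
})

test_that("stimulus arrays have the documented geometry", {
  spec <- texture_spec(group = "AB_1_2", probs = c(0, 0, 1))
  st <- make_stimulus(spec, side = "top", structured_target = TRUE, seed = 4)
  expect_identical(dim(st), c(64L, 64L))
  expect_identical(attr(st, "strip_rows"), 9:24)
  # the structured strip satisfies its constraint exactly
  strip <- gray_patch(unclass(st)[9:24, ])
  expect_equal(unname(tv_probs(analyze(strip), "AB_1_2")), c(0, 0, 1))
  # background is i.i.d.-like, not structured
  bg <- gray_patch(unclass(st)[30:64, ])
  expect_gt(tv_probs(analyze(bg), "AB_1_2")[1], 0.15)
  # sides place the strip correctly
  sr <- make_stimulus(spec, side = "right", seed = 4)
  expect_identical(attr(sr, "strip_cols"), 41:56)
  # structured background variant flips which region is structured
  sb <- make_stimulus(spec, side = "top", structured_target = FALSE, seed = 4)
  bg2 <- gray_patch(unclass(sb)[30:64, ])
  expect_equal(unname(tv_probs(analyze(bg2), "AB_1_2"))[3], 1)
  # determinism
  expect_identical(make_stimulus(spec, side = "left", seed = 8),
                   make_stimulus(spec, side = "left", seed = 8))
  expect_error(make_stimulus(spec, side = "up"), "arg")
})
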