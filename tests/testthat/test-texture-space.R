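# The translation-invariant coordinate system for 2x2 gliders.

test_that("canonical group counts and space dimensions are correct", {
  expect_length(enumerate_groups(3), 33)
  expect_length(enumerate_groups(3, order = 1), 1)
  expect_length(enumerate_groups(3, order = 2), 8)
  expect_length(enumerate_groups(3, order = 3), 16)
  expect_length(enumerate_groups(3, order = 4), 8)
  expect_identical(space_dimension(3), 66L)
  expect_identical(space_dimension(3, order = 2), 16L)
  expect_identical(space_dimension(3, order = 3), 32L)
  expect_identical(space_dimension(3, order = 4), 16L)
  expect_length(enumerate_groups(2), 10)
  expect_identical(space_dimension(2), 10L)
  expect_error(enumerate_groups(1), "G")
})

test_that("canonical groups touch row 1 and column 1 with leading coefficient 1", {
  for (G in 2:3) for (g in enumerate_groups(G)) {
    rows <- c(1, 1, 2, 2)[g$support]; cols <- c(1, 2, 1, 2)[g$support]
    expect_identical(min(rows), 1)
    expect_identical(min(cols), 1)
    expect_identical(g$coeffs[g$support][1], 1L)
  }
})

test_that("analyze matches hand counts and trivial cases", {
  zeros <- gray_patch(matrix(0L, 8, 8))
  expect_equal(unname(tv_probs(analyze(zeros), "AB_1_2")), c(1, 0, 0))
  expect_equal(unname(tv_probs(analyze(zeros), "AB_1_1")), c(1, 0, 0))
  # exhaustive hand count: periodic 2x2 patch [[0,1],[2,0]], horizontal sums
  # per wrapped placement are {0+1, 1+0, 2+0, 0+2} = {1,1,2,2}
  p <- gray_patch(matrix(c(0L, 1L, 2L, 0L), 2, 2, byrow = TRUE))
  expect_equal(unname(tv_probs(analyze(p, boundary = "periodic"), "AB_1_1")),
               c(0, 0.5, 0.5))
  # valid boundary glides the minimal 1x2 shape: 2 placements per row
  expect_equal(attr(analyze(p, boundary = "valid"), "placements")[2], 2)
  expect_error(analyze(gray_patch(matrix(0L, 2, 2))[, 1, drop = FALSE]),
               "too small")
})

test_that("each group's probabilities sum to one exactly", {
  set.seed(11)
  for (rep in 1:5) {
    v <- analyze(random_patch(7, 9), boundary = sample(c("valid", "periodic"), 1))
    sums <- colSums(matrix(as.numeric(v), nrow = 3))
    expect_identical(sums, rep(1, 33))
  }
})

test_that("block probabilities enumerate G^4 configurations", {
  zeros <- gray_patch(matrix(0L, 6, 6))
  P <- block_probabilities(zeros)
  expect_length(P, 81)
  expect_equal(which(P == 1), 1L) # point mass on the all-zeros configuration
  p <- gray_patch(matrix(c(0L, 1L, 2L, 0L), 2, 2, byrow = TRUE))
  Pp <- block_probabilities(p, boundary = "periodic")
  expect_equal(sort(Pp[Pp > 0]), rep(0.25, 4)) # 4 wrapped placements
  # large i.i.d. uniform patch: roughly uniform over the 81 bins
  set.seed(2)
  Pu <- block_probabilities(random_patch(300, 300))
  expect_lt(max(abs(Pu - 1 / 81)), 5 / sqrt(300^2))
})

test_that("analyze equals block-probability marginalization under periodic boundaries", {
  set.seed(3)
  for (G in 2:3) for (rep in 1:20) {
    patch <- random_patch(sample(2:6, 1), sample(2:6, 1), G = G)
    v1 <- analyze(patch, boundary = "periodic")
    v2 <- coords_from_block_probs(block_probabilities(patch, "periodic"), G = G)
    expect_identical(as.numeric(v1), as.numeric(v2))
  }
})

test_that("block probabilities reconstruct exactly from coordinates", {
  # uniform distribution maps to the origin of texture space
  set.seed(4)
  vu <- coords_from_block_probs(structure(rep(1 / 81, 81), G = 3L))
  expect_equal(as.numeric(vu), rep(1 / 3, 99))
  # point mass on all-zeros: every group at (1, 0, 0)
  P0 <- structure(c(1, rep(0, 80)), G = 3L)
  v0 <- coords_from_block_probs(P0)
  expect_equal(as.numeric(matrix(v0, nrow = 3)[1, ]), rep(1, 33))
  expect_equal(as.numeric(block_probs_from_coords(v0)), as.numeric(P0))
  # round trip on empirical translation-invariant distributions
  for (G in 2:3) for (rep in 1:10) {
    patch <- random_patch(sample(3:6, 1), sample(3:6, 1), G = G)
    P <- block_probabilities(patch, "periodic")
    P2 <- block_probs_from_coords(coords_from_block_probs(P, G = G))
    expect_equal(as.numeric(P2), as.numeric(P), tolerance = 1e-12)
  }
  # infeasible coordinates: a vector that is not translation-consistent
  bad <- plane_point(plane_direction("AB_1_1", angle = 0), 1.8)
  expect_error(block_probs_from_coords(bad), "infeasible")
})

test_that("relabeling gray levels permutes coordinates predictably", {
  set.seed(5)
  t <- gray_exchange("exch(B,W)")
  for (rep in 1:10) {
    patch <- random_patch(5, 5)
    v1 <- analyze(apply_to_patch(t, patch), boundary = "periodic")
    v2 <- transform_coordinates(t, analyze(patch, boundary = "periodic"))
    expect_identical(as.numeric(v1), as.numeric(v2))
  }
})

test_that("coordinates of large i.i.d. patches approach the origin", {
  set.seed(6)
  sizes <- c(32, 128)
  devs <- vapply(sizes, function(n) {
    max(abs(as.numeric(analyze(random_patch(n, n))) - 1 / 3))
  }, numeric(1))
  # deviation shrinks roughly like 1/sqrt(#placements)
  expect_lt(devs[2], devs[1])
  expect_lt(devs[2], 10 / 128)
})

test_that("plane geometry: origin, vertices, saturation, and embedding norms", {
  d0 <- plane_direction("AB_1_1", angle = pi / 2)
  expect_equal(as.numeric(plane_point(d0, 0)), rep(1 / 3, 99))
  # angle pi/2 points at the p0 vertex; contrast 1 reaches (1,0,0)
  expect_equal(unname(tv_probs(plane_point(d0, 1), "AB_1_1")), c(1, 0, 0))
  # mixed plane, angle 0, contrast 1: the first axis probability reaches 1
  dm <- plane_direction("AB_1_1", angle = 0, h_a = 0, group_b = "AB_1_2", h_b = 1)
  expect_equal(unname(tv_probs(plane_point(dm, 1), "AB_1_1"))[1], 1)
  # direction vectors are unit and consistent with the embedding
  for (dir in list(d0, dm, plane_direction("BC_1_2", angle = 1.1))) {
    u <- direction_vector(dir)
    expect_equal(sum(u^2), 1)
    expect_equal(embed_coords(plane_point(dir, 0.4)), 0.4 * u,
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  expect_error(plane_point(d0, -1), "contrast")
})

test_that("texture vectors and patches round-trip through text formats", {
  td <- withr::local_tempdir()
  patch <- random_patch(9, 7)
  write_patch_txt(patch, file.path(td, "p.txt"))
  expect_identical(unclass(read_patch_txt(file.path(td, "p.txt"))),
                   unclass(patch), ignore_attr = TRUE)
  write_patch_png(patch, file.path(td, "p.png"))
  expect_equal(unclass(read_patch_png(file.path(td, "p.png"))),
               unclass(patch), ignore_attr = TRUE)
  v <- analyze(patch)
  write_texture_vector_csv(v, file.path(td, "v.csv"))
  expect_equal(as.numeric(read_texture_vector_csv(file.path(td, "v.csv"))),
               as.numeric(v))
  write_texture_vector_json(v, file.path(td, "v.json"))
  expect_equal(unlist(jsonlite::read_json(file.path(td, "v.json"))),
               as.numeric(v), ignore_attr = TRUE)
})
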