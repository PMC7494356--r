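# Shared test helpers: random patches and a cached standard pipeline run so
# several test files (pipeline properties, acceptance checks) can reuse one
# synthetic-ensemble analysis.

random_patch <- function(nr, nc, G = 3L) {
  gray_patch(matrix(sample.int(G, nr * nc, replace = TRUE) - 1L, nr, nc), G = G)
}

.test_cache <- new.env(parent = emptyenv())

# Standard synthetic-ensemble analysis: 24 images of 256x256, default
# pipeline (N = 2, R = 32), fixed seeds.
standard_pipeline <- function() {
  if (is.null(.test_cache$pipe)) {
    fx <- generate_images(fixture_spec(), seed = 42)
    pipe <- suppressMessages(run_pipeline(fx$images, pipeline_config(), seed = 7))
    .test_cache$fx <- fx
    .test_cache$pipe <- pipe
    .test_cache$model <- fit_gaussian(pipe$vectors[pipe$mask, , drop = FALSE])
  }
  list(fx = .test_cache$fx, pipe = .test_cache$pipe, model = .test_cache$model)
}

# The second-order planes probed in the end-to-end experiment: the four
# simple planes plus four representative mixed planes.
test_planes <- function() {
  list("AB_1_1", "AB_1_2", "AC_1_1", "AC_1_2",
       list("AB_1_1", 0, "AB_1_2", 1), list("AB_1_1", 0, "AC_1_1", 0),
       list("AD_1_1", 0, "BC_1_1", 0), list("AD_1_2", 1, "BC_1_2", 1))
}

all_symmetry_transforms <- function() {
  geoms <- c("identity", "lrFlip", "udFlip", "rot90", "rot180", "rot270")
  vals <- list(c(1, 0), c(2, 2), c(2, 1), c(2, 0), c(1, 1), c(1, 2))
  out <- list()
  for (g in geoms) for (ab in vals)
    out[[length(out) + 1L]] <- symmetry_transformation(g, ab[1], ab[2])
  out
}
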