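# Gaussian texture model and variance-to-threshold predictions.

test_that("fit_gaussian recovers planted parameters", {
  set.seed(21)
  d <- 6; n <- 20000
  A <- matrix(rnorm(d * d), d); S <- crossprod(A) / d
  mu <- rnorm(d)
  x <- matrix(rnorm(n * d), n, d) %*% chol(S)
  x <- sweep(x, 2, mu, `+`)
  m <- fit_gaussian(x)
  expect_lt(max(abs(m$mean - mu)), 5 * sqrt(max(diag(S)) / n))
  expect_lt(max(abs(m$cov - S)), 10 * max(diag(S)) / sqrt(n))
  expect_error(fit_gaussian(x[1, , drop = FALSE]), "at least 2")
  # single repeated vector with ridge: covariance is the ridge itself
  mr <- suppressMessages(fit_gaussian(matrix(1, 5, 3), ridge = 1e-6))
  expect_equal(diag(mr$cov), rep(1e-6, 3))
})

test_that("predicted thresholds follow the inverse standard deviation", {
  groups <- enumerate_groups(3)
  d <- 2 * length(groups)
  iso <- structure(list(mean = rep(0, d), cov = diag(d), n = 10),
                   class = "gaussian_texture_model")
  dirs <- plane_directions(test_planes())
  pred <- predict_thresholds(iso, dirs)
  expect_equal(pred, rep(1, length(pred))) # isotropy
  # 2D toy: variance 4 along axis 1, 1 along axis 2
  m2 <- structure(list(mean = c(0, 0), cov = diag(c(4, 1)), n = 10),
                  class = "gaussian_texture_model")
  expect_equal(predict_threshold(m2, c(1, 0)), 0.5)
  expect_equal(predict_threshold(m2, c(0, 1)), 1)
  expect_equal(predict_threshold(m2, c(0, 2)), 1) # normalization
  # eta = 0: predictions carry no information from the data
  expect_equal(predict_thresholds(m2, list(c(1, 0), c(0, 1)), eta = 0),
               c(1, 1))
  expect_error(predict_threshold(m2, c(0, 0)), "nonzero")
  m0 <- structure(list(mean = c(0, 0), cov = diag(c(1, 0)), n = 10),
                  class = "gaussian_texture_model")
  expect_error(predict_threshold(m0, c(0, 1)), "zero variance")
})

test_that("within-plane predictions lie on an ellipse by construction", {
  set.seed(22)
  std <- standard_pipeline()
  angles <- 2 * pi * (0:11) / 12
  for (pl in list("AB_1_1", list("AB_1_1", 0, "AC_1_2", 1))) {
    dirs <- if (is.character(pl))
      lapply(angles, function(a) plane_direction(pl, angle = a))
    else
      lapply(angles, function(a)
        plane_direction(pl[[1]], angle = a, h_a = pl[[2]],
                        group_b = pl[[3]], h_b = pl[[4]]))
    r <- predict_thresholds(std$model, dirs)
    fit <- fit_threshold_ellipse(list(angle = angles, threshold = r))
    expect_lt(fit$residual, 1e-8)
  }
})

test_that("parameter recovery: sampled vectors reproduce analytic thresholds", {
  set.seed(23)
  d <- 66
  # planted covariance with structured spectrum
  Q <- qr.Q(qr(matrix(rnorm(d * d), d)))
  S <- Q %*% diag(exp(seq(log(0.5), log(8), length.out = d))) %*% t(Q) * 1e-4
  n <- 1e5
  x <- matrix(rnorm(n * d), n, d) %*% chol(S)
  model <- fit_gaussian(x)
  dirs <- plane_directions(test_planes())
  pred <- predict_thresholds(model, dirs)
  anal <- vapply(dirs, function(dd) {
    u <- direction_vector(dd)
    drop(t(u) %*% S %*% u)^-0.5
  }, numeric(1))
  expect_lt(max(abs(pred / anal - 1)), 0.02)
})

test_that("fit_scale equals the brute-force minimizer of the stated objective", {
  expect_equal(fit_scale(c(2, 4, 8), c(1, 2, 4)), 0.5)
  expect_equal(fit_scale(1, exp(1)), exp(1))
  set.seed(24)
  y <- exp(rnorm(40)); x <- exp(rnorm(40)); eps <- runif(40, 0.05, 0.5)
  sc <- fit_scale(y, x, eps)
  # exact numeric minimizer: the objective is quadratic in log(scale)
  obj <- function(u) mean(((log(x) - log(y) - u) / eps)^2)
  f <- vapply(c(-1, 0, 1), obj, numeric(1))
  brute <- exp(0.5 * (f[1] - f[3]) / (f[1] - 2 * f[2] + f[3]))
  expect_lt(abs(sc - brute), 1e-10 * brute)
  expect_error(fit_scale(c(1, -1), c(1, 1)), "positive")
})

test_that("fit_eta recovers planted exponents", {
  set.seed(25)
  sds <- exp(runif(60, -2, 0))
  for (eta0 in c(0.8, 1)) {
    meas <- 0.3 * sds^(-eta0) * exp(rnorm(60, 0, 0.02))
    est <- fit_eta(sds, meas, rep(0.02, 60))
    expect_lt(abs(est$eta - eta0), 0.05)
  }
  expect_error(fit_eta(rep(0.5, 10), exp(rnorm(10))), "degenerate")
  expect_error(fit_eta(c(1, 2), c(1, 2)), "at least 3")
})
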