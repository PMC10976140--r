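# Empirical variogram, parametric variogram fitting and ordinary kriging,
# checked against closed forms and an independently assembled dense solve.

test_that("the Matheron estimator matches the one-pair closed form", {
  coords <- rbind(c(0, 0), c(1000, 0))
  emp <- suppressWarnings(
    empirical_variogram(c(2, 6), coords, n_bins = 1, max_lag = 2000))
  expect_equal(emp$gamma, 8)  # (2-6)^2 / 2
  expect_equal(emp$npairs, 1L)
})

test_that("identical residuals give zero semivariance in every bin", {
  coords <- make_coords(15, seed = 1)
  emp <- empirical_variogram(rep(3.3, 15), coords, n_bins = 5)
  expect_true(all(emp$gamma == 0))
  expect_lte(sum(emp$npairs), 15 * 14 / 2)
  expect_true(all(diff(emp$lag) > 0))
})

test_that("empirical semivariance near the range matches theory", {
  # exponential model: gamma(range) = sill * (1 - exp(-1)) ~ 2.53
  vals <- numeric(20)
  for (s in 1:20) {
    coords <- make_coords(200, size = 20000, seed = 1000 + s)
    z <- sim_expo_field(coords, sill = 4, range = 5000, seed = 2000 + s)
    emp <- empirical_variogram(z, coords, n_bins = 12)
    vals[s] <- emp$gamma[which.min(abs(emp$lag - 5000))]
  }
  expect_gt(mean(vals), 2.0)
  expect_lt(mean(vals), 3.4)
})

test_that("noise-free exponential points are recovered within 1%", {
  truth <- variogram_model("exponential", nugget = 0.5, psill = 4,
                           range = 6000)
  lags <- seq(500, 15000, length.out = 12)
  emp <- data.frame(lag = lags, gamma = variogram_gamma(truth, lags),
                    npairs = rep(50L, 12))
  fit <- fit_variogram(emp, "exponential")
  expect_equal(fit$nugget, 0.5, tolerance = 0.01)
  expect_equal(fit$psill, 4, tolerance = 0.01)
  expect_equal(fit$range, 6000, tolerance = 0.01)
})

test_that("a flat empirical variogram yields a pure-nugget model", {
  emp <- data.frame(lag = c(1000, 2000, 3000), gamma = rep(2.5, 3),
                    npairs = rep(10L, 3))
  expect_warning(fit <- fit_variogram(emp), "pure-nugget")
  expect_equal(fit$nugget, 2.5, tolerance = 1e-8)
  expect_equal(fit$psill, 0, tolerance = 1e-8)
})

test_that("fitted range is within a factor of two of truth (median, 20 seeds)", {
  ranges <- numeric(20)
  for (s in 1:20) {
    coords <- make_coords(120, size = 20000, seed = 3000 + s)
    z <- sim_expo_field(coords, sill = 4, range = 5000, seed = 4000 + s)
    emp <- empirical_variogram(z, coords)
    ranges[s] <- fit_variogram(emp, "exponential")$range
  }
  expect_gte(median(ranges), 2500)
  expect_lte(median(ranges), 10000)
})

test_that("kriging interpolates exactly at support points when nugget is 0", {
  coords <- make_coords(8, seed = 2)
  z <- rnorm(8, 0, 2)
  vgm <- variogram_model("exponential", nugget = 0, psill = 3, range = 5000)
  out <- ok_predict(coords, z, vgm, coords)
  expect_equal(out$prediction, z, tolerance = 1e-8)
  expect_equal(out$variance, rep(0, 8), tolerance = 1e-8)
})

test_that("symmetric support points share the weight equally", {
  support <- rbind(c(-1000, 0), c(1000, 0))
  target <- rbind(c(0, 0))
  for (fam in c("exponential", "spherical", "gaussian")) {
    vgm <- variogram_model(fam, nugget = 0.2, psill = 2, range = 3000)
    out <- ok_predict(support, c(4, 10), vgm, target, return_weights = TRUE)
    expect_equal(as.numeric(out$weights), c(0.5, 0.5), tolerance = 1e-10)
    expect_equal(out$prediction, 7, tolerance = 1e-10)
  }
})

test_that("kriging matches a dense independently assembled solve", {
  for (s in 1:50) {
    set.seed(5000 + s)
    n <- sample(4:10, 1)
    coords <- matrix(runif(2 * n, 0, 10000), n, 2)
    z <- rnorm(n, 0, 3)
    vgm <- variogram_model("exponential", nugget = runif(1, 0, 1),
                           psill = runif(1, 0.5, 4),
                           range = runif(1, 1000, 8000))
    target <- matrix(runif(2, 0, 10000), 1, 2)
    got <- ok_predict(coords, z, vgm, target, return_weights = TRUE)
    # oracle: assemble the OK equations from scratch and solve densely
    gfun <- function(h) ifelse(h == 0, 0,
                               vgm$nugget + vgm$psill * (1 - exp(-h / vgm$range)))
    G <- matrix(0, n + 1, n + 1)
    for (i in 1:n) for (j in 1:n) {
      G[i, j] <- gfun(sqrt(sum((coords[i, ] - coords[j, ])^2)))
    }
    G[n + 1, 1:n] <- 1; G[1:n, n + 1] <- 1
    g0 <- c(vapply(1:n, function(i)
      gfun(sqrt(sum((coords[i, ] - target)^2))), numeric(1)), 1)
    sol <- solve(G, g0)
    expect_equal(as.numeric(got$weights), sol[1:n], tolerance = 1e-8)
    expect_equal(got$lagrange, sol[n + 1], tolerance = 1e-8)
    expect_equal(got$prediction, sum(sol[1:n] * z), tolerance = 1e-8)
    expect_equal(sum(got$weights), 1, tolerance = 1e-8)
    expect_gte(got$variance, -1e-10)
  }
})

test_that("kriging is translation-invariant and duplicate-safe", {
  coords <- make_coords(10, seed = 6)
  z <- rnorm(10, 0, 2)
  vgm <- variogram_model("exponential", nugget = 0.1, psill = 2,
                         range = 4000)
  targets <- make_coords(5, seed = 7)
  p1 <- ok_predict(coords, z, vgm, targets)$prediction
  p2 <- ok_predict(coords, z + 100, vgm, targets)$prediction
  expect_equal(p2, p1 + 100, tolerance = 1e-8)
  dup <- rbind(coords, coords[1, ])
  vgm0 <- variogram_model("exponential", nugget = 0, psill = 2, range = 4000)
  expect_error(ok_predict(dup, c(z, z[1]), vgm0, targets), "duplicate")
})

test_that("a pure-nugget variogram krigs to the residual mean", {
  coords <- make_coords(12, seed = 8)
  z <- rnorm(12, 0, 2)
  vgm <- variogram_model("exponential", nugget = 1.5, psill = 0,
                         range = 4000)
  targets <- make_coords(4, seed = 9)
  out <- ok_predict(coords, z, vgm, targets, return_weights = TRUE)
  expect_equal(out$prediction, rep(mean(z), 4), tolerance = 1e-8)
  expect_equal(as.numeric(out$weights), rep(1 / 12, 48), tolerance = 1e-8)
})

test_that("hybrid with zero nugget reproduces training data exactly", {
  X <- make_X(25, 5, seed = 10)
  coords <- make_coords(25, seed = 11)
  y <- make_linear_y(X, c(2, -1, 0, 0, 0), intercept = 40, noise_sd = 2) +
    sim_expo_field(coords, sill = 4, range = 6000, seed = 12)
  hyb <- fit_hybrid("SLR", X, y, coords)
  hyb$variogram$nugget <- 0  # force exact interpolation of residuals
  pin <- predict(hyb, X, coords)
  expect_equal(rmse(y, pin), 0, tolerance = 1e-6)
})

test_that("hybrid equals the plain LUR under a zero partial sill", {
  X <- make_X(20, 4, seed = 13)
  coords <- make_coords(20, seed = 14)
  y <- make_linear_y(X, c(3, 1, 0, 0), intercept = 35, noise_sd = 2)
  hyb <- fit_hybrid("SLR", X, y, coords)
  hyb$variogram$psill <- 0
  hyb$variogram$nugget <- 1
  Xnew <- make_X(30, 4, seed = 15)
  cnew <- make_coords(30, seed = 16)
  # SLR residuals average zero, so the kriged residual vanishes
  expect_equal(predict(hyb, Xnew, cnew, floor_zero = FALSE),
               predict(hyb$lur, Xnew), tolerance = 1e-8)
})
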