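# Exposure surfaces, population-weighted means, person-level quartiles,
# misclassification cross-tabs and cross-model divergence.

test_that("population-weighted mean hits its closed forms", {
  s <- make_surface(c(10, 20))
  expect_equal(population_weighted_mean(s, make_grid(c(1, 3))), 17.5)
  expect_equal(population_weighted_mean(s, make_grid(c(5, 5))), 15)
  g1 <- make_grid(c(0, 7))
  expect_equal(population_weighted_mean(s, g1), 20)
  expect_error(population_weighted_mean(s, make_grid(c(0, 0))), "zero")
})

test_that("uniform-population quartiles split 1..8 as 1,1,2,2,3,3,4,4", {
  s <- make_surface(1:8)
  g <- make_grid(rep(10, 8))
  qc <- quartile_classify(s, g)
  expect_equal(qc$class, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  # doubling populations changes nothing
  qc2 <- quartile_classify(s, make_grid(rep(20, 8)))
  expect_equal(qc2$cutpoints, qc$cutpoints)
  expect_equal(qc2$class, qc$class)
})

test_that("classification agrees with the per-person expansion oracle", {
  # the skewed 4-cell case: one cell holds 70% of the population
  s <- make_surface(1:4)
  g <- make_grid(c(70, 10, 10, 10))
  qc <- quartile_classify(s, g)
  expect_equal(qc$class, person_quartile_oracle(1:4, c(70, 10, 10, 10)))
  # random grids up to 10,000 persons
  for (seed in 1:12) {
    set.seed(seed)
    n <- sample(4:40, 1)
    pred <- round(runif(n, 10, 80), 2)
    pop <- sample(1:400, n, replace = TRUE)
    qc <- quartile_classify(make_surface(pred), make_grid(pop))
    expect_equal(qc$class, person_quartile_oracle(pred, pop))
  }
})

test_that("grid-count weighting is available as a sensitivity mode", {
  s <- make_surface(1:8)
  g <- make_grid(c(1000, rep(1, 7)))
  qp <- quartile_classify(s, g, weighting = "population")
  qg <- quartile_classify(s, g, weighting = "grid")
  expect_equal(qg$class, c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L))
  expect_false(identical(qp$class, qg$class))
})

test_that("identical predictions collapse to quartile 1 with a warning", {
  s <- make_surface(rep(5, 6))
  expect_warning(qc <- quartile_classify(s, make_grid(rep(1, 6))),
                 "identical")
  expect_true(all(qc$class == 1L))
})

test_that("misclassification matches the hand-counted 8-cell case", {
  g <- make_grid(rep(10, 8))
  A <- list(grid_id = g$grid_id, class = c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L),
            tag = "A")
  # mismatches: cells 1, 4, 6 one quartile up, cell 7 one quartile down
  B <- list(grid_id = g$grid_id, class = c(2L, 1L, 2L, 3L, 3L, 4L, 3L, 4L),
            tag = "B")
  m <- misclassification(A, B, g)
  expect_equal(m$total, 50)
  expect_equal(m$overestimated, 37.5)
  expect_equal(m$underestimated, 12.5)
  expect_equal(m$non_adjacent, 0)
  expect_equal(sum(m$matrix), 100, tolerance = 1e-6)
  expect_equal(m$total, m$overestimated + m$underestimated)
})

test_that("self-comparison and reversal bracket the misclassification", {
  g <- make_grid(rep(10, 8))
  cls <- c(1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L)
  A <- list(grid_id = g$grid_id, class = cls, tag = "A")
  self <- misclassification(A, A, g)
  expect_equal(self$total, 0)
  expect_equal(sum(diag(self$matrix)), 100, tolerance = 1e-6)
  R <- list(grid_id = g$grid_id, class = 5L - cls, tag = "R")
  rev <- misclassification(A, R, g)
  expect_equal(rev$total, 100)
  expect_equal(rev$non_adjacent, 50)
})

test_that("misclassification is symmetric with swapped roles", {
  set.seed(41)
  g <- make_grid(sample(50:500, 30))
  A <- list(grid_id = g$grid_id, class = sample(1:4, 30, replace = TRUE),
            tag = "A")
  B <- list(grid_id = g$grid_id, class = sample(1:4, 30, replace = TRUE),
            tag = "B")
  ab <- misclassification(A, B, g)
  ba <- misclassification(B, A, g)
  expect_equal(ab$total, ba$total, tolerance = 1e-10)
  expect_equal(ab$overestimated, ba$underestimated, tolerance = 1e-10)
  expect_equal(unname(ab$matrix), unname(t(ba$matrix)), tolerance = 1e-10)
})

test_that("population-quartile marginals are near 25% on a large grid", {
  set.seed(42)
  n <- 500
  pred <- runif(n, 20, 70)
  pop <- sample(100:2000, n, replace = TRUE)
  g <- make_grid(pop)
  qc <- quartile_classify(make_surface(pred), g)
  shares <- vapply(1:4, function(k) sum(pop[qc$class == k]) / sum(pop),
                   numeric(1))
  tol <- max(pop) / sum(pop)  # one grid cell's population share
  expect_true(all(abs(shares - 0.25) <= tol + 1e-12))
})

test_that("cross-model COV matches hand computation and scales out", {
  s1 <- make_surface(c(10, 5), tag = "a")
  s2 <- make_surface(c(10, 5), tag = "b")
  s3 <- make_surface(c(40, 5), tag = "c")
  cv <- cross_model_cov(list(s1, s2, s3))
  expect_equal(cv$cov[1], 100 * sd(c(10, 10, 40)) / 20, tolerance = 1e-10)
  expect_equal(cv$cov[1], 86.60, tolerance = 1e-3)
  expect_equal(cv$cov[2], 0)
  # identical surfaces -> zero COV everywhere
  cv0 <- cross_model_cov(list(s1, s2))
  expect_true(all(cv0$cov == 0))
  # multiplying every surface by c > 0 leaves COV unchanged
  sc <- function(s, c) make_surface(s$prediction * c, attr(s, "tag"))
  cvs <- cross_model_cov(list(sc(s1, 3), sc(s2, 3), sc(s3, 3)))
  expect_equal(cvs$cov, cv$cov, tolerance = 1e-10)
})

test_that("cross-model correlations hit their closed forms", {
  set.seed(43)
  a <- runif(3301, 10, 60)
  s1 <- make_surface(a, tag = "a")
  expect_equal(cross_model_correlation(list(s1, make_surface(a, "b")))[1, 2],
               1)
  neg <- make_surface(max(a) + min(a) - a, tag = "neg")
  expect_equal(cross_model_correlation(list(s1, neg))[1, 2], -1)
  b <- make_surface(runif(3301, 10, 60), tag = "indep")
  R <- cross_model_correlation(list(s1, b))
  expect_lt(abs(R[1, 2]), 0.1)
  expect_equal(diag(R), c(a = 1, indep = 1))
  const <- make_surface(rep(5, 3301), tag = "const")
  expect_true(is.na(cross_model_correlation(list(s1, const))[1, 2]))
})

test_that("predict_surface floors negatives and names missing columns", {
  X <- make_X(15, 3, seed = 26, expected_sign = c(1, 0, 0))
  coords <- make_coords(15, seed = 27)
  y <- make_linear_y(X, c(3, 1, 0), intercept = 2, noise_sd = 1)
  hyb <- fit_hybrid("SLR", X, y, coords)
  grid <- cbind(make_grid(rep(10, 20))[, c("grid_id", "population")],
                make_coords(20, seed = 28), make_X(20, 3, seed = 29))
  surf <- predict_surface(hyb, grid)
  expect_true(all(surf$prediction >= 0))
  expect_identical(predict_surface(hyb, grid)$prediction, surf$prediction)
  bad <- grid[, setdiff(names(grid), "V02")]
  expect_error(predict_surface(hyb, bad), "V02")
})
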