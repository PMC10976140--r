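# Exposure assessment over the population grid: gridded prediction,
# population-weighted exposure estimates (PEE), person-level exposure
# quartiles, pairwise quartile misclassification between models, and
# cross-model divergence (coefficient of variation, correlation).

#' Predict an exposure surface over the population grid
#'
#' Hybrid (or plain LUR) prediction at every grid-cell center; negative
#' concentrations are floored at zero and the count is attached as
#' attribute `n_floored` on the prediction column.
#'
#' @param model a `lurok_hybrid` or `lurok_lur` model.
#' @param grid a population grid from [generate_population_grid()] (or any
#'   data.frame with `grid_id`, `x`, `y` and the training covariate
#'   columns).
#' @param tag model tag recorded on the surface (default built from the
#'   model).
#' @return a data.frame of class `lurok_surface` with columns `grid_id`
#'   and `prediction` plus attribute `tag`.
#' @export
predict_surface <- function(model, grid, tag = NULL) {
  Xg <- grid[, setdiff(names(grid), c("grid_id", "x", "y", "population")),
             drop = FALSE]
  if (inherits(model, "lurok_hybrid")) {
    pred <- predict(model, Xg, as.matrix(grid[, c("x", "y")]),
                    floor_zero = TRUE)
    if (is.null(tag)) tag <- paste0(model$lur$family, "-OK")
  } else {
    pred <- predict(model, Xg)
    n_fl <- sum(pred < 0)
    pred <- pmax(pred, 0)
    attr(pred, "n_floored") <- n_fl
    if (is.null(tag)) tag <- model$family
  }
  out <- data.frame(grid_id = grid$grid_id, prediction = as.numeric(pred),
                    stringsAsFactors = FALSE)
  attr(out, "n_floored") <- attr(pred, "n_floored")
  attr(out, "tag") <- tag
  class(out) <- c("lurok_surface", "data.frame")
  out
}

#' Population-weighted mean exposure
#'
#' sum(pop_i * pred_i) / sum(pop_i) over the grid cells, ug/m3.
#'
#' @param surface a [predict_surface()] result (or data.frame with
#'   `grid_id`, `prediction`).
#' @param grid the population grid (must contain the same `grid_id`s).
#' @return a single number, ug/m3.
#' @export
population_weighted_mean <- function(surface, grid) {
  pop <- grid$population[match(surface$grid_id, grid$grid_id)]
  if (anyNA(pop)) stop("surface and grid do not share grid_ids", call. = FALSE)
  tot <- sum(pop)
  if (tot <= 0) stop("total population is zero", call. = FALSE)
  sum(pop * surface$prediction) / tot
}

# Person-level (population-weighted) quantile: smallest exposure value v
# such that the share of persons with exposure <= v reaches p.  With unit
# weights this is the inverse-ECDF (type-1) quantile, so it agrees exactly
# with materializing one row per person.
weighted_quantile_type1 <- function(x, w, p) {
  o <- order(x)
  cw <- cumsum(w[o]) / sum(w)
  vapply(p, function(pp) x[o][which(cw >= pp - 1e-12)[1]], numeric(1))
}

#' Classify grid cells into exposure quartiles
#'
#' Cutpoints are the 25/50/75% quantiles of exposure over persons (each
#' person carries their grid cell's exposure) under population weighting,
#' or over cells under grid weighting.  Cells are assigned class
#' 1 + (number of cutpoints strictly below their exposure); ties at a
#' cutpoint go to the lower quartile.
#'
#' @param surface a [predict_surface()] result.
#' @param grid the population grid.
#' @param weighting "population" (person-level quantiles, the default) or
#'   "grid" (cell-count quantiles).
#' @return an object of class `lurok_quartiles`: list with `grid_id`,
#'   `class` (integer 1-4), `cutpoints`, `weighting`.
#' @export
quartile_classify <- function(surface, grid,
                              weighting = c("population", "grid")) {
  weighting <- match.arg(weighting)
  if (nrow(surface) < 4) stop("need at least 4 cells", call. = FALSE)
  pop <- grid$population[match(surface$grid_id, grid$grid_id)]
  if (anyNA(pop)) stop("surface and grid do not share grid_ids", call. = FALSE)
  x <- surface$prediction
  w <- if (weighting == "population") pop else rep(1, length(x))
  if (stats::sd(x) == 0) {
    warning("all predictions identical: every cell assigned to quartile 1")
    cut3 <- rep(x[1], 3)
    cls <- rep(1L, length(x))
  } else {
    cut3 <- weighted_quantile_type1(x, w, c(0.25, 0.5, 0.75))
    cls <- 1L + vapply(x, function(v) sum(v > cut3), integer(1))
  }
  structure(list(grid_id = surface$grid_id, class = cls, cutpoints = cut3,
                 weighting = weighting, tag = attr(surface, "tag")),
            class = "lurok_quartiles")
}

#' Population-weighted quartile misclassification between two models
#'
#' Cross-tabulates the population shares (in %) of the 4 x 4 quartile
#' combinations under two classifications of the same grid.  Reports the
#' total misclassified share (off-diagonal), the overestimated share
#' (model B in a higher quartile than model A), the underestimated share,
#' the non-adjacent share (two or more quartiles apart) and per-quartile
#' agreement.
#'
#' @param classA,classB [quartile_classify()] results on the same grid.
#' @param grid the population grid.
#' @return an object of class `lurok_misclass`: list with `matrix` (4 x 4,
#'   % of population), `total`, `overestimated`, `underestimated`,
#'   `non_adjacent`, `agreement_by_quartile`, `pair`.
#' @export
misclassification <- function(classA, classB, grid) {
  if (!identical(classA$grid_id, classB$grid_id)) {
    stop("classifications are on different grids", call. = FALSE)
  }
  pop <- grid$population[match(classA$grid_id, grid$grid_id)]
  if (anyNA(pop)) stop("grid does not cover the classified cells",
                       call. = FALSE)
  M <- matrix(0, 4, 4, dimnames = list(paste0("A", 1:4), paste0("B", 1:4)))
  for (a in 1:4) for (b in 1:4) {
    M[a, b] <- sum(pop[classA$class == a & classB$class == b])
  }
  M <- 100 * M / sum(pop)
  off <- row(M) != col(M)
  structure(list(
    matrix = M,
    total = sum(M[off]),
    overestimated = sum(M[col(M) > row(M)]),
    underestimated = sum(M[col(M) < row(M)]),
    non_adjacent = sum(M[abs(col(M) - row(M)) >= 2]),
    agreement_by_quartile = diag(M),
    pair = paste(classA$tag %||% "A", classB$tag %||% "B", sep = " vs ")),
    class = "lurok_misclass")
}

#' @export
print.lurok_misclass <- function(x, ...) {
  cat(sprintf("<quartile misclassification %s>\n", x$pair))
  cat(sprintf("  total %.2f%%  over %.2f%%  under %.2f%%  non-adjacent %.2f%%\n",
              x$total, x$overestimated, x$underestimated, x$non_adjacent))
  invisible(x)
}

#' Cross-model coefficient of variation per grid cell
#'
#' For each cell, 100 * sample SD / mean of the predictions across models;
#' cells with zero mean are flagged undefined (NA).
#'
#' @param surfaces a list of two or more surfaces on the same grid.
#' @return a list with `cov` (per-cell %, NA where undefined) and
#'   `summary` (min / median / max over defined cells).
#' @export
cross_model_cov <- function(surfaces) {
  P <- surface_matrix(surfaces)
  mu <- rowMeans(P)
  sdv <- apply(P, 1, stats::sd)
  cov <- ifelse(mu == 0, NA_real_, 100 * sdv / mu)
  list(cov = cov,
       summary = c(min = min(cov, na.rm = TRUE),
                   median = stats::median(cov, na.rm = TRUE),
                   max = max(cov, na.rm = TRUE)),
       n_undefined = sum(is.na(cov)))
}

#' Pairwise Pearson correlation between model surfaces
#'
#' @param surfaces a list of two or more surfaces on the same grid.
#' @return a symmetric correlation matrix with unit diagonal; rows of a
#'   constant surface are NA (flagged undefined).
#' @export
cross_model_correlation <- function(surfaces) {
  P <- surface_matrix(surfaces)
  k <- ncol(P)
  R <- diag(1, k)
  dimnames(R) <- list(colnames(P), colnames(P))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    R[i, j] <- R[j, i] <-
      if (stats::sd(P[, i]) == 0 || stats::sd(P[, j]) == 0) NA_real_
      else stats::cor(P[, i], P[, j])
  }
  R
}

surface_matrix <- function(surfaces) {
  stopifnot(is.list(surfaces), length(surfaces) >= 2)
  ids <- surfaces[[1]]$grid_id
  for (s in surfaces[-1]) {
    if (!identical(s$grid_id, ids)) stop("surfaces are on different grids",
                                         call. = FALSE)
  }
  P <- vapply(surfaces, function(s) s$prediction,
              numeric(length(ids)))
  tags <- vapply(seq_along(surfaces), function(i)
    attr(surfaces[[i]], "tag") %||% paste0("model", i), character(1))
  colnames(P) <- make.unique(tags)
  P
}
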