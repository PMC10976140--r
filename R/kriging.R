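# Ordinary kriging of land-use-regression residuals: Matheron empirical
# semivariogram, weighted-least-squares fit of a parametric variogram
# model, the ordinary-kriging linear system with unbiasedness constraint,
# and the two-step hybrid predictor (LUR prediction + kriged residual).

#' Empirical (Matheron) semivariogram
#'
#' Bins site pairs by Euclidean distance up to `max_lag` (half the maximum
#' inter-site distance by default, 12 bins) and computes
#' gamma(h) = sum (z_i - z_j)^2 / (2 N(h)) per bin.  Empty bins are
#' dropped and listed in the `dropped_bins` attribute.
#'
#' @param residuals numeric residuals at the sites.
#' @param coords two-column matrix or data.frame of site coordinates,
#'   meters.
#' @param n_bins number of distance bins (default 12).
#' @param max_lag maximum pair distance considered, meters.
#' @return a data.frame of class `lurok_empvgm` with columns `lag` (mean
#'   pair distance), `gamma` and `npairs`.
#' @export
empirical_variogram <- function(residuals, coords, n_bins = 12,
                                max_lag = NULL) {
  coords <- as.matrix(coords)
  n <- length(residuals)
  stopifnot(nrow(coords) == n)
  if (n < 2) stop("need at least 2 sites", call. = FALSE)
  if (n < 10) warning("fewer than 10 sites: empirical variogram will be noisy")
  h <- cross_dist(coords, coords)
  iu <- which(upper.tri(h))
  d <- h[iu]
  g <- 0.5 * (outer(residuals, residuals, "-")^2)[iu]
  if (is.null(max_lag)) max_lag <- max(d) / 2
  stopifnot_scalar_number(max_lag, "max_lag", lower = 1e-12)
  keep <- d <= max_lag & d > 0
  d <- d[keep]; g <- g[keep]
  breaks <- seq(0, max_lag, length.out = n_bins + 1)
  bin <- cut(d, breaks, include.lowest = TRUE, labels = FALSE)
  lag <- tapply(d, bin, mean)
  gamma <- tapply(g, bin, mean)
  npairs <- tapply(g, bin, length)
  present <- sort(unique(bin))
  out <- data.frame(lag = as.numeric(lag), gamma = as.numeric(gamma),
                    npairs = as.integer(npairs))
  attr(out, "dropped_bins") <- setdiff(seq_len(n_bins), present)
  attr(out, "max_lag") <- max_lag
  class(out) <- c("lurok_empvgm", "data.frame")
  out
}

#' Semivariance of a parametric variogram model
#'
#' gamma(0) = 0; for h > 0, gamma(h) = nugget + partial sill times the
#' family's unit correlogram complement (exponential, spherical or
#' gaussian).
#'
#' @param model a list with `family`, `nugget`, `psill`, `range` (e.g. from
#'   [fit_variogram()] or [variogram_model()]).
#' @param h distances, meters.
#' @return semivariances, same length as `h`.
#' @export
variogram_gamma <- function(model, h) {
  s <- switch(model$family,
              exponential = 1 - exp(-h / model$range),
              spherical = ifelse(h >= model$range, 1,
                                 1.5 * h / model$range -
                                   0.5 * (h / model$range)^3),
              gaussian = 1 - exp(-(h / model$range)^2),
              stop("unknown variogram family: ", model$family, call. = FALSE))
  out <- model$nugget + model$psill * s
  out[h == 0] <- 0
  out
}

#' Construct a variogram model by hand
#'
#' @param family "exponential", "spherical" or "gaussian".
#' @param nugget nugget variance, (ug/m3)^2.
#' @param psill partial sill, (ug/m3)^2.
#' @param range range parameter, meters.
#' @return a list of class `lurok_vgm`.
#' @export
variogram_model <- function(family = c("exponential", "spherical", "gaussian"),
                            nugget, psill, range) {
  family <- match.arg(family)
  stopifnot_scalar_number(nugget, "nugget", lower = 0)
  stopifnot_scalar_number(psill, "psill", lower = 0)
  stopifnot_scalar_number(range, "range", lower = 1e-12)
  structure(list(family = family, nugget = nugget, psill = psill,
                 range = range), class = "lurok_vgm")
}

#' @export
print.lurok_vgm <- function(x, ...) {
  cat(sprintf("<%s variogram: nugget %.4g, partial sill %.4g, range %.0f m>\n",
              x$family, x$nugget, x$psill, x$range))
  invisible(x)
}

#' Fit a parametric variogram to an empirical one
#'
#' Weighted least squares with the standard weights N(h) / h^2,
#' box-constrained to nonnegative nugget / partial sill and positive
#' range, multistarted from method-of-moments initial values.  A flat
#' empirical variogram yields a pure-nugget model with a warning.
#'
#' @param emp an [empirical_variogram()] result.
#' @param family variogram family (default exponential).
#' @return a `lurok_vgm` model with attribute `wls_objective`.
#' @export
fit_variogram <- function(emp, family = c("exponential", "spherical",
                                          "gaussian")) {
  family <- match.arg(family)
  emp <- emp[is.finite(emp$gamma) & emp$npairs > 0, ]
  if (nrow(emp) < 3) stop("need at least 3 non-empty bins", call. = FALSE)
  w <- emp$npairs / pmax(emp$lag, 1e-9)^2
  sill0 <- mean(emp$gamma[emp$lag >= stats::median(emp$lag)])
  if (!is.finite(sill0) || sill0 <= 0 ||
      stats::sd(emp$gamma) < 1e-12 * max(sill0, 1)) {
    warning("flat empirical variogram: returning a pure-nugget model")
    return(variogram_model(family, nugget = max(mean(emp$gamma), 0),
                           psill = 0, range = max(emp$lag)))
  }
  obj <- function(par) {
    m <- list(family = family, nugget = par[1], psill = par[2],
              range = par[3])
    sum(w * (emp$gamma - variogram_gamma(m, emp$lag))^2)
  }
  nug0 <- max(min(emp$gamma), 0)
  starts <- expand.grid(nugget = c(0, nug0),
                        psill = c(sill0, max(sill0 - nug0, sill0 / 2)),
                        range = max(emp$lag) * c(1 / 6, 1 / 3, 2 / 3, 4 / 3))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(stats::optim(as.numeric(starts[i, ]), obj, method = "L-BFGS-B",
                            lower = c(0, 0, max(emp$lag) * 1e-4),
                            upper = c(Inf, Inf, max(emp$lag) * 100),
                            control = list(factr = 1e2, maxit = 500,
                                           parscale = c(sill0, sill0,
                                                        max(emp$lag)))),
               silent = TRUE)
    if (!inherits(fit, "try-error") && all(is.finite(fit$par)) &&
        is.finite(fit$value) &&
        (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best)) {
    # all starts diverged: fall back to the method-of-moments values
    warning("variogram optimization failed; using method-of-moments values")
    return(variogram_model(family, nugget = nug0,
                           psill = max(sill0 - nug0, 1e-12),
                           range = max(emp$lag) / 3))
  }
  # L-BFGS-B can land an epsilon outside its box; clamp to the constraints
  out <- variogram_model(family, nugget = max(best$par[1], 0),
                         psill = max(best$par[2], 0),
                         range = max(best$par[3], max(emp$lag) * 1e-4))
  attr(out, "wls_objective") <- best$value
  out
}

#' Ordinary-kriging prediction
#'
#' Solves the ordinary-kriging system (pairwise semivariance matrix with
#' the unbiasedness row and Lagrange multiplier) once for all targets.
#' Weights sum to 1 within 1e-8 by construction (checked).  With zero
#' nugget, a target coinciding with a support point reproduces that
#' support value exactly.
#'
#' @param support_coords n x 2 support coordinates, meters.
#' @param support_values residual values at the support points.
#' @param variogram a `lurok_vgm` model.
#' @param target_coords m x 2 target coordinates.
#' @param return_weights also return the n x m weight matrix and Lagrange
#'   multipliers (default FALSE).
#' @return a list with `prediction` and `variance` (length m), plus
#'   `weights` and `lagrange` when requested.
#' @export
ok_predict <- function(support_coords, support_values, variogram,
                       target_coords, return_weights = FALSE) {
  S <- as.matrix(support_coords)
  Tg <- as.matrix(target_coords)
  z <- as.numeric(support_values)
  n <- nrow(S)
  if (n < 2) stop("need at least 2 support points", call. = FALSE)
  stopifnot(length(z) == n)
  h <- cross_dist(S, S)
  if (variogram$nugget == 0 && variogram$psill == 0) {
    stop("degenerate variogram (zero nugget and zero sill)", call. = FALSE)
  }
  dup <- which(h < 1e-9 & upper.tri(h), arr.ind = TRUE)
  if (nrow(dup) > 0 && variogram$nugget == 0) {
    stop("duplicate support coordinates with zero nugget (singular system): ",
         paste(apply(dup, 1, paste, collapse = "/"), collapse = ", "),
         call. = FALSE)
  }
  A <- rbind(cbind(variogram_gamma(variogram, h), 1), c(rep(1, n), 0))
  B <- rbind(variogram_gamma(variogram, cross_dist(S, Tg)), 1)
  sol <- solve(A, B)
  W <- sol[seq_len(n), , drop = FALSE]
  lambda <- sol[n + 1L, ]
  csum <- colSums(W)
  if (any(abs(csum - 1) > 1e-8)) {
    stop("kriging weights failed the unbiasedness check", call. = FALSE)
  }
  pred <- drop(crossprod(W, z))
  vari <- colSums(W * B[seq_len(n), , drop = FALSE]) + lambda
  vari <- pmax(vari, 0)  # clip tiny negative round-off
  out <- list(prediction = unname(pred), variance = unname(vari))
  if (return_weights) {
    out$weights <- W
    out$lagrange <- unname(lambda)
  }
  out
}

#' Fit a hybrid LUR + ordinary-kriging model
#'
#' Two steps: fit the land-use-regression model, then fit a variogram to
#' its training-site residuals (observed minus in-sample prediction) and
#' keep those residuals as the kriging support.  The hybrid prediction at
#' a new location is the LUR prediction plus the kriged residual.
#'
#' @param family LUR family ("PLS", "RF", "SLR").
#' @param X training covariates.
#' @param y training concentrations, ug/m3.
#' @param coords site coordinates aligned with the rows of `X`.
#' @param lur_spec family spec (family default if NULL).
#' @param vgm_family variogram family (default exponential).
#' @param n_bins,max_lag passed to [empirical_variogram()].
#' @return an object of class `lurok_hybrid` with elements `lur`,
#'   `variogram`, `support` (coords + residuals) and `empirical`.
#' @export
fit_hybrid <- function(family, X, y, coords, lur_spec = NULL,
                       vgm_family = "exponential", n_bins = 12,
                       max_lag = NULL) {
  coords <- as.matrix(coords)
  y <- as.numeric(y)
  stopifnot(nrow(coords) == length(y))
  lur <- fit_lur(family, X, y, lur_spec)
  resid <- y - predict(lur, X)
  emp <- suppressWarnings(
    empirical_variogram(resid, coords, n_bins = n_bins, max_lag = max_lag))
  vgm <- if (nrow(emp) >= 3 && stats::sd(resid) > 1e-12) {
    suppressWarnings(fit_variogram(emp, vgm_family))
  } else {
    variogram_model(vgm_family, nugget = max(stats::var(resid), 1e-12),
                    psill = 0, range = max(cross_dist(coords, coords)) / 2)
  }
  if (vgm$nugget == 0 && vgm$psill == 0) {
    vgm$nugget <- 1e-12  # keep the kriging system nonsingular
  }
  structure(list(lur = lur, variogram = vgm, empirical = emp,
                 support = list(coords = coords, residuals = resid),
                 family = family),
            class = "lurok_hybrid")
}

#' @export
print.lurok_hybrid <- function(x, ...) {
  cat(sprintf("<lurok hybrid %s + ordinary kriging>\n", x$lur$family))
  print(x$variogram)
  invisible(x)
}

#' Predict from a hybrid LUR-OK model
#'
#' @param object a `lurok_hybrid` model.
#' @param newdata covariates at the target locations.
#' @param coords_new target coordinates aligned with `newdata` rows.
#' @param floor_zero floor negative hybrid concentrations at zero
#'   (default TRUE; the number floored is attached as attribute
#'   `n_floored`).
#' @param ... unused.
#' @return hybrid concentration predictions, ug/m3.
#' @export
predict.lurok_hybrid <- function(object, newdata, coords_new,
                                 floor_zero = TRUE, ...) {
  coords_new <- as.matrix(coords_new)
  base <- predict(object$lur, newdata)
  stopifnot(length(base) == nrow(coords_new))
  kr <- ok_predict(object$support$coords, object$support$residuals,
                   object$variogram, coords_new)
  out <- base + kr$prediction
  if (floor_zero) {
    n_floored <- sum(out < 0)
    out <- pmax(out, 0)
    attr(out, "n_floored") <- n_floored
  }
  out
}
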