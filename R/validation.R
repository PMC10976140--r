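# Leave-one-site-out cross-validation and the accuracy metrics used for
# exposure-model evaluation: RMSE, the mean-squared-error-based R2 (fit to
# the 1:1 line, clamped at zero) and the regression R2 (squared Pearson
# correlation).

#' Root-mean-square error
#'
#' sqrt(mean((y - yhat)^2)), in ug/m3.
#'
#' @param y observed values.
#' @param yhat predicted values.
#' @return a single number.
#' @export
rmse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("`y` and `yhat` must be nonempty and of equal length", call. = FALSE)
  }
  sqrt(mean((y - yhat)^2))
}

#' Mean-squared-error-based R-squared
#'
#' max(0, 1 - RMSE^2 / (sum((y - mean(y))^2) / n)): a measure of fit to
#' the 1:1 line, clamped at zero, and never larger than [r2_reg()].
#'
#' @inheritParams rmse
#' @return a number in [0, 1].
#' @export
r2_mse <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("`y` and `yhat` must be nonempty and of equal length", call. = FALSE)
  }
  denom <- sum((y - mean(y))^2) / length(y)
  if (denom == 0) stop("constant observations: R2_mse undefined", call. = FALSE)
  max(0, 1 - rmse(y, yhat)^2 / denom)
}

#' Regression-based R-squared
#'
#' Squared Pearson correlation between observations and predictions: a
#' measure of fit to the regression line.  Zero-variance predictions give
#' 0 with attribute `flagged = TRUE`.
#'
#' @inheritParams rmse
#' @return a number in [0, 1].
#' @export
r2_reg <- function(y, yhat) {
  if (length(y) == 0 || length(y) != length(yhat)) {
    stop("`y` and `yhat` must be nonempty and of equal length", call. = FALSE)
  }
  if (stats::var(y) == 0) stop("constant observations: R2_reg undefined",
                               call. = FALSE)
  if (stats::var(yhat) == 0) {
    return(structure(0, flagged = TRUE))
  }
  stats::cor(y, yhat)^2
}

#' Leave-one-site-out cross-validation
#'
#' Each site with an available observation is held out in turn; the full
#' model - the land-use regression and, when `kriging = TRUE`, the
#' residual variogram and kriging support - is refit on the remaining
#' sites only (no scaling constant, residual or variogram parameter ever
#' sees the held-out site), and the held-out site is predicted.  Metrics
#' are computed on the pooled held-out pairs.  A fold whose training fit
#' fails is recorded, excluded from the metrics, and reported with a
#' warning.
#'
#' @param family LUR family ("PLS", "RF", "SLR").
#' @param X covariates for all sites.
#' @param y observed concentrations (NA entries drop the site from CV).
#' @param coords site coordinates aligned with `X` rows.
#' @param kriging add the ordinary-kriging residual step (default FALSE).
#' @param lur_spec,vgm_family,n_bins,max_lag passed to the fitters.
#' @return an object of class `lurok_cv`: list with `predictions`
#'   (site-level data.frame), `rmse`, `r2_mse`, `r2_reg`, `n`,
#'   `failed_folds`.
#' @export
loocv <- function(family, X, y, coords, kriging = FALSE, lur_spec = NULL,
                  vgm_family = "exponential", n_bins = 12, max_lag = NULL) {
  cx <- as_cov_matrix(X)
  Xm <- cx$values
  meta_attr <- cx$expected_sign
  coords <- as.matrix(coords)
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y), nrow(coords) == length(y))
  avail <- which(!is.na(y))
  if (length(avail) < 5) stop("need at least 5 sites with observations",
                              call. = FALSE)
  ids <- rownames(Xm) %||% as.character(seq_len(nrow(Xm)))
  preds <- rep(NA_real_, length(avail))
  failed <- character(0)
  for (k in seq_along(avail)) {
    i <- avail[k]
    tr <- setdiff(avail, i)
    Xtr <- Xm[tr, , drop = FALSE]
    attr(Xtr, "expected_sign") <- meta_attr
    Xte <- Xm[i, , drop = FALSE]
    res <- tryCatch({
      if (kriging) {
        m <- fit_hybrid(family, Xtr, y[tr], coords[tr, , drop = FALSE],
                        lur_spec = lur_spec, vgm_family = vgm_family,
                        n_bins = n_bins, max_lag = max_lag)
        as.numeric(predict(m, Xte, coords[i, , drop = FALSE]))
      } else {
        m <- fit_lur(family, Xtr, y[tr], lur_spec)
        as.numeric(predict(m, Xte))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, ids[i])
    } else {
      preds[k] <- res
    }
  }
  if (length(failed)) {
    warning("fold(s) failed and were excluded: ",
            paste(failed, collapse = ", "))
  }
  ok <- !is.na(preds)
  yy <- y[avail][ok]; pp <- preds[ok]
  structure(list(
    predictions = data.frame(site_id = ids[avail], observed = y[avail],
                             predicted = preds, stringsAsFactors = FALSE),
    n = sum(ok), rmse = rmse(yy, pp), r2_mse = r2_mse(yy, pp),
    r2_reg = as.numeric(r2_reg(yy, pp)), failed_folds = failed,
    family = family, kriging = kriging),
    class = "lurok_cv")
}

#' @export
print.lurok_cv <- function(x, ...) {
  cat(sprintf("<lurok LOOCV: %s%s, n = %d>\n", x$family,
              if (x$kriging) "-OK" else "", x$n))
  cat(sprintf("  RMSE %.3f  R2_mse %.3f  R2_reg %.3f\n",
              x$rmse, x$r2_mse, x$r2_reg))
  invisible(x)
}
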