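# Supervised stepwise linear regression: forward selection driven by the
# R-squared gain, with direction-of-effect (sign) plausibility enforced
# against the covariates' expected signs, followed by iterative removal of
# variables with variance inflation factor above a threshold.

#' SLR specification
#'
#' @param r2_gain_threshold minimum R-squared rise for a candidate to enter
#'   (default 0.1, the conventional printed value for this procedure;
#'   ESCAPE-style analyses often use 0.01 - override as needed).
#' @param vif_threshold maximum tolerated variance inflation factor
#'   (default 3).
#' @param enforce_sign require each sign-constrained coefficient to match
#'   its expected sign (default TRUE).
#' @return a list of class `lurok_slr_spec`.
#' @export
slr_spec <- function(r2_gain_threshold = 0.1, vif_threshold = 3,
                     enforce_sign = TRUE) {
  stopifnot_scalar_number(r2_gain_threshold, "r2_gain_threshold", lower = 1e-12)
  stopifnot_scalar_number(vif_threshold, "vif_threshold", lower = 1e-12)
  structure(list(r2_gain_threshold = r2_gain_threshold,
                 vif_threshold = vif_threshold,
                 enforce_sign = isTRUE(enforce_sign)),
            class = "lurok_slr_spec")
}

# R-squared and coefficients of an OLS fit of y on X[, vars].
ols_fit <- function(Xm, y, vars) {
  fit <- stats::lm.fit(cbind(`(Intercept)` = 1, Xm[, vars, drop = FALSE]), y)
  r2 <- 1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
  list(r2 = r2, coef = fit$coefficients)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j) from regressing covariate j on the other
#' covariates in the subset; +Inf for exact collinearity, and 1 by
#' definition for a single variable.
#'
#' @param X covariates (`lurok_covariates`, matrix or data.frame).
#' @param variables character vector of column names (default: all).
#' @return a named numeric vector of VIFs.
#' @export
compute_vif <- function(X, variables = NULL) {
  Xm <- as_cov_matrix(X)$values
  if (is.null(variables)) variables <- colnames(Xm)
  Xm <- Xm[, variables, drop = FALSE]
  if (ncol(Xm) == 1L) return(stats::setNames(1, variables))
  vapply(seq_along(variables), function(j) {
    r2 <- ols_fit(Xm[, -j, drop = FALSE], Xm[, j],
                  colnames(Xm)[-j])$r2
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1)) |> stats::setNames(variables)
}

sign_ok <- function(coef, expected_sign, vars, enforce) {
  if (!enforce) return(TRUE)
  es <- expected_sign[vars]
  b <- coef[vars]
  b[is.na(b)] <- 0  # rank-deficient fit: treat as sign-implausible
  all(es == 0 | sign(b) == es)
}

#' Fit a supervised stepwise linear-regression model
#'
#' Round 0 picks the single covariate with the highest univariate
#' R-squared among those whose coefficient sign is plausible (matches the
#' covariate's expected sign, when one is declared).  Each later round adds
#' the covariate giving the largest R-squared rise while keeping every
#' sign constraint satisfied, and stops when the best rise falls below
#' `r2_gain_threshold`.  Finally, the variable with the worst variance
#' inflation factor is removed (refitting each time) until all VIFs are at
#' or below `vif_threshold`.  The full selection trace is recorded.
#'
#' @param X covariates; expected signs are taken from the
#'   `lurok_covariates` metadata or an `expected_sign` attribute on a
#'   matrix input.
#' @param y response concentrations, ug/m3.
#' @param spec an [slr_spec()].
#' @return an object of classes `lurok_slr` / `lurok_lur` with elements
#'   `selected`, `coefficients`, `r2` and `trace`.
#' @export
fit_slr <- function(X, y, spec = slr_spec()) {
  cx <- as_cov_matrix(X)
  Xm <- cx$values
  es <- rep(0, ncol(Xm)); names(es) <- colnames(Xm)
  es[names(cx$expected_sign)] <- cx$expected_sign
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y))
  if (length(y) < 4) stop("need at least 4 units", call. = FALSE)

  vars <- colnames(Xm)
  trace <- list()
  # round 0: best sign-plausible univariate fit
  cand0 <- lapply(vars, function(v) ols_fit(Xm, y, v))
  names(cand0) <- vars
  plaus0 <- vapply(vars, function(v)
    sign_ok(cand0[[v]]$coef, es, v, spec$enforce_sign), logical(1))
  if (!any(plaus0)) {
    signs <- vapply(vars, function(v) sign(cand0[[v]]$coef[v]), numeric(1))
    stop("no sign-plausible starting variable; candidate coefficient signs: ",
         paste(sprintf("%s=%+d(exp %+d)", vars, signs, es[vars]),
               collapse = ", "), call. = FALSE)
  }
  r2s0 <- vapply(vars, function(v) cand0[[v]]$r2, numeric(1))
  r2s0[!plaus0] <- -Inf
  selected <- vars[which.max(r2s0)]
  cur_r2 <- max(r2s0)
  trace[[1]] <- data.frame(round = 0L, variable = selected, r2 = cur_r2,
                           decision = "enter", stringsAsFactors = FALSE)

  repeat {
    remaining <- setdiff(vars, selected)
    if (!length(remaining)) break
    gains <- vapply(remaining, function(v) {
      f <- ols_fit(Xm, y, c(selected, v))
      if (!sign_ok(f$coef, es, c(selected, v), spec$enforce_sign))
        return(-Inf)
      f$r2 - cur_r2
    }, numeric(1))
    best <- which.max(gains)
    if (!is.finite(gains[best]) || gains[best] < spec$r2_gain_threshold) break
    selected <- c(selected, remaining[best])
    cur_r2 <- cur_r2 + gains[best]
    trace[[length(trace) + 1]] <-
      data.frame(round = length(selected) - 1L, variable = remaining[best],
                 r2 = cur_r2, decision = "enter", stringsAsFactors = FALSE)
  }

  # iterative worst-first VIF removal with refit
  repeat {
    if (length(selected) < 2L) break
    v <- compute_vif(Xm, selected)
    if (max(v) <= spec$vif_threshold) break
    worst <- names(v)[which.max(v)]
    selected <- setdiff(selected, worst)
    cur_r2 <- ols_fit(Xm, y, selected)$r2
    trace[[length(trace) + 1]] <-
      data.frame(round = NA_integer_, variable = worst, r2 = cur_r2,
                 decision = "vif_remove", stringsAsFactors = FALSE)
  }

  final <- ols_fit(Xm, y, selected)
  structure(list(family = "SLR", columns = colnames(Xm),
                 selected = selected, coefficients = final$coef,
                 r2 = final$r2, trace = do.call(rbind, trace),
                 expected_sign = es, spec = spec),
            class = c("lurok_slr", "lurok_lur"))
}

#' @rdname fit_slr
#' @param object fitted model.
#' @param newdata covariates to predict at (training covariates if omitted).
#' @param ... unused.
#' @export
predict.lurok_slr <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    stop("supply `newdata` (no training design is stored)", call. = FALSE)
  }
  Xm <- align_columns(object, newdata)
  b <- object$coefficients
  unname(b[1] + drop(Xm[, object$selected, drop = FALSE] %*%
                       b[object$selected]))
}
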