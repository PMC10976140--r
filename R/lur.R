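# Uniform fit/predict contract over the three land-use-regression
# families, used by the cross-validation and exposure modules.

#' Fit a land-use-regression model of any family
#'
#' Dispatches to [fit_pls()], [fit_rf()] or [fit_slr()].  All families
#' share the contract: `predict(model, X_new)` accepts any covariate set
#' containing the training columns (in any order) and returns finite
#' concentration predictions.
#'
#' @param family one of "PLS", "RF", "SLR" (case-insensitive).
#' @param X covariates (`lurok_covariates`, matrix or data.frame).
#' @param y response concentrations, ug/m3.
#' @param spec family specification ([pls_spec()], [rf_spec()] or
#'   [slr_spec()]; family default if NULL).
#' @return a fitted model of class `lurok_lur`.
#' @export
fit_lur <- function(family, X, y, spec = NULL) {
  fam <- toupper(family)
  switch(fam,
         PLS = fit_pls(X, y, spec %||% pls_spec()),
         RF = fit_rf(X, y, spec %||% rf_spec()),
         SLR = fit_slr(X, y, spec %||% slr_spec()),
         stop("unknown model family: ", family, call. = FALSE))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.lurok_lur <- function(x, ...) {
  cat(sprintf("<lurok %s land-use-regression model on %d covariates>\n",
              x$family, length(x$columns)))
  if (x$family == "SLR") {
    cat("  selected:", paste(x$selected, collapse = ", "), "\n")
    cat(sprintf("  in-sample R2: %.3f\n", x$r2))
  }
  if (x$family == "PLS") cat(sprintf("  scores: %d\n", x$n_scores))
  invisible(x)
}

default_spec <- function(family, seed = 1) {
  switch(toupper(family),
         PLS = pls_spec(),
         RF = rf_spec(seed = seed),
         SLR = slr_spec(),
         stop("unknown model family: ", family, call. = FALSE))
}
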