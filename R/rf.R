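# Random-forest land-use regression via the randomForest package, with the
# hyperparameters conventional for this application: mtry 50 (clamped to
# the number of variables when fewer are available), 500 trees, minimum
# node size 5, and permutation (IncMSE-style) variable importance.

#' Random-forest specification
#'
#' @param mtry candidate variables per split (default 50; clamped to the
#'   number of covariates at fit time with a warning).
#' @param ntree number of trees (default 500).
#' @param node_size minimum terminal-node size (default 5).
#' @param seed RNG seed for the forest.
#' @return a list of class `lurok_rf_spec`.
#' @export
rf_spec <- function(mtry = 50, ntree = 500, node_size = 5, seed = 1) {
  stopifnot_scalar_number(mtry, "mtry", lower = 1)
  stopifnot_scalar_number(ntree, "ntree", lower = 1)
  stopifnot_scalar_number(node_size, "node_size", lower = 1)
  structure(list(mtry = as.integer(mtry), ntree = as.integer(ntree),
                 node_size = as.integer(node_size), seed = as.integer(seed)),
            class = "lurok_rf_spec")
}

#' Fit a random-forest land-use-regression model
#'
#' @param X covariates (`lurok_covariates`, matrix or data.frame).
#' @param y response concentrations, ug/m3.
#' @param spec an [rf_spec()].
#' @return an object of classes `lurok_rf` / `lurok_lur`.
#' @export
fit_rf <- function(X, y, spec = rf_spec()) {
  cx <- as_cov_matrix(X)
  Xm <- cx$values
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y))
  if (length(y) < spec$node_size + 1L) {
    stop("need at least node_size + 1 units to fit a forest", call. = FALSE)
  }
  mtry <- spec$mtry
  if (mtry > ncol(Xm)) {
    warning(sprintf("mtry clamped from %d to %d (number of covariates)",
                    mtry, ncol(Xm)))
    mtry <- ncol(Xm)
  }
  fit <- with_seed(spec$seed,
    randomForest::randomForest(x = Xm, y = y, mtry = mtry,
                               ntree = spec$ntree,
                               nodesize = spec$node_size,
                               importance = TRUE, keep.forest = TRUE))
  structure(list(family = "RF", columns = colnames(Xm), forest = fit,
                 spec = spec, y_range = range(y)),
            class = c("lurok_rf", "lurok_lur"))
}

#' @rdname fit_rf
#' @param object fitted model.
#' @param newdata covariates to predict at (training covariates if omitted;
#'   note: in-sample forest predictions, not out-of-bag).
#' @param ... unused.
#' @export
predict.lurok_rf <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) {
    return(unname(stats::predict(object$forest)))  # out-of-bag
  }
  Xm <- align_columns(object, newdata)
  unname(stats::predict(object$forest, newdata = Xm))
}

#' Permutation importance of random-forest covariates
#'
#' IncMSE-style importance: the increase in out-of-bag mean squared error
#' when each variable is permuted, ranked in decreasing order.
#'
#' @param model a fitted `lurok_rf` model.
#' @param top_k return only the top k variables (NULL = all; the study
#'   convention is a top-10 view).
#' @return a data.frame with columns `variable`, `importance`, ordered by
#'   decreasing importance.
#' @export
rf_importance <- function(model, top_k = NULL) {
  stopifnot(inherits(model, "lurok_rf"))
  imp <- randomForest::importance(model$forest, type = 1, scale = FALSE)
  out <- data.frame(variable = rownames(imp), importance = imp[, 1],
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  out
}
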