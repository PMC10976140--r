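# Partial least squares (PLS1, NIPALS) on centered-and-scaled covariates
# and a centered response.  Three latent scores by default, following the
# common practice for geographic-covariate exposure surfaces.

#' PLS specification
#'
#' @param n_scores number of latent scores (default 3).
#' @return a list of class `lurok_pls_spec`.
#' @export
pls_spec <- function(n_scores = 3) {
  stopifnot_scalar_number(n_scores, "n_scores", lower = 1)
  structure(list(n_scores = as.integer(n_scores)), class = "lurok_pls_spec")
}

# Coerce a covariate input (lurok_covariates or plain matrix/data.frame)
# to a numeric matrix plus sign metadata.
as_cov_matrix <- function(X) {
  if (inherits(X, "lurok_covariates")) {
    list(values = X$values,
         expected_sign = stats::setNames(X$meta$expected_sign,
                                         X$meta$variable))
  } else {
    m <- as.matrix(X)
    if (is.null(colnames(m))) colnames(m) <- sprintf("V%02d", seq_len(ncol(m)))
    es <- attr(X, "expected_sign")
    if (is.null(es)) es <- stats::setNames(rep(0, ncol(m)), colnames(m))
    list(values = m, expected_sign = es)
  }
}

#' Fit a PLS land-use-regression model
#'
#' NIPALS PLS1: covariate columns are centered and scaled (constants
#' recorded for prediction), the response is centered, and `n_scores`
#' orthogonal score vectors are extracted to maximize covariance with the
#' response.  The sign of the first score is fixed so that it correlates
#' non-negatively with the response.  Zero-variance columns are dropped
#' with a warning.
#'
#' @param X covariates (`lurok_covariates`, matrix or data.frame).
#' @param y response concentrations (annual or long-term means), ug/m3.
#' @param spec a [pls_spec()].
#' @return an object of classes `lurok_pls` / `lurok_lur` supporting
#'   [predict()].
#' @export
fit_pls <- function(X, y, spec = pls_spec()) {
  cx <- as_cov_matrix(X)
  Xm <- cx$values
  y <- as.numeric(y)
  stopifnot(nrow(Xm) == length(y))
  if (stats::var(y) == 0) stop("constant response: PLS undefined", call. = FALSE)
  sds <- apply(Xm, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance columns: ",
            paste(colnames(Xm)[sds == 0], collapse = ", "))
    Xm <- Xm[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  p <- ncol(Xm); n <- nrow(Xm)
  K <- min(spec$n_scores, p, n - 1L)
  if (K < spec$n_scores) {
    warning(sprintf("n_scores reduced from %d to %d (rank limit)",
                    spec$n_scores, K))
  }
  ctr <- colMeans(Xm)
  Xs <- sweep(sweep(Xm, 2, ctr), 2, sds, "/")
  ybar <- mean(y)
  E <- Xs; f <- y - ybar
  W <- P <- matrix(0, p, K); q <- numeric(K)
  Tm <- matrix(0, n, K)
  for (k in seq_len(K)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { K <- k - 1L; break }
    w <- w / nw
    t <- drop(E %*% w)
    tt <- sum(t^2)
    pk <- drop(crossprod(E, t)) / tt
    qk <- sum(f * t) / tt
    if (k == 1L && qk < 0) {  # fix score-1 sign: positive association with y
      w <- -w; t <- -t; pk <- -pk; qk <- -qk
    }
    W[, k] <- w; P[, k] <- pk; q[k] <- qk; Tm[, k] <- t
    E <- E - tcrossprod(t, pk)
    f <- f - t * qk
  }
  W <- W[, seq_len(K), drop = FALSE]; P <- P[, seq_len(K), drop = FALSE]
  q <- q[seq_len(K)]; Tm <- Tm[, seq_len(K), drop = FALSE]
  B <- W %*% solve(crossprod(P, W), q)  # coefficients in standardized space
  model <- structure(
    list(family = "PLS", columns = colnames(Xm), center = ctr, scale = sds,
         weights = W, loadings = P, q = q, coef_std = drop(B),
         y_mean = ybar, scores = Tm, n_scores = K, X_std = Xs,
         fitted = ybar + drop(Xs %*% B)),
    class = c("lurok_pls", "lurok_lur"))
  model
}

# Align a new covariate matrix to the model's training columns.
align_columns <- function(model, X_new) {
  m <- as_cov_matrix(X_new)$values
  missing <- setdiff(model$columns, colnames(m))
  if (length(missing)) {
    stop("missing covariate column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m[, model$columns, drop = FALSE]
}

#' @rdname fit_pls
#' @param object fitted model.
#' @param newdata covariates to predict at (training covariates if omitted).
#' @param ... unused.
#' @export
predict.lurok_pls <- function(object, newdata = NULL, ...) {
  if (is.null(newdata)) return(object$fitted)
  Xm <- align_columns(object, newdata)
  Xs <- sweep(sweep(Xm, 2, object$center), 2, object$scale, "/")
  unname(object$y_mean + drop(Xs %*% object$coef_std))
}

#' Correlation of each covariate with the first PLS score
#'
#' Pearson correlation between each standardized covariate column and the
#' first latent score, the standard diagnostic for which geographic
#' variables drive the PLS surface.  Zero-variance columns get correlation
#' 0 and are listed in the `flagged` attribute.
#'
#' @param model a fitted `lurok_pls` model.
#' @param X covariates to evaluate at (training data if omitted).
#' @return a named numeric vector of correlations in [-1, 1].
#' @export
pls_score_correlations <- function(model, X = NULL) {
  stopifnot(inherits(model, "lurok_pls"))
  if (is.null(X)) {
    Xs <- model$X_std
  } else {
    Xm <- align_columns(model, X)
    Xs <- sweep(sweep(Xm, 2, model$center), 2, model$scale, "/")
  }
  t1 <- drop(Xs %*% model$weights[, 1])
  sds <- apply(Xs, 2, stats::sd)
  out <- rep(0, ncol(Xs)); names(out) <- colnames(Xs)
  ok <- sds > 0 & stats::sd(t1) > 0
  out[ok] <- drop(stats::cor(Xs[, ok, drop = FALSE], t1))
  attr(out, "flagged") <- names(out)[!ok]
  out
}
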