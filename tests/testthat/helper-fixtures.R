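# Shared fixtures: small covariate/response sets built in code.

# n x p covariate matrix with named columns and optional expected signs.
make_X <- function(n, p, seed = 1, expected_sign = rep(0, p)) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(sprintf("S%02d", seq_len(n)),
                              sprintf("V%02d", seq_len(p))))
  attr(X, "expected_sign") <- stats::setNames(expected_sign, colnames(X))
  X
}

# Linear response y = intercept + X beta + noise.
make_linear_y <- function(X, beta, intercept = 30, noise_sd = 0, seed = 2) {
  set.seed(seed)
  drop(intercept + X %*% beta + rnorm(nrow(X), 0, noise_sd))
}

# Random site coordinates on a square domain.
make_coords <- function(n, size = 20000, seed = 3) {
  set.seed(seed)
  cbind(x = runif(n, 0, size), y = runif(n, 0, size))
}

# Simulate a zero-mean Gaussian field with exponential covariance at the
# given coordinates (independent of the package's own simulator: plain
# multivariate-normal via Cholesky of the covariance assembled here).
sim_expo_field <- function(coords, sill, range, nugget = 0, seed = 1) {
  h <- as.matrix(dist(coords))
  C <- sill * exp(-h / range)
  diag(C) <- sill + nugget + 1e-10
  set.seed(seed)
  drop(t(chol(C)) %*% rnorm(nrow(coords)))
}

# Hourly fixture: one site, chosen UTC+8 local days each with a given
# number of present hours at given values.
make_hourly_days <- function(day_hours, values, site = "S1",
                             pollutant = "NO2", utc_offset = 8) {
  rows <- list()
  for (i in seq_along(day_hours)) {
    d <- as.Date(names(day_hours)[i])
    nh <- day_hours[[i]]
    local <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC") +
      3600 * (seq_len(nh) - 1)
    rows[[i]] <- data.frame(site_id = site,
                            timestamp = local - utc_offset * 3600,
                            pollutant = pollutant,
                            value = rep_len(values[[i]], nh),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# Tiny population grid with explicit populations and predictions.
make_surface <- function(pred, tag = "M") {
  out <- data.frame(grid_id = sprintf("G%03d", seq_along(pred)),
                    prediction = pred, stringsAsFactors = FALSE)
  attr(out, "tag") <- tag
  class(out) <- c("lurok_surface", "data.frame")
  out
}

make_grid <- function(pop) {
  data.frame(grid_id = sprintf("G%03d", seq_along(pop)),
             x = seq_along(pop) * 1000, y = rep(0, length(pop)),
             population = pop, stringsAsFactors = FALSE)
}

# Independent stepwise-selection oracle: enumerate every candidate
# addition each round with plain lm(), apply the same sign-plausibility
# and R2-gain rules, return the entry order.
slr_forward_oracle <- function(X, y, es, gain = 0.1) {
  vars <- colnames(X)
  fit_r2 <- function(v) {
    f <- lm(y ~ ., data = data.frame(y = y, X[, v, drop = FALSE],
                                     check.names = FALSE))
    list(r2 = summary(f)$r.squared, coef = coef(f)[-1])
  }
  plaus <- function(coefs) {
    e <- es[names(coefs)]
    cc <- ifelse(is.na(coefs), 0, coefs)
    all(e == 0 | sign(cc) == e)
  }
  sel <- character(0); cur <- -Inf
  repeat {
    cand <- setdiff(vars, sel)
    if (!length(cand)) break
    scores <- sapply(cand, function(v) {
      f <- fit_r2(c(sel, v))
      if (!plaus(f$coef)) -Inf else f$r2
    })
    best <- which.max(scores)
    if (!is.finite(scores[best])) break
    if (length(sel) == 0) {
      sel <- cand[best]; cur <- scores[best]
    } else {
      if (scores[best] - cur < gain) break
      sel <- c(sel, cand[best]); cur <- scores[best]
    }
  }
  sel
}

# Per-person brute force: expand to one row per person (integer
# populations), take empirical type-1 quartiles, classify with ties to
# the lower class.
person_quartile_oracle <- function(pred, pop) {
  expanded <- rep(pred, times = pop)
  cuts <- stats::quantile(expanded, c(0.25, 0.5, 0.75), type = 1)
  1L + vapply(pred, function(v) sum(v > cuts), integer(1))
}
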