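# Synthetic monitoring networks, covariates, concentration series and
# population grids with the statistical structure the downstream analysis
# assumes: a handful of sites of four types on a planar domain, smooth
# spatially correlated covariates, concentrations that are a linear function
# of a covariate subset plus a spatially autocorrelated residual, and a
# center-peaked 1-km population grid.

#' Simulation configuration
#'
#' Bundles every knob of the synthetic-data generator.  The defaults emulate
#' a six-year, 35-site urban monitoring network (1 background, 7 traffic,
#' 14 urban, 13 suburban sites) on an abstract 70-km planar domain, with a
#' dozen smooth geographic covariates of which four drive the concentration
#' field, an exponential-covariance spatial residual, an annual seasonal
#' cycle, hourly noise and 15% missingness (a mixture of random gaps and
#' contiguous block outages).
#'
#' @param n_sites number of monitoring sites (>= 4, one per site type).
#' @param years integer vector of calendar years to simulate hourly data for.
#' @param n_variables number of geographic covariates (>= 2); the last two
#'   are the planar coordinates themselves.
#' @param beta true linear coefficients, one per covariate (recycled /
#'   truncated to `n_variables`); zero entries are pure distractors.
#' @param intercept baseline concentration, ug/m3.
#' @param residual_sill partial sill of the spatial residual field, (ug/m3)^2.
#' @param residual_range range of the exponential residual covariance, meters.
#' @param nugget nugget variance of the residual field, (ug/m3)^2.
#' @param noise_sd standard deviation of iid hourly noise, ug/m3.
#' @param seasonal_amplitude amplitude of the 1-year sinusoid, ug/m3.
#' @param missing_rate fraction of site-hours removed, in [0, 1).
#' @param domain_size side length of the square study domain, meters.
#' @param grid_cell_size population-grid cell size, meters.
#' @param n_grid_cells number of population-grid cells.
#' @param pop_min,pop_max clip bounds for population density, persons/km2.
#' @param pop_total target total population over the grid.
#' @param pollutant label attached to generated series ("NO2" or "PM2.5").
#' @param seed master seed; every generator output is a deterministic
#'   function of it.
#'
#' @return an object of class `lurok_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_sites = 35, years = 2015, seed = 1)
#' net <- generate_network(cfg)
#' table(net$site_type)
sim_config <- function(n_sites = 35,
                       years = 2015:2020,
                       n_variables = 12,
                       beta = c(8, 6, -5, 4, rep(0, 8)),
                       intercept = 40,
                       residual_sill = 6,
                       residual_range = 12000,
                       nugget = 0.5,
                       noise_sd = 8,
                       seasonal_amplitude = 15,
                       missing_rate = 0.15,
                       domain_size = 70000,
                       grid_cell_size = 1000,
                       n_grid_cells = 3301,
                       pop_min = 211,
                       pop_max = 32097,
                       pop_total = 15.94e6,
                       pollutant = c("NO2", "PM2.5"),
                       seed = 1) {
  pollutant <- match.arg(pollutant)
  stopifnot_scalar_number(n_sites, "n_sites", lower = 4)
  stopifnot_scalar_number(n_variables, "n_variables", lower = 2)
  stopifnot_scalar_number(residual_sill, "residual_sill", lower = 0)
  stopifnot_scalar_number(residual_range, "residual_range", lower = 1e-9)
  stopifnot_scalar_number(nugget, "nugget", lower = 0)
  stopifnot_scalar_number(noise_sd, "noise_sd", lower = 0)
  stopifnot_scalar_number(missing_rate, "missing_rate", lower = 0)
  if (missing_rate >= 1) stop("`missing_rate` must be < 1", call. = FALSE)
  beta <- rep_len(as.numeric(beta), n_variables)
  cfg <- list(n_sites = as.integer(n_sites), years = as.integer(years),
              n_variables = as.integer(n_variables), beta = beta,
              intercept = intercept, residual_sill = residual_sill,
              residual_range = residual_range, nugget = nugget,
              noise_sd = noise_sd, seasonal_amplitude = seasonal_amplitude,
              missing_rate = missing_rate, domain_size = domain_size,
              grid_cell_size = grid_cell_size,
              n_grid_cells = as.integer(n_grid_cells),
              pop_min = pop_min, pop_max = pop_max, pop_total = pop_total,
              pollutant = pollutant, seed = as.integer(seed))
  class(cfg) <- "lurok_config"
  cfg
}

#' @export
print.lurok_config <- function(x, ...) {
  cat("<lurok simulation config>\n")
  cat(sprintf("  sites: %d   years: %s   covariates: %d (%d signal)\n",
              x$n_sites, paste(range(x$years), collapse = "-"),
              x$n_variables, sum(x$beta != 0)))
  cat(sprintf("  residual: sill %.3g, range %.0f m, nugget %.3g; noise sd %.3g\n",
              x$residual_sill, x$residual_range, x$nugget, x$noise_sd))
  cat(sprintf("  missing rate %.2f, seed %d\n", x$missing_rate, x$seed))
  invisible(x)
}

# Allocate site-type counts: always one background site, the rest split
# between traffic/urban/suburban in the 7:14:13 proportion of the study
# network (exact {1,7,14,13} at n = 35).
site_type_counts <- function(n_sites) {
  if (n_sites < 4) stop("need at least 4 sites, one per type", call. = FALSE)
  rest <- n_sites - 1L
  traffic <- max(1L, as.integer(round(rest * 7 / 34)))
  urban <- max(1L, as.integer(round(rest * 14 / 34)))
  suburban <- rest - traffic - urban
  while (suburban < 1L) {
    if (urban > traffic && urban > 1L) urban <- urban - 1L
    else traffic <- traffic - 1L
    suburban <- rest - traffic - urban
  }
  c(background = 1L, traffic = traffic, urban = urban, suburban = suburban)
}

#' Generate a monitoring-site network
#'
#' Places `n_sites` monitors on the square domain: urban and traffic sites
#' clustered near the center, suburban sites on the periphery, and a single
#' background site at maximal distance from the center (the cleanest corner
#' of the domain).
#'
#' @param config a [sim_config()] object.
#' @return a data.frame with columns `site_id`, `x`, `y` (meters) and
#'   `site_type` (factor with levels background/traffic/urban/suburban).
#' @export
generate_network <- function(config) {
  stopifnot(inherits(config, "lurok_config"))
  counts <- site_type_counts(config$n_sites)
  L <- config$domain_size
  ctr <- c(L / 2, L / 2)
  with_seed(derive_seed(config$seed, 1), {
    place_ring <- function(n, r_min, r_max) {
      ang <- stats::runif(n, 0, 2 * pi)
      r <- sqrt(stats::runif(n, (r_min / L)^2, (r_max / L)^2)) * L
      cbind(ctr[1] + r * cos(ang), ctr[2] + r * sin(ang))
    }
    urban <- place_ring(counts["urban"], 0, 0.12 * L)
    traffic <- place_ring(counts["traffic"], 0.02 * L, 0.18 * L)
    suburban <- place_ring(counts["suburban"], 0.22 * L, 0.42 * L)
    bg_ang <- stats::runif(1, 0, 2 * pi)
    background <- cbind(ctr[1] + 0.48 * L * cos(bg_ang),
                        ctr[2] + 0.48 * L * sin(bg_ang))
    xy <- rbind(background, traffic, urban, suburban)
    xy[, 1] <- pmin(pmax(xy[, 1], 0), L)
    xy[, 2] <- pmin(pmax(xy[, 2], 0), L)
    type <- factor(rep(names(counts), counts),
                   levels = c("background", "traffic", "urban", "suburban"))
    data.frame(site_id = sprintf("S%03d", seq_len(config$n_sites)),
               x = xy[, 1], y = xy[, 2], site_type = type,
               stringsAsFactors = FALSE)
  })
}

# Smooth stationary random field as a random cosine expansion; evaluating
# the same (seed, variable) pair at any set of locations samples one fixed
# underlying field, so site and grid covariates are mutually consistent.
field_eval <- function(x, y, config, variable_index, n_terms = 48,
                       length_scale = 0.2) {
  ls <- length_scale * config$domain_size
  with_seed(derive_seed(config$seed, 100 + variable_index), {
    w1 <- stats::rnorm(n_terms) / ls
    w2 <- stats::rnorm(n_terms) / ls
    ph <- stats::runif(n_terms, 0, 2 * pi)
  })
  v <- numeric(length(x))
  for (k in seq_len(n_terms)) {
    v <- v + cos(x * w1[k] + y * w2[k] + ph[k])
  }
  v * sqrt(2 / n_terms)
}

covariate_groups <- c("population", "traffic", "landuse", "ndvi", "poi")

#' Generate the geographic covariate matrix for a set of units
#'
#' Evaluates `n_variables` smooth spatial fields at the unit locations
#' (monitoring sites or grid-cell centers).  The last two variables are the
#' planar coordinates themselves (the analogue of longitude / projected-y
#' covariates); the others are seeded Gaussian-like random fields standing
#' in for population density, road network, land-use, vegetation-index and
#' point-of-interest variables.  Variables with nonzero entries in
#' `config$beta` carry the matching expected sign in the metadata; all
#' others are unconstrained (sign 0).
#'
#' @param units a data.frame with columns `x`, `y` and either `site_id` or
#'   `grid_id`.
#' @param n_variables number of covariates (default from `config`).
#' @param config a [sim_config()] object.
#' @return a list of class `lurok_covariates` with elements `values` (a
#'   units x variables numeric matrix with unit-id rownames) and `meta`
#'   (data.frame `variable`, `expected_sign` in {-1, 0, 1}, `group`).
#' @export
generate_covariates <- function(units, n_variables = config$n_variables,
                                config) {
  stopifnot(inherits(config, "lurok_config"))
  if (n_variables < 2) stop("`n_variables` must be >= 2", call. = FALSE)
  ids <- if ("site_id" %in% names(units)) units$site_id else units$grid_id
  n_field <- n_variables - 2L
  vals <- matrix(0, nrow(units), n_variables)
  scales <- 0.08 + 0.3 * ((seq_len(max(n_field, 1)) - 1) %% 5) / 5
  for (j in seq_len(n_field)) {
    vals[, j] <- field_eval(units$x, units$y, config, j,
                            length_scale = scales[j])
  }
  # coordinate covariates, centered and put on a unit-ish scale
  vals[, n_field + 1L] <- (units$x - config$domain_size / 2) /
    (config$domain_size / 4)
  vals[, n_field + 2L] <- (units$y - config$domain_size / 2) /
    (config$domain_size / 4)
  vn <- c(if (n_field > 0)
    sprintf("%s_%02d", covariate_groups[(seq_len(n_field) - 1) %% 5 + 1],
            seq_len(n_field)), "coord_x", "coord_y")
  colnames(vals) <- vn
  rownames(vals) <- ids
  beta <- rep_len(config$beta, n_variables)
  meta <- data.frame(variable = vn,
                     expected_sign = sign(beta),
                     group = c(if (n_field > 0)
                       covariate_groups[(seq_len(n_field) - 1) %% 5 + 1],
                       "coordinate", "coordinate"),
                     stringsAsFactors = FALSE)
  structure(list(values = vals, meta = meta), class = "lurok_covariates")
}

#' @export
print.lurok_covariates <- function(x, ...) {
  cat(sprintf("<lurok covariates: %d units x %d variables (%d sign-constrained)>\n",
              nrow(x$values), ncol(x$values), sum(x$meta$expected_sign != 0)))
  invisible(x)
}

# Simulate the spatially correlated residual field at site locations by
# Cholesky factorization of the exponential covariance.
spatial_residual <- function(coords, config, stream = 2) {
  n <- nrow(coords)
  if (config$residual_sill <= 0 && config$nugget <= 0) return(numeric(n))
  h <- cross_dist(coords, coords)
  C <- config$residual_sill * exp(-h / config$residual_range)
  diag(C) <- config$residual_sill + config$nugget + 1e-10
  R <- chol(C)
  with_seed(derive_seed(config$seed, stream),
            drop(crossprod(R, stats::rnorm(n))))
}

#' Generate hourly concentration series for a network
#'
#' Hourly value = intercept + X beta + S(x, y) + seasonal sinusoid + iid
#' noise, floored at zero, where S is a zero-mean Gaussian field with
#' exponential covariance (sill `residual_sill`, range `residual_range`)
#' plus a nugget.  The seasonal sinusoid has a one-year period and sums to
#' zero exactly over each calendar year.  A fraction `missing_rate` of
#' site-hours is removed: roughly one third as contiguous multi-week block
#' outages and the rest completely at random, so that every completeness
#' rule in the temporal-aggregation stage has both passing and failing
#' cases.
#'
#' @param network output of [generate_network()].
#' @param covariates output of [generate_covariates()] for the same sites.
#' @param config a [sim_config()] object.
#' @return a data.frame of observed hours with columns `site_id`,
#'   `timestamp` (POSIXct, UTC), `pollutant`, `value` (ug/m3); missing
#'   hours are absent as rows.  The true site-level annual means are
#'   attached as attribute `site_mean`.
#' @export
generate_concentrations <- function(network, covariates, config) {
  stopifnot(inherits(config, "lurok_config"),
            inherits(covariates, "lurok_covariates"))
  if (!identical(rownames(covariates$values), network$site_id)) {
    stop("covariates are not aligned to the network sites", call. = FALSE)
  }
  mu <- config$intercept +
    drop(covariates$values %*% rep_len(config$beta, ncol(covariates$values))) +
    spatial_residual(network[, c("x", "y")], config)
  names(mu) <- network$site_id

  t0 <- as.POSIXct(sprintf("%d-01-01 00:00:00", min(config$years)), tz = "UTC")
  t1 <- as.POSIXct(sprintf("%d-12-31 23:00:00", max(config$years)), tz = "UTC")
  hours <- seq(t0, t1, by = "hour")
  yr <- as.POSIXlt(hours)$year + 1900L
  hours_in_year <- as.vector(table(yr))[match(yr, sort(unique(yr)))]
  hour_of_year <- sequence(rle(yr)$lengths) - 1L
  seasonal <- config$seasonal_amplitude *
    sin(2 * pi * hour_of_year / hours_in_year)
  nh <- length(hours)
  n <- nrow(network)

  vals <- with_seed(derive_seed(config$seed, 3), {
    noise <- if (config$noise_sd > 0) stats::rnorm(n * nh, 0, config$noise_sd)
             else numeric(n * nh)
    rep(mu, each = nh) + rep(seasonal, times = n) + noise
  })
  vals <- pmax(vals, 0)
  keep <- with_seed(derive_seed(config$seed, 4), {
    keep <- rep(TRUE, n * nh)
    if (config$missing_rate > 0) {
      block_target <- config$missing_rate / 3
      n_blocks <- if (nh > 24 * 42) max(0L, round(block_target * nh / (24 * 21)))
                  else 0L
      for (i in seq_len(n)) {
        if (n_blocks > 0) {
          starts <- sample.int(nh - 24 * 21, n_blocks)
          len <- sample(c(24 * 7, 24 * 14, 24 * 21), n_blocks, replace = TRUE)
          for (b in seq_len(n_blocks)) {
            keep[(i - 1) * nh + seq(starts[b], starts[b] + len[b] - 1)] <- FALSE
          }
        }
      }
      still <- which(keep)
      frac_blocked <- 1 - length(still) / (n * nh)
      p_mcar <- max(0, (config$missing_rate - frac_blocked) / (1 - frac_blocked))
      if (p_mcar > 0) {
        drop_idx <- still[stats::runif(length(still)) < p_mcar]
        keep[drop_idx] <- FALSE
      }
    }
    keep
  })
  out <- data.frame(site_id = rep(network$site_id, each = nh),
                    timestamp = rep(hours, times = n),
                    pollutant = config$pollutant,
                    value = vals, stringsAsFactors = FALSE)[keep, ]
  rownames(out) <- NULL
  attr(out, "site_mean") <- mu
  out
}

#' Generate the 1-km population grid
#'
#' Lays out `n_grid_cells` square cells nearest the domain center (a clipped
#' square block), assigns a center-peaked population-density surface with
#' multiplicative lognormal texture, clips densities to
#' `[pop_min, pop_max]`, and rescales the total to `pop_total` by solving
#' for a power transform of the density shape (so the clip bounds are
#' respected exactly).  Covariates are evaluated at the cell centers from
#' the same underlying fields as the site covariates.
#'
#' @param config a [sim_config()] object.
#' @param with_covariates evaluate the covariate fields at cell centers
#'   (default TRUE).
#' @return a data.frame with `grid_id`, `x`, `y`, `population` and, when
#'   requested, one column per covariate.
#' @export
generate_population_grid <- function(config, with_covariates = TRUE) {
  stopifnot(inherits(config, "lurok_config"))
  cell <- config$grid_cell_size
  m <- ceiling(sqrt(config$n_grid_cells))
  side <- seq_len(m + 2L) - (m + 2L + 1) / 2
  ctr <- config$domain_size / 2
  gx <- rep(ctr + side * cell, times = m + 2L)
  gy <- rep(ctr + side * cell, each = m + 2L)
  d <- sqrt((gx - ctr)^2 + (gy - ctr)^2)
  ord <- order(d, gx, gy)[seq_len(config$n_grid_cells)]
  gx <- gx[sort(ord)]; gy <- gy[sort(ord)]
  d <- sqrt((gx - ctr)^2 + (gy - ctr)^2)

  sigma <- 0.22 * config$domain_size
  shape <- exp(-d^2 / (2 * sigma^2))
  shape <- shape * with_seed(derive_seed(config$seed, 5),
                             exp(stats::rnorm(length(shape), 0, 0.35)))
  shape <- (shape - min(shape)) / (max(shape) - min(shape))
  total_at <- function(t) sum(config$pop_min +
                                (config$pop_max - config$pop_min) * shape^t)
  lo <- 1e-3; hi <- 60
  if (config$pop_total >= total_at(lo) || config$pop_total <= total_at(hi)) {
    stop("`pop_total` is outside the range achievable under the clip bounds",
         call. = FALSE)
  }
  t_star <- stats::uniroot(function(t) total_at(t) - config$pop_total,
                           c(lo, hi), tol = 1e-10)$root
  pop <- config$pop_min + (config$pop_max - config$pop_min) * shape^t_star

  grid <- data.frame(grid_id = sprintf("G%04d", seq_along(gx)),
                     x = gx, y = gy, population = pop,
                     stringsAsFactors = FALSE)
  if (with_covariates) {
    cov <- generate_covariates(grid, config$n_variables, config)
    grid <- cbind(grid, as.data.frame(cov$values))
  }
  grid
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper producing the network, site covariates, hourly
#' concentrations and population grid from one configuration.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements `config`, `network`, `covariates`,
#'   `hourly` and `grid`.
#' @export
simulate_study <- function(config = sim_config()) {
  network <- generate_network(config)
  covariates <- generate_covariates(network, config$n_variables, config)
  hourly <- generate_concentrations(network, covariates, config)
  grid <- generate_population_grid(config)
  list(config = config, network = network, covariates = covariates,
       hourly = hourly, grid = grid)
}
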