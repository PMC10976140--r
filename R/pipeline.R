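# End-to-end orchestration: simulate -> aggregate -> fit the model
# variants -> leave-one-site-out cross-validation -> gridded prediction ->
# cross-model comparison, from a single configuration, with a
# deterministic manifest of everything written.

#' Pipeline run configuration
#'
#' @param sim a [sim_config()] for the synthetic inputs.
#' @param years years to evaluate (default: the simulated years); the
#'   long-term mean over them is always evaluated too.
#' @param families model families to run (default all three).
#' @param kriging logical vector of kriging settings to run per family
#'   (default `c(FALSE, TRUE)`, i.e. each family with and without the
#'   ordinary-kriging step).
#' @param site_subset "all" or "urban-only" (train on urban and traffic
#'   sites near the domain core only, emulating an urban-subset model).
#' @param pls,rf,slr family specifications.
#' @param vgm_family variogram family for the kriging step.
#' @param utc_offset local-time offset for daily aggregation.
#' @param seed master seed for the model stages (the simulation stage uses
#'   `sim$seed`).
#' @return a list of class `lurok_run_config`.
#' @export
run_config <- function(sim = sim_config(), years = NULL,
                       families = c("PLS", "RF", "SLR"),
                       kriging = c(FALSE, TRUE),
                       site_subset = c("all", "urban-only"),
                       pls = pls_spec(), rf = NULL, slr = slr_spec(),
                       vgm_family = "exponential", utc_offset = 8,
                       seed = 1) {
  site_subset <- match.arg(site_subset)
  families <- match.arg(toupper(families), c("PLS", "RF", "SLR"),
                        several.ok = TRUE)
  if (is.null(years)) years <- sim$years
  if (is.null(rf)) rf <- rf_spec(seed = seed)
  structure(list(sim = sim, years = as.integer(years), families = families,
                 kriging = as.logical(kriging), site_subset = site_subset,
                 pls = pls, rf = rf, slr = slr, vgm_family = vgm_family,
                 utc_offset = utc_offset, seed = as.integer(seed)),
            class = "lurok_run_config")
}

#' Demonstration pipeline configuration
#'
#' A reduced-scale run-everything configuration: the full 35-site network
#' but a single simulated year, a 400-cell population grid and a 1.2
#' million target population, so the complete pipeline (simulate,
#' aggregate, six model variants of LOOCV, surfaces, comparison) finishes
#' in a couple of minutes.
#'
#' @param seed master seed.
#' @return a [run_config()].
#' @export
demo_run_config <- function(seed = 1) {
  run_config(sim = sim_config(n_sites = 35, years = 2015,
                              n_grid_cells = 400, pop_total = 1.2e6,
                              seed = seed),
             seed = seed)
}

family_spec <- function(config, family) {
  switch(family, PLS = config$pls, RF = config$rf, SLR = config$slr)
}

subset_sites <- function(network, config) {
  if (config$site_subset == "all") return(network$site_id)
  L <- config$sim$domain_size
  r <- sqrt((network$x - L / 2)^2 + (network$y - L / 2)^2)
  core <- r <= 0.2 * L
  keep <- (network$site_type %in% c("urban", "traffic")) |
    (network$site_type == "background" & core)
  network$site_id[keep]
}

#' Run the full analysis pipeline
#'
#' Executes simulate, aggregate, per-period LOOCV for every requested
#' family x kriging variant, long-term-mean surface prediction over the
#' population grid, and cross-model comparison (quartile
#' misclassification, coefficient of variation, correlation).  All
#' outputs are plain text under `output_dir`; the manifest records each
#' file's MD5 checksum, so two runs with the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param output_dir directory for outputs (created if needed).
#' @return the manifest (list), invisibly; also written as manifest.json.
#' @export
run_pipeline <- function(config, output_dir) {
  stopifnot(inherits(config, "lurok_run_config"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(output_dir, ...)
  files <- character(0)
  log_stage <- function(fmt, ...) message(sprintf(paste0("[lurok] ", fmt), ...))

  log_stage("simulate: %d sites, years %s", config$sim$n_sites,
            paste(range(config$sim$years), collapse = "-"))
  study <- simulate_study(config$sim)
  keep_ids <- subset_sites(study$network, config)
  network <- study$network[study$network$site_id %in% keep_ids, ]
  cov_vals <- study$covariates$values[keep_ids, , drop = FALSE]
  covariates <- structure(list(values = cov_vals,
                               meta = study$covariates$meta),
                          class = "lurok_covariates")
  hourly <- study$hourly[study$hourly$site_id %in% keep_ids, ]
  files <- c(files,
             write_sites_csv(network, out("sites.csv")),
             write_hourly_csv(hourly, out("hourly.csv")),
             write_covariates_csv(covariates, out("covariates.csv"),
                                  out("variable_meta.csv")),
             out("variable_meta.csv"),
             write_grid_csv(study$grid, out("grid.csv")))

  log_stage("aggregate: %d hourly rows", nrow(hourly))
  agg <- aggregate_concentrations(hourly, utc_offset = config$utc_offset,
                                  years = config$years)
  all_agg <- rbind(agg$daily, agg$weekly, agg$annual, agg$ltm)
  files <- c(files, write_aggregates_csv(all_agg, out("aggregates.csv")))

  # period -> named vector of site values (NA = unavailable)
  period_values <- function(period_df, key) {
    rows <- period_df[period_df$period_key == key, ]
    stats::setNames(rows$value, rows$site_id)[network$site_id]
  }
  periods <- c(as.character(config$years),
               unique(agg$ltm$period_key))
  coords <- as.matrix(network[, c("x", "y")])

  cv_rows <- list(); pred_rows <- list()
  for (key in periods) {
    src <- if (key %in% as.character(config$years)) agg$annual else agg$ltm
    y <- period_values(src, key)
    if (sum(!is.na(y)) < 5) next
    for (fam in config$families) for (kr in config$kriging) {
      log_stage("cv: %s%s %s (n=%d)", fam, if (kr) "-OK" else "", key,
                sum(!is.na(y)))
      Xs <- cov_vals
      attr(Xs, "expected_sign") <-
        stats::setNames(study$covariates$meta$expected_sign,
                        study$covariates$meta$variable)
      cv <- loocv(fam, Xs, y, coords, kriging = kr,
                  lur_spec = family_spec(config, fam),
                  vgm_family = config$vgm_family)
      cv_rows[[length(cv_rows) + 1]] <-
        data.frame(family = fam, kriging = kr, period = key, n = cv$n,
                   RMSE = cv$rmse, R2_mse = cv$r2_mse, R2_reg = cv$r2_reg,
                   stringsAsFactors = FALSE)
      pr <- cv$predictions
      pr$family <- fam; pr$kriging <- kr; pr$period <- key
      pred_rows[[length(pred_rows) + 1]] <- pr
    }
  }
  cv_metrics <- do.call(rbind, cv_rows)
  data.table::fwrite(cv_metrics, out("cv_metrics.csv"))
  data.table::fwrite(do.call(rbind, pred_rows), out("cv_predictions.csv"))
  files <- c(files, out("cv_metrics.csv"), out("cv_predictions.csv"))

  # long-term-mean exposure surfaces with the kriging variants
  ltm_key <- unique(agg$ltm$period_key)
  y_ltm <- period_values(agg$ltm, ltm_key)
  ok_sites <- !is.na(y_ltm)
  surfaces <- list(); class_list <- list()
  for (fam in config$families) {
    log_stage("predict: %s-OK surface over %d cells", fam, nrow(study$grid))
    Xs <- cov_vals[ok_sites, , drop = FALSE]
    attr(Xs, "expected_sign") <-
      stats::setNames(study$covariates$meta$expected_sign,
                      study$covariates$meta$variable)
    hyb <- fit_hybrid(fam, Xs, y_ltm[ok_sites], coords[ok_sites, ,
                                                       drop = FALSE],
                      lur_spec = family_spec(config, fam),
                      vgm_family = config$vgm_family)
    surf <- predict_surface(hyb, study$grid)
    surfaces[[paste0(fam, "-OK")]] <- surf
    class_list[[paste0(fam, "-OK")]] <-
      quartile_classify(surf, study$grid, weighting = "population")
    sf <- as.data.frame(surf)
    sf$model <- attr(surf, "tag")
    data.table::fwrite(sf, out(sprintf("surface_%s.csv", fam)))
    files <- c(files, out(sprintf("surface_%s.csv", fam)))
  }

  log_stage("compare: %d surfaces", length(surfaces))
  pee <- vapply(surfaces, population_weighted_mean, numeric(1),
                grid = study$grid)
  pairs <- if (length(surfaces) >= 2) {
    utils::combn(names(surfaces), 2, simplify = FALSE)
  } else list()
  mis <- lapply(pairs, function(p) {
    m <- misclassification(class_list[[p[1]]], class_list[[p[2]]],
                           study$grid)
    list(pair = paste(p, collapse = " vs "), total = m$total,
         overestimated = m$overestimated,
         underestimated = m$underestimated, non_adjacent = m$non_adjacent,
         matrix = m$matrix)
  })
  comparison <- list(pee = as.list(pee), misclassification = mis)
  jsonlite::write_json(comparison, out("misclassification.json"),
                       auto_unbox = TRUE, digits = NA)
  files <- c(files, out("misclassification.json"))
  covr <- NULL
  if (length(surfaces) >= 2) {
    covr <- cross_model_cov(unname(surfaces))
    data.table::fwrite(data.frame(grid_id = study$grid$grid_id,
                                  cov = covr$cov), out("cov.csv"))
    cormat <- cross_model_correlation(unname(surfaces))
    data.table::fwrite(data.frame(model = rownames(cormat), cormat),
                       out("correlation.csv"))
    files <- c(files, out("cov.csv"), out("correlation.csv"))
  }

  manifest <- list(
    config = list(n_sites = config$sim$n_sites,
                  n_sites_used = nrow(network),
                  site_subset = config$site_subset,
                  years = config$years, families = config$families,
                  kriging = config$kriging, seed = config$seed,
                  sim_seed = config$sim$seed,
                  pollutant = config$sim$pollutant),
    cov_summary = if (!is.null(covr)) as.list(covr$summary),
    pee = as.list(pee),
    files = lapply(stats::setNames(nm = basename(files)), function(f)
      unname(tools::md5sum(file.path(output_dir, f)))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}
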