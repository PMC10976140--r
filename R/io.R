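# Plain-text readers and writers for the pipeline's file formats: CSV
# schemas for sites, hourly series, covariates, grids, aggregates and
# model diagnostics, plus GeoJSON point export.

#' Write the monitoring-site table
#'
#' Columns: site_id, x, y, site_type.
#' @param network a [generate_network()] data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_sites_csv <- function(network, path) {
  data.table::fwrite(network, path)
  invisible(path)
}

#' Write hourly concentrations (missing hours absent as rows)
#'
#' Columns: site_id, timestamp (ISO-8601 UTC), pollutant, value.
#' @param hourly a [generate_concentrations()] data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_hourly_csv <- function(hourly, path) {
  out <- data.table::as.data.table(hourly)
  out[, timestamp := format(timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")]
  data.table::fwrite(out, path)
  invisible(path)
}

#' Read hourly concentrations written by [write_hourly_csv()]
#' @param path CSV path.
#' @return a data.frame with POSIXct timestamps (UTC).
#' @export
read_hourly_csv <- function(path) {
  dt <- data.table::fread(path, colClasses = list(character = "timestamp"))
  dt[, timestamp := as.POSIXct(timestamp, format = "%Y-%m-%dT%H:%M:%SZ",
                               tz = "UTC")]
  as.data.frame(dt)
}

#' Write the covariate matrix and its sign metadata
#'
#' covariates.csv: unit_id + one column per variable.
#' variable_meta.csv: variable, expected_sign (+ / - / 0), group.
#' @param covariates a `lurok_covariates` object.
#' @param path output CSV path for the matrix.
#' @param meta_path output CSV path for the metadata (default:
#'   variable_meta.csv next to `path`).
#' @return the matrix path, invisibly.
#' @export
write_covariates_csv <- function(covariates, path,
                                 meta_path = file.path(dirname(path),
                                                       "variable_meta.csv")) {
  df <- data.frame(unit_id = rownames(covariates$values),
                   covariates$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  data.table::fwrite(df, path)
  meta <- covariates$meta
  meta$expected_sign <- c("-", "0", "+")[meta$expected_sign + 2]
  data.table::fwrite(meta, meta_path)
  invisible(path)
}

#' Read a covariate matrix written by [write_covariates_csv()]
#' @param path matrix CSV path.
#' @param meta_path metadata CSV path.
#' @return a `lurok_covariates` object.
#' @export
read_covariates_csv <- function(path,
                                meta_path = file.path(dirname(path),
                                                      "variable_meta.csv")) {
  df <- as.data.frame(data.table::fread(path))
  vals <- as.matrix(df[, -1, drop = FALSE])
  rownames(vals) <- df[[1]]
  meta <- as.data.frame(data.table::fread(meta_path,
                                          colClasses = list(character =
                                                              "expected_sign")))
  meta$expected_sign <- match(meta$expected_sign, c("-", "0", "+")) - 2L
  structure(list(values = vals, meta = meta), class = "lurok_covariates")
}

#' Write the population grid
#' @param grid a [generate_population_grid()] data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_grid_csv <- function(grid, path) {
  data.table::fwrite(grid, path)
  invisible(path)
}

#' Export point features as GeoJSON
#'
#' Writes a FeatureCollection of Point features; every non-coordinate
#' column becomes a feature property.
#'
#' @param df a data.frame with `x` and `y` columns.
#' @param path output .geojson path.
#' @return the path, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  stopifnot(all(c("x", "y") %in% names(df)))
  props <- setdiff(names(df), c("x", "y"))
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df$x[i], df$y[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write an aggregate table (any temporal level)
#' @param agg an aggregate data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_aggregates_csv <- function(agg, path) {
  data.table::fwrite(agg, path)
  invisible(path)
}
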