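# configuration and geo-interchange I/O

read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop_cfg("reading YAML configs requires the 'yaml' package")
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Read a simulation configuration from YAML or JSON
#'
#' File fields mirror the arguments of \code{\link{simulation_config}};
#' \code{call_rate_per_day} must be a number or per-day vector in a file
#' (functions are only available programmatically), and mixture components
#' are given as parallel \code{weight}/\code{min}/\code{max} arrays.
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file.
#' @return a \code{\link{simulation_config}}.
#' @export
read_simulation_config <- function(path) {
  raw <- read_config_file(path)
  if (!is.null(raw$offshore_distribution$components))
    raw$offshore_distribution$components <-
      as.data.frame(raw$offshore_distribution$components)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_cfg("unknown simulation config fields: %s",
             paste(unknown, collapse = ", "))
  do.call(simulation_config, raw)
}

#' Read a survey geometry from YAML or JSON
#'
#' @param path path to a \code{.yaml}/\code{.yml} or \code{.json} file whose
#'   fields mirror the arguments of \code{\link{survey_geometry}}.
#' @return a \code{\link{survey_geometry}}.
#' @export
read_survey_geometry <- function(path) {
  raw <- read_config_file(path)
  if (!is.null(raw$hydrophone_positions))
    raw$hydrophone_positions <- matrix(unlist(raw$hydrophone_positions),
                                       ncol = 2, byrow = TRUE)
  known <- names(formals(survey_geometry))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop_cfg("unknown geometry fields: %s", paste(unknown, collapse = ", "))
  do.call(survey_geometry, raw)
}

#' Write point records as GeoJSON
#'
#' Exports a data.frame of georeferenced records (detections, sightings) as
#' a GeoJSON FeatureCollection of points; all non-coordinate columns become
#' feature properties.
#'
#' @param df data.frame with latitude/longitude columns.
#' @param path output file path.
#' @param lat_col,lon_col coordinate column names.
#' @return invisibly, the path.
#' @export
write_points_geojson <- function(df, path, lat_col = "lat",
                                 lon_col = "lon") {
  if (!all(c(lat_col, lon_col) %in% names(df)))
    stop_cfg("columns '%s' and '%s' are required", lat_col, lon_col)
  props <- df[, setdiff(names(df), c(lat_col, lon_col)), drop = FALSE]
  features <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(df[[lon_col]][i], df[[lat_col]][i])),
         properties = as.list(props[i, , drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
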