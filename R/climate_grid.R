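#' Construct a century-resolution climate grid set
#'
#' Container for gridded per-century terrestrial climate: mean annual
#' temperature (degC), mean annual precipitation (mm/yr), and the spatial
#' SDs of each. All centuries share one grid geometry; values are stored
#' as `nlon x nlat x ncenturies` arrays. Centuries are identified by their
#' midpoint in cal BP, ascending.
#'
#' @param lon,lat cell-center coordinate vectors (decimal degrees,
#'   ascending).
#' @param centuries century midpoints in cal BP, ascending.
#' @param vars named list of arrays `(nlon, nlat, ncenturies)`; names must
#'   include `mean_temperature`, `mean_precipitation`, `sd_temperature`,
#'   `sd_precipitation`.
#' @return object of class `climate_grid_set`.
#' @export
climate_grid_set <- function(lon, lat, centuries, vars) {
  need <- c("mean_temperature", "mean_precipitation",
            "sd_temperature", "sd_precipitation")
  if (!all(need %in% names(vars))) {
    stop_ctx("missing climate variables: ",
             paste(setdiff(need, names(vars)), collapse = ", "),
             class = "grid_error")
  }
  dims <- c(length(lon), length(lat), length(centuries))
  for (v in names(vars)) {
    if (!identical(dim(vars[[v]]), as.integer(dims))) {
      stop_ctx("variable ", v, " has wrong dimensions", class = "grid_error")
    }
  }
  if (is.unsorted(centuries, strictly = TRUE)) {
    stop_ctx("centuries must be strictly ascending", class = "grid_error")
  }
  structure(list(lon = lon, lat = lat, centuries = centuries, vars = vars),
            class = "climate_grid_set")
}

#' @export
print.climate_grid_set <- function(x, ...) {
  cat(sprintf("<climate_grid_set: %dx%d cells, %d centuries (%g-%g cal BP)>\n",
              length(x$lon), length(x$lat), length(x$centuries),
              min(x$centuries), max(x$centuries)))
  invisible(x)
}

#' Serialize a climate grid set to long-format CSV
#'
#' One row per (century, cell) with the four climate variables as columns.
#' Plain-text stand-in for raster formats; [read_climate_csv()] inverts it.
#'
#' @param grid_set a `climate_grid_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_climate_csv <- function(grid_set, path) {
  g <- expand.grid(lon = grid_set$lon, lat = grid_set$lat,
                   century = grid_set$centuries)
  df <- data.frame(century = g$century, lon = g$lon, lat = g$lat)
  for (v in names(grid_set$vars)) df[[v]] <- as.vector(grid_set$vars[[v]])
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_climate_csv
#' @export
read_climate_csv <- function(path) {
  df <- read.csv(path)
  lon <- sort(unique(df$lon))
  lat <- sort(unique(df$lat))
  centuries <- sort(unique(df$century))
  o <- order(df$century, df$lat, df$lon)
  df <- df[o, ]
  dims <- c(length(lon), length(lat), length(centuries))
  vars <- list()
  for (v in setdiff(names(df), c("century", "lon", "lat"))) {
    vars[[v]] <- array(df[[v]], dim = dims)
  }
  climate_grid_set(lon, lat, centuries, vars)
}
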