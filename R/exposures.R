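#' Classify a site or individual as coastal or inland
#'
#' The coastal zone is defined as less than 15 km from the coast AND under
#' 500 m above sea level; everything else (further inland or higher) is
#' inland. Both inequalities are strict, so a site at exactly 15 km or
#' exactly 500 masl is inland.
#'
#' @param distance_to_coast distance in km (nonnegative).
#' @param elevation elevation in masl (nonnegative).
#' @return character vector, `"coast"` or `"inland"`.
#' @export
#' @examples
#' classify_region(10, 300)   # coast
#' classify_region(15, 499)   # inland (boundary is strict)
classify_region <- function(distance_to_coast, elevation) {
  if (anyNA(distance_to_coast) || anyNA(elevation)) {
    stop_ctx("missing distance or elevation", class = "classification_error")
  }
  ifelse(distance_to_coast < 15 & elevation < 500, "coast", "inland")
}

#' Mean of a gridded climate variable within a great-circle buffer
#'
#' Arithmetic mean over all cells whose centers lie within `radius_km`
#' (haversine) of the location, for one century layer. This captures the
#' locally accessed area around a site rather than a single cell.
#'
#' @param grid_set a `climate_grid_set`.
#' @param lon,lat location, decimal degrees.
#' @param radius_km buffer radius in km (default 20).
#' @param century century midpoint (cal BP) identifying the layer; the
#'   nearest stored century is used.
#' @param variable variable name in `grid_set$vars`.
#' @return scalar mean value.
#' @export
buffer_mean <- function(grid_set, lon, lat, radius_km = 20, century,
                        variable) {
  idx <- buffer_cells(grid_set, lon, lat, radius_km)
  if (length(idx$i) == 0L) {
    stop_ctx("no grid cells within ", radius_km, " km of (", lon, ", ",
             lat, ")", class = "coverage_error")
  }
  k <- which.min(abs(grid_set$centuries - century))
  v <- grid_set$vars[[variable]]
  if (is.null(v)) stop_ctx("unknown variable ", variable, class = "grid_error")
  mean(v[cbind(idx$i, idx$j, k)])
}

# Cell centers within radius; returns parallel index vectors (i = lon, j = lat).
buffer_cells <- function(grid_set, lon, lat, radius_km) {
  # cheap bounding box first, exact haversine second
  dlat <- radius_km / 111.2
  dlon <- radius_km / (111.2 * cos(lat * pi / 180))
  ii <- which(abs(grid_set$lon - lon) <= dlon * 1.05)
  jj <- which(abs(grid_set$lat - lat) <= dlat * 1.05)
  if (!length(ii) || !length(jj)) return(list(i = integer(0), j = integer(0)))
  g <- expand.grid(i = ii, j = jj)
  d <- gc_distance_km(grid_set$lon[g$i], grid_set$lat[g$j], lon, lat)
  keep <- d <= radius_km
  list(i = g$i[keep], j = g$j[keep])
}

# Centuries whose 100-yr interval overlaps the window [end, start] (cal BP).
window_centuries <- function(centuries, window_start, window_end) {
  step <- if (length(centuries) > 1) min(diff(centuries)) else 100
  which(centuries + step / 2 >= window_end &
          centuries - step / 2 <= window_start)
}

#' Monte-Carlo climate draws for one individual
#'
#' Builds the candidate set of buffer-mean climate conditions (all four
#' terrestrial variables jointly) for every century overlapping the
#' individual's time window, then samples candidate centuries uniformly
#' with replacement. Joint sampling of a century index preserves the
#' within-century covariance between variables.
#'
#' @param individual one-row data.frame with `lon`, `lat`,
#'   `window_start`, `window_end`.
#' @param grid_set a `climate_grid_set`.
#' @param n number of draws (default 1000).
#' @param radius_km buffer radius (default 20).
#' @return matrix `n x 4` with the four terrestrial variables as columns.
#' @export
draw_climate <- function(individual, grid_set, n = 1000, radius_km = 20) {
  ks <- window_centuries(grid_set$centuries, individual$window_start,
                         individual$window_end)
  if (!length(ks)) {
    stop_ctx("individual window does not overlap climate centuries",
             class = "coverage_error")
  }
  vars <- c("mean_temperature", "mean_precipitation",
            "sd_temperature", "sd_precipitation")
  cand <- matrix(NA_real_, length(ks), 4, dimnames = list(NULL, vars))
  for (a in seq_along(ks)) {
    for (v in vars) {
      cand[a, v] <- buffer_mean(grid_set, individual$lon, individual$lat,
                                radius_km, grid_set$centuries[ks[a]], v)
    }
  }
  cand[sample.int(nrow(cand), n, replace = TRUE), , drop = FALSE]
}

#' Nearest SST core for a coastal individual
#'
#' @param individual one-row data.frame with `lon`, `lat`, `region`.
#' @param cores list of core records (`core_id`, `lon`, `lat`, ...).
#' @return the `core_id` of the great-circle-nearest core; ties broken by
#'   the smallest `core_id`.
#' @export
assign_sst_core <- function(individual, cores) {
  if (!identical(individual$region, "coast")) {
    stop_ctx("SST applies to coastal individuals only",
             class = "not_applicable_error")
  }
  if (!length(cores)) stop_ctx("no SST cores", class = "coverage_error")
  d <- gc_distance_km(individual$lon, individual$lat,
                      vapply(cores, `[[`, 0, "lon"),
                      vapply(cores, `[[`, 0, "lat"))
  ids <- vapply(cores, `[[`, "", "core_id")
  cand <- ids[d == min(d)]
  sort(cand)[1]
}

#' Monte-Carlo draws from a century series within a time window
#'
#' Uniform with-replacement resampling of the series values whose
#' centuries overlap the individual's window. Used for SST cores and the
#' ENSO events-per-century series.
#'
#' @param series a list with `centuries` (ascending cal BP) and `values`.
#' @param window_start,window_end window in cal BP (`start >= end`).
#' @param n number of draws.
#' @return numeric vector of length `n`.
#' @export
draw_series <- function(series, window_start, window_end, n = 1000) {
  ks <- window_centuries(series$centuries, window_start, window_end)
  if (!length(ks)) {
    stop_ctx("window does not overlap series", class = "coverage_error")
  }
  series$values[ks][sample.int(length(ks), n, replace = TRUE)]
}

#' Monte-Carlo relative-population draws for one individual
#'
#' Each draw selects one KDE replicate uniformly, one grid year uniformly
#' from the individual's window, and records that replicate's density at
#' that year — propagating both the bootstrap uncertainty of the
#' population proxy and the individual's temporal uncertainty.
#'
#' @param window_start,window_end window in cal BP.
#' @param kdes a `pop_kde_set` for the individual's region.
#' @param n number of draws.
#' @return numeric vector of length `n` of relative-density values.
#' @export
draw_population <- function(window_start, window_end, kdes, n = 1000) {
  g <- kdes$grid
  sel <- which(g >= window_end & g <= window_start)
  if (!length(sel)) {
    stop_ctx("window outside population-KDE grid", class = "coverage_error")
  }
  reps <- sample.int(nrow(kdes$density), n, replace = TRUE)
  yrs <- sel[sample.int(length(sel), n, replace = TRUE)]
  kdes$density[cbind(reps, yrs)]
}

#' Build the full exposure-draw set for a table of individuals
#'
#' Attaches to every individual `n_draws` Monte-Carlo draws of the
#' climatic (four terrestrial variables, joint century sampling), oceanic
#' (nearest-core SST for coastal individuals, single-core ENSO frequency),
#' and demographic (regional population KDE) conditions they may have
#' experienced. Climate, SST, ENSO and population draws are mutually
#' independent across sources within a draw index.
#'
#' @param individuals data.frame in the `individuals.csv` schema.
#' @param grid_set a `climate_grid_set`.
#' @param sst_cores list of SST core records.
#' @param enso ENSO event series (list with `centuries`, `values`).
#' @param kdes named list: `coast` and `inland` `pop_kde_set`s.
#' @param n_draws draws per individual (default 1000).
#' @param radius_km buffer radius for climate extraction (default 20).
#' @param seed integer seed.
#' @return object of class `exposure_draws`: `individuals`, `n_draws`,
#'   and `draws`, a named list of `n_individuals x n_draws` matrices (SST
#'   rows are `NA` for inland individuals).
#' @export
build_exposures <- function(individuals, grid_set, sst_cores, enso, kdes,
                            n_draws = 1000, radius_km = 20, seed = 1L) {
  set.seed(seed)
  n <- nrow(individuals)
  vars <- c("mean_temperature", "mean_precipitation", "sd_temperature",
            "sd_precipitation", "sst", "enso_frequency", "population")
  draws <- lapply(vars, function(v) matrix(NA_real_, n, n_draws))
  names(draws) <- vars

  # candidate climate tables cached per (site, century-set); individuals
  # at one site share coordinates, so cache by site_id
  clim_cache <- new.env(parent = emptyenv())
  cvars <- vars[1:4]
  for (i in seq_len(n)) {
    ind <- individuals[i, ]
    ks <- window_centuries(grid_set$centuries, ind$window_start,
                           ind$window_end)
    if (!length(ks)) {
      stop_ctx("individual ", ind$id,
               ": window does not overlap climate centuries",
               class = "coverage_error")
    }
    key <- paste0(ind$site_id, "|", ks[1], "-", ks[length(ks)])
    cand <- clim_cache[[key]]
    if (is.null(cand)) {
      cand <- matrix(NA_real_, length(ks), 4, dimnames = list(NULL, cvars))
      for (a in seq_along(ks)) {
        for (v in cvars) {
          cand[a, v] <- buffer_mean(grid_set, ind$lon, ind$lat, radius_km,
                                    grid_set$centuries[ks[a]], v)
        }
      }
      clim_cache[[key]] <- cand
    }
    pick <- sample.int(nrow(cand), n_draws, replace = TRUE)
    for (v in cvars) draws[[v]][i, ] <- cand[pick, v]

    draws$enso_frequency[i, ] <- draw_series(enso, ind$window_start,
                                             ind$window_end, n_draws)
    if (identical(ind$region, "coast")) {
      cid <- assign_sst_core(ind, sst_cores)
      core <- sst_cores[[which(vapply(sst_cores, `[[`, "", "core_id") == cid)]]
      draws$sst[i, ] <- draw_series(core, ind$window_start, ind$window_end,
                                    n_draws)
    }
    draws$population[i, ] <- draw_population(ind$window_start,
                                             ind$window_end,
                                             kdes[[ind$region]], n_draws)
  }
  structure(list(individuals = individuals, n_draws = n_draws,
                 draws = draws),
            class = "exposure_draws")
}

#' @export
print.exposure_draws <- function(x, ...) {
  cat(sprintf("<exposure_draws: %d individuals x %d draws x %d variables>\n",
              nrow(x$individuals), x$n_draws, length(x$draws)))
  invisible(x)
}

#' Per-individual mean exposures across draws
#'
#' @param x an `exposure_draws`.
#' @return data.frame of draw means, one row per individual (SST `NA`
#'   inland), plus the fixed `complexity` covariate.
#' @export
exposure_means <- function(x) {
  out <- as.data.frame(lapply(x$draws, rowMeans))
  out$complexity <- x$individuals$complexity
  out
}

#' Write exposure draws as a long-format CSV
#'
#' One row per (individual, draw index) with the draw variables as
#' columns — large but plain-text and tool-friendly.
#'
#' @param x an `exposure_draws`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_exposures_csv <- function(x, path) {
  n <- nrow(x$individuals)
  df <- data.frame(
    individual_id = rep(x$individuals$id, times = x$n_draws),
    draw_index = rep(seq_len(x$n_draws), each = n))
  for (v in names(x$draws)) df[[v]] <- as.vector(x$draws[[v]])
  df$complexity <- rep(x$individuals$complexity, times = x$n_draws)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Extract the draw-`i` predictor table
#'
#' Run `i` of the ensemble uses draw index `i` for every individual; this
#' returns that slice plus the fixed complexity covariate.
#'
#' @param x an `exposure_draws`.
#' @param i draw index in `1..n_draws`.
#' @param variables which draw variables to include (default all).
#' @return data.frame, one row per individual.
#' @export
exposure_slice <- function(x, i, variables = names(x$draws)) {
  stopifnot(i >= 1, i <= x$n_draws)
  out <- as.data.frame(lapply(x$draws[variables], function(m) m[, i]))
  out$complexity <- x$individuals$complexity
  out
}
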