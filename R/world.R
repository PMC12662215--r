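#' Configuration for the synthetic study world
#'
#' The generator's defaults describe a study system of the scale of the
#' real Central Andean compilation: 116 sites, 7983 adult individuals
#' (about 44% coastal), a few thousand radiocarbon dates, and a Holocene
#' time span at century resolution. The trauma model is logistic on
#' standardized true exposures with one quadratic population term and one
#' climate-by-population interaction, so downstream inference has a known
#' ground truth. Tests and examples scale `n_sites` / `n_individuals`
#' down; the defaults are the stated world, not a tuning surface.
#'
#' @param seed integer seed; all world randomness derives from it.
#' @param n_sites number of sites.
#' @param n_individuals number of adult individuals.
#' @param n_dates number of radiocarbon dates.
#' @param time_span `c(oldest, youngest)` cal BP, oldest > youngest >= 0.
#' @param grid_extent list with `lon = c(min, max)`, `lat = c(min, max)`,
#'   `cell_deg` (cell size in degrees).
#' @param century_step years per climate century (default 100).
#' @param trauma_coefficients named numeric vector of log-odds-of-trauma
#'   coefficients on standardized exposures: `intercept`, linear terms
#'   (`mean_temperature`, `mean_precipitation`, `sd_temperature`, `sst`,
#'   `enso_frequency`, `population`, `complexity`), `population_sq`
#'   (coefficient on z^2 - 1), and `temp_x_population` (interaction).
#' @param coastal_fraction proportion of sites on the coast, in \[0, 1\].
#' @return object of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_sites = 116L,
                         n_individuals = 7983L,
                         n_dates = 3000L,
                         time_span = c(11500, 0),
                         grid_extent = list(lon = c(-76, -73),
                                            lat = c(-16, -12),
                                            cell_deg = 0.05),
                         century_step = 100,
                         trauma_coefficients = c(
                           intercept = -1.55,
                           mean_temperature = -0.4,
                           mean_precipitation = 0.3,
                           sd_temperature = 0.3,
                           sst = -0.2,
                           enso_frequency = 0.2,
                           population = 0.25,
                           population_sq = 0.45,
                           complexity = 0.1,
                           temp_x_population = 0.2),
                         coastal_fraction = 0.44) {
  cfg <- list(seed = as.integer(seed), n_sites = as.integer(n_sites),
              n_individuals = as.integer(n_individuals),
              n_dates = as.integer(n_dates), time_span = time_span,
              grid_extent = grid_extent, century_step = century_step,
              trauma_coefficients = trauma_coefficients,
              coastal_fraction = coastal_fraction)
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  if (!(cfg$time_span[1] > cfg$time_span[2] && cfg$time_span[2] >= 0)) {
    stop_ctx("time_span must be (oldest, youngest) with oldest > youngest >= 0",
             class = "config_error")
  }
  if (cfg$n_sites <= 0 || cfg$n_individuals <= 0 || cfg$n_dates < 0) {
    stop_ctx("counts must be positive (n_dates may be 0)",
             class = "config_error")
  }
  if (cfg$coastal_fraction < 0 || cfg$coastal_fraction > 1) {
    stop_ctx("coastal_fraction must be in [0, 1]", class = "config_error")
  }
  ex <- cfg$grid_extent
  if (ex$lon[1] >= ex$lon[2] || ex$lat[1] >= ex$lat[2] || ex$cell_deg <= 0) {
    stop_ctx("invalid grid extent", class = "config_error")
  }
  invisible(cfg)
}

#' Synthetic calibration curve in the atmospheric / marine layout
#'
#' A strictly increasing calendar-to-14C mapping with realistic
#' centennial- and decadal-scale wiggles, plus a smooth curve error term.
#' This is a stand-in with the structure of a real curve, not a real
#' curve; the marine variant adds a global reservoir-like offset and
#' smoother wiggles.
#'
#' @param kind `"atmospheric"` or `"marine"`.
#' @param span `c(min, max)` cal BP covered.
#' @param step knot spacing in years.
#' @return a `cal_curve`.
#' @export
synthetic_curve <- function(kind = c("atmospheric", "marine"),
                            span = c(0, 12500), step = 20) {
  kind <- match.arg(kind)
  t <- seq(span[1], span[2], by = step)
  if (kind == "atmospheric") {
    c14 <- 0.95 * t + 150 * sin(t / 800) + 80 * sin(t / 180)
    sig <- 12 + 4 * sin(t / 1000) + 2 * sin(t / 150)
  } else {
    c14 <- 0.95 * t + 400 + 100 * sin(t / 900)
    sig <- 18 + 5 * sin(t / 1100)
  }
  new_cal_curve(paste0("synthetic_", kind), t, c14, sig)
}

# Evaluate curve 14C mean and error at arbitrary calendar years.
curve_at <- function(curve, t) {
  list(mu = approx(curve$cal_bp, curve$c14_age, t)$y,
       sigma = approx(curve$cal_bp, curve$sigma, t)$y)
}

#' Build the synthetic climate grid set
#'
#' Smooth spatial gradients plus a spatially coherent century-scale AR(1)
#' anomaly. SD fields are tied to the mean fields so the collinearity
#' structure of real reconstructions is reproduced: SD precipitation is
#' strongly positively correlated with mean precipitation, and SD
#' temperature negatively with mean temperature.
#'
#' @param extent grid extent list (as in [world_config()]).
#' @param centuries century midpoints, ascending cal BP.
#' @param seed integer seed.
#' @return a `climate_grid_set`.
#' @export
build_synthetic_climate <- function(extent, centuries, seed = 1L) {
  set.seed(seed)
  half <- extent$cell_deg / 2
  lon <- seq(extent$lon[1] + half, extent$lon[2] - half, by = extent$cell_deg)
  lat <- seq(extent$lat[1] + half, extent$lat[2] - half, by = extent$cell_deg)
  nc <- length(centuries)
  ar1 <- function(n, rho, sd_innov) {
    x <- numeric(n)
    x[1] <- rnorm(1, 0, sd_innov / sqrt(1 - rho^2))
    for (i in seq_len(n - 1)) x[i + 1] <- rho * x[i] + rnorm(1, 0, sd_innov)
    x
  }
  t_anom <- ar1(nc, 0.8, 0.5)           # degC, shared over space
  p_anom <- ar1(nc, 0.8, 0.10)          # log-scale precip anomaly
  lonm <- outer(lon, rep(1, length(lat)))
  latm <- outer(rep(1, length(lon)), lat)
  t_spat <- 24 + 1.6 * (latm - mean(lat)) - 1.0 * (lonm - mean(lon)) +
    0.8 * sin(2 * pi * lonm / 1.5) * cos(2 * pi * latm / 2)
  p_spat <- log(350) + 0.35 * (latm - mean(lat)) +
    0.4 * (lonm - mean(lon)) + 0.08 * sin(2 * pi * latm / 3)
  dims <- c(length(lon), length(lat), nc)
  mt <- array(0, dims); mp <- array(0, dims)
  for (k in seq_len(nc)) {
    mt[, , k] <- t_spat + t_anom[k] +
      matrix(rnorm(length(lonm), 0, 0.1), nrow(lonm))
    mp[, , k] <- exp(p_spat + p_anom[k] +
                       matrix(rnorm(length(lonm), 0, 0.01), nrow(lonm)))
  }
  # SD fields proportional to / anti-tied to means, with small noise
  st <- 2.8 - 0.07 * mt + array(rnorm(length(mt), 0, 0.05), dims)
  st[st < 0.05] <- 0.05
  sp <- 0.30 * mp * (1 + array(rnorm(length(mp), 0, 0.04), dims))
  climate_grid_set(lon, lat, centuries,
                   list(mean_temperature = mt, mean_precipitation = mp,
                        sd_temperature = st, sd_precipitation = sp))
}

# Occupation density per site: mixture of 1-3 Gaussians over the span.
sample_occupation <- function(n, occ, span) {
  if (n == 0L) return(numeric(0))
  out <- numeric(0)
  while (length(out) < n) {
    k <- sample.int(length(occ$w), n, replace = TRUE, prob = occ$w)
    y <- rnorm(n, occ$mu[k], occ$sd[k])
    out <- c(out, y[y <= span[1] & y >= span[2]])
  }
  out[seq_len(n)]
}

occupation_density <- function(occ, t) {
  d <- numeric(length(t))
  for (k in seq_along(occ$w)) {
    d <- d + occ$w[k] * dnorm(t, occ$mu[k], occ$sd[k])
  }
  d
}

#' Generate a complete synthetic study world
#'
#' Builds sites, gridded climate, SST cores, an ENSO event series,
#' radiocarbon dates with known true calendar years, and adult individuals
#' whose craniofacial-trauma outcome is drawn from a logistic model on
#' their standardized true exposures (see [world_config()]). Everything is
#' reproducible from `config$seed`, and the true exposures and
#' probabilities are retained so downstream stages can be validated
#' against ground truth.
#'
#' @param config a `world_config`.
#' @return object of class `synthetic_world` with elements `config`,
#'   `sites`, `climate`, `sst_cores`, `enso`, `curves`, `dates`,
#'   `individuals`, `site_occupations`, `true_exposures`,
#'   `true_trauma_probability`.
#' @export
generate_world <- function(config) {
  stopifnot(inherits(config, "world_config"))
  validate_world_config(config)
  span <- config$time_span
  ex <- config$grid_extent
  set.seed(derive_seed(config$seed, "world"))

  # --- sites ---------------------------------------------------------
  n_coast <- round(config$coastal_fraction * config$n_sites)
  is_coast <- seq_len(config$n_sites) <= n_coast
  margin <- 0.25  # keep 20-km buffers inside the grid
  sites <- data.frame(
    site_id = sprintf("S%03d", seq_len(config$n_sites)),
    lon = runif(config$n_sites, ex$lon[1] + margin, ex$lon[2] - margin),
    lat = runif(config$n_sites, ex$lat[1] + margin, ex$lat[2] - margin),
    elevation = ifelse(is_coast, runif(config$n_sites, 5, 450),
                       runif(config$n_sites, 600, 4200)),
    distance_to_coast = ifelse(is_coast, runif(config$n_sites, 0.5, 12),
                               runif(config$n_sites, 20, 300))
  )
  sites$region <- classify_region(sites$distance_to_coast, sites$elevation)

  # Regional occupation "master" densities: a few broad demographic booms
  # plus a uniform background. Site occupation phases cluster inside the
  # booms, so the regional dates-as-data signal is shared across sites —
  # the regime in which a binned CKDE proxy is informative.
  masters <- lapply(c(coast = 1, inland = 2), function(dummy) {
    K <- 3
    w <- runif(K); w <- 0.9 * w / sum(w)
    list(w = w,
         mu = runif(K, span[2] + 0.1 * diff(rev(span)),
                    span[1] - 0.1 * diff(rev(span))),
         sd = runif(K, 400, 800), background = 0.1)
  })
  rmaster <- function(m, n) {
    comp <- sample.int(length(m$w) + 1L, n, replace = TRUE,
                       prob = c(m$w, m$background))
    bg <- comp > length(m$w)
    out <- numeric(n)
    out[bg] <- runif(sum(bg), span[2], span[1])
    out[!bg] <- rnorm(sum(!bg), m$mu[comp[!bg]], m$sd[comp[!bg]])
    out
  }
  # occupation histories: 1-3 Gaussian phases per site, centered on years
  # drawn from the site's regional master
  occs <- lapply(seq_len(config$n_sites), function(i) {
    k <- sample.int(3, 1)
    w <- runif(k); w <- w / sum(w)
    mu <- rmaster(masters[[sites$region[i]]], k)
    list(w = w,
         mu = pmin(pmax(mu, span[2] + 300), span[1] - 300),
         sd = runif(k, 150, 400))
  })
  names(occs) <- sites$site_id
  # moderately heavy-tailed site sizes: big centers dominate without one
  # site swamping a region (real compilations look like this)
  site_weight <- stats::rgamma(config$n_sites, shape = 2, rate = 1) + 0.1
  site_weight <- site_weight / sum(site_weight)

  # --- climate, cores, ENSO -----------------------------------------
  centuries <- seq(span[2] + config$century_step / 2, span[1],
                   by = config$century_step)
  climate <- build_synthetic_climate(ex, centuries,
                                     seed = derive_seed(config$seed, "climate"))
  core_lat <- c(-4.5, -11, -15, -17.3)
  sst_cores <- lapply(seq_along(core_lat), function(i) {
    x <- numeric(length(centuries))
    x[1] <- rnorm(1, 0, 0.8)
    for (k in seq_len(length(centuries) - 1)) {
      x[k + 1] <- 0.85 * x[k] + rnorm(1, 0, 0.4)
    }
    list(core_id = sprintf("CORE%d", i), lon = ex$lon[1] - 1,
         lat = core_lat[i],
         centuries = centuries,
         values = 19 + 0.25 * (core_lat[i] + 11) + x)
  })
  # events-per-century reconstruction: slow forcing + Poisson event noise,
  # smoothed as a sediment-derived series would be
  enso_lambda <- 16 + 12 * sin(2 * pi * centuries / 4000) +
    6 * (1 - centuries / max(centuries))
  enso_raw <- stats::rpois(length(centuries), pmax(enso_lambda, 0.5))
  enso_sm <- as.numeric(stats::filter(enso_raw, rep(1 / 5, 5), sides = 2))
  enso_sm[is.na(enso_sm)] <- enso_raw[is.na(enso_sm)]
  enso <- list(core_id = "ENSO1", lon = ex$lon[2] + 2, lat = -2,
               centuries = centuries, values = round(enso_sm, 1))

  curves <- list(atmospheric = synthetic_curve("atmospheric",
                                               span = c(0, span[1] + 1000)),
                 marine = synthetic_curve("marine",
                                          span = c(0, span[1] + 1000)))

  # --- individuals ---------------------------------------------------
  ind_site <- sample.int(config$n_sites, config$n_individuals,
                         replace = TRUE, prob = site_weight)
  true_year <- numeric(config$n_individuals)
  for (i in seq_len(config$n_sites)) {
    sel <- which(ind_site == i)
    true_year[sel] <- sample_occupation(length(sel), occs[[i]], span)
  }
  width <- sample(c(100, 200, 300, 400, 500), config$n_individuals,
                  replace = TRUE, prob = c(0.25, 0.3, 0.2, 0.15, 0.1))
  w_start <- pmin(true_year + width / 2, span[1])
  w_end <- pmax(w_start - width, span[2])
  w_start <- w_end + width
  complexity <- ifelse(true_year > 1500, 0L, ifelse(true_year > 550, 1L, 2L))
  individuals <- data.frame(
    id = sprintf("I%05d", seq_len(config$n_individuals)),
    site_id = sites$site_id[ind_site],
    lon = sites$lon[ind_site], lat = sites$lat[ind_site],
    elevation = sites$elevation[ind_site],
    distance_to_coast = sites$distance_to_coast[ind_site],
    window_start = w_start, window_end = w_end,
    complexity = complexity,
    region = sites$region[ind_site],
    stringsAsFactors = FALSE
  )

  # --- true exposures ------------------------------------------------
  cent_idx <- pmin(pmax(findInterval(true_year, centuries -
                                       config$century_step / 2), 1L),
                   length(centuries))
  expo <- matrix(NA_real_, config$n_individuals, 7,
                 dimnames = list(NULL, c("mean_temperature",
                                         "mean_precipitation",
                                         "sd_temperature", "sd_precipitation",
                                         "sst", "enso_frequency",
                                         "population")))
  for (i in seq_len(config$n_sites)) {
    sel <- which(ind_site == i)
    if (!length(sel)) next
    for (k in unique(cent_idx[sel])) {
      ssel <- sel[cent_idx[sel] == k]
      for (v in c("mean_temperature", "mean_precipitation",
                  "sd_temperature", "sd_precipitation")) {
        expo[ssel, v] <- buffer_mean(climate, sites$lon[i], sites$lat[i],
                                     radius_km = 20,
                                     century = centuries[k], variable = v)
      }
    }
  }
  # regional true population intensity: the size-weighted mixture of site
  # occupations — the same intensity that generates the radiocarbon dates
  # ("more people produce more dateable material")
  for (reg in c("coast", "inland")) {
    sel <- which(individuals$region == reg)
    if (!length(sel)) next
    in_reg <- which(sites$region == reg)
    wreg <- site_weight[in_reg] / sum(site_weight[in_reg])
    dens <- numeric(length(sel))
    for (j in seq_along(in_reg)) {
      dens <- dens + wreg[j] * occupation_density(occs[[in_reg[j]]],
                                                  true_year[sel])
    }
    expo[sel, "population"] <- dens
  }
  expo[, "enso_frequency"] <- enso$values[cent_idx]
  coast_sel <- which(individuals$region == "coast")
  if (length(coast_sel)) {
    core_of_site <- vapply(seq_len(config$n_sites), function(i) {
      which.min(gc_distance_km(sites$lon[i], sites$lat[i],
                               vapply(sst_cores, `[[`, 0, "lon"),
                               vapply(sst_cores, `[[`, 0, "lat")))
    }, integer(1))
    expo[coast_sel, "sst"] <- vapply(coast_sel, function(j) {
      sst_cores[[core_of_site[ind_site[j]]]]$values[cent_idx[j]]
    }, numeric(1))
  }

  # --- trauma model --------------------------------------------------
  zs <- function(x) {
    s <- sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) return(rep(0, length(x)))
    z <- (x - mean(x, na.rm = TRUE)) / s
    z[is.na(z)] <- 0   # SST for inland individuals contributes nothing
    z
  }
  co <- config$trauma_coefficients
  z_temp <- zs(expo[, "mean_temperature"])
  z_pop <- zs(expo[, "population"])
  eta <- co[["intercept"]] +
    co[["mean_temperature"]] * z_temp +
    co[["mean_precipitation"]] * zs(expo[, "mean_precipitation"]) +
    co[["sd_temperature"]] * zs(expo[, "sd_temperature"]) +
    co[["sst"]] * zs(expo[, "sst"]) +
    co[["enso_frequency"]] * zs(expo[, "enso_frequency"]) +
    co[["population"]] * z_pop +
    co[["population_sq"]] * (z_pop^2 - 1) +
    co[["complexity"]] * zs(individuals$complexity) +
    co[["temp_x_population"]] * z_temp * z_pop
  p_trauma <- 1 / (1 + exp(-eta))
  individuals$trauma <- rbinom(config$n_individuals, 1L, p_trauma)
  individuals$true_year <- true_year

  world <- structure(list(
    config = config, sites = sites, climate = climate,
    sst_cores = sst_cores, enso = enso, curves = curves,
    individuals = individuals, site_occupations = occs,
    region_masters = masters,
    site_weight = site_weight,
    true_exposures = expo,
    true_trauma_probability = p_trauma
  ), class = "synthetic_world")
  world$dates <- generate_dates(world, config)
  world
}

#' Generate synthetic radiocarbon dates for a world
#'
#' Dates are allocated to sites with the same heavy-tailed weights as
#' individuals, a true calendar year is drawn from each site's occupation
#' density, mapped through the appropriate synthetic curve (atmospheric or
#' marine, the latter with a reservoir offset), and Gaussian lab error is
#' added. True years are retained for round-trip testing.
#'
#' @param world a `synthetic_world` (sites, occupations, curves present).
#' @param config the `world_config` (uses `n_dates`, `time_span`, `seed`).
#' @return data.frame of dates: `lab_id`, `site_id`, `c14_age`, `error`,
#'   `material`, `delta_r`, `region`, `true_year`.
#' @export
generate_dates <- function(world, config = world$config) {
  n <- config$n_dates
  if (n == 0L) {
    return(data.frame(lab_id = character(0), site_id = character(0),
                      c14_age = numeric(0), error = numeric(0),
                      material = character(0), delta_r = numeric(0),
                      region = character(0), true_year = numeric(0)))
  }
  set.seed(derive_seed(config$seed, "dates"))
  span <- config$time_span
  site_idx <- sample.int(nrow(world$sites), n, replace = TRUE,
                         prob = world$site_weight)
  true_year <- numeric(n)
  for (i in unique(site_idx)) {
    sel <- which(site_idx == i)
    true_year[sel] <- sample_occupation(length(sel),
                                        world$site_occupations[[i]], span)
  }
  curve_span <- range(world$curves$atmospheric$cal_bp)
  if (any(true_year < curve_span[1] | true_year > curve_span[2])) {
    stop_ctx("sampled calendar year outside curve span",
             class = "generation_error")
  }
  region <- world$sites$region[site_idx]
  marine <- region == "coast" & runif(n) < 0.10
  err <- sample(c(15, 20, 30, 40, 60, 80, 120), n, replace = TRUE,
                prob = c(0.1, 0.2, 0.3, 0.2, 0.1, 0.05, 0.05))
  delta_r <- ifelse(marine, round(runif(n, 80, 250)), 0)
  c14 <- numeric(n)
  atm <- curve_at(world$curves$atmospheric, true_year)
  mar <- curve_at(world$curves$marine, true_year)
  c14[!marine] <- rnorm(sum(!marine), atm$mu[!marine],
                        sqrt(err[!marine]^2 + atm$sigma[!marine]^2))
  c14[marine] <- rnorm(sum(marine), mar$mu[marine] + delta_r[marine],
                       sqrt(err[marine]^2 + mar$sigma[marine]^2))
  data.frame(
    lab_id = sprintf("LAB%05d", seq_len(n)),
    site_id = world$sites$site_id[site_idx],
    c14_age = round(c14), error = err,
    material = ifelse(marine, "marine", "terrestrial"),
    delta_r = delta_r, region = region, true_year = true_year,
    stringsAsFactors = FALSE
  )
}

#' Write a synthetic world to disk as plain-text files
#'
#' Emits the same CSV schemas the pipeline reads (`individuals.csv`,
#' `dates.csv`, `sst_cores.csv`, `enso.csv`, `climate.csv`), the two
#' synthetic calibration curves in `.14c` layout, and a `manifest.json`
#' with all true generative parameters.
#'
#' @param world a `synthetic_world`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(world$individuals, file.path(dir, "individuals.csv"),
            row.names = FALSE)
  write.csv(world$dates, file.path(dir, "dates.csv"), row.names = FALSE)
  sst <- do.call(rbind, lapply(world$sst_cores, function(cc) {
    data.frame(core_id = cc$core_id, lon = cc$lon, lat = cc$lat,
               century = cc$centuries, sst = cc$values)
  }))
  write.csv(sst, file.path(dir, "sst_cores.csv"), row.names = FALSE)
  write.csv(data.frame(core_id = world$enso$core_id,
                       century = world$enso$centuries,
                       events = world$enso$values),
            file.path(dir, "enso.csv"), row.names = FALSE)
  write_climate_csv(world$climate, file.path(dir, "climate.csv"))
  for (k in names(world$curves)) {
    cv <- world$curves[[k]]
    writeLines(c(sprintf("# %s — synthetic calibration curve", cv$name),
                 "# CAL BP, 14C age, error",
                 sprintf("%g,%g,%g", cv$cal_bp, cv$c14_age, cv$sigma)),
               file.path(dir, paste0(cv$name, ".14c")))
  }
  cfg <- world$config
  manifest <- list(seed = cfg$seed, n_sites = cfg$n_sites,
                   n_individuals = cfg$n_individuals, n_dates = cfg$n_dates,
                   time_span = cfg$time_span,
                   century_step = cfg$century_step,
                   coastal_fraction = cfg$coastal_fraction,
                   trauma_coefficients = as.list(cfg$trauma_coefficients))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_world: %d sites, %d individuals ",
                     "(%.1f%% trauma), %d dates, span %g-%g cal BP>\n"),
              nrow(x$sites), nrow(x$individuals),
              100 * mean(x$individuals$trauma), nrow(x$dates),
              x$config$time_span[1], x$config$time_span[2]))
  invisible(x)
}
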