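# Shared fixtures, all generated in code.

# A small, fast world configuration; tests override fields as needed.
tiny_world_config <- function(seed = 7L, n_individuals = 300L,
                              n_sites = 20L, n_dates = 150L,
                              time_span = c(6000, 0),
                              grid_extent = list(lon = c(-76, -74.5),
                                                 lat = c(-14, -12.5),
                                                 cell_deg = 0.1), ...) {
  world_config(seed = seed, n_sites = n_sites,
               n_individuals = n_individuals, n_dates = n_dates,
               time_span = time_span, grid_extent = grid_extent, ...)
}

# Strictly monotone linear toy curve: c14 = slope * cal + offset.
linear_curve <- function(span = c(0, 6000), step = 5, slope = 1,
                         offset = 0, sigma = 0) {
  t <- seq(span[1], span[2], by = step)
  new_cal_curve("linear", t, slope * t + offset, rep(sigma, length(t)))
}

# Flat curve: every calendar year maps to the same 14C age.
flat_curve <- function(span = c(0, 1000), step = 10, age = 1000,
                       sigma = 0) {
  t <- seq(span[1], span[2], by = step)
  # strictly monotone grid is required; c14 constant is fine
  new_cal_curve("flat", t, rep(age, length(t)), rep(sigma, length(t)))
}

# Uniform climate grid set: every variable constant at `value`.
uniform_grid <- function(value = 10, nlon = 9, nlat = 9,
                         centuries = seq(50, 950, 100)) {
  lon <- seq(-75, -74.6, length.out = nlon)
  lat <- seq(-13.4, -13, length.out = nlat)
  dims <- c(nlon, nlat, length(centuries))
  v <- array(value, dims)
  climate_grid_set(lon, lat, centuries,
                   list(mean_temperature = v, mean_precipitation = v,
                        sd_temperature = v, sd_precipitation = v))
}

# Single-row individual for exposure tests.
one_individual <- function(lon = -74.8, lat = -13.2, start = 500, end = 300,
                           region = "coast", site_id = "S1") {
  data.frame(id = "I1", site_id = site_id, lon = lon, lat = lat,
             elevation = 100, distance_to_coast = 5,
             window_start = start, window_end = end, trauma = 0L,
             complexity = 0L, region = region, stringsAsFactors = FALSE)
}

# Logistic-world predictor table with one dominant variable, for forest
# tests: y ~ Bernoulli(plogis(beta * x1)), x2..xk pure noise.
signal_frame <- function(n = 400, beta = 2, k = 4, seed = 1) {
  set.seed(seed)
  x <- as.data.frame(matrix(rnorm(n * k), n, k))
  names(x) <- paste0("x", seq_len(k))
  y <- rbinom(n, 1, stats::plogis(beta * x$x1))
  list(x = x, y = y)
}
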