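#' Read a radiocarbon calibration curve in the standard .14c layout
#'
#' Curve files carry comment/header lines starting with `#`, followed by
#' rows of `CAL BP, 14C age, error` (comma- or whitespace-separated;
#' additional columns such as Delta14C are ignored). The calendar grid must
#' be strictly monotone and curve errors nonnegative.
#'
#' @param path path to the `.14c` file.
#' @param name curve name; defaults to the file name without extension.
#' @return an object of class `cal_curve` with fields `name`, `cal_bp`,
#'   `c14_age`, `sigma`.
#' @export
read_14c_curve <- function(path, name = NULL) {
  if (!file.exists(path)) {
    stop_ctx("calibration curve file not found: ", path, class = "parse_error")
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) {
    stop_ctx("no data rows in curve file: ", path, class = "parse_error")
  }
  rows <- lapply(idx, function(i) {
    fields <- strsplit(trimws(lines[i]), "[,\\s]+")[[1]]
    if (length(fields) < 3L) {
      stop_ctx("ragged row at line ", i, " of ", path, class = "parse_error")
    }
    vals <- suppressWarnings(as.numeric(fields[1:3]))
    if (anyNA(vals)) {
      stop_ctx("non-numeric value at line ", i, " of ", path,
               class = "parse_error")
    }
    vals
  })
  m <- do.call(rbind, rows)
  new_cal_curve(name %||% sub("\\.[^.]*$", "", basename(path)),
                cal_bp = m[, 1], c14_age = m[, 2], sigma = m[, 3])
}

#' Construct a calibration curve from vectors
#'
#' @param name curve name.
#' @param cal_bp strictly monotone calendar grid (cal BP).
#' @param c14_age conventional 14C age at each grid year.
#' @param sigma 1-sigma curve error at each grid year (>= 0).
#' @return a `cal_curve` object.
#' @export
new_cal_curve <- function(name, cal_bp, c14_age, sigma) {
  if (!(length(cal_bp) == length(c14_age) &&
        length(cal_bp) == length(sigma))) {
    stop_ctx("curve arrays must have equal length", class = "parse_error")
  }
  d <- diff(cal_bp)
  if (length(d) && !(all(d > 0) || all(d < 0))) {
    stop_ctx("curve calendar grid must be strictly monotone",
             class = "parse_error")
  }
  if (any(sigma < 0)) {
    stop_ctx("curve sigma must be nonnegative", class = "parse_error")
  }
  o <- order(cal_bp)
  structure(list(name = name, cal_bp = cal_bp[o], c14_age = c14_age[o],
                 sigma = sigma[o]),
            class = "cal_curve")
}

#' @export
print.cal_curve <- function(x, ...) {
  cat(sprintf("<cal_curve %s: %d knots, %g-%g cal BP>\n", x$name,
              length(x$cal_bp), min(x$cal_bp), max(x$cal_bp)))
  invisible(x)
}

#' Calibrate a radiocarbon date against a curve
#'
#' The calendar-year posterior is the standard intercept-free density:
#' at each grid year `t`, the normal density of the reservoir-adjusted
#' 14C age at the interpolated curve mean, with variance equal to the sum
#' of the squared lab error and squared curve error, normalized to sum to
#' one over the grid. The grid is 1-yr steps (configurable) with curve
#' mean and error interpolated linearly between knots.
#'
#' @param c14_age conventional 14C age (yr BP).
#' @param error 1-sigma lab error (> 0).
#' @param curve a `cal_curve` (marine dates must use the marine curve).
#' @param delta_r local reservoir offset (yr); subtracted from `c14_age`
#'   before calibration. 0 for terrestrial dates.
#' @param grid_step calendar grid step in years (default 1).
#' @return an object of class `cal_density` with fields `cal_bp` and `p`
#'   (`sum(p) == 1`).
#' @export
calibrate_date <- function(c14_age, error, curve, delta_r = 0,
                           grid_step = 1) {
  stopifnot(inherits(curve, "cal_curve"))
  if (!is.finite(error) || error <= 0) {
    stop_ctx("date error must be positive", class = "calibration_error")
  }
  adj <- c14_age - delta_r
  max_sig <- sqrt(error^2 + max(curve$sigma)^2)
  if (adj < min(curve$c14_age) - 4 * max_sig ||
      adj > max(curve$c14_age) + 4 * max_sig) {
    stop_ctx("date ", adj, " outside curve 14C range +/- 4 sigma",
             class = "calibration_range_error")
  }
  grid <- seq(min(curve$cal_bp), max(curve$cal_bp), by = grid_step)
  mu <- approx(curve$cal_bp, curve$c14_age, grid)$y
  sig <- approx(curve$cal_bp, curve$sigma, grid)$y
  p <- dnorm(adj, mean = mu, sd = sqrt(error^2 + sig^2))
  s <- sum(p)
  if (!is.finite(s) || s <= 0) {
    stop_ctx("date has no posterior mass on the curve support",
             class = "calibration_range_error")
  }
  structure(list(cal_bp = grid, p = p / s), class = "cal_density")
}

#' Mode (maximum-density calendar year) of a calibrated density
#' @param x a `cal_density`.
#' @return calendar year (cal BP) of maximum posterior density.
#' @export
cal_mode <- function(x) x$cal_bp[which.max(x$p)]

#' Highest-posterior-density interval of a calibrated density
#'
#' Greedy accumulation of grid years by descending density until the
#' target mass is reached — the discrete HPD set, reported as its range.
#'
#' @param x a `cal_density`.
#' @param mass target probability mass (default 0.954).
#' @return list with `lo`, `hi` (cal BP) and the achieved `mass`.
#' @export
cal_hpd <- function(x, mass = 0.954) {
  o <- order(x$p, decreasing = TRUE)
  cum <- cumsum(x$p[o])
  k <- which(cum >= mass)[1]
  years <- x$cal_bp[o[seq_len(k)]]
  list(lo = min(years), hi = max(years), mass = cum[k])
}

#' Drop radiocarbon dates with large lab errors
#'
#' Quality-control filter: dates with 1-sigma errors strictly greater than
#' `max_error` are removed (an error exactly equal to the cutoff is kept).
#' The number dropped is attached as attribute `n_dropped` and messaged.
#'
#' @param dates data.frame with at least an `error` column.
#' @param max_error cutoff in years (default 100).
#' @return the retained rows, with attribute `n_dropped`.
#' @export
filter_dates <- function(dates, max_error = 100) {
  keep <- dates$error <= max_error
  out <- dates[keep, , drop = FALSE]
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(n_dropped, " date(s) dropped with error > ", max_error, " yr")
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Bin same-site dates by hierarchical clustering
#'
#' Agglomerative clustering (complete linkage on absolute differences of
#' uncalibrated 14C ages) cut at `cutoff` years, so that intensively dated
#' site phases collapse to one bin and do not dominate the population
#' proxy. Deterministic in input order: dates are pre-sorted by 14C age
#' with ties broken by `lab_id`.
#'
#' @param dates data.frame of dates from a single site (`site_id`,
#'   `lab_id`, `c14_age` columns).
#' @param cutoff tree cut height in 14C years (default 200).
#' @return list of bins; each bin is a list with `site_id`, `lab_ids`, and
#'   `idx` (row indices into `dates`).
#' @export
bin_dates <- function(dates, cutoff = 200) {
  if (nrow(dates) == 0L) return(list())
  if (length(unique(dates$site_id)) != 1L) {
    stop_ctx("bin_dates() expects dates from a single site",
             class = "binning_error")
  }
  o <- order(dates$c14_age, dates$lab_id)
  if (nrow(dates) == 1L) {
    cl <- 1L
  } else {
    hc <- stats::hclust(stats::dist(dates$c14_age[o]), method = "complete")
    cl <- stats::cutree(hc, h = cutoff)
  }
  lapply(split(seq_along(cl), cl), function(k) {
    idx <- o[k]
    list(site_id = dates$site_id[[1]], lab_ids = dates$lab_id[idx],
         idx = idx)
  })
}

#' Bin all dates, site by site
#'
#' @param dates data.frame of dates with `site_id`, `lab_id`, `c14_age`.
#' @param cutoff tree cut height in 14C years.
#' @return flat list of bins across sites; indices refer to rows of
#'   `dates`.
#' @export
bin_all_dates <- function(dates, cutoff = 200) {
  out <- list()
  for (s in sort(unique(dates$site_id))) {
    rows <- which(dates$site_id == s)
    bins <- bin_dates(dates[rows, , drop = FALSE], cutoff = cutoff)
    for (b in bins) {
      b$idx <- rows[b$idx]
      out[[length(out) + 1L]] <- b
    }
  }
  out
}

#' Build composite kernel density estimates (CKDE) of relative population
#'
#' The bootstrap "dates as data" population proxy: for each replicate, one
#' date is drawn uniformly from every bin, one calendar year is drawn from
#' that date's calibrated density, and a Gaussian kernel density with the
#' stated bandwidth is fitted to the sampled years on the output grid and
#' renormalized (trapezoid) to integrate to one. Replicates are
#' independent given the seed.
#'
#' @param bins list of bins from [bin_all_dates()]; each bin must have at
#'   least one calibrated member.
#' @param densities list of `cal_density`, parallel to the rows the bin
#'   indices refer to.
#' @param n_replicates number of bootstrap replicates (default 1000).
#' @param bandwidth Gaussian kernel SD in years (default 50).
#' @param grid equispaced calendar grid (cal BP) for the output densities.
#' @param seed integer seed.
#' @return object of class `pop_kde_set`: fields `grid`,
#'   `density` (matrix `n_replicates` x `length(grid)`), `bandwidth`,
#'   `corrected` (FALSE).
#' @export
build_ckde <- function(bins, densities, n_replicates = 1000,
                       bandwidth = 50, grid, seed = 1L) {
  if (length(bins) == 0L) {
    stop_ctx("no bins supplied to build_ckde()", class = "ckde_error")
  }
  stopifnot(all(abs(diff(diff(grid))) < 1e-8))
  set.seed(seed)
  dens <- matrix(0, nrow = n_replicates, ncol = length(grid))
  for (r in seq_len(n_replicates)) {
    years <- vapply(bins, function(b) {
      j <- b$idx[[sample.int(length(b$idx), 1L)]]
      d <- densities[[j]]
      d$cal_bp[[sample.int(length(d$p), 1L, prob = d$p)]]
    }, numeric(1))
    k <- density(years, bw = bandwidth, kernel = "gaussian",
                 from = min(grid), to = max(grid), n = length(grid))
    z <- trapz(grid, k$y)
    dens[r, ] <- if (z > 0) k$y / z else k$y
  }
  structure(list(grid = grid, density = dens, bandwidth = bandwidth,
                 corrected = FALSE),
            class = "pop_kde_set")
}

#' @export
print.pop_kde_set <- function(x, ...) {
  cat(sprintf("<pop_kde_set: %d replicates on %d-yr grid %g-%g cal BP%s>\n",
              nrow(x$density), round(diff(x$grid[1:2])), min(x$grid),
              max(x$grid), if (x$corrected) ", taphonomically corrected"
              else ""))
  invisible(x)
}

#' Taphonomic correction of population KDEs
#'
#' Divides each replicate density by the empirical survival curve
#' `n(t) = a * (t + b)^c` (the age-dependent loss of datable material) and
#' renormalizes, so older material destroyed by taphonomic processes is
#' up-weighted. Defaults are the published survival-curve coefficients
#' commonly used for this correction.
#'
#' @param kdes a `pop_kde_set`.
#' @param a,b,c survival-curve parameters.
#' @return a new `pop_kde_set` with `corrected = TRUE`.
#' @export
taphonomic_correct <- function(kdes, a = 5.726442e6, b = 2176.4,
                               c = -1.3925309) {
  stopifnot(inherits(kdes, "pop_kde_set"))
  t <- kdes$grid
  if (any(t + b <= 0)) {
    stop_ctx("survival curve undefined: t + b <= 0 on grid",
             class = "taphonomy_error")
  }
  surv <- a * (t + b)^c
  dens <- sweep(kdes$density, 2, surv, `/`)
  for (r in seq_len(nrow(dens))) {
    z <- trapz(t, dens[r, ])
    if (z > 0) dens[r, ] <- dens[r, ] / z
  }
  structure(list(grid = t, density = dens, bandwidth = kdes$bandwidth,
                 corrected = TRUE),
            class = "pop_kde_set")
}

#' Write / read a pop_kde_set as long-format CSV
#' @param kdes a `pop_kde_set`.
#' @param path output CSV path (`replicate_id, cal_bp, density`).
#' @return `path`, invisibly.
#' @export
write_ckde_csv <- function(kdes, path) {
  df <- data.frame(
    replicate_id = rep(seq_len(nrow(kdes$density)), each = ncol(kdes$density)),
    cal_bp = rep(kdes$grid, times = nrow(kdes$density)),
    density = as.vector(t(kdes$density))
  )
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
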