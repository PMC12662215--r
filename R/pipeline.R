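#' Read an individuals table and validate its schema
#'
#' Expected columns: `id`, `site_id`, `lon`, `lat`, `elevation`,
#' `distance_to_coast`, `window_start`, `window_end`, `trauma` (0/1),
#' `complexity` (0/1/2). `region` is recomputed from distance and
#' elevation if absent.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_individuals <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "site_id", "lon", "lat", "elevation",
            "distance_to_coast", "window_start", "window_end", "trauma",
            "complexity")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_ctx("individuals.csv missing columns: ",
             paste(missing, collapse = ", "), class = "data_error")
  }
  if (!all(df$trauma %in% c(0, 1))) {
    stop_ctx("trauma must be 0/1", class = "data_error")
  }
  if (!all(df$complexity %in% 0:2)) {
    stop_ctx("complexity must be 0, 1 or 2", class = "data_error")
  }
  if (any(df$window_start < df$window_end)) {
    stop_ctx("window_start must be >= window_end (cal BP)",
             class = "data_error")
  }
  if (is.null(df$region)) {
    df$region <- classify_region(df$distance_to_coast, df$elevation)
  }
  df
}

#' Read a radiocarbon date list
#' @param path CSV with `lab_id`, `site_id`, `c14_age`, `error`,
#'   `material`, `delta_r` (and optionally `region`).
#' @return validated data.frame.
#' @export
read_dates <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("lab_id", "site_id", "c14_age", "error", "material", "delta_r")
  missing <- setdiff(need, names(df))
  if (length(missing)) {
    stop_ctx("dates.csv missing columns: ",
             paste(missing, collapse = ", "), class = "data_error")
  }
  if (any(df$error <= 0)) stop_ctx("date errors must be > 0",
                                   class = "data_error")
  if (!all(df$material %in% c("terrestrial", "marine"))) {
    stop_ctx("material must be terrestrial or marine", class = "data_error")
  }
  df
}

#' Summarize an individuals table
#'
#' Totals and per-region trauma composition with prevalences rounded to
#' one decimal, the desk check against a compiled trauma database.
#'
#' @param individuals data.frame with `trauma`, `region`, `site_id`.
#' @return list: `n_total`, `n_trauma`, `n_no_trauma`,
#'   `prevalence_pct` (1-decimal percentage, `NA` when empty),
#'   `n_sites`, `regions` (per-region data.frame).
#' @export
summarize_dataset <- function(individuals) {
  n <- nrow(individuals)
  prev <- function(tr, tot) if (tot > 0) round(100 * tr / tot, 1) else
    NA_real_
  n_tr <- sum(individuals$trauma == 1)
  regs <- lapply(split(individuals, individuals$region), function(d) {
    data.frame(region = d$region[[1]], n = nrow(d),
               n_trauma = sum(d$trauma == 1),
               n_no_trauma = sum(d$trauma == 0),
               prevalence_pct = prev(sum(d$trauma == 1), nrow(d)))
  })
  regs <- if (length(regs)) do.call(rbind, regs) else
    data.frame(region = character(0), n = integer(0),
               n_trauma = integer(0), n_no_trauma = integer(0),
               prevalence_pct = numeric(0))
  rownames(regs) <- NULL
  list(n_total = n, n_trauma = n_tr, n_no_trauma = n - n_tr,
       prevalence_pct = prev(n_tr, n),
       n_sites = length(unique(individuals$site_id)),
       regions = regs)
}

#' Declarative configuration for the full pipeline
#'
#' @param output_dir directory for all artifacts.
#' @param seed global seed; every stage derives its own stream from it.
#' @param world a `world_config`, or `NULL` to load data from `paths`.
#' @param paths named list of input paths (`individuals`, `dates`,
#'   `climate`, `sst_cores`, `enso`, `curve_atmospheric`,
#'   `curve_marine`) used when `world` is `NULL`.
#' @param model a `model_config`.
#' @param n_draws Monte-Carlo exposure draws per individual (default
#'   1000; must be >= `model$n_models`).
#' @param radius_km climate buffer radius (default 20).
#' @param n_kde_replicates population-KDE bootstrap replicates (default
#'   1000).
#' @param kde_bandwidth KDE bandwidth in years (default 50).
#' @param kde_grid_step population-KDE grid step in years (default 20).
#' @param max_date_error QC cutoff for date errors (default 100).
#' @param bin_cutoff binning cutoff in 14C years (default 200).
#' @param taphonomic apply taphonomic correction to the KDEs (default
#'   FALSE).
#' @param regions regions to model (default both).
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(output_dir, seed = 1L, world = NULL,
                            paths = list(), model = model_config(),
                            n_draws = 1000, radius_km = 20,
                            n_kde_replicates = 1000, kde_bandwidth = 50,
                            kde_grid_step = 20, max_date_error = 100,
                            bin_cutoff = 200, taphonomic = FALSE,
                            regions = c("coast", "inland")) {
  if (model$n_models > n_draws) {
    stop_ctx("n_models (", model$n_models, ") exceeds n_draws (",
             n_draws, ")", class = "config_error")
  }
  structure(list(output_dir = output_dir, seed = as.integer(seed),
                 world = world, paths = paths, model = model,
                 n_draws = n_draws, radius_km = radius_km,
                 n_kde_replicates = n_kde_replicates,
                 kde_bandwidth = kde_bandwidth,
                 kde_grid_step = kde_grid_step,
                 max_date_error = max_date_error,
                 bin_cutoff = bin_cutoff, taphonomic = taphonomic,
                 regions = regions),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Stages: (optional) simulate a synthetic world -> calibrate, QC-filter
#' and bin the dates and build per-region population CKDEs -> attach
#' Monte-Carlo exposure draws to every individual -> run the
#' probability-forest ensemble per region -> aggregate and write the
#' summary artifacts. Reruns with the same config reproduce the same
#' outputs; stage seeds all derive from the global seed.
#'
#' @param config a `pipeline_config`.
#' @param quiet suppress stage messages.
#' @return named list of summaries (one per region), invisibly; artifacts
#'   are written under `config$output_dir`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)

  # --- stage: data ---------------------------------------------------
  if (!is.null(config$world)) {
    say("stage simulate: generating synthetic world")
    world <- generate_world(config$world)
    individuals <- world$individuals
    dates <- world$dates
    climate <- world$climate
    sst_cores <- world$sst_cores
    enso <- world$enso
    curves <- world$curves
  } else {
    say("stage load: reading inputs")
    p <- config$paths
    individuals <- read_individuals(p$individuals)
    dates <- read_dates(p$dates)
    climate <- read_climate_csv(p$climate)
    sst_df <- read.csv(p$sst_cores)
    sst_cores <- lapply(split(sst_df, sst_df$core_id), function(d) {
      d <- d[order(d$century), ]
      list(core_id = d$core_id[[1]], lon = d$lon[[1]], lat = d$lat[[1]],
           centuries = d$century, values = d$sst)
    })
    enso_df <- read.csv(p$enso)
    enso_df <- enso_df[order(enso_df$century), ]
    enso <- list(core_id = enso_df$core_id[[1]], centuries = enso_df$century,
                 values = enso_df$events)
    curves <- list(atmospheric = read_14c_curve(p$curve_atmospheric),
                   marine = read_14c_curve(p$curve_marine))
  }
  if (is.null(dates$region)) {
    site_region <- tapply(individuals$region, individuals$site_id,
                          function(r) r[[1]])
    dates$region <- site_region[dates$site_id]
  }

  # --- stage: radiocarbon -> population proxy ------------------------
  say("stage ckde: calibrating %d dates", nrow(dates))
  dates <- filter_dates(dates, config$max_date_error)
  grid_span <- range(curves$atmospheric$cal_bp)
  grid <- seq(grid_span[1], grid_span[2], by = config$kde_grid_step)
  kdes <- list()
  for (reg in config$regions) {
    dr <- dates[dates$region == reg, , drop = FALSE]
    if (!nrow(dr)) stop_ctx("no dates in region ", reg,
                            class = "data_error")
    dens <- vector("list", nrow(dr))
    for (j in seq_len(nrow(dr))) {
      cv <- if (dr$material[j] == "marine") curves$marine else
        curves$atmospheric
      dens[[j]] <- calibrate_date(dr$c14_age[j], dr$error[j], cv,
                                  delta_r = dr$delta_r[j],
                                  grid_step = config$kde_grid_step)
    }
    bins <- bin_all_dates(dr, cutoff = config$bin_cutoff)
    k <- build_ckde(bins, dens, n_replicates = config$n_kde_replicates,
                    bandwidth = config$kde_bandwidth, grid = grid,
                    seed = derive_seed(config$seed, paste0("ckde_", reg)))
    if (config$taphonomic) k <- taphonomic_correct(k)
    kdes[[reg]] <- k
    write_ckde_csv(k, file.path(config$output_dir,
                                paste0("ckde_", reg, ".csv")))
  }

  # --- stage: exposures ----------------------------------------------
  say("stage exposures: %d individuals x %d draws",
      nrow(individuals), config$n_draws)
  individuals <- individuals[individuals$region %in% config$regions, ,
                             drop = FALSE]
  exposures <- build_exposures(individuals, climate, sst_cores, enso,
                               kdes, n_draws = config$n_draws,
                               radius_km = config$radius_km,
                               seed = derive_seed(config$seed, "exposures"))

  # --- stage: ensembles + reports ------------------------------------
  summaries <- list()
  for (reg in config$regions) {
    say("stage fit: %d models for region %s", config$model$n_models, reg)
    cfg <- config$model
    cfg$seed <- derive_seed(config$seed, paste0("ensemble_", reg))
    ens <- run_ensemble(exposures, cfg, region = reg)
    summ <- aggregate_runs(ens)
    write_summary(summ, config$output_dir)
    met <- do.call(rbind, lapply(ens$runs, function(r) {
      data.frame(run_id = r$run_id, auc = r$metrics$auc,
                 mse = r$metrics$mse, log_loss = r$metrics$log_loss,
                 log_loss_probability = r$metrics$log_loss_probability)
    }))
    write.csv(met, file.path(config$output_dir,
                             paste0("run_metrics_", reg, ".csv")),
              row.names = FALSE)
    summaries[[reg]] <- summ
  }

  ds <- summarize_dataset(individuals)
  manifest <- list(
    seed = config$seed, n_draws = config$n_draws,
    n_models = config$model$n_models, regions = config$regions,
    taphonomic = config$taphonomic,
    dataset = list(n_total = ds$n_total,
                   prevalence_pct = ds$prevalence_pct),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    package_version = as.character(utils::packageVersion("peacetrace")))
  jsonlite::write_json(manifest,
                       file.path(config$output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("pipeline complete in %.1f s", manifest$elapsed_s)
  invisible(summaries)
}
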