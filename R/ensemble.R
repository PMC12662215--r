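#' Configuration for the probability-forest ensemble
#'
#' @param n_models models per region (default 1000; each uses one draw
#'   index of the exposure Monte-Carlo draws).
#' @param site_cap maximal individuals per site per run (default 30).
#' @param test_fraction held-out fraction for the stratified split
#'   (default 0.25).
#' @param n_trees trees per forest (default 500).
#' @param variables_per_split mtry; `NULL` = `floor(sqrt(p))`.
#' @param min_node minimal node size (default 10).
#' @param collinearity_threshold |r| at or above which one of a variable
#'   pair is dropped (default 0.7).
#' @param pd_grid_size partial-dependence grid points per variable
#'   (default 25).
#' @param pd_rows maximal rows averaged over per partial-dependence
#'   evaluation (default 200; `NULL` = all rows). Standard practice to
#'   keep PD tractable across hundreds of runs; the subsample is drawn
#'   per run from that run's (site-capped) rows.
#' @param pd_2d_runs number of leading runs for which 2-variable partial
#'   dependence surfaces are computed (default 0; they are expensive, so
#'   only a subset of runs carries them).
#' @param pd_2d_pairs list of character pairs for the surfaces; `NULL`
#'   picks the two most important variables lazily per run.
#' @param seed integer seed.
#' @return object of class `model_config`.
#' @export
model_config <- function(n_models = 1000, site_cap = 30,
                         test_fraction = 0.25, n_trees = 500,
                         variables_per_split = NULL, min_node = 10,
                         collinearity_threshold = 0.7, pd_grid_size = 25,
                         pd_rows = 200, pd_2d_runs = 0, pd_2d_pairs = NULL,
                         seed = 1L) {
  if (!(test_fraction > 0 && test_fraction < 1)) {
    stop_ctx("test_fraction must be in (0, 1)", class = "config_error")
  }
  if (site_cap < 1) stop_ctx("site_cap must be >= 1", class = "config_error")
  if (!(collinearity_threshold > 0 && collinearity_threshold <= 1)) {
    stop_ctx("collinearity_threshold must be in (0, 1]",
             class = "config_error")
  }
  structure(list(n_models = n_models, site_cap = site_cap,
                 test_fraction = test_fraction, n_trees = n_trees,
                 variables_per_split = variables_per_split,
                 min_node = min_node,
                 collinearity_threshold = collinearity_threshold,
                 pd_grid_size = pd_grid_size, pd_rows = pd_rows,
                 pd_2d_runs = pd_2d_runs,
                 pd_2d_pairs = pd_2d_pairs, seed = as.integer(seed)),
            class = "model_config")
}

#' Screen predictors for collinearity
#'
#' Pairwise Pearson correlations on per-individual draw means; for every
#' pair with `|r| >=` the threshold, the variable lower in the preference
#' order is dropped (means are preferred over SDs, so mean precipitation
#' survives a clash with SD precipitation). Iterates until no retained
#' pair is flagged. The full correlation matrix is returned for
#' reporting.
#'
#' @param draw_means data.frame of per-individual mean exposures.
#' @param threshold flagging threshold on |r| (default 0.7).
#' @param preference_order character vector, highest-priority first;
#'   variables not listed rank below all listed ones.
#' @return list with `retained`, `dropped`, `cor_matrix`.
#' @export
screen_collinearity <- function(draw_means, threshold = 0.7,
                                preference_order = c(
                                  "mean_temperature", "mean_precipitation",
                                  "sst", "enso_frequency", "population",
                                  "complexity", "sd_temperature",
                                  "sd_precipitation")) {
  vars <- names(draw_means)
  if (length(vars) < 2L || nrow(draw_means) < 3L) {
    stop_ctx("need >= 2 variables and >= 3 rows", class = "screen_error")
  }
  for (v in vars) {
    if (sd(draw_means[[v]], na.rm = TRUE) == 0 ||
        !is.finite(sd(draw_means[[v]], na.rm = TRUE))) {
      stop_ctx("constant column: ", v, class = "screen_error")
    }
  }
  cm <- cor(draw_means, use = "pairwise.complete.obs")
  prio <- function(v) {
    i <- match(v, preference_order)
    ifelse(is.na(i), length(preference_order) + match(v, sort(vars)), i)
  }
  retained <- vars
  dropped <- character(0)
  repeat {
    sub <- abs(cm[retained, retained, drop = FALSE])
    diag(sub) <- 0
    if (all(sub < threshold)) break
    worst <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    pair <- retained[worst]
    loser <- pair[which.max(prio(pair))]
    dropped <- c(dropped, loser)
    retained <- setdiff(retained, loser)
    if (length(retained) < 2L) break
  }
  list(retained = retained, dropped = dropped, cor_matrix = cm)
}

#' Cap the number of individuals per site
#'
#' Sites with more rows than `cap` contribute a uniform without-
#' replacement sample of size `cap`; smaller sites contribute all rows,
#' so every site stays represented while large sites cannot dominate.
#'
#' @param rows data.frame with a `site_id` column.
#' @param cap maximal rows per site (default 30).
#' @return row indices into `rows` (sorted).
#' @export
subsample_sites <- function(rows, cap = 30) {
  idx <- unlist(lapply(split(seq_len(nrow(rows)), rows$site_id),
                       function(k) {
                         if (length(k) <= cap) k else sample(k, cap)
                       }), use.names = FALSE)
  sort(idx)
}

#' Stratified train/test split
#'
#' Disjoint, exhaustive split preserving the trauma / no-trauma ratio:
#' per class, `round(class_n * test_fraction)` rows go to the test set.
#'
#' @param y 0/1 outcome vector.
#' @param test_fraction fraction held out.
#' @return list with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_fraction = 0.25) {
  if (length(unique(y)) < 2L) {
    stop_ctx("both outcome classes required for a stratified split",
             class = "stratification_error")
  }
  test <- integer(0)
  for (cl in unique(y)) {
    k <- which(y == cl)
    n_test <- round(length(k) * test_fraction)
    test <- c(test, if (n_test > 0) sample(k, n_test) else integer(0))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

#' Run the iterated probability-forest ensemble for one region
#'
#' Run `i` uses draw index `i` of the exposure Monte-Carlo draws as that
#' run's "true" predictor table, so the ensemble of `n_models` runs
#' propagates each individual's temporal uncertainty into the model
#' output. Each run: cap individuals per site, stratified train/test
#' split, fit a probability forest for P(no trauma), record held-out AUC
#' and MSE, permutation importance, and per-variable partial-dependence
#' curves on fixed shared grids; a second forest on all (capped) rows
#' yields log-loss and log-loss-as-probability. Collinearity screening is
#' done once, up front, on the per-individual draw means.
#'
#' @param exposures an `exposure_draws`.
#' @param config a `model_config` (`n_models` must not exceed
#'   `exposures$n_draws`).
#' @param region `"coast"` or `"inland"`; inland drops the SST variable.
#' @return object of class `ensemble_runs`: `runs` (list of per-run
#'   records), `region`, `screen` (collinearity result), `pd_grids`,
#'   `draw_means`, `config`.
#' @export
run_ensemble <- function(exposures, config = model_config(),
                         region = c("coast", "inland")) {
  region <- match.arg(region)
  stopifnot(inherits(exposures, "exposure_draws"))
  if (config$n_models > exposures$n_draws) {
    stop_ctx("n_models (", config$n_models, ") exceeds n_draws (",
             exposures$n_draws, ")", class = "config_error")
  }
  sel <- which(exposures$individuals$region == region)
  if (!length(sel)) stop_ctx("no individuals in region ", region,
                             class = "config_error")
  ind <- exposures$individuals[sel, , drop = FALSE]
  y <- 1L - ind$trauma  # class 1 = no trauma (peace)

  vars <- c("mean_temperature", "mean_precipitation", "sd_temperature",
            "sd_precipitation", "enso_frequency", "population")
  if (region == "coast") vars <- c(vars, "sst")
  means <- as.data.frame(lapply(exposures$draws[vars],
                                function(m) rowMeans(m[sel, , drop = FALSE])))
  means$complexity <- ind$complexity
  # a variable constant within the region (e.g. complexity in a span with
  # no state presence) carries no information: drop before screening
  const <- vapply(means, function(v) sd(v, na.rm = TRUE) == 0, logical(1))
  if (any(const)) {
    warning("dropping constant variable(s) in region ", region, ": ",
            paste(names(means)[const], collapse = ", "))
    means <- means[, !const, drop = FALSE]
  }
  screen <- screen_collinearity(means, config$collinearity_threshold)
  retained <- screen$retained

  # fixed PD grids from pooled draw means: all runs aggregate pointwise
  pd_grids <- lapply(retained, function(v) {
    q <- quantile(means[[v]], c(0.01, 0.99), names = FALSE)
    if (q[1] == q[2]) q[1] else seq(q[1], q[2],
                                    length.out = config$pd_grid_size)
  })
  names(pd_grids) <- retained

  draw_vars <- setdiff(retained, "complexity")
  runs <- vector("list", config$n_models)
  for (i in seq_len(config$n_models)) {
    set.seed(derive_seed(config$seed, paste0(region, "_run", i)))
    x <- as.data.frame(lapply(exposures$draws[draw_vars],
                              function(m) m[sel, i]))
    if ("complexity" %in% retained) x$complexity <- ind$complexity
    x <- x[, retained, drop = FALSE]

    keep <- subsample_sites(ind, config$site_cap)
    xs <- x[keep, , drop = FALSE]
    ys <- y[keep]
    sp <- stratified_split(ys, config$test_fraction)
    fit <- fit_probability_forest(
      xs[sp$train, , drop = FALSE], ys[sp$train],
      n_trees = config$n_trees, mtry = config$variables_per_split,
      min_node = config$min_node,
      seed = derive_seed(config$seed, paste0(region, "_fit", i)))
    p_test <- predict(fit, xs[sp$test, , drop = FALSE])
    met <- suppressWarnings(evaluate_predictions(p_test, ys[sp$test]))
    imp <- permutation_importance(
      fit, xs[sp$test, , drop = FALSE], ys[sp$test],
      seed = derive_seed(config$seed, paste0(region, "_imp", i)))
    xpd <- xs
    if (!is.null(config$pd_rows) && nrow(xs) > config$pd_rows) {
      xpd <- xs[sample.int(nrow(xs), config$pd_rows), , drop = FALSE]
    }
    pd <- lapply(retained, function(v) {
      partial_dependence(fit, xpd, v, grids = pd_grids)
    })
    names(pd) <- retained

    pd2 <- NULL
    if (i <= config$pd_2d_runs) {
      pairs <- config$pd_2d_pairs %||%
        list(names(sort(imp, decreasing = TRUE))[1:2])
      pd2 <- lapply(pairs, function(pr) {
        partial_dependence(fit, xpd, pr, grids = pd_grids)
      })
      names(pd2) <- vapply(pairs, paste, "", collapse = ":")
    }

    # second, all-data model for the accuracy (log-loss) metrics
    fit_all <- fit_probability_forest(
      xs, ys, n_trees = config$n_trees,
      mtry = config$variables_per_split, min_node = config$min_node,
      seed = derive_seed(config$seed, paste0(region, "_full", i)))
    met_full <- suppressWarnings(
      evaluate_predictions(predict(fit_all, xs), ys))

    runs[[i]] <- list(
      run_id = i, region = region, draw_index = i,
      metrics = list(auc = met$auc, mse = met$mse,
                     log_loss = met_full$log_loss,
                     log_loss_probability = met_full$log_loss_probability),
      importance = imp, pd_curves = pd, pd_surfaces = pd2)
  }
  structure(list(runs = runs, region = region, screen = screen,
                 pd_grids = pd_grids, draw_means = means, config = config),
            class = "ensemble_runs")
}

#' @export
print.ensemble_runs <- function(x, ...) {
  cat(sprintf("<ensemble_runs: %d runs, region %s, variables: %s>\n",
              length(x$runs), x$region,
              paste(x$screen$retained, collapse = ", ")))
  invisible(x)
}
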