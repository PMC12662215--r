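#' Aggregate an ensemble of model runs into summary surfaces
#'
#' Across runs: arithmetic means, SD, a 2-SD band, and a 95% normal CI on
#' the mean (`mean +/- 1.96 * SD / sqrt(n)`) for every metric and for
#' each variable's permutation importance; partial-dependence curves are
#' averaged pointwise on the shared grid, and each mean curve is reduced
#' to its PPI range (predicted probability of no trauma at the low and
#' high predictor end, plus the curve minimum and maximum for
#' non-monotone responses).
#'
#' @param ens an `ensemble_runs`, or a bare list of run records with
#'   consistent variable sets and PD grids (>= 2 runs).
#' @return object of class `ensemble_summary`: `region`, `n_runs`,
#'   `metrics` (data.frame), `importance` (data.frame with mean, sd,
#'   band and CI columns), `pd_mean` (named list of mean curves),
#'   `ppi_range` (data.frame), `cor_matrix`.
#' @export
aggregate_runs <- function(ens) {
  runs <- if (inherits(ens, "ensemble_runs")) ens$runs else ens
  if (length(runs) < 2L) {
    stop_ctx("need >= 2 runs to aggregate", class = "aggregation_error")
  }
  vars <- names(runs[[1]]$importance)
  for (r in runs) {
    if (!identical(names(r$importance), vars)) {
      stop_ctx("inconsistent variable sets across runs",
               class = "aggregation_error")
    }
  }
  ci <- function(v) {
    v <- v[is.finite(v)]
    m <- mean(v); s <- sd(v); n <- length(v)
    c(mean = m, sd = s, lo2sd = m - 2 * s, hi2sd = m + 2 * s,
      ci_lo = m - 1.96 * s / sqrt(n), ci_hi = m + 1.96 * s / sqrt(n))
  }
  met_names <- c("auc", "mse", "log_loss", "log_loss_probability")
  metrics <- as.data.frame(t(vapply(met_names, function(m) {
    ci(vapply(runs, function(r) r$metrics[[m]] %||% NA_real_, numeric(1)))
  }, numeric(6))))
  metrics$metric <- met_names

  importance <- as.data.frame(t(vapply(vars, function(v) {
    ci(vapply(runs, function(r) r$importance[[v]], numeric(1)))
  }, numeric(6))))
  importance$variable <- vars

  pd_mean <- list()
  ppi <- list()
  for (v in vars) {
    g <- runs[[1]]$pd_curves[[v]][[v]]
    mat <- vapply(runs, function(r) {
      cur <- r$pd_curves[[v]]
      if (!isTRUE(all.equal(cur[[v]], g))) {
        stop_ctx("inconsistent PD grids for ", v,
                 class = "aggregation_error")
      }
      cur$p_no_trauma
    }, numeric(length(g)))
    m <- rowMeans(mat)
    cur <- data.frame(g, p_no_trauma = m)
    names(cur)[1] <- v
    pd_mean[[v]] <- cur
    pr <- ppi_range(cur)
    ppi[[v]] <- data.frame(variable = v, p_low_end = pr$p_low_end,
                           p_high_end = pr$p_high_end, p_min = pr$p_min,
                           p_max = pr$p_max)
  }
  ppi <- do.call(rbind, ppi)
  rownames(ppi) <- NULL

  cm <- if (inherits(ens, "ensemble_runs")) {
    correlation_matrix(ens$draw_means)
  } else NULL
  structure(list(
    region = if (inherits(ens, "ensemble_runs")) ens$region else
      runs[[1]]$region,
    n_runs = length(runs), metrics = metrics, importance = importance,
    pd_mean = pd_mean, ppi_range = ppi, cor_matrix = cm),
    class = "ensemble_summary")
}

#' PPI range of a mean partial-dependence curve
#'
#' The probability of peaceful interactions at the low and high end of
#' the predictor grid, reported as the ordered pair (low end, high end).
#' Because some responses are non-monotone (a "sweet spot"), the curve
#' minimum and maximum are also returned.
#'
#' @param curve data.frame whose first column is the predictor grid and
#'   which has a `p_no_trauma` column.
#' @return list with `p_low_end`, `p_high_end`, `p_min`, `p_max`.
#' @export
ppi_range <- function(curve) {
  if (nrow(curve) == 0L) stop_ctx("empty PD curve", class = "ppi_error")
  o <- order(curve[[1]])
  p <- curve$p_no_trauma[o]
  list(p_low_end = p[1], p_high_end = p[length(p)],
       p_min = min(p), p_max = max(p))
}

#' Predictor correlation matrix for reporting
#'
#' Pairwise Pearson correlations of per-individual mean exposures, unit
#' diagonal. Constant columns are flagged and their rows/columns set to
#' `NA` rather than erroring, since the matrix is a reporting artifact.
#'
#' @param draw_means data.frame of per-individual mean exposures
#'   (>= 3 rows).
#' @return symmetric correlation matrix.
#' @export
correlation_matrix <- function(draw_means) {
  if (nrow(draw_means) < 3L) {
    stop_ctx("need >= 3 individuals", class = "reporting_error")
  }
  cm <- suppressWarnings(cor(draw_means, use = "pairwise.complete.obs"))
  const <- vapply(draw_means,
                  function(v) isTRUE(sd(v, na.rm = TRUE) == 0), logical(1))
  if (any(const)) {
    warning("constant column(s): ",
            paste(names(draw_means)[const], collapse = ", "))
    cm[const, ] <- NA_real_
    cm[, const] <- NA_real_
  }
  diag(cm) <- 1
  cm
}

#' @export
print.ensemble_summary <- function(x, ...) {
  cat(sprintf("<ensemble_summary: region %s, %d runs>\n", x$region,
              x$n_runs))
  cat("metrics:\n")
  print(x$metrics[, c("metric", "mean", "ci_lo", "ci_hi")],
        row.names = FALSE, digits = 3)
  cat("PPI ranges:\n")
  print(x$ppi_range, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write an ensemble summary to plot-ready text files
#'
#' Emits `summary_<region>.json` plus CSVs for importance bands, mean PD
#' curves, the PPI table and the correlation matrix.
#'
#' @param summary an `ensemble_summary`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_summary <- function(summary, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  reg <- summary$region
  js <- list(region = reg, n_runs = summary$n_runs,
             metrics = summary$metrics,
             importance = summary$importance,
             ppi_range = summary$ppi_range)
  jsonlite::write_json(js, file.path(dir, paste0("summary_", reg, ".json")),
                       auto_unbox = TRUE, digits = 12, dataframe = "rows")
  write.csv(summary$importance,
            file.path(dir, paste0("importance_", reg, ".csv")),
            row.names = FALSE)
  pd <- do.call(rbind, lapply(names(summary$pd_mean), function(v) {
    cur <- summary$pd_mean[[v]]
    data.frame(variable = v, grid_value = cur[[1]],
               p_no_trauma = cur$p_no_trauma)
  }))
  write.csv(pd, file.path(dir, paste0("pd_mean_", reg, ".csv")),
            row.names = FALSE)
  write.csv(summary$ppi_range,
            file.path(dir, paste0("ppi_range_", reg, ".csv")),
            row.names = FALSE)
  if (!is.null(summary$cor_matrix)) {
    write.csv(as.data.frame(summary$cor_matrix),
              file.path(dir, paste0("correlation_", reg, ".csv")))
  }
  invisible(dir)
}
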