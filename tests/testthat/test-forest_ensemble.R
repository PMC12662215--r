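# Builds a hand-made exposure_draws object whose draws carry a known
# signal, so ensemble machinery can be tested without the full pipeline.
fake_exposures <- function(n = 240, n_draws = 10, beta = 2, seed = 1,
                           region = "coast", shuffle_labels = FALSE) {
  set.seed(seed)
  site <- sample(sprintf("S%02d", 1:12), n, replace = TRUE)
  signal <- rnorm(n)
  vars <- c("mean_temperature", "mean_precipitation", "sd_temperature",
            "sd_precipitation", "sst", "enso_frequency", "population")
  draws <- lapply(vars, function(v) {
    base <- if (v == "mean_temperature") signal else rnorm(n)
    base + matrix(rnorm(n * n_draws, 0, 0.1), n, n_draws)
  })
  names(draws) <- vars
  # higher temperature -> more trauma -> PPI decreasing in temperature
  y_trauma <- rbinom(n, 1, stats::plogis(-1 + beta * signal))
  if (shuffle_labels) y_trauma <- sample(y_trauma)
  individuals <- data.frame(
    id = sprintf("I%04d", 1:n), site_id = site, lon = -75, lat = -13,
    elevation = 100, distance_to_coast = 5, window_start = 500,
    window_end = 300, trauma = y_trauma,
    complexity = sample(0:2, n, replace = TRUE), region = region,
    stringsAsFactors = FALSE)
  structure(list(individuals = individuals, n_draws = n_draws,
                 draws = draws),
            class = "exposure_draws")
}

test_that("screen_collinearity drops the lower-preference variable", {
  set.seed(1)
  x <- rnorm(200)
  df <- data.frame(x = x, y = x)
  sc <- screen_collinearity(df, preference_order = c("x", "y"))
  expect_equal(sc$retained, "x")
  expect_equal(sc$dropped, "y")
  expect_equal(unname(sc$cor_matrix["x", "y"]), 1)

  ind <- as.data.frame(matrix(rnorm(1000 * 4), 1000, 4))
  sc2 <- screen_collinearity(ind, preference_order = names(ind))
  expect_length(sc2$retained, 4L)

  df3 <- data.frame(a = rnorm(50), b = rep(1, 50))
  expect_error(screen_collinearity(df3), "constant column: b")
})

test_that("screening reproduces the SD-precipitation drop", {
  set.seed(2)
  mp <- rnorm(500)
  df <- data.frame(mean_precipitation = mp,
                   sd_precipitation = 0.9 * mp + rnorm(500, 0, 0.3),
                   mean_temperature = rnorm(500))
  sc <- screen_collinearity(df)
  expect_true("mean_precipitation" %in% sc$retained)
  expect_true("sd_precipitation" %in% sc$dropped)
})

test_that("subsample_sites caps large sites and keeps every site", {
  rows <- data.frame(site_id = rep(c("A", "B", "C"), c(5, 30, 100)))
  set.seed(3)
  idx <- subsample_sites(rows, cap = 30)
  tab <- table(rows$site_id[idx])
  expect_equal(as.integer(tab[c("A", "B", "C")]), c(5, 30, 30))
  expect_setequal(names(tab), c("A", "B", "C"))

  small <- data.frame(site_id = rep(c("A", "B"), c(3, 4)))
  expect_equal(subsample_sites(small, cap = 30), 1:7)
})

test_that("stratified_split preserves class ratios and partitions rows", {
  y <- rep(c(0, 1), c(80, 20))
  set.seed(4)
  sp <- stratified_split(y, 0.25)
  expect_equal(sum(y[sp$test] == 0), 20)
  expect_equal(sum(y[sp$test] == 1), 5)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
  expect_length(intersect(sp$train, sp$test), 0L)

  y2 <- rep(c(0, 1), each = 4)
  sp2 <- stratified_split(y2, 0.5)
  expect_equal(sum(y2[sp2$test] == 0), 2)
  expect_equal(sum(y2[sp2$test] == 1), 2)
  expect_error(stratified_split(rep(1, 10), 0.25),
               class = "stratification_error")
})

test_that("probability forest separates, bounds and nulls correctly", {
  # single perfectly separating variable -> training AUC 1
  x <- data.frame(v = c(rnorm(50, -3), rnorm(50, 3)))
  y <- rep(c(0, 1), each = 50)
  f <- fit_probability_forest(x, y, n_trees = 100, seed = 1)
  p <- predict(f, x)
  expect_equal(peacetrace:::auc_rank(p, y), 1)
  expect_true(all(p >= 0 & p <= 1))

  expect_error(fit_probability_forest(x[0, , drop = FALSE], integer(0)),
               class = "forest_error")
  expect_error(fit_probability_forest(x, rep(1, 100)),
               class = "forest_error")

  # shuffled labels -> held-out AUC ~ 0.5 across seeds (null simulation)
  aucs <- vapply(1:20, function(s) {
    set.seed(s)
    xs <- as.data.frame(matrix(rnorm(200 * 3), 200, 3))
    ys <- sample(rep(c(0, 1), each = 100))
    tr <- sample(200, 150)
    fs <- fit_probability_forest(xs[tr, ], ys[tr], n_trees = 60, seed = s)
    peacetrace:::auc_rank(predict(fs, xs[-tr, ]), ys[-tr])
  }, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})

test_that("evaluate_predictions matches closed-form oracles", {
  # constant prediction = prevalence q -> MSE = q(1-q) exactly
  y <- rep(c(1, 0), c(30, 70))
  q <- 0.3
  m <- evaluate_predictions(rep(q, 100), y)
  expect_equal(m$mse, q * (1 - q))

  # perfect probabilities -> log-loss ~ 0, accuracy-probability ~ 1
  mp <- evaluate_predictions(y, y)
  expect_lt(mp$log_loss, 1e-10)
  expect_equal(mp$log_loss_probability, 1, tolerance = 1e-10)

  # hand-computable 4-row case
  p4 <- c(0.9, 0.8, 0.3, 0.1); y4 <- c(1, 1, 0, 0)
  m4 <- evaluate_predictions(p4, y4)
  expect_equal(m4$auc, 1)
  expect_equal(m4$log_loss,
               -mean(c(log(0.9), log(0.8), log(0.7), log(0.9))))
  expect_equal(m4$log_loss_probability, exp(-m4$log_loss))

  expect_warning(m1 <- evaluate_predictions(c(0.2, 0.8), c(1, 1)),
                 "single class")
  expect_true(is.na(m1$auc))
  expect_false(is.na(m1$mse))
})

test_that("permutation importance ranks the informative variable first", {
  wins <- 0L
  for (s in 1:40) {
    sf <- signal_frame(n = 250, beta = 2, k = 4, seed = s)
    f <- fit_probability_forest(sf$x, sf$y, n_trees = 80, seed = s)
    imp <- permutation_importance(f, sf$x, sf$y, n_permutations = 3,
                                  seed = s)
    if (names(which.max(imp)) == "x1") wins <- wins + 1L
  }
  expect_gte(wins, 38L)  # >= 95% of 40 seeded runs
})

test_that("pure-noise importance is negligible and masking does not crash", {
  sf <- signal_frame(n = 400, beta = 2, k = 4, seed = 5)
  tr <- 1:300; ho <- 301:400
  f <- fit_probability_forest(sf$x[tr, ], sf$y[tr], n_trees = 150,
                              seed = 5)
  # held-out importance: noise splits do not generalize, so the noise
  # variable's error increase must be tiny both absolutely and relative
  # to the informative variable's
  imp <- permutation_importance(f, sf$x[ho, ], sf$y[ho],
                                n_permutations = 8, seed = 5)
  expect_lt(abs(imp[["x3"]]), 0.01)
  expect_lt(abs(imp[["x3"]]), 0.1 * imp[["x1"]])

  x2 <- sf$x
  x2$x1_copy <- x2$x1  # identical copy can mask the original
  f2 <- fit_probability_forest(x2, sf$y, n_trees = 80, seed = 6)
  imp2 <- permutation_importance(f2, x2, sf$y, seed = 6)
  expect_true(all(is.finite(imp2)))
})

test_that("partial dependence is flat under independence, monotone under signal", {
  sf <- signal_frame(n = 400, beta = 1.5, k = 3, seed = 7)
  f <- fit_probability_forest(sf$x, sf$y, n_trees = 150, seed = 7)
  pd_noise <- partial_dependence(f, sf$x, "x2")
  expect_true(all(pd_noise$p_no_trauma >= 0 & pd_noise$p_no_trauma <= 1))

  pd_sig <- partial_dependence(f, sf$x, "x1")
  rho <- cor(pd_sig$x1, pd_sig$p_no_trauma, method = "spearman")
  expect_gt(rho, 0.9)
  # flat within Monte-Carlo tolerance: a fraction of the signal range
  expect_lt(diff(range(pd_noise$p_no_trauma)),
            0.3 * diff(range(pd_sig$p_no_trauma)))

  pd2 <- partial_dependence(f, sf$x, c("x1", "x2"), grid_size = 5)
  expect_equal(nrow(pd2), 25L)
  expect_true(all(pd2$p_no_trauma >= 0 & pd2$p_no_trauma <= 1))
  expect_error(partial_dependence(f, sf$x, "nope"), class = "pd_error")
})

test_that("run_ensemble is reproducible and honors the draw-index contract", {
  ex <- fake_exposures(n = 200, n_draws = 5, seed = 8)
  cfg <- model_config(n_models = 3, n_trees = 40, pd_grid_size = 8,
                      seed = 11L)
  e1 <- run_ensemble(ex, cfg, region = "coast")
  e2 <- run_ensemble(ex, cfg, region = "coast")
  expect_identical(e1$runs, e2$runs)
  expect_equal(e1$runs[[2]]$draw_index, 2L)
  expect_error(run_ensemble(ex, model_config(n_models = 99), "coast"),
               class = "config_error")

  # 2D PD surfaces only for the configured leading runs
  cfg2 <- model_config(n_models = 2, n_trees = 30, pd_grid_size = 6,
                       pd_2d_runs = 1, seed = 12L)
  e3 <- run_ensemble(ex, cfg2, region = "coast")
  expect_false(is.null(e3$runs[[1]]$pd_surfaces))
  expect_null(e3$runs[[2]]$pd_surfaces)
})

test_that("a strong-signal world yields discriminating ensembles", {
  ex <- fake_exposures(n = 300, n_draws = 12, beta = 2, seed = 9)
  cfg <- model_config(n_models = 12, n_trees = 60, pd_grid_size = 8,
                      seed = 13L)
  ens <- run_ensemble(ex, cfg, region = "coast")
  aucs <- vapply(ens$runs, function(r) r$metrics$auc, numeric(1))
  expect_gt(mean(aucs), 0.85)
  # dominant predictor ranks first in mean importance
  imp <- rowMeans(vapply(ens$runs, function(r) r$importance,
                         numeric(length(ens$runs[[1]]$importance))))
  expect_equal(names(which.max(imp)), "mean_temperature")
  # PPI decreases in the trauma-increasing predictor
  s <- aggregate_runs(ens)
  pr <- s$ppi_range[s$ppi_range$variable == "mean_temperature", ]
  expect_gt(pr$p_low_end, pr$p_high_end)
})
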