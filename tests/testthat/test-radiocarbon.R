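# Independent fine-grid calibration oracle: brute-force numerical
# integration at 0.2-yr resolution, written against the math, not the
# implementation.
oracle_calibrate <- function(c14_age, error, curve, delta_r = 0,
                             step = 0.2) {
  t <- seq(min(curve$cal_bp), max(curve$cal_bp), by = step)
  mu <- approx(curve$cal_bp, curve$c14_age, t)$y
  sig <- approx(curve$cal_bp, curve$sigma, t)$y
  d <- dnorm(c14_age - delta_r, mu, sqrt(error^2 + sig^2))
  w <- d / sum(d)
  list(t = t, w = w, mode = t[which.max(d)])
}

oracle_hpd_mass <- function(or, lo, hi) sum(or$w[or$t >= lo & or$t <= hi])

test_that("read_14c_curve parses toy files and rejects bad ones", {
  f <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# header", "0,100,10", "50,150,12", "100,210,9"), f)
  cv <- read_14c_curve(f)
  expect_s3_class(cv, "cal_curve")
  expect_length(cv$cal_bp, 3L)
  expect_equal(cv$c14_age, c(100, 150, 210))

  f2 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("# only", "# comments"), f2)
  expect_error(read_14c_curve(f2), "no data rows")

  f3 <- withr::local_tempfile(fileext = ".14c")
  writeLines(c("0,100,10", "50,not_a_number,12"), f3)
  expect_error(read_14c_curve(f3), "line 2")
})

test_that("shipped stand-in curve file loads and spans the Holocene", {
  # synthetic stand-in for a real atmospheric curve (none available here)
  f <- system.file("extdata", "synthetic_shcal.14c", package = "peacetrace")
  cv <- read_14c_curve(f)
  expect_lte(min(cv$cal_bp), 0)
  expect_gte(max(cv$cal_bp), 11950)
  expect_true(all(diff(cv$cal_bp) > 0))
  expect_true(all(diff(cv$c14_age) > 0))  # built strictly increasing
})

test_that("calibration is uniform on a flat curve and always normalized", {
  fc <- flat_curve(age = 1000, sigma = 0)
  d <- calibrate_date(1000, 10, fc)
  expect_equal(sum(d$p), 1)
  expect_true(all(abs(d$p - d$p[1]) < 1e-12))  # symmetry -> uniform

  # normalization + support containment over random valid dates
  cv <- synthetic_curve("atmospheric", span = c(0, 6000))
  set.seed(1)
  for (k in 1:10) {
    age <- runif(1, 300, 5200)
    d <- calibrate_date(age, runif(1, 10, 90), cv)
    expect_equal(sum(d$p), 1, tolerance = 1e-9)
    expect_true(all(d$p >= 0))
    expect_true(min(d$cal_bp) >= min(cv$cal_bp) &&
                  max(d$cal_bp) <= max(cv$cal_bp))
  }
})

test_that("calibrate matches the fine-grid oracle (mode and HPD mass)", {
  cv <- synthetic_curve("atmospheric", span = c(0, 8000))
  for (spec in list(c(2450, 30), c(5100, 45), c(700, 15))) {
    d <- calibrate_date(spec[1], spec[2], cv)
    or <- oracle_calibrate(spec[1], spec[2], cv)
    expect_lte(abs(cal_mode(d) - or$mode), 1)  # one 1-yr grid step
    h <- cal_hpd(d, 0.954)
    # a 1-yr grid cell at year t spans [t - 0.5, t + 0.5] on the fine grid
    expect_lte(abs(oracle_hpd_mass(or, h$lo - 0.5, h$hi + 0.5) - h$mass),
               1e-3)
  }
})

test_that("calibration range errors and reservoir offsets behave", {
  cv <- linear_curve(span = c(0, 1000), slope = 1, sigma = 0)
  expect_error(calibrate_date(5000, 20, cv), class = "calibration_range_error")
  expect_error(calibrate_date(500, -5, cv), class = "calibration_error")
  # delta_r shifts the posterior like a reduced age
  d1 <- calibrate_date(600, 20, cv, delta_r = 100)
  d2 <- calibrate_date(500, 20, cv, delta_r = 0)
  expect_equal(d1$p, d2$p, tolerance = 1e-12)
})

test_that("zero-ish-error date on a monotone curve round-trips to its year", {
  cv <- linear_curve(span = c(0, 6000), slope = 1, sigma = 0)
  for (true_year in c(1234, 4321)) {
    d <- calibrate_date(true_year, 1, cv)
    expect_lte(abs(cal_mode(d) - true_year), 1)
  }
})

test_that("filter_dates uses a strict > cutoff and logs drops", {
  dd <- data.frame(lab_id = c("a", "b", "c"), error = c(30, 100, 101))
  out <- suppressMessages(filter_dates(dd))
  expect_equal(out$lab_id, c("a", "b"))  # 100 kept, 101 dropped
  expect_equal(attr(out, "n_dropped"), 1L)

  expect_equal(nrow(suppressMessages(filter_dates(dd[0, ]))), 0L)
  all_big <- data.frame(lab_id = letters[1:3], error = rep(500, 3))
  out2 <- suppressMessages(filter_dates(all_big))
  expect_equal(nrow(out2), 0L)
  expect_equal(attr(out2, "n_dropped"), 3L)
})

# Naive complete-linkage oracle: merge the closest pair of clusters by
# max pairwise age gap until the minimum is above the cutoff.
oracle_bins <- function(ages, cutoff) {
  cl <- as.list(seq_along(ages))
  repeat {
    if (length(cl) == 1L) break
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(cl)) for (j in seq_along(cl)) {
      if (i < j) {
        d <- max(abs(outer(ages[cl[[i]]], ages[cl[[j]]], "-")))
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > cutoff) break
    cl[[best[1]]] <- c(cl[[best[1]]], cl[[best[2]]])
    cl[[best[2]]] <- NULL
  }
  sort(vapply(cl, length, integer(1)))
}

test_that("bin_dates matches spec examples and the linkage oracle", {
  mk <- function(ages) data.frame(site_id = "S1",
                                  lab_id = sprintf("L%02d", seq_along(ages)),
                                  c14_age = ages)
  expect_length(bin_dates(mk(c(1000, 1150))), 1L)  # gap 150 < 200
  expect_length(bin_dates(mk(c(1000, 1300))), 2L)  # gap 300 > 200
  expect_length(bin_dates(mk(1500)), 1L)

  set.seed(42)
  for (k in 1:15) {
    ages <- sort(sample(0:4000, sample(2:9, 1)))
    bins <- bin_dates(mk(ages), cutoff = 200)
    sizes <- sort(unname(vapply(bins, function(b) length(b$idx),
                                integer(1))))
    expect_equal(sizes, oracle_bins(ages, 200))
  }
})

test_that("binning is permutation-invariant and never crosses sites", {
  set.seed(3)
  dd <- data.frame(site_id = "S1", lab_id = sprintf("L%02d", 1:8),
                   c14_age = sample(0:3000, 8))
  canon <- function(bins) {
    sig <- lapply(bins, function(b) sort(b$lab_ids))
    sig[order(vapply(sig, `[[`, "", 1))]
  }
  b1 <- bin_dates(dd)
  b2 <- bin_dates(dd[sample(8), ])
  expect_equal(canon(b1), canon(b2))

  two <- data.frame(site_id = c("A", "A", "B"), lab_id = c("a", "b", "c"),
                    c14_age = c(1000, 1050, 1010))
  bins <- bin_all_dates(two)
  expect_length(bins, 2L)
  for (b in bins) expect_length(unique(dd$site_id[b$idx]), 1L)
  expect_error(bin_dates(two), class = "binning_error")
})

test_that("build_ckde: single sharp date gives a Gaussian bump at Y", {
  grid <- seq(0, 2000, by = 10)
  Y <- 1000
  dens <- list(structure(list(cal_bp = Y, p = 1), class = "cal_density"))
  bins <- list(list(site_id = "S1", lab_ids = "L1", idx = 1L))
  k <- build_ckde(bins, dens, n_replicates = 1, bandwidth = 50,
                  grid = grid, seed = 1)
  expect_equal(grid[which.max(k$density[1, ])], Y)
  ref <- dnorm(grid, Y, 50)
  ref <- ref / peacetrace:::trapz(grid, ref)
  expect_equal(k$density[1, ], ref, tolerance = 1e-3)
})

test_that("every CKDE replicate integrates to one", {
  cv <- linear_curve(span = c(0, 4000), sigma = 0)
  set.seed(9)
  ages <- runif(20, 500, 3500)
  dens <- lapply(ages, function(a) calibrate_date(a, 20, cv))
  dd <- data.frame(site_id = rep(sprintf("S%d", 1:5), each = 4),
                   lab_id = sprintf("L%02d", 1:20), c14_age = ages)
  bins <- bin_all_dates(dd)
  grid <- seq(0, 4000, by = 20)
  k <- build_ckde(bins, dens, n_replicates = 25, bandwidth = 50,
                  grid = grid, seed = 2)
  ints <- apply(k$density, 1, function(y) peacetrace:::trapz(grid, y))
  expect_true(all(abs(ints - 1) < 1e-6))
  expect_error(build_ckde(list(), dens, grid = grid), class = "ckde_error")
})

test_that("taphonomic correction follows the survival-curve algebra", {
  grid <- seq(0, 4000, by = 20)
  flat <- matrix(1 / 4000, nrow = 2, ncol = length(grid), byrow = TRUE)
  k <- structure(list(grid = grid, density = flat, bandwidth = 50,
                      corrected = FALSE), class = "pop_kde_set")
  kc <- taphonomic_correct(k)
  expect_true(kc$corrected)
  # constant input, c < 0 => corrected density increases with age
  expect_true(all(diff(kc$density[1, ]) > 0))
  expect_equal(peacetrace:::trapz(grid, kc$density[1, ]), 1,
               tolerance = 1e-9)
  # ratio identity at two arbitrary grid years (direct evaluation oracle)
  a <- 5.726442e6; b <- 2176.4; cc <- -1.3925309
  n_t <- function(t) a * (t + b)^cc
  i <- 30L; j <- 150L
  lhs <- (kc$density[1, i] / kc$density[1, j]) /
    (k$density[1, i] / k$density[1, j])
  expect_equal(lhs, n_t(grid[j]) / n_t(grid[i]), tolerance = 1e-9)
  # t + b <= 0 guard
  k_bad <- structure(list(grid = c(-3000, 0), density = matrix(1, 1, 2),
                          bandwidth = 50, corrected = FALSE),
                     class = "pop_kde_set")
  expect_error(taphonomic_correct(k_bad), class = "taphonomy_error")
})

test_that("CKDE mean is stable across independent ensembles", {
  cv <- linear_curve(span = c(0, 3000), sigma = 0)
  set.seed(11)
  ages <- runif(30, 400, 2600)
  dens <- lapply(ages, function(a) calibrate_date(a, 25, cv))
  dd <- data.frame(site_id = rep(sprintf("S%d", 1:10), each = 3),
                   lab_id = sprintf("L%02d", 1:30), c14_age = ages)
  bins <- bin_all_dates(dd)
  grid <- seq(0, 3000, by = 25)
  k1 <- build_ckde(bins, dens, n_replicates = 150, grid = grid, seed = 1)
  k2 <- build_ckde(bins, dens, n_replicates = 150, grid = grid, seed = 2)
  m1 <- colMeans(k1$density); m2 <- colMeans(k2$density)
  se <- sqrt(apply(k1$density, 2, var) / nrow(k1$density) +
               apply(k2$density, 2, var) / nrow(k2$density))
  ok <- abs(m1 - m2) <= 3 * se + 1e-12
  expect_gte(mean(ok), 0.97)  # pointwise 3-SE agreement, allow rare tails
})
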