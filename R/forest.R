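#' Fit a probability forest
#'
#' A bagged ensemble of regression trees on a 0/1 outcome, returning the
#' estimated probability of class 1. Per-split candidate-variable
#' subsampling (`mtry`) prevents overreliance on any single predictor;
#' variance-reduction splits on the 0/1 outcome make each leaf mean a
#' class-1 probability (the regression, rather than majority-vote,
#' formulation of a random forest).
#'
#' @param x data.frame or numeric matrix of predictors.
#' @param y 0/1 outcome vector (class 1 is the event whose probability is
#'   predicted; in this package, "no trauma").
#' @param n_trees number of trees (default 500).
#' @param mtry candidate variables per split (default `floor(sqrt(p))`).
#' @param min_node minimal node size to attempt a split (default 10).
#' @param max_depth maximal tree depth; 0 = unlimited.
#' @param seed integer seed.
#' @return object of class `prob_forest`.
#' @export
fit_probability_forest <- function(x, y, n_trees = 500, mtry = NULL,
                                   min_node = 10, max_depth = 0,
                                   seed = 1L) {
  xm <- as.matrix(x)
  storage.mode(xm) <- "double"
  if (nrow(xm) == 0L) {
    stop_ctx("empty training set", class = "forest_error")
  }
  if (anyNA(xm)) stop_ctx("NA in predictors", class = "forest_error")
  if (!all(y %in% c(0, 1))) {
    stop_ctx("y must be 0/1", class = "forest_error")
  }
  if (length(unique(y)) < 2L) {
    stop_ctx("training outcome has a single class", class = "forest_error")
  }
  p <- ncol(xm)
  if (p < 1L) stop_ctx("no predictors", class = "forest_error")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  fr <- cpp_forest_fit(xm, as.numeric(y), as.integer(n_trees),
                       as.integer(mtry), as.integer(min_node),
                       as.integer(max_depth), as.integer(seed))
  structure(list(forest = fr, variables = colnames(xm), n_trees = n_trees,
                 mtry = mtry, min_node = min_node),
            class = "prob_forest")
}

#' @export
print.prob_forest <- function(x, ...) {
  cat(sprintf("<prob_forest: %d trees, mtry %d, variables: %s>\n",
              x$n_trees, x$mtry, paste(x$variables, collapse = ", ")))
  invisible(x)
}

#' Predict class-1 probabilities from a probability forest
#'
#' @param object a `prob_forest`.
#' @param newdata data.frame or matrix with the training variables.
#' @param ... unused.
#' @return numeric vector of probabilities in \[0, 1\].
#' @export
predict.prob_forest <- function(object, newdata, ...) {
  xm <- as.matrix(newdata[, object$variables, drop = FALSE])
  storage.mode(xm) <- "double"
  cpp_forest_predict(object$forest, xm)
}

# Rank-based AUC of score p for class y (ties handled by midranks).
auc_rank <- function(p, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(p)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate predicted probabilities against 0/1 outcomes
#'
#' Computes the discrimination and accuracy metrics tracked per model run:
#' AUC (rank statistic of the predicted probability against the class),
#' MSE (Brier score: mean squared error of the probability against the
#' 0/1 outcome), log-loss with probabilities clipped to
#' `[1e-15, 1 - 1e-15]`, and log-loss expressed as a probability,
#' `exp(-log_loss)`.
#'
#' @param p predicted class-1 probabilities.
#' @param y 0/1 outcomes.
#' @return list with `auc`, `mse`, `log_loss`, `log_loss_probability`.
#'   `auc` is `NA` (with a warning) when the test set has one class; the
#'   other metrics are still returned.
#' @export
evaluate_predictions <- function(p, y) {
  stopifnot(length(p) == length(y))
  if (length(y) == 0L) stop_ctx("empty test set", class = "metric_error")
  auc <- auc_rank(p, y)
  if (is.na(auc)) warning("AUC undefined: test set has a single class")
  pc <- pmin(pmax(p, 1e-15), 1 - 1e-15)
  ll <- -mean(y * log(pc) + (1 - y) * log(1 - pc))
  list(auc = auc, mse = mean((p - y)^2), log_loss = ll,
       log_loss_probability = exp(-ll))
}

#' Permutation variable importance
#'
#' For each predictor, the increase in mean-squared prediction error when
#' that column is randomly permuted (breaking its association with the
#' outcome while preserving its marginal distribution), averaged over
#' `n_permutations` shuffles. Near-zero or negative values mean the model
#' does not rely on the variable; correlated copies of an informative
#' variable can mask each other's importance.
#'
#' @param model a `prob_forest`.
#' @param x data.frame of predictors (typically held-out rows).
#' @param y 0/1 outcomes for `x`.
#' @param n_permutations shuffles per variable (default 5).
#' @param seed integer seed.
#' @return named numeric vector of mean error increases.
#' @export
permutation_importance <- function(model, x, y, n_permutations = 5,
                                   seed = 1L) {
  set.seed(seed)
  base <- mean((predict(model, x) - y)^2)
  out <- vapply(model$variables, function(v) {
    d <- 0
    for (r in seq_len(n_permutations)) {
      xp <- x
      xp[[v]] <- sample(xp[[v]])
      d <- d + mean((predict(model, xp) - y)^2) - base
    }
    d / n_permutations
  }, numeric(1))
  out
}

#' Partial dependence of the predicted probability on one or two variables
#'
#' For each grid value (equally spaced between the variable's 1st and
#' 99th percentiles unless an explicit grid is given), every row of `x`
#' has the variable forced to that value and the mean model prediction is
#' recorded — the average response with all other variables held at their
#' observed values. With two variables the Cartesian grid is used.
#'
#' @param model a `prob_forest`.
#' @param x data.frame of predictor rows to average over.
#' @param variables one or two variable names.
#' @param grid_size points per variable (default 25).
#' @param grids optional named list of fixed grids (shared across ensemble
#'   runs so curves aggregate pointwise).
#' @return data.frame with the grid column(s) and `p_no_trauma`.
#' @export
partial_dependence <- function(model, x, variables, grid_size = 25,
                               grids = NULL) {
  if (!all(variables %in% model$variables)) {
    stop_ctx("unknown variable(s): ",
             paste(setdiff(variables, model$variables), collapse = ", "),
             class = "pd_error")
  }
  if (!length(variables) %in% 1:2) {
    stop_ctx("partial dependence takes 1 or 2 variables", class = "pd_error")
  }
  mk_grid <- function(v) {
    if (!is.null(grids) && !is.null(grids[[v]])) return(grids[[v]])
    q <- quantile(x[[v]], c(0.01, 0.99), names = FALSE)
    if (q[1] == q[2]) return(q[1])
    seq(q[1], q[2], length.out = grid_size)
  }
  xm <- as.matrix(x[, model$variables, drop = FALSE])
  storage.mode(xm) <- "double"
  if (length(variables) == 1L) {
    v <- variables
    g <- mk_grid(v)
    p <- cpp_partial_dependence(model$forest, xm,
                                match(v, model$variables) - 1L,
                                as.numeric(g))
    out <- data.frame(g, p_no_trauma = p)
    names(out)[1] <- v
    out
  } else {
    g1 <- mk_grid(variables[1])
    g2 <- mk_grid(variables[2])
    p <- cpp_partial_dependence2(model$forest, xm,
                                 match(variables[1], model$variables) - 1L,
                                 match(variables[2], model$variables) - 1L,
                                 as.numeric(g1), as.numeric(g2))
    grid <- expand.grid(g1, g2)
    names(grid) <- variables
    grid$p_no_trauma <- p
    grid
  }
}
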