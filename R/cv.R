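#' Median absolute error
#'
#' The median of absolute prediction errors (median, not mean, throughout
#' this package). Even-length samples use the usual mid-point convention.
#'
#' @param y_true,y_pred numeric vectors of equal, positive length.
#' @return the MAE in the units of `y` (days).
#' @export
mae <- function(y_true, y_pred) {
  if (!length(y_true) || length(y_true) != length(y_pred)) {
    stop("y_true and y_pred must have equal, positive length")
  }
  median(abs(y_true - y_pred))
}

# run expr with a local RNG state derived from `seed`, restoring the
# caller's stream afterwards
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# permutation-derived partition of n samples into k folds of near-equal size
make_folds <- function(n, k, seed) {
  if (k < 2L || k > n) stop("fold count must satisfy 2 <= k <= n")
  perm <- with_seed(seed, sample.int(n))
  folds <- integer(n)
  folds[perm] <- rep(seq_len(k), length.out = n)
  folds
}

#' Cross-validated MAE curve along the penalty path
#'
#' Splits the samples into `k` folds (a permutation-derived partition from
#' `seed`), fits the grouped elastic-net path on each training set, pools
#' the out-of-fold predictions over all folds, and returns the MAE over all
#' samples for each penalty. Every sample is predicted exactly once.
#'
#' @inheritParams fit_penalized_path
#' @param k number of folds (each training fold must keep >= 2 samples).
#' @param seed integer controlling the fold assignment.
#' @param lambda descending penalty path, shared across folds (computed on
#'   the full data when `NULL`).
#' @param pooled pool out-of-fold predictions over all samples before
#'   taking the MAE (default); `FALSE` averages the per-fold MAEs instead.
#' @return list with `lambda`, `cv_mae_curve` (per penalty), `lambda_opt`,
#'   `cv_mae` (the curve minimum), `folds` (the assignment) and
#'   `predictions` (samples x penalties out-of-fold predictions).
#' @export
cross_validate <- function(X, y, groups = NULL, alpha, lambda = NULL,
                           k = 3L, seed = 1L, pooled = TRUE) {
  n <- nrow(X)
  if (is.null(groups)) groups <- paste0("site", seq_len(ncol(X)))
  if (is.null(lambda)) lambda <- lambda_path(X, y, groups, alpha)
  folds <- make_folds(n, k, seed)
  if (min(n - tabulate(folds, k)) < 2L) {
    stop("a training fold would have fewer than 2 samples")
  }
  preds <- matrix(NA_real_, n, length(lambda))
  for (f in seq_len(k)) {
    test <- folds == f
    fit <- fit_penalized_path(X[!test, , drop = FALSE], y[!test],
                              groups, alpha, lambda)
    preds[test, ] <- X[test, , drop = FALSE] %*% fit$beta +
      matrix(fit$intercept, sum(test), length(lambda), byrow = TRUE)
  }
  curve <- if (pooled) {
    apply(preds, 2L, function(p) mae(y, p))
  } else {
    rowMeans(vapply(seq_len(k), function(f) {
      apply(preds[folds == f, , drop = FALSE], 2L,
            function(p) mae(y[folds == f], p))
    }, numeric(length(lambda))))
  }
  iopt <- which.min(curve)
  list(lambda = lambda, cv_mae_curve = curve, lambda_opt = lambda[iopt],
       cv_mae = curve[iopt], folds = folds, predictions = preds)
}

#' Fit one clock candidate
#'
#' Runs [cross_validate()] for one (grouping scheme, alpha, fold count,
#' fold-assignment seed) combination, refits on all samples at the
#' CV-optimal penalty, and packages the result.
#'
#' @param design a `clock_design` from [build_design_matrix()].
#' @param scheme grouping scheme (subset of the four site features; see
#'   [make_group_labels()]).
#' @param alpha penalty-mixing factor.
#' @param k fold count.
#' @param seed fold-assignment seed for this iteration.
#' @param lambda optional penalty path; computed on the full design when
#'   `NULL`.
#' @param full_fit optional precomputed [fit_penalized_path()] result on
#'   the full design for the same `lambda` (reused across iterations by
#'   [grid_search()]).
#' @return a `fitted_clock`: list with `intercept`, `beta` (named per
#'   site), `lambda`, `alpha`, `scheme`, `k`, `seed`, `n_selected`,
#'   `cv_mae`, `train_mae`, `meta` (site metadata), `ages`, `dataset`.
#' @export
fit_candidate <- function(design, scheme = character(0), alpha, k = 3L,
                          seed = 1L, lambda = NULL, full_fit = NULL) {
  groups <- make_group_labels(design$meta, scheme)
  if (is.null(lambda)) {
    lambda <- lambda_path(design$X, design$ages, groups, alpha)
  }
  cv <- cross_validate(design$X, design$ages, groups, alpha, lambda,
                       k = k, seed = seed)
  if (is.null(full_fit)) {
    full_fit <- fit_penalized_path(design$X, design$ages, groups, alpha,
                                   lambda)
  }
  iopt <- which.min(cv$cv_mae_curve)
  beta <- full_fit$beta[, iopt]
  b0 <- full_fit$intercept[iopt]
  train_pred <- as.numeric(design$X %*% beta + b0)
  structure(list(
    intercept = b0,
    beta = setNames(beta, colnames(design$X)),
    lambda = cv$lambda_opt, alpha = alpha,
    scheme = as.character(scheme), k = as.integer(k),
    seed = as.integer(seed),
    n_selected = sum(beta != 0),
    cv_mae = cv$cv_mae,
    train_mae = mae(design$ages, train_pred),
    meta = design$meta, ages = design$ages, dataset = design$dataset
  ), class = "fitted_clock")
}

#' @export
print.fitted_clock <- function(x, ...) {
  scheme <- if (length(x$scheme)) paste(x$scheme, collapse = "+") else "none"
  cat("fitted_clock (", x$dataset, "): alpha=", x$alpha,
      ", grouping=", scheme, ", k=", x$k, "\n",
      "  cv MAE ", round(x$cv_mae, 3), " d; train MAE ",
      round(x$train_mae, 3), " d; ", x$n_selected, "/",
      length(x$beta), " sites selected\n", sep = "")
  invisible(x)
}
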