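#' Group labels from site features
#'
#' Builds the per-site penalty-group label for a grouping scheme: a subset
#' of the four site features {`gene`, `mod_type`, `coverage`,
#' `reliability`}. The selected features' values are pasted together with
#' `"|"` in that fixed order, so sites sharing the pasted label are
#' penalized as one group. Quantitative features are discretized before
#' pasting: `mean_coverage` is rounded to the nearest integer and
#' `mean_reliability` to 1 decimal. The empty scheme gives every site its
#' own label (no grouping: ordinary elastic net).
#'
#' @param meta site metadata data frame with columns `gene`, `mod_type`,
#'   `mean_coverage`, `mean_reliability`.
#' @param scheme character vector, a subset of
#'   `c("gene", "mod_type", "coverage", "reliability")`; `character(0)` for
#'   no grouping.
#' @return character vector of group labels, one per site.
#' @export
make_group_labels <- function(meta, scheme = character(0)) {
  features <- c("gene", "mod_type", "coverage", "reliability")
  scheme <- as.character(scheme)
  if (length(setdiff(scheme, features))) {
    stop("unknown grouping feature(s): ",
         paste(setdiff(scheme, features), collapse = ", "))
  }
  if (!length(scheme)) {
    return(paste0("site", seq_len(nrow(meta))))
  }
  cols <- list(gene = meta$gene,
               mod_type = meta$mod_type,
               coverage = as.character(round(meta$mean_coverage)),
               reliability = as.character(round(meta$mean_reliability, 1)))
  use <- cols[features[features %in% scheme]]
  if (any(vapply(use, function(v) anyNA(v) || any(!nzchar(v)), logical(1L)))) {
    stop("missing site feature value for grouping")
  }
  do.call(paste, c(use, sep = "|"))
}

#' All 16 grouping schemes
#'
#' Every subset of the four groupable site features, from no grouping to
#' all four pasted together.
#'
#' @return named list of 16 character vectors (the names are the pasted
#'   feature names, `"none"` for the empty scheme).
#' @export
all_schemes <- function() {
  features <- c("gene", "mod_type", "coverage", "reliability")
  out <- list()
  for (k in 0:4) {
    for (s in combn(4, k, simplify = FALSE)) {
      sel <- features[s]
      nm <- if (length(sel)) paste(sel, collapse = "+") else "none"
      out[[nm]] <- sel
    }
  }
  out
}

# Standardize columns to mean 0 and population variance 1 (divide by n).
# Zero-variance columns are flagged; they are excluded from the solve and
# their coefficients forced to 0.
standardize_columns <- function(X) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  keep <- sdv > 0
  Xs <- sweep(X[, keep, drop = FALSE], 2L, mu[keep])
  Xs <- sweep(Xs, 2L, sdv[keep], "/")
  list(Xs = Xs, mu = mu, sd = sdv, keep = keep)
}

# Precompute everything about (X, y, groups) that does not depend on alpha
# or lambda: standardization, group-contiguous column ordering and group
# offsets. Reused across the penalty grid by grid_search().
grpnet_prepare <- function(X, y, groups) {
  n <- nrow(X); p <- ncol(X)
  std <- standardize_columns(X)
  keep_idx <- which(std$keep)
  g <- groups[keep_idx]
  ord <- order(g)
  Xo <- std$Xs[, ord, drop = FALSE]
  runs <- rle(g[ord])
  grp_end <- cumsum(runs$lengths)
  grp_start <- grp_end - runs$lengths + 1L
  list(Xo = Xo, yc = y - mean(y), ymean = mean(y), mu = std$mu,
       sd = std$sd, keep_idx = keep_idx, ord = ord,
       grp_start = grp_start, grp_end = grp_end,
       w = sqrt(runs$lengths), n = n, p = p,
       gty = as.numeric(crossprod(Xo, y - mean(y))))
}

# group norms ||X_g' yc||_2 / w_g over the prepared (ordered) columns
prep_group_scores <- function(prep) {
  v2 <- prep$gty^2
  sums <- vapply(seq_along(prep$grp_start), function(i) {
    sum(v2[prep$grp_start[i]:prep$grp_end[i]])
  }, numeric(1L))
  sqrt(sums) / prep$w
}

# solve the path for one alpha on a prepared problem; returns coefficients
# on the original scale plus intercepts (same arithmetic as
# fit_penalized_path, which wraps this)
grpnet_engine <- function(prep, alpha, lambda, tol = 1e-4, maxit = 10000L,
                          want_std = FALSE) {
  L <- length(lambda)
  beta <- matrix(0, prep$p, L)
  beta_std <- if (want_std) matrix(0, prep$p, L)
  if (length(prep$keep_idx)) {
    bpath <- grpnet_path_cpp(prep$Xo, prep$yc,
                             as.integer(prep$grp_start - 1L),
                             as.integer(prep$grp_end - 1L), prep$w, alpha,
                             lambda, tol, as.integer(maxit))
    jj <- prep$keep_idx[prep$ord]
    beta[jj, ] <- bpath / prep$sd[jj]
    if (want_std) beta_std[jj, ] <- bpath
  }
  intercept <- prep$ymean - as.numeric(crossprod(beta, prep$mu))
  list(beta = beta, intercept = intercept, beta_std = beta_std)
}

#' Largest penalty on the path
#'
#' The smallest penalty at which every coefficient is exactly zero for the
#' group elastic net: `max_g ||X_g' (y - mean(y))||_2 / (n * max(alpha,
#' 0.001) * w_g)` over standardized predictor groups, with group weight
#' `w_g = sqrt(|g|)`. The `max(alpha, 0.001)` floor keeps the path finite
#' for pure ridge.
#'
#' @param X predictor matrix (raw scale; standardized internally).
#' @param y response vector.
#' @param groups group label per column.
#' @param alpha penalty-mixing factor in `[0, 1]`.
#' @return the scalar `lambda_max`.
#' @export
lambda_max <- function(X, y, groups = colnames(X), alpha) {
  prep <- grpnet_prepare(X, y, groups)
  s <- prep_group_scores(prep)
  if (!length(s)) return(NA_real_)  # no non-constant columns
  max(s) / (prep$n * max(alpha, 0.001))
}

#' Descending log-spaced penalty path
#'
#' @inheritParams lambda_max
#' @param nlambda number of penalties (default 100).
#' @param lambda_min_ratio smallest penalty as a fraction of `lambda_max`
#'   (default 0.01, the usual choice when sites outnumber samples).
#' @return strictly descending numeric vector.
#' @export
lambda_path <- function(X, y, groups = colnames(X), alpha,
                        nlambda = 100L, lambda_min_ratio = 0.01) {
  lmax <- lambda_max(X, y, groups, alpha)
  lambda_path_from_max(lmax, nlambda, lambda_min_ratio)
}

lambda_path_from_max <- function(lmax, nlambda = 100L,
                                 lambda_min_ratio = 0.01) {
  # a degenerate problem (all columns constant, or y constant) has no
  # finite positive lambda_max; any descending path gives the null model
  if (!is.finite(lmax) || lmax <= 0) lmax <- 1
  exp(seq(log(lmax), log(lmax * lambda_min_ratio), length.out = nlambda))
}

#' Fit the grouped elastic-net coefficient path
#'
#' Solves, for each penalty on a descending path (with warm starts),
#' \deqn{\min_{b_0,\beta}\ \frac{1}{2n}\sum_i (y_i - b_0 - x_i^\top\beta)^2
#'   + \lambda \sum_g w_g\left[\alpha\,\lVert\beta_g\rVert_2 +
#'   \frac{1-\alpha}{2}\,\lVert\beta_g\rVert_2^2\right]}
#' with group weights \eqn{w_g = \sqrt{|g|}}, by block coordinate descent
#' on internally standardized predictors. With all-singleton groups the
#' penalty reduces to the ordinary elastic net
#' (\eqn{\alpha\lVert\beta\rVert_1 + \frac{1-\alpha}{2}
#' \lVert\beta\rVert_2^2}). Coefficients are returned on the original
#' predictor scale; zero-variance columns get coefficient 0.
#'
#' @param X numeric predictor matrix (samples x sites), raw scale.
#' @param y numeric response (ages, days post-hatch).
#' @param groups group label per column; default every column its own
#'   group.
#' @param alpha penalty-mixing factor: 0 = ridge, 1 = (group) lasso.
#' @param lambda descending penalty path; computed by [lambda_path()] when
#'   `NULL`.
#' @param tol coordinate-descent convergence tolerance on the maximum
#'   standardized-coefficient change per sweep. The default suits model
#'   selection; pass a tighter value (e.g. `1e-10`) for solver-accuracy
#'   studies.
#' @param maxit maximum sweeps per penalty.
#' @return list with `beta` (sites x penalties matrix, original scale),
#'   `intercept` (per penalty), `lambda`, `alpha`, `groups`, and
#'   `beta_std` (standardized-scale coefficients, for objective checks).
#' @export
fit_penalized_path <- function(X, y, groups = NULL, alpha,
                               lambda = NULL, tol = 1e-4, maxit = 10000L) {
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("non-finite values in predictors or response")
  }
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1) {
    stop("alpha must lie in [0, 1]")
  }
  n <- nrow(X); p <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)")
  if (is.null(groups)) groups <- paste0("site", seq_len(p))
  if (length(groups) != p) stop("one group label per column required")
  prep <- grpnet_prepare(X, y, groups)
  if (is.null(lambda)) {
    s <- prep_group_scores(prep)
    smax <- if (length(s)) max(s) else NA_real_
    lambda <- lambda_path_from_max(smax / (n * max(alpha, 0.001)))
  }
  if (any(diff(lambda) >= 0)) stop("lambda path must be strictly descending")
  sol <- grpnet_engine(prep, alpha, lambda, tol, maxit, want_std = TRUE)
  rownames(sol$beta) <- rownames(sol$beta_std) <- colnames(X)
  list(beta = sol$beta, intercept = sol$intercept, lambda = lambda,
       alpha = alpha, groups = groups, beta_std = sol$beta_std)
}

#' Objective value of the grouped elastic net
#'
#' Evaluates the penalized objective on the standardized scale for given
#' standardized coefficients; used to compare solutions between solvers.
#'
#' @param X raw predictor matrix.
#' @param y response vector.
#' @param beta_std standardized-scale coefficients (one column of
#'   `beta_std` from [fit_penalized_path()]).
#' @inheritParams fit_penalized_path
#' @param lambda a single penalty value.
#' @return the scalar objective value.
#' @export
grpnet_objective <- function(X, y, beta_std, groups, alpha, lambda) {
  std <- standardize_columns(X)
  yc <- y - mean(y)
  b <- beta_std[std$keep]
  g <- groups[std$keep]
  rss <- sum((yc - std$Xs %*% b)^2) / (2 * nrow(X))
  pen <- sum(vapply(split(seq_along(b), g), function(j) {
    nrm <- sqrt(sum(b[j]^2))
    sqrt(length(j)) * (alpha * nrm + (1 - alpha) / 2 * nrm^2)
  }, numeric(1L)))
  rss + lambda * pen
}
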