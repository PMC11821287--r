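# Independent convex-optimization oracle for the grouped elastic net:
# accelerated proximal gradient (FISTA) with restart-free fixed steps,
# written against the objective definition only — shares no code with the
# package's block coordinate-descent path solver.
#
#   min_b (1/2n)||yc - Xs b||^2
#         + lambda * sum_g w_g [ alpha ||b_g|| + (1-alpha)/2 ||b_g||^2 ]
#
# on columns standardized to population variance 1, like the solver.
oracle_grpnet <- function(X, y, groups, alpha, lambda,
                          max_iter = 200000L, tol = 1e-14) {
  n <- nrow(X)
  mu <- colMeans(X)
  sdv <- sqrt(colMeans(sweep(X, 2L, mu)^2))
  keep <- sdv > 0
  Xs <- sweep(sweep(X[, keep, drop = FALSE], 2L, mu[keep]), 2L,
              sdv[keep], "/")
  yc <- y - mean(y)
  gi <- split(seq_len(ncol(Xs)), groups[keep])
  wg <- sqrt(lengths(gi))
  wvec <- numeric(ncol(Xs))
  for (k in seq_along(gi)) wvec[gi[[k]]] <- wg[k]

  objective <- function(b) {
    s <- sum((yc - Xs %*% b)^2) / (2 * n)
    for (k in seq_along(gi)) {
      nb <- sqrt(sum(b[gi[[k]]]^2))
      s <- s + lambda * wg[k] * (alpha * nb + (1 - alpha) / 2 * nb^2)
    }
    s
  }

  if (ncol(Xs) == 0L) {
    out <- numeric(ncol(X))
    return(list(beta_std = out, objective = objective(numeric(0L))))
  }

  Lip <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                   only.values = TRUE)$values) +
    lambda * (1 - alpha) * max(wg)
  b <- z <- numeric(ncol(Xs))
  t_k <- 1
  prev <- objective(b)
  for (it in seq_len(max_iter)) {
    grad <- -crossprod(Xs, yc - Xs %*% z) / n +
      lambda * (1 - alpha) * wvec * z
    u <- as.numeric(z - grad / Lip)
    bn <- u
    for (k in seq_along(gi)) {
      idx <- gi[[k]]
      nu <- sqrt(sum(u[idx]^2))
      thr <- lambda * alpha * wg[k] / Lip
      bn[idx] <- if (nu <= thr) 0 else (1 - thr / nu) * u[idx]
    }
    t_next <- (1 + sqrt(1 + 4 * t_k^2)) / 2
    z <- bn + ((t_k - 1) / t_next) * (bn - b)
    b <- bn
    t_k <- t_next
    if (it %% 100L == 0L) {
      cur <- objective(b)
      if (abs(prev - cur) < tol * max(1, abs(cur))) break
      prev <- cur
    }
  }
  beta_std <- numeric(ncol(X))
  beta_std[keep] <- b
  list(beta_std = beta_std, objective = objective(b))
}
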