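ages6 <- c(10, 12, 14, 17, 19, 24)

test_that("group labels paste selected features in fixed order", {
  meta <- data.frame(gene = c("ND1", "ND1", "COX1"),
                     mod_type = c("6mA", "6mA", "5mC"),
                     mean_coverage = c(3.2, 2.6, 3.0),
                     mean_reliability = c(0.96, 1.0, 0.87),
                     stringsAsFactors = FALSE)
  expect_equal(make_group_labels(meta, c("gene", "mod_type")),
               c("ND1|6mA", "ND1|6mA", "COX1|5mC"))
  # feature order is fixed regardless of how the scheme is written
  expect_equal(make_group_labels(meta, c("mod_type", "gene")),
               make_group_labels(meta, c("gene", "mod_type")))
  # quantitative features are discretized before pasting
  expect_equal(make_group_labels(meta, c("coverage", "reliability")),
               c("3|1", "3|1", "3|0.9"))
  # empty scheme: every site its own group
  expect_equal(anyDuplicated(make_group_labels(meta, character(0))), 0L)
  expect_error(make_group_labels(meta, "colour"), "unknown")
  meta$gene[2] <- NA
  expect_error(make_group_labels(meta, "gene"), "missing")
})

test_that("all 16 grouping schemes are enumerated", {
  s <- all_schemes()
  expect_length(s, 16L)
  expect_equal(as.integer(table(lengths(s))), c(1L, 4L, 6L, 4L, 1L))
  expect_equal(anyDuplicated(names(s)), 0L)
  expect_true("none" %in% names(s))
})

test_that("MAE is the median absolute error with mid-point convention", {
  expect_equal(mae(c(0, 0, 0), c(1, 2, 10)), 2)
  expect_equal(mae(ages6, ages6), 0)
  expect_equal(mae(c(0, 0), c(1, 3)), 2)
  expect_error(mae(numeric(0), numeric(0)))
})

test_that("all coefficients vanish at lambda_max; ridge never zeroes", {
  inst <- random_instance(6, 10, seed = 1)
  lmax <- lambda_max(inst$X, inst$y, alpha = 1)
  fit <- fit_penalized_path(inst$X, inst$y, alpha = 1,
                            lambda = c(2 * lmax, lmax * 1.000001,
                                       lmax * 0.5))
  expect_true(all(fit$beta[, 1] == 0))
  expect_true(all(fit$beta[, 2] == 0))
  expect_equal(fit$intercept[1], mean(inst$y))
  expect_true(any(fit$beta[, 3] != 0))
  # ridge shrinks but never zeroes
  rfit <- fit_penalized_path(inst$X, inst$y, alpha = 0)
  expect_true(all(rfit$beta[, 100] != 0))
  expect_error(fit_penalized_path(inst$X, inst$y, alpha = 1.2), "alpha")
  bad <- inst$X; bad[1, 1] <- NA
  expect_error(fit_penalized_path(bad, inst$y, alpha = 1), "non-finite")
})

test_that("singleton-group path matches glmnet's lasso coefficients", {
  skip_if_not_installed("glmnet")
  inst <- random_instance(8, 12, seed = 3)
  fit <- fit_penalized_path(inst$X, inst$y, alpha = 1, tol = 1e-10)
  g <- glmnet::glmnet(inst$X, inst$y, alpha = 1, lambda = fit$lambda,
                      standardize = TRUE, thresh = 1e-14)
  expect_lt(max(abs(fit$beta - as.matrix(g$beta))), 1e-5)
  expect_lt(max(abs(fit$intercept - as.numeric(g$a0))), 1e-4)
})

test_that("ridge solution matches the closed form on standardized data", {
  inst <- random_instance(6, 9, seed = 5)
  fit <- fit_penalized_path(inst$X, inst$y, alpha = 0, tol = 1e-10)
  n <- nrow(inst$X)
  mu <- colMeans(inst$X)
  sdv <- sqrt(colMeans(sweep(inst$X, 2, mu)^2))
  Xs <- sweep(sweep(inst$X, 2, mu), 2, sdv, "/")
  yc <- inst$y - mean(inst$y)
  for (i in c(20L, 60L, 100L)) {
    closed <- solve(crossprod(Xs) / n + fit$lambda[i] * diag(ncol(Xs)),
                    crossprod(Xs, yc) / n)
    expect_lt(max(abs(closed - fit$beta_std[, i])), 1e-8)
  }
})

test_that("alpha = 1 with multi-site groups gives group sparsity", {
  inst <- random_instance(6, 12, seed = 9, grouped = TRUE)
  fit <- fit_penalized_path(inst$X, inst$y, inst$groups, alpha = 1,
                            tol = 1e-10)
  for (i in seq_along(fit$lambda)) {
    for (g in unique(inst$groups)) {
      b <- fit$beta[inst$groups == g, i]
      expect_true(all(b == 0) || all(b != 0))
    }
  }
})

test_that("cross-validation pools out-of-fold predictions exactly once", {
  inst <- random_instance(6, 20, seed = 13)
  cv <- cross_validate(inst$X, inst$y, alpha = 0.5, k = 3, seed = 7)
  expect_false(anyNA(cv$predictions))
  expect_equal(sort(unique(cv$folds)), 1:3)
  expect_equal(tabulate(cv$folds), c(2L, 2L, 2L))
  expect_equal(cv$cv_mae, min(cv$cv_mae_curve))
  # deterministic: same seed, same folds and curve
  cv2 <- cross_validate(inst$X, inst$y, alpha = 0.5, k = 3, seed = 7)
  expect_identical(cv2$folds, cv$folds)
  expect_identical(cv2$cv_mae_curve, cv$cv_mae_curve)
  # at lambda >= lambda_max the CV predictor is the training-fold mean
  lmax <- lambda_max(inst$X, inst$y, alpha = 0.5)
  cvm <- cross_validate(inst$X, inst$y, alpha = 0.5,
                        lambda = c(3 * lmax, 1.5 * lmax), k = 3, seed = 7)
  for (f in 1:3) {
    test <- cvm$folds == f
    expect_equal(unname(cvm$predictions[test, 1]),
                 rep(mean(inst$y[!test]), sum(test)))
  }
  small <- random_instance(3, 8, seed = 2)
  expect_error(cross_validate(small$X, small$y, alpha = 0.5, k = 2,
                              seed = 1),
               "fewer than 2")
})

test_that("a noise-free linear site is found and fitted to ~zero error", {
  set.seed(21)
  X <- matrix(runif(6 * 10, 0, 100), 6, 10)
  X[, 4] <- (ages6 - 10) * (100 / 14)  # exact linear encoding of age
  colnames(X) <- paste0("MT:", 1:10, ":+:6mA")
  design <- structure(list(
    X = X, ages = ages6,
    meta = data.frame(gene = rep(c("ND1", "COX1"), 5),
                      mod_type = "6mA", mean_coverage = 3,
                      mean_reliability = 0.9, stringsAsFactors = FALSE),
    dataset = "full"), class = "clock_design")
  clock <- fit_candidate(design, character(0), alpha = 1, k = 3, seed = 1)
  expect_lt(clock$train_mae, 0.3)
  expect_true(clock$beta[4] != 0)
  # predictions on the training matrix reproduce train_mae exactly
  expect_identical(mae(ages6, predict_ages(clock, X)), clock$train_mae)
})

test_that("a constant design yields the mean-age predictor", {
  X <- matrix(55, 6, 5, dimnames = list(NULL, paste0("s", 1:5)))
  design <- structure(list(
    X = X, ages = ages6,
    meta = data.frame(gene = rep("ND1", 5), mod_type = "5mC",
                      mean_coverage = 3, mean_reliability = 0.9,
                      stringsAsFactors = FALSE),
    dataset = "full"), class = "clock_design")
  clock <- fit_candidate(design, character(0), alpha = 0.5, k = 3, seed = 2)
  expect_true(all(clock$beta == 0))
  expect_equal(unname(predict_ages(clock, X)), rep(mean(ages6), 6))
  expect_equal(clock$train_mae, mae(ages6, rep(mean(ages6), 6)))
})

test_that("the dual standardized-MAE criterion selects and breaks ties", {
  cands <- data.frame(cv_mae = c(2, 3), train_mae = c(1, 0.5),
                      alpha = c(0.3, 0.2), iteration = c(1L, 1L))
  sel <- select_best(cands)
  # hand z-scores: both rows score 0; tie broken by lower cv_mae
  expect_equal(sel$score, c(0, 0), tolerance = 1e-12)
  expect_equal(sel$best, 1L)
  # single candidate: itself, score 0 (sd = 0 columns contribute 0)
  expect_equal(select_best(cands[1, ])$best, 1L)
  expect_equal(select_best(cands[1, ])$score, 0)
  # dominating candidate wins
  dom <- data.frame(cv_mae = c(1, 3), train_mae = c(0.2, 0.8),
                    alpha = c(0.5, 0.1), iteration = c(1L, 2L))
  expect_equal(select_best(dom)$best, 1L)
  expect_error(select_best(dom[0, ]), "no candidates")
})

test_that("selection ranking is invariant under common affine transforms", {
  set.seed(31)
  cands <- data.frame(cv_mae = runif(40, 1, 5), train_mae = runif(40, 0, 2),
                      alpha = rep(seq(0, 1, length.out = 8), 5),
                      iteration = rep(1:5, each = 8))
  best0 <- select_best(cands)$best
  for (tr in list(c(2.5, 1), c(0.1, -3), c(7, 0))) {
    shifted <- cands
    shifted$cv_mae <- tr[1] * cands$cv_mae + tr[2]
    shifted$train_mae <- tr[1] * cands$train_mae + tr[2]
    expect_equal(select_best(shifted)$best, best0)
  }
})

test_that("grid search bookkeeping: one row per candidate, reproducible", {
  gen <- generate_dataset(synthetic_config(n_spike = 4, n_ramp = 4,
                                           n_constant = 10, n_incomplete = 0,
                                           n_conflict = 0, seed = 17),
                          tempfile())
  design <- dataset_to_design(gen, ages6)
  ss <- grid_search(design, alphas = c(0, 1),
                    schemes = all_schemes()["gene"], B = 2, base_seed = 5)
  expect_equal(nrow(ss$candidates), 4L)
  expect_equal(unique(ss$candidates$scheme), "gene")
  expect_s3_class(ss$best_clock, "fitted_clock")
  # re-running with the same base seed reproduces the summary exactly
  ss2 <- grid_search(design, alphas = c(0, 1),
                     schemes = all_schemes()["gene"], B = 2, base_seed = 5)
  expect_identical(ss2$candidates, ss$candidates)
  expect_identical(ss2$best_clock$beta, ss$best_clock$beta)
})

test_that("age prediction applies the linear clock and checks sites", {
  clock <- structure(list(
    intercept = 10, beta = c(`MT:5:+:6mA` = 0.1),
    meta = data.frame(gene = "ND1", mod_type = "6mA"),
    ages = ages6, dataset = "full"), class = "fitted_clock")
  X <- matrix(50, 1, 1, dimnames = list(NULL, "MT:5:+:6mA"))
  expect_equal(predict_ages(clock, X), 15)
  expect_equal(predict_ages(clock, X * 0), 10)  # all-zero row -> intercept
  bad <- matrix(1, 1, 1, dimnames = list(NULL, "MT:9:+:6mA"))
  expect_error(predict_ages(clock, bad), "MT:5")
})

test_that("gene importance sums absolute coefficients per gene", {
  clock <- structure(list(
    intercept = 0,
    beta = c(a = 0.2, b = -0.3, c = 0.5),
    meta = data.frame(gene = c("ND1", "ND1", "COX1")),
    dataset = "full"), class = "fitted_clock")
  imp <- gene_importance(clock)
  expect_equal(sum(imp$proportion), 1)
  expect_equal(imp$proportion[imp$gene == "ND1"], 0.5)
  expect_equal(imp$proportion[imp$gene == "COX1"], 0.5)
  expect_equal(imp$n_selected[imp$gene == "ND1"], 2L)
  # one gene only -> 100%
  clock$meta$gene <- "ND5"
  expect_equal(gene_importance(clock)$proportion, 1)
  clock$beta[] <- 0
  expect_error(gene_importance(clock), "undefined")
})

test_that("scaled MAE divides by the age range", {
  expect_equal(scaled_mae(0, 10, 24), 0)
  expect_equal(scaled_mae(14, 10, 24), 1)
  expect_error(scaled_mae(1, 24, 24), "exceed")
})
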