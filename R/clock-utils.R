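#' Predict ages from a fitted clock
#'
#' Applies `b0 + X beta` to a new methylation matrix. Columns are matched
#' to the clock's sites by site key (the `contig:pos:strand:mod_type`
#' column names of the design matrix); every site the clock was fitted on
#' must be present.
#'
#' @param clock a `fitted_clock`.
#' @param X_new numeric matrix (samples x sites) of methylation levels (%),
#'   with site keys as column names.
#' @return numeric vector of predicted ages (days post-hatch).
#' @export
predict_ages <- function(clock, X_new) {
  if (!all(is.finite(X_new))) stop("non-finite methylation levels in X_new")
  need <- names(clock$beta)
  missing_sites <- setdiff(need, colnames(X_new))
  if (length(missing_sites)) {
    stop("X_new is missing clock site(s): ",
         paste(utils::head(missing_sites, 5L), collapse = ", "),
         if (length(missing_sites) > 5L) " ...")
  }
  as.numeric(X_new[, need, drop = FALSE] %*% clock$beta + clock$intercept)
}

#' @export
predict.fitted_clock <- function(object, newdata, ...) {
  predict_ages(object, newdata)
}

#' Gene importance of a fitted clock
#'
#' For each gene, the sum of the absolute coefficients of its sites as a
#' fraction of the total over all sites — a weight-based importance that,
#' unlike the raw count of selected sites per gene, is not tied to the
#' penalty mix. Selected-site counts per gene are reported alongside.
#'
#' @param clock a `fitted_clock` (site metadata is carried inside).
#' @return data frame with `gene`, `sum_abs_coef`, `proportion`,
#'   `n_sites`, `n_selected`, sorted by decreasing proportion; the
#'   proportions sum to 1.
#' @export
gene_importance <- function(clock) {
  ab <- abs(clock$beta)
  if (sum(ab) == 0) {
    stop("all coefficients are zero; gene importance is undefined")
  }
  gene <- clock$meta$gene
  agg <- tapply(ab, gene, sum)
  nsel <- tapply(clock$beta != 0, gene, sum)
  nsite <- tapply(rep(1L, length(gene)), gene, sum)
  out <- data.frame(gene = names(agg),
                    sum_abs_coef = as.numeric(agg),
                    proportion = as.numeric(agg) / sum(ab),
                    n_sites = as.integer(nsite),
                    n_selected = as.integer(nsel),
                    stringsAsFactors = FALSE)
  out[order(-out$proportion), , drop = FALSE]
}

#' MAE scaled to the age range
#'
#' Divides an MAE in days by the span of ages the clock covers, allowing
#' accuracy comparisons between clocks fitted on different age ranges.
#' Reported to 2 decimals.
#'
#' @param mae_days MAE in days.
#' @param age_min,age_max the youngest and oldest ages (days); the range
#'   must be positive.
#' @return `mae_days / (age_max - age_min)`, rounded to 2 decimals.
#' @examples
#' scaled_mae(2.61, 10, 24)  # 0.19
#' @export
scaled_mae <- function(mae_days, age_min, age_max) {
  if (age_max <= age_min) stop("age_max must exceed age_min")
  round(mae_days / (age_max - age_min), 2)
}
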