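CLOCK_FORMAT_VERSION <- "1.0"

#' Serialize a fitted clock to JSON
#'
#' Writes every field of a `fitted_clock` to a JSON file with full numeric
#' precision and an embedded format-version tag, so a read/write round trip
#' reproduces predictions bit-identically.
#'
#' @param clock a `fitted_clock`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_clock <- function(clock, path) {
  stopifnot(inherits(clock, "fitted_clock"))
  payload <- list(
    format_version = CLOCK_FORMAT_VERSION,
    intercept = clock$intercept,
    site_keys = names(clock$beta),
    beta = unname(clock$beta),
    lambda = clock$lambda, alpha = clock$alpha,
    scheme = clock$scheme, k = clock$k, seed = clock$seed,
    n_selected = clock$n_selected,
    cv_mae = clock$cv_mae, train_mae = clock$train_mae,
    ages = clock$ages, dataset = clock$dataset,
    meta = clock$meta
  )
  # 17 significant digits round-trip IEEE doubles exactly
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' Read a fitted clock from JSON
#'
#' @param path path written by [write_clock()].
#' @return the `fitted_clock`.
#' @export
read_clock <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) {
                        stop("cannot parse clock file ", path, ": ",
                             conditionMessage(e))
                      })
  if (is.null(payload$format_version) ||
      !identical(payload$format_version, CLOCK_FORMAT_VERSION)) {
    stop("clock file format version mismatch: found '",
         payload$format_version %||% "<none>", "', expected '",
         CLOCK_FORMAT_VERSION, "'")
  }
  beta <- setNames(as.numeric(payload$beta),
                   as.character(payload$site_keys))
  structure(list(
    intercept = payload$intercept, beta = beta,
    lambda = payload$lambda, alpha = payload$alpha,
    scheme = as.character(payload$scheme %||% character(0)),
    k = as.integer(payload$k), seed = as.integer(payload$seed),
    n_selected = as.integer(payload$n_selected),
    cv_mae = payload$cv_mae, train_mae = payload$train_mae,
    ages = as.numeric(payload$ages), dataset = payload$dataset,
    meta = as.data.frame(payload$meta, stringsAsFactors = FALSE)
  ), class = "fitted_clock")
}
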