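#' Read and validate a pipeline run configuration
#'
#' The run configuration is a flat YAML file (keys and lists only) with:
#' `bedmethyl_dir`, `genbank`, `out_dir` (paths), `ages` (whitelist of ages
#' in days post-hatch), `datasets` (subset of full/modC/modA), and the
#' clock hyperparameters `alpha_step`, `folds`, `bootstrap`, `seed`,
#' `min_coverage`, plus optional `sam` (enables the QC stage). Validation
#' happens before any stage runs; unknown keys are an error so typos fail
#' fast.
#'
#' @param path YAML file path.
#' @param overrides named list of values overriding the file's (CLI-style
#'   precedence).
#' @return a validated `run_config` list.
#' @export
read_run_config <- function(path, overrides = list()) {
  cfg <- yaml::read_yaml(path)
  cfg[names(overrides)] <- overrides
  known <- c("bedmethyl_dir", "genbank", "out_dir", "ages", "datasets",
             "alpha_step", "folds", "bootstrap", "seed", "min_coverage",
             "sam")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  defaults <- list(datasets = c("full", "modC", "modA"), alpha_step = 0.01,
                   folds = 3L, bootstrap = 10L, seed = 42L,
                   min_coverage = 1L, sam = NULL)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  required <- c("bedmethyl_dir", "genbank", "out_dir", "ages")
  miss <- required[!required %in% names(cfg)]
  if (length(miss)) {
    stop("missing required config key(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!dir.exists(cfg$bedmethyl_dir)) {
    stop("bedmethyl_dir does not exist: ", cfg$bedmethyl_dir, call. = FALSE)
  }
  if (!file.exists(cfg$genbank)) {
    stop("genbank file does not exist: ", cfg$genbank, call. = FALSE)
  }
  cfg$ages <- sort(as.numeric(cfg$ages))
  cfg$datasets <- match.arg(cfg$datasets, c("full", "modC", "modA"),
                            several.ok = TRUE)
  stopifnot(cfg$alpha_step > 0, cfg$alpha_step <= 1,
            cfg$folds >= 2, cfg$bootstrap >= 1, cfg$min_coverage >= 1)
  class(cfg) <- "run_config"
  cfg
}

# locate <age>_<submodel>.bed files for the whitelisted ages
discover_bedmethyl <- function(dir, ages) {
  out <- list()
  for (age in ages) {
    for (sm in SUBMODELS) {
      f <- file.path(dir, paste0(age, "_", sm, ".bed"))
      if (!file.exists(f)) {
        stop("expected bedMethyl file not found: ", f)
      }
      out[[length(out) + 1L]] <- list(path = f, age = age, submodel = sm)
    }
  }
  out
}

#' Run the whole pipeline
#'
#' Executes sites -> clock fitting (per dataset variant) -> gene
#' importance, plus alignment QC when a SAM path is configured. Every
#' stage's input/output counts are logged to `run.log` in the output
#' directory, and the resolved configuration is serialized there for
#' provenance. Outputs: `sites.tsv`, `summary.tsv` (one row per optimal
#' candidate per scheme x dataset), `clock_<dataset>.json`,
#' `importance_<dataset>.tsv`, `qc.tsv` (optional), `run.log`,
#' `config.yaml`.
#'
#' @param config a `run_config` from [read_run_config()], or a path to a
#'   YAML config file.
#' @return invisibly, a list with the per-dataset `selection_summary`
#'   objects, the aging `methyl_sites`, the stage `counts` and the output
#'   directory.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(...) {
    cat(paste0(format(Sys.time(), "%H:%M:%S"), "  ", ..., "\n"),
        file = log_path, append = TRUE)
  }
  cat("", file = log_path)
  yaml::write_yaml(unclass(config), file.path(config$out_dir, "config.yaml"))

  stage <- "ingest"
  result <- tryCatch({
    files <- discover_bedmethyl(config$bedmethyl_dir, config$ages)
    records <- do.call(rbind, lapply(files, function(f) {
      read_bedmethyl(f$path, sample_id = as.character(f$age),
                     submodel = f$submodel)
    }))
    logf("ingest: ", nrow(records), " bedMethyl records from ",
         length(files), " files")

    stage <- "sites"
    sites <- reconcile_modtypes(records)
    n_conflicts <- attr(sites, "n_conflicts")
    covered <- filter_complete_coverage(sites, ages = config$ages,
                                        min_coverage = config$min_coverage)
    aging <- detect_aging_sites(covered)
    intervals <- read_genbank_features(config$genbank)
    aging <- annotate_genes(aging, intervals)
    counts <- list(
      candidates = n_sites(sites),
      conflicts_dropped = n_conflicts,
      dropped_by_coverage = attr(covered, "n_dropped_by_coverage"),
      retained_after_coverage = n_sites(covered),
      non_differential = attr(aging, "n_nondifferential"),
      aging = n_sites(aging)
    )
    logf("sites: ", counts$candidates, " candidates = ",
         counts$retained_after_coverage, " covered + ",
         counts$dropped_by_coverage, " dropped by coverage; ",
         counts$conflicts_dropped, " conflicting sites removed")
    logf("sites: ", counts$retained_after_coverage, " covered = ",
         counts$aging, " aging + ", counts$non_differential,
         " non-differential")
    write_sites_tsv(aging, file.path(config$out_dir, "sites.tsv"))

    stage <- "fit"
    alphas <- seq(0, 1, by = config$alpha_step)
    summaries <- list()
    summary_rows <- list()
    for (ds in config$datasets) {
      design <- build_design_matrix(aging, ds)
      logf("fit[", ds, "]: ", ncol(design$X), " sites x ",
           nrow(design$X), " ages")
      ss <- grid_search(design, alphas = alphas, folds = config$folds,
                        B = config$bootstrap, base_seed = config$seed)
      summaries[[ds]] <- ss
      summary_rows[[ds]] <- ss$per_scheme_best
      write_clock(ss$best_clock,
                  file.path(config$out_dir, paste0("clock_", ds, ".json")))
      imp <- tryCatch(gene_importance(ss$best_clock), error = function(e) {
        logf("fit[", ds, "]: gene importance undefined (",
             conditionMessage(e), ")")
        data.frame(gene = character(0), sum_abs_coef = numeric(0),
                   proportion = numeric(0), n_sites = integer(0),
                   n_selected = integer(0))
      })
      write.table(imp, file.path(config$out_dir,
                                 paste0("importance_", ds, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      b <- ss$candidates[ss$best, ]
      logf("fit[", ds, "]: best scheme=", b$scheme, " alpha=", b$alpha,
           " cv_mae=", round(b$cv_mae, 3), " train_mae=",
           round(b$train_mae, 3), " n_selected=", b$n_selected)
    }
    write.table(do.call(rbind, summary_rows),
                file.path(config$out_dir, "summary.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)

    if (!is.null(config$sam)) {
      stage <- "qc"
      cig <- read_sam_cigars(config$sam)
      stats <- alignment_stats(cig)
      qc <- summarize_identity(stats, sample_id = basename(config$sam))
      write.table(stats, file.path(config$out_dir, "qc.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      logf("qc: ", qc$n_reads, " reads, median identity ",
           round(qc$median_identity, 4))
    }

    list(summaries = summaries, aging_sites = aging, counts = counts,
         out_dir = config$out_dir)
  }, error = function(e) {
    logf("ERROR in stage '", stage, "': ", conditionMessage(e))
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}

# one row per aging site: key, mod_type, gene, means, per-age levels
write_sites_tsv <- function(x, path) {
  lev <- as.data.frame(x$levels)
  names(lev) <- paste0("level_", x$ages)
  out <- cbind(x$sites, lev)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
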