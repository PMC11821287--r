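#' Reconcile modification calls across submodels
#'
#' Collapses bedMethyl records from the three modification-calling
#' submodels (`5mC`, `5mCG_5hmCG`, `6mA`) into one canonical modification
#' type per genomic site. A site is keyed by (contig, 1-based position,
#' strand); records for the same site from different submodels are
#' compared:
#'
#' * adenine sites (code `a` from the 6mA submodel) become `6mA`;
#' * cytosine sites become `5mC` when the 5mC submodel calls `m` and the
#'   CpG submodel does not call `h`; `5hmC` when the CpG submodel calls `h`
#'   and the 5mC submodel does not call `m`; `other_modC` when the site is
#'   modified but neither characterisation holds;
#' * sites called `m` by the 5mC submodel *and* `h` by the CpG submodel are
#'   contradictory and dropped (counted in attribute `n_conflicts`).
#'
#' A submodel "calls" a code at a site when it has a record with that code
#' and a positive percent modified in at least one sample. Methylation
#' levels, coverage and reliability are then taken per age from the
#' canonical record for the assigned type (for `other_modC`, the first
#' available cytosine record by submodel order 5mC then CpG and code order
#' `C`, `m`, `h`).
#'
#' @param records data frame of bedMethyl records, the row-bound output of
#'   [read_bedmethyl()] over all samples and submodels.
#' @param sample_ages named numeric vector mapping `sample_id` to age in
#'   days post-hatch; if `NULL`, sample ids are parsed as numbers.
#' @return a `methyl_sites` object: a list with `sites` (data frame with
#'   `contig`, `pos`, `strand`, `mod_type`, `gene`), matrices `levels`,
#'   `coverage` and `reliability` (sites x ages; unobserved ages have
#'   coverage 0), and `ages` (ordered). Attribute `n_conflicts` counts
#'   dropped contradictory sites.
#' @export
reconcile_modtypes <- function(records, sample_ages = NULL) {
  if (!nrow(records)) stop("no methylation records supplied")
  if (is.null(sample_ages)) {
    ids <- unique(records$sample_id)
    sample_ages <- setNames(as.numeric(ids), ids)
    if (anyNA(sample_ages)) {
      stop("sample ids are not numeric ages; supply `sample_ages`")
    }
  }
  missing_ids <- setdiff(unique(records$sample_id), names(sample_ages))
  if (length(missing_ids)) {
    stop("no age supplied for sample(s): ", paste(missing_ids, collapse = ", "))
  }
  ages <- sort(unique(unname(sample_ages)))
  records$age <- unname(sample_ages[records$sample_id])

  key <- paste(records$contig, records$pos, records$strand, sep = "\r")
  keys <- unique(key)
  idx_by_site <- split(seq_len(nrow(records)), factor(key, levels = keys))

  n <- length(keys)
  mod_type <- character(n)
  keep <- logical(n)
  n_conflicts <- 0L
  lev <- cov <- rel <- matrix(NA_real_, n, length(ages),
                              dimnames = list(NULL, ages))

  for (i in seq_len(n)) {
    rs <- records[idx_by_site[[i]], , drop = FALSE]
    is_a <- rs$mod_code == "a"
    if (any(is_a) && any(!is_a)) {
      stop("site ", gsub("\r", ":", keys[i]),
           " carries both adenine and cytosine modification codes")
    }
    if (any(is_a)) {
      mod_type[i] <- "6mA"
      canon <- rs[rs$submodel == "6mA" & rs$mod_code == "a", , drop = FALSE]
    } else {
      m_call <- any(rs$submodel == "5mC" & rs$mod_code == "m" &
                      rs$percent_modified > 0)
      h_call <- any(rs$submodel == "5mCG_5hmCG" & rs$mod_code == "h" &
                      rs$percent_modified > 0)
      if (m_call && h_call) {
        n_conflicts <- n_conflicts + 1L
        next
      }
      if (m_call) {
        mod_type[i] <- "5mC"
        canon <- rs[rs$submodel == "5mC" & rs$mod_code == "m", , drop = FALSE]
      } else if (h_call) {
        mod_type[i] <- "5hmC"
        canon <- rs[rs$submodel == "5mCG_5hmCG" & rs$mod_code == "h", ,
                    drop = FALSE]
      } else {
        mod_type[i] <- "other_modC"
        pri <- order(match(rs$submodel, c("5mC", "5mCG_5hmCG")),
                     match(rs$mod_code, c("C", "m", "h")))
        canon <- rs[pri, , drop = FALSE]
        canon <- canon[!duplicated(canon$age), , drop = FALSE]
      }
    }
    keep[i] <- TRUE
    j <- match(canon$age, ages)
    lev[i, j] <- canon$percent_modified
    cov[i, j] <- canon$coverage
    rel[i, j] <- canon$score / 1000
  }

  lev[is.na(lev)] <- 0
  rel[is.na(rel)] <- 0
  cov[is.na(cov)] <- 0

  km <- do.call(rbind, strsplit(keys[keep], "\r", fixed = TRUE))
  out <- structure(list(
    sites = data.frame(contig = km[, 1L], pos = as.integer(km[, 2L]),
                       strand = km[, 3L], mod_type = mod_type[keep],
                       gene = NA_character_, stringsAsFactors = FALSE),
    levels = lev[keep, , drop = FALSE],
    coverage = cov[keep, , drop = FALSE],
    reliability = rel[keep, , drop = FALSE],
    ages = ages
  ), class = "methyl_sites")
  attr(out, "n_conflicts") <- n_conflicts
  out
}

#' @export
print.methyl_sites <- function(x, ...) {
  cat("methyl_sites:", nrow(x$sites), "sites x", length(x$ages), "ages (",
      paste(x$ages, collapse = ", "), "DPH )\n")
  cat("  mod types:", paste(names(table(x$sites$mod_type)),
                            table(x$sites$mod_type), collapse = "; "), "\n")
  invisible(x)
}

n_sites <- function(x) nrow(x$sites)

subset_sites <- function(x, i) {
  structure(list(sites = x$sites[i, , drop = FALSE],
                 levels = x$levels[i, , drop = FALSE],
                 coverage = x$coverage[i, , drop = FALSE],
                 reliability = x$reliability[i, , drop = FALSE],
                 ages = x$ages), class = "methyl_sites")
}

#' Keep sites covered at every age of interest
#'
#' Restricts a `methyl_sites` object to the required ages and retains only
#' sites whose coverage is at least `min_coverage` at *every* one of them.
#' Differential methylation across ages can only be assessed at sites
#' observed at all ages, so this is a precondition of
#' [detect_aging_sites()]. Per-site `mean_coverage` and `mean_reliability`
#' (score/1000) are computed over the required ages and added to the site
#' table.
#'
#' @param x a `methyl_sites` object.
#' @param ages required ages (days post-hatch); must be present in `x`.
#' @param min_coverage minimum number of valid calls per age (default 1).
#' @return the filtered `methyl_sites` object, with attribute
#'   `n_dropped_by_coverage`.
#' @export
filter_complete_coverage <- function(x, ages = x$ages, min_coverage = 1) {
  if (!length(ages)) stop("required age list is empty")
  j <- match(ages, x$ages)
  if (anyNA(j)) stop("required age(s) absent from data: ",
                     paste(ages[is.na(j)], collapse = ", "))
  covered <- rowSums(x$coverage[, j, drop = FALSE] >= min_coverage) ==
    length(j)
  out <- structure(list(
    sites = x$sites[covered, , drop = FALSE],
    levels = x$levels[covered, j, drop = FALSE],
    coverage = x$coverage[covered, j, drop = FALSE],
    reliability = x$reliability[covered, j, drop = FALSE],
    ages = x$ages[j]
  ), class = "methyl_sites")
  out$sites$mean_coverage <- rowMeans(out$coverage)
  out$sites$mean_reliability <- rowMeans(out$reliability)
  attr(out, "n_dropped_by_coverage") <- sum(!covered)
  out
}

#' Detect aging sites (differential methylation across ages)
#'
#' An aging site is a fully covered site whose methylation level is not
#' identical across all ages: at least one unequal level, evaluated
#' literally on the percent values rounded to 2 decimals (the input
#' precision), with no statistical test.
#'
#' @param x a `methyl_sites` object, after [filter_complete_coverage()].
#' @return the `methyl_sites` object restricted to aging sites, with
#'   attribute `n_nondifferential`.
#' @export
detect_aging_sites <- function(x) {
  lv <- round(x$levels, 2)
  differential <- apply(lv, 1L, function(v) length(unique(v)) > 1L)
  if (!nrow(lv)) differential <- logical(0)
  out <- subset_sites(x, differential)
  out$sites <- x$sites[differential, , drop = FALSE]
  attr(out, "n_nondifferential") <- sum(!differential)
  out
}

#' Annotate sites with the gene interval containing them
#'
#' Labels each site with the name of the interval (from
#' [read_genbank_features()]) containing its 1-based position. Intervals
#' must partition the contig; a position outside `[1, sequence length]` is
#' an error.
#'
#' @param x a `methyl_sites` object.
#' @param intervals data frame from [read_genbank_features()].
#' @return `x` with the `gene` column of `x$sites` filled in.
#' @export
annotate_genes <- function(x, intervals) {
  L <- max(intervals$end)
  pos <- x$sites$pos
  if (length(pos) && (min(pos) < 1L || max(pos) > L)) {
    stop("site position outside [1, ", L, "]")
  }
  idx <- findInterval(pos, intervals$start)
  stopifnot(all(pos <= intervals$end[idx]))
  x$sites$gene <- intervals$name[idx]
  x
}

#' Aging-site density per gene
#'
#' Number of sites per interval divided by interval length, the per-gene
#' density used to compare small tRNA genes against long coding genes.
#'
#' @param x an annotated `methyl_sites` object.
#' @param intervals data frame from [read_genbank_features()].
#' @return data frame with `gene`, `feature_kind`, `length`, `n_sites`,
#'   `density` (sites per base).
#' @export
gene_site_density <- function(x, intervals) {
  counts <- table(factor(x$sites$gene, levels = intervals$name))
  data.frame(
    gene = intervals$name,
    feature_kind = intervals$feature_kind,
    length = intervals$end - intervals$start + 1L,
    n_sites = as.integer(counts),
    density = as.integer(counts) / (intervals$end - intervals$start + 1L),
    stringsAsFactors = FALSE
  )
}

#' Assemble the clock design matrix
#'
#' Builds the samples x sites predictor matrix of methylation levels (%)
#' with ages as the response, for one of the three dataset variants: the
#' full site set, cytosine modifications only (`modC`: 5mC, 5hmC,
#' other_modC) or adenine modifications only (`modA`: 6mA). Columns are
#' ordered lexicographically by (contig, position, strand, mod_type) so the
#' matrix is stable across runs.
#'
#' @param x an annotated, filtered `methyl_sites` object of aging sites.
#' @param dataset `"full"`, `"modC"` or `"modA"`.
#' @return a `clock_design` object: list with `X` (ages x sites matrix,
#'   columns named `contig:pos:strand:mod_type`), `ages` (the response,
#'   days post-hatch), `meta` (site metadata: gene, mod_type,
#'   mean_coverage, mean_reliability) and `dataset`.
#' @export
build_design_matrix <- function(x, dataset = c("full", "modC", "modA")) {
  dataset <- match.arg(dataset)
  sel <- switch(dataset,
                full = rep(TRUE, n_sites(x)),
                modC = x$sites$mod_type %in% c("5mC", "5hmC", "other_modC"),
                modA = x$sites$mod_type == "6mA")
  if (!any(sel)) stop("no aging sites left for dataset variant '",
                      dataset, "'")
  x <- subset_sites(x, sel)
  ord <- order(x$sites$contig, x$sites$pos, x$sites$strand, x$sites$mod_type)
  x <- subset_sites(x, ord)
  key <- paste(x$sites$contig, x$sites$pos, x$sites$strand, x$sites$mod_type,
               sep = ":")
  X <- t(x$levels)
  dimnames(X) <- list(x$ages, key)
  structure(list(X = X, ages = x$ages, meta = x$sites, dataset = dataset),
            class = "clock_design")
}

#' @export
print.clock_design <- function(x, ...) {
  cat("clock_design (", x$dataset, "): ", nrow(x$X), " samples x ",
      ncol(x$X), " aging sites; ages ", paste(x$ages, collapse = ", "),
      " DPH\n", sep = "")
  invisible(x)
}
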