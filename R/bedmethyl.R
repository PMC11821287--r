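#' Read a bedMethyl methylation summary file
#'
#' Parses the tab-separated bedMethyl format emitted by modified-base
#' summarisers (BED9 + coverage + percent modified, >= 11 columns). Each row
#' summarises one genomic position for one modification code: column 4 holds
#' the code (`m` = 5mC, `h` = 5hmC, `C` = ambiguous modified cytosine,
#' `a` = 6mA), column 5 the reliability score (0-1000), column 10 the number
#' of valid calls (coverage) and column 11 the percent of modified calls.
#'
#' Positions are normalised to 1-based single-base coordinates at ingestion
#' (`pos = start + 1`), so downstream gene annotation can join directly
#' against 1-based GenBank intervals. Rows with coverage 0 are retained;
#' they are removed later by [filter_complete_coverage()].
#'
#' @param path path to a bedMethyl file.
#' @param sample_id sample label, typically the age label (e.g. `"P3"` or
#'   `"10"` for 10 days post-hatch). Must be non-empty.
#' @param submodel the modification-calling submodel that produced the file:
#'   one of `"5mC"`, `"5mCG_5hmCG"`, `"6mA"`.
#' @return a data frame with one row per input row and columns `contig`,
#'   `start` (0-based), `end`, `pos` (1-based), `mod_code`, `strand`,
#'   `score`, `coverage`, `percent_modified`, `sample_id`, `submodel`.
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("MT\t100\t101\tm\t1000\t+\t100\t101\t0,0,0\t3\t66.67", f)
#' read_bedmethyl(f, sample_id = "P3", submodel = "5mC")
#' @export
read_bedmethyl <- function(path, sample_id, submodel) {
  stopifnot(is.character(sample_id), nzchar(sample_id),
            length(sample_id) == 1L)
  submodel <- match.arg(submodel, SUBMODELS)
  if (!file.exists(path)) stop("bedMethyl file not found: ", path)

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_bedmethyl(sample_id, submodel))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < 11L)
  if (length(bad)) {
    stop("malformed bedMethyl row at line ", bad[1L], " of ", path,
         ": expected >= 11 tab-separated columns, found ", nf[bad[1L]])
  }

  col <- function(i) vapply(fields, `[[`, character(1L), i)
  mod_code <- col(4L)
  unknown <- setdiff(unique(mod_code), MOD_CODES)
  if (length(unknown)) {
    stop("unknown modification code(s) ", paste(unknown, collapse = ", "),
         " in ", path, "; accepted codes: ", paste(MOD_CODES, collapse = ", "))
  }

  start <- as.integer(col(2L))
  out <- data.frame(
    contig = col(1L),
    start = start,
    end = as.integer(col(3L)),
    pos = start + 1L,
    mod_code = mod_code,
    strand = col(6L),
    score = as.integer(col(5L)),
    coverage = as.integer(col(10L)),
    percent_modified = as.numeric(col(11L)),
    sample_id = sample_id,
    submodel = submodel,
    stringsAsFactors = FALSE
  )
  validate_bedmethyl(out, path)
  out
}

empty_bedmethyl <- function(sample_id = character(0), submodel = character(0)) {
  data.frame(contig = character(0), start = integer(0), end = integer(0),
             pos = integer(0), mod_code = character(0), strand = character(0),
             score = integer(0), coverage = integer(0),
             percent_modified = numeric(0), sample_id = character(0),
             submodel = character(0), stringsAsFactors = FALSE)
}

validate_bedmethyl <- function(x, path = "<data>") {
  if (anyNA(x$start) || anyNA(x$coverage) || anyNA(x$percent_modified) ||
      anyNA(x$score)) {
    stop("non-numeric value in a numeric bedMethyl column of ", path)
  }
  if (any(x$percent_modified < 0 | x$percent_modified > 100)) {
    stop("percent modified outside [0, 100] in ", path)
  }
  if (any(x$score < 0L | x$score > 1000L)) {
    stop("score outside [0, 1000] in ", path)
  }
  if (any(x$coverage < 0L)) stop("negative coverage in ", path)
  invisible(x)
}

#' Write methylation records back to bedMethyl
#'
#' Inverse of [read_bedmethyl()]: serialises the numeric columns exactly so
#' that a read/write round trip reproduces them.
#'
#' @param records data frame as returned by [read_bedmethyl()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(records, path) {
  pct <- formatC(records$percent_modified, format = "fg", digits = 15)
  lines <- paste(records$contig, records$start, records$end,
                 records$mod_code, records$score, records$strand,
                 records$start, records$end, "0,0,0",
                 records$coverage, pct, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
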