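#' Extract CIGAR operation counts from a SAM file
#'
#' Reads a plain-text SAM alignment file and returns, for each usable
#' record, the total count of each CIGAR operation (`=`, `X`, `I`, `D`,
#' `M`, `S`, `H`, `N`) plus the `NM` tag when present. Unmapped records
#' (flag 0x4) and records with CIGAR `*` are skipped; secondary (0x100) and
#' supplementary (0x800) alignments are excluded by default.
#'
#' Binary BAM input is not parsed here; convert with `samtools view` first.
#'
#' @param path path to a SAM text file.
#' @param include_secondary keep secondary/supplementary alignments?
#' @return a data frame with one row per usable record: `read_id`, one
#'   column per CIGAR op (`eq`, `X`, `I`, `D`, `M`, `S`, `H`, `N`) and
#'   `nm` (NA when the tag is absent). The number of skipped records is
#'   attached as attribute `"n_skipped"` and reported with a warning when
#'   nonzero.
#' @export
read_sam_cigars <- function(path, include_secondary = FALSE) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  con <- file(path, "rb")
  magic <- readBin(con, "raw", 2L)
  close(con)
  if (length(magic) == 2L && identical(as.integer(magic), c(31L, 139L))) {
    stop("binary/gzipped alignment input; convert to text SAM with ",
         "'samtools view -h' first")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "@") & nzchar(lines)]
  if (!length(lines)) return(empty_cigar_table(0L))

  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short)) {
    stop("malformed SAM record (fewer than 11 fields) at alignment line ",
         short[1L])
  }
  flag <- vapply(fields, function(f) as.integer(f[2L]), integer(1L))
  cigar <- vapply(fields, `[[`, character(1L), 6L)

  unmapped <- bitwAnd(flag, 4L) > 0L
  secondary <- bitwAnd(flag, 256L) > 0L | bitwAnd(flag, 2048L) > 0L
  no_cigar <- cigar == "*"
  drop <- unmapped | no_cigar | (!include_secondary & secondary)
  n_skipped <- sum(drop)
  if (any(no_cigar & !unmapped)) {
    warning(sum(no_cigar & !unmapped), " mapped record(s) without a CIGAR ",
            "string skipped")
  }
  keep <- which(!drop)
  if (!length(keep)) {
    out <- empty_cigar_table(n_skipped)
    return(out)
  }

  ops <- t(vapply(cigar[keep], parse_cigar, numeric(8L),
                  USE.NAMES = FALSE))
  colnames(ops) <- c("eq", "X", "I", "D", "M", "S", "H", "N")
  nm <- vapply(fields[keep], function(f) {
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag)) as.integer(sub("^NM:i:", "", tag[1L])) else NA_integer_
  }, integer(1L))

  out <- data.frame(
    read_id = vapply(fields[keep], `[[`, character(1L), 1L),
    ops, nm = nm, stringsAsFactors = FALSE
  )
  attr(out, "n_skipped") <- n_skipped
  out
}

empty_cigar_table <- function(n_skipped) {
  out <- data.frame(read_id = character(0), eq = numeric(0), X = numeric(0),
                    I = numeric(0), D = numeric(0), M = numeric(0),
                    S = numeric(0), N = numeric(0), H = numeric(0))
  out <- out[, c("read_id", "eq", "X", "I", "D", "M", "S", "H", "N")]
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Parse one CIGAR string into operation counts
#'
#' @param cigar a CIGAR string such as `"5=1X4="`.
#' @return a named numeric vector with elements `eq`, `X`, `I`, `D`, `M`,
#'   `S`, `H`, `N` (`eq` is the `=` operation).
#' @examples
#' parse_cigar("5=1X4=")
#' @export
parse_cigar <- function(cigar) {
  lens <- as.numeric(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  if (length(lens) != length(ops)) stop("malformed CIGAR string: ", cigar)
  out <- c(eq = 0, X = 0, I = 0, D = 0, M = 0, S = 0, H = 0, N = 0)
  for (k in seq_along(ops)) {
    key <- if (ops[k] == "=") "eq" else ops[k]
    if (key %in% names(out)) out[key] <- out[key] + lens[k]
  }
  out
}
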