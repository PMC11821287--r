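#' Read accuracy: matches over alignment length
#'
#' The fraction of matched bases over the full alignment length, gaps
#' included: `matches / (matches + mismatches + insertions + deletions)`.
#' Soft/hard clips and reference skips are excluded from the denominator.
#'
#' With extended CIGARs (`=`/`X`) matches are read directly. With `M`-only
#' CIGARs a mismatch count must be supplied via the `NM` tag: mismatches =
#' NM - inserted - deleted bases, matches = M - mismatches. When both are
#' available, `=`/`X` wins.
#'
#' @param ops named counts for one read, as one row of [read_sam_cigars()]
#'   or the output of [parse_cigar()] (optionally with an `nm` element).
#' @return read accuracy in `[0, 1]`.
#' @examples
#' read_accuracy(c(parse_cigar("90=5X5D")))  # 90 / 100
#' @export
read_accuracy <- function(ops) {
  mm <- match_mismatch(ops)
  aln_len <- mm$matches + mm$mismatches + num(ops, "I") + num(ops, "D")
  if (aln_len <= 0) stop("no aligned bases in record")
  mm$matches / aln_len
}

#' Read identity: matches over aligned bases
#'
#' The fraction of matched bases over bases actually aligned to the
#' reference, i.e. *not* counting gaps: `matches / (matches + mismatches)`.
#' Always at least the read accuracy, with equality when the alignment has
#' no insertions or deletions.
#'
#' @inheritParams read_accuracy
#' @return read identity in `[0, 1]`.
#' @examples
#' read_identity(c(parse_cigar("90=5X5D")))  # 90 / 95
#' @export
read_identity <- function(ops) {
  mm <- match_mismatch(ops)
  aligned <- mm$matches + mm$mismatches
  if (aligned <= 0) stop("no aligned bases in record")
  mm$matches / aligned
}

num <- function(ops, key) {
  v <- if (is.data.frame(ops)) ops[[key]] else unname(ops[key])
  if (is.null(v) || length(v) == 0L || is.na(v)) 0 else as.numeric(v)
}

# matches/mismatches from =/X when present, else from M plus the NM tag
match_mismatch <- function(ops) {
  eq <- num(ops, "eq"); x <- num(ops, "X"); m <- num(ops, "M")
  if (eq + x > 0) return(list(matches = eq, mismatches = x))
  if (m > 0) {
    nm <- if (is.data.frame(ops)) ops[["nm"]] else ops["nm"]
    if (is.null(nm) || length(nm) == 0L || is.na(nm)) {
      stop("matches indeterminable: M-only CIGAR without NM tag")
    }
    mism <- as.numeric(nm) - num(ops, "I") - num(ops, "D")
    if (mism < 0 || mism > m) stop("NM tag inconsistent with CIGAR")
    return(list(matches = m - mism, mismatches = mism))
  }
  list(matches = 0, mismatches = 0)
}

#' Per-read alignment statistics
#'
#' Computes matches, mismatches, indel counts, read accuracy and read
#' identity for every record of a CIGAR table.
#'
#' @param cigars data frame from [read_sam_cigars()].
#' @return data frame with columns `read_id`, `matches`, `mismatches`,
#'   `insertions`, `deletions`, `accuracy`, `identity`.
#' @export
alignment_stats <- function(cigars) {
  if (!nrow(cigars)) stop("no alignment records")
  rows <- lapply(seq_len(nrow(cigars)), function(i) {
    r <- cigars[i, , drop = FALSE]
    mm <- match_mismatch(r)
    data.frame(read_id = r$read_id, matches = mm$matches,
               mismatches = mm$mismatches, insertions = num(r, "I"),
               deletions = num(r, "D"), accuracy = read_accuracy(r),
               identity = read_identity(r), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Summarise read accuracy and identity for one sample
#'
#' Median accuracy, median identity and the median basecalling-error proxy
#' (1 - median identity) over all reads of a sample.
#'
#' @param stats data frame from [alignment_stats()].
#' @param sample_id sample label carried into the output.
#' @return one-row data frame with `sample_id`, `n_reads`,
#'   `median_accuracy`, `median_identity`, `median_error_rate`.
#' @export
summarize_identity <- function(stats, sample_id = "sample") {
  if (is.null(stats) || !nrow(stats)) stop("empty alignment statistics")
  data.frame(
    sample_id = sample_id,
    n_reads = nrow(stats),
    median_accuracy = median(stats$accuracy),
    median_identity = median(stats$identity),
    median_error_rate = 1 - median(stats$identity),
    stringsAsFactors = FALSE
  )
}
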