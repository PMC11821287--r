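#' Parse gene intervals from a GenBank flat file
#'
#' Extracts CDS, tRNA, rRNA and D-loop features from the FEATURES table of a
#' GenBank flat file and tiles the remainder of the sequence with synthetic
#' non-coding intervals named `NC1`, `NC2`, ... numbered left to right, so
#' that every position in `[1, sequence length]` belongs to exactly one
#' interval. Coordinates are 1-based inclusive, the GenBank convention.
#'
#' Features that span the origin (`join(a..L,1..b)`) are split into two
#' intervals carrying the same name. Where features overlap, precedence is
#' CDS > tRNA > rRNA > D-loop, and within the same kind the shorter feature
#' wins, so every position is assigned a single deterministic label.
#'
#' @param path path to a GenBank flat file (must contain a FEATURES block
#'   and declare the sequence length on its LOCUS line).
#' @return a data frame with columns `name`, `start`, `end`, `feature_kind`
#'   (one of CDS, tRNA, rRNA, D-loop, NC), sorted by `start`, whose
#'   intervals partition `[1, sequence_length]`. The sequence length is
#'   attached as attribute `"sequence_length"`.
#' @export
read_genbank_features <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (!length(locus)) stop("not a GenBank flat file (no LOCUS line): ", path)
  m <- regmatches(locus[1L], regexpr("[0-9]+(?=\\s+bp)", locus[1L], perl = TRUE))
  if (!length(m)) stop("LOCUS line does not declare a sequence length in bp")
  seq_len <- as.integer(m)

  feat_start <- grep("^FEATURES", lines)
  if (!length(feat_start)) stop("no FEATURES block in GenBank file: ", path)
  feat_end <- grep("^(ORIGIN|CONTIG|//)", lines)
  feat_end <- feat_end[feat_end > feat_start[1L]]
  feat_end <- if (length(feat_end)) feat_end[1L] - 1L else length(lines)
  block <- lines[(feat_start[1L] + 1L):feat_end]

  feats <- parse_feature_block(block)
  keep_kinds <- c("CDS", "tRNA", "rRNA", "D-loop")
  feats <- feats[feats$kind %in% keep_kinds, , drop = FALSE]

  intervals <- data.frame(name = character(0), start = integer(0),
                          end = integer(0), feature_kind = character(0),
                          stringsAsFactors = FALSE)
  for (i in seq_len(nrow(feats))) {
    spans <- parse_location(feats$location[i], seq_len)
    for (s in spans) {
      intervals <- rbind(intervals, data.frame(
        name = feats$name[i], start = s[1L], end = s[2L],
        feature_kind = feats$kind[i], stringsAsFactors = FALSE))
    }
  }
  tile_intervals(intervals, seq_len)
}

# Split the FEATURES block into (kind, location, name) rows. Feature headers
# start at column 6; qualifiers at column 22 with a leading '/'.
parse_feature_block <- function(block) {
  hdr <- grep("^\\s{5}\\S", block)
  kinds <- character(0); locs <- character(0); names_ <- character(0)
  for (j in seq_along(hdr)) {
    i0 <- hdr[j]
    i1 <- if (j < length(hdr)) hdr[j + 1L] - 1L else length(block)
    head_fields <- strsplit(trimws(block[i0]), "\\s+")[[1L]]
    kind <- head_fields[1L]
    loc <- paste(head_fields[-1L], collapse = "")
    quals <- block[seq.int(i0, i1)][-1L]
    # continuation lines of the location (no leading '/')
    cont <- quals[!grepl("^\\s*/", quals)]
    if (length(cont)) loc <- paste0(loc, paste(trimws(cont), collapse = ""))
    nm <- NA_character_
    for (q in c("gene", "product")) {
      qm <- grep(paste0('^\\s*/', q, '="?'), quals, value = TRUE)
      if (length(qm)) {
        nm <- sub('".*$', "", sub(paste0('^\\s*/', q, '="?'), "", qm[1L]))
        break
      }
    }
    if (is.na(nm)) nm <- kind
    kinds <- c(kinds, kind); locs <- c(locs, loc); names_ <- c(names_, nm)
  }
  data.frame(kind = kinds, location = locs, name = names_,
             stringsAsFactors = FALSE)
}

# Returns a list of c(start, end) spans; wrap-around joins yield two spans.
parse_location <- function(loc, seq_len) {
  loc <- gsub("complement\\(|join\\(|order\\(|\\)|<|>", "", loc)
  parts <- strsplit(loc, ",", fixed = TRUE)[[1L]]
  spans <- lapply(parts, function(p) {
    nums <- as.integer(strsplit(p, "\\.\\.")[[1L]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (anyNA(nums)) stop("cannot parse feature location: ", loc)
    nums
  })
  for (s in spans) {
    if (s[1L] > s[2L] || s[2L] > seq_len) {
      stop("feature location outside sequence or inverted: ", loc)
    }
  }
  spans
}

# Resolve overlaps by precedence and fill gaps with NC<k> intervals.
tile_intervals <- function(intervals, seq_len) {
  lab <- rep(NA_integer_, seq_len)
  if (nrow(intervals)) {
    prec <- match(intervals$feature_kind, c("CDS", "tRNA", "rRNA", "D-loop"))
    width <- intervals$end - intervals$start + 1L
    # paint weakest precedence first, and within a kind longest first, so
    # the strongest (and, on ties, shortest) feature painted last wins
    ord <- order(-prec, -width)
    for (i in ord) lab[intervals$start[i]:intervals$end[i]] <- i
  }
  # run-length encode the per-position labels into final intervals
  r <- rle(ifelse(is.na(lab), 0L, lab))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nc_k <- 0L
  out <- vector("list", length(r$values))
  for (j in seq_along(r$values)) {
    v <- r$values[j]
    if (v == 0L) {
      nc_k <- nc_k + 1L
      out[[j]] <- data.frame(name = paste0("NC", nc_k), start = starts[j],
                             end = ends[j], feature_kind = "NC",
                             stringsAsFactors = FALSE)
    } else {
      out[[j]] <- data.frame(name = intervals$name[v], start = starts[j],
                             end = ends[j],
                             feature_kind = intervals$feature_kind[v],
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  attr(res, "sequence_length") <- seq_len
  res
}
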