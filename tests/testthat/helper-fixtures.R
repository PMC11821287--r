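# shared fixture builders: everything is generated in code at test time

write_bed_lines <- function(lines, path = tempfile(fileext = ".bed")) {
  writeLines(lines, path)
  path
}

# minimal GenBank flat file with the given (kind, name, start, end) features
write_genbank <- function(features, seq_len,
                          path = tempfile(fileext = ".gb")) {
  lines <- c(
    sprintf("LOCUS       TESTSEQ %16d bp    DNA     circular VRT 01-JAN-2026",
            seq_len),
    "FEATURES             Location/Qualifiers",
    sprintf("     source          1..%d", seq_len))
  for (f in features) {
    loc <- if (length(f) >= 5L && isTRUE(f[[5]])) {
      sprintf("join(%d..%d,1..%d)", f[[3]], seq_len, f[[4]])
    } else {
      sprintf("%d..%d", f[[3]], f[[4]])
    }
    lines <- c(lines,
               sprintf("     %-16s%s", f[[1]], loc),
               sprintf('                     /gene="%s"', f[[2]]))
  }
  writeLines(c(lines, "ORIGIN", "//"), path)
  path
}

# read every bedMethyl file of a generated dataset into one record table
read_generated <- function(gen) {
  do.call(rbind, lapply(names(gen$files), function(nm) {
    parts <- strsplit(nm, "_")[[1L]]
    read_bedmethyl(gen$files[[nm]], sample_id = parts[1L],
                   submodel = paste(parts[-1L], collapse = "_"))
  }))
}

# generated dataset -> annotated aging-site design matrix
dataset_to_design <- function(gen, ages, dataset = "full",
                              min_coverage = 1) {
  sites <- reconcile_modtypes(read_generated(gen))
  covered <- filter_complete_coverage(sites, ages = ages,
                                      min_coverage = min_coverage)
  aging <- detect_aging_sites(covered)
  aging <- annotate_genes(aging, read_genbank_features(gen$genbank))
  build_design_matrix(aging, dataset)
}

# small random regression instance for solver tests
random_instance <- function(n, p, seed, grouped = FALSE) {
  set.seed(seed)
  X <- matrix(rnorm(n * p, mean = 50, sd = 20), n, p)
  colnames(X) <- paste0("s", seq_len(p))
  y <- sort(runif(n, 10, 24))
  groups <- if (grouped) {
    sample(paste0("g", seq_len(max(2L, p %/% 3L))), p, replace = TRUE)
  } else {
    paste0("site", seq_len(p))
  }
  list(X = X, y = y, groups = groups)
}
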