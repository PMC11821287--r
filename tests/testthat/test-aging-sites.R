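# build a record table directly, one row per (sample, submodel, code)
rec_row <- function(pos, code, submodel, sample, pct, cov = 3L,
                    score = 900L, contig = "MT", strand = "+") {
  data.frame(contig = contig, start = pos - 1L, end = pos, pos = pos,
             mod_code = code, strand = strand, score = score,
             coverage = cov, percent_modified = pct, sample_id = sample,
             submodel = submodel, stringsAsFactors = FALSE)
}

test_that("modification types reconcile across submodels per the rules", {
  recs <- rbind(
    # pos 10: m by 5mC submodel, m by CpG submodel -> 5mC
    rec_row(10, "m", "5mC", "10", 80), rec_row(10, "m", "5mCG_5hmCG", "10", 75),
    # pos 20: m by 5mC AND h by CpG -> contradictory, dropped
    rec_row(20, "m", "5mC", "10", 60), rec_row(20, "h", "5mCG_5hmCG", "10", 55),
    # pos 30: adenine only -> 6mA
    rec_row(30, "a", "6mA", "10", 40),
    # pos 40: h only -> 5hmC
    rec_row(40, "h", "5mCG_5hmCG", "10", 30),
    # pos 50: ambiguous modC only -> other_modC
    rec_row(50, "C", "5mC", "10", 20))
  sites <- reconcile_modtypes(recs, sample_ages = c("10" = 10))
  expect_equal(attr(sites, "n_conflicts"), 1L)
  got <- setNames(sites$sites$mod_type, sites$sites$pos)
  expect_equal(got[["10"]], "5mC")
  expect_equal(got[["30"]], "6mA")
  expect_equal(got[["40"]], "5hmC")
  expect_equal(got[["50"]], "other_modC")
  expect_false("20" %in% names(got))
  # levels come from the canonical record (5mC submodel for 5mC sites)
  expect_equal(unname(sites$levels[sites$sites$pos == 10, 1]), 80)
})

test_that("a site with both adenine and cytosine codes is a data error", {
  recs <- rbind(rec_row(10, "m", "5mC", "10", 50),
                rec_row(10, "a", "6mA", "10", 50))
  expect_error(reconcile_modtypes(recs, sample_ages = c("10" = 10)),
               "adenine and cytosine")
})

test_that("strands are distinct sites and an m call on one sample suffices", {
  recs <- rbind(rec_row(10, "m", "5mC", "10", 0),
                rec_row(10, "m", "5mC", "12", 90),
                rec_row(10, "m", "5mC", "10", 70, strand = "-"))
  sites <- reconcile_modtypes(recs, sample_ages = c("10" = 10, "12" = 12))
  expect_equal(nrow(sites$sites), 2L)  # + and - at pos 10
  plus <- sites$sites$strand == "+"
  expect_equal(sites$sites$mod_type[plus], "5mC")
  expect_equal(as.numeric(sites$levels[plus, ]), c(0, 90))
})

test_that("coverage filtering keeps only sites covered at every age", {
  recs <- do.call(rbind, c(
    lapply(1:6, function(j) rec_row(10, "m", "5mC", as.character(j), 50,
                                    cov = c(1L, 1L, 1L, 1L, 1L, 1L)[j])),
    lapply(1:5, function(j) rec_row(20, "m", "5mC", as.character(j), 50)),
    lapply(1:6, function(j) rec_row(30, "m", "5mC", as.character(j), 50,
                                    cov = c(3L, 2L, 2L, 2L, 2L, 1L)[j]))))
  ages <- setNames(1:6, as.character(1:6))
  sites <- reconcile_modtypes(recs, sample_ages = ages)
  kept <- filter_complete_coverage(sites, ages = 1:6)
  expect_setequal(kept$sites$pos, c(10L, 30L))  # pos 20 misses age 6
  expect_equal(attr(kept, "n_dropped_by_coverage"), 1L)
  # with min_coverage 2 the [3,2,2,2,2,1] site and the all-1x site drop
  kept2 <- filter_complete_coverage(sites, ages = 1:6, min_coverage = 2)
  expect_equal(nrow(kept2$sites), 0L)
  expect_error(filter_complete_coverage(sites, ages = numeric(0)), "empty")
  # mean coverage/reliability computed over the required ages
  expect_equal(kept$sites$mean_coverage[kept$sites$pos == 30L], mean(c(3, 2, 2, 2, 2, 1)))
  expect_equal(kept$sites$mean_reliability[kept$sites$pos == 10L], 0.9)
})

test_that("aging sites are exactly the non-constant level vectors", {
  mk <- function(pos, levels) {
    do.call(rbind, lapply(seq_along(levels), function(j) {
      rec_row(pos, "m", "5mC", as.character(j), levels[j])
    }))
  }
  recs <- rbind(mk(10, rep(20, 6)),           # constant: excluded
                mk(20, c(0, 0, 0, 0, 0, 100)),  # differential
                mk(30, rep(0, 6)),            # all-zero: non-differential
                mk(40, c(10, 10, 10.004, 10, 10, 10)))  # equal at 2 dp
  sites <- reconcile_modtypes(recs, sample_ages = setNames(1:6, 1:6))
  aging <- detect_aging_sites(filter_complete_coverage(sites, 1:6))
  expect_equal(aging$sites$pos, 20L)
  expect_equal(attr(aging, "n_nondifferential"), 3L)
  # idempotent: re-detecting changes nothing
  again <- detect_aging_sites(aging)
  expect_equal(again$sites, aging$sites, ignore_attr = TRUE)
  expect_equal(attr(again, "n_nondifferential"), 0L)
})

test_that("gene annotation is total over the contig and boundary-inclusive", {
  gb <- write_genbank(list(list("CDS", "ND1", 1L, 100L)), seq_len = 150L)
  iv <- read_genbank_features(gb)
  recs <- rbind(rec_row(120, "m", "5mC", "10", 50),
                rec_row(100, "m", "5mC", "10", 60),
                rec_row(1, "a", "6mA", "10", 10))
  sites <- reconcile_modtypes(recs, sample_ages = c("10" = 10))
  ann <- annotate_genes(sites, iv)
  got <- setNames(ann$sites$gene, ann$sites$pos)
  expect_equal(got[["120"]], "NC1")
  expect_equal(got[["100"]], "ND1")  # interval end is inclusive
  expect_equal(got[["1"]], "ND1")
  expect_false(anyNA(ann$sites$gene))

  bad <- sites
  bad$sites$pos[1] <- 151L
  expect_error(annotate_genes(bad, iv), "outside")

  dens <- gene_site_density(ann, iv)
  expect_equal(dens$n_sites[dens$gene == "ND1"], 2L)
  expect_equal(dens$density[dens$gene == "ND1"], 2 / 100)
})

test_that("design matrices have stable dataset-filtered columns", {
  gen <- generate_dataset(synthetic_config(n_spike = 3, n_ramp = 3,
                                           n_constant = 4, n_incomplete = 0,
                                           n_conflict = 0, seed = 8),
                          tempfile())
  ages <- c(10, 12, 14, 17, 19, 24)
  sites <- reconcile_modtypes(read_generated(gen))
  all_sites <- annotate_genes(filter_complete_coverage(sites, ages),
                              read_genbank_features(gen$genbank))
  full <- build_design_matrix(all_sites, "full")
  expect_equal(dim(full$X), c(6L, 10L))
  expect_equal(as.numeric(rownames(full$X)), ages)
  # dataset variants partition by modification type
  is_a <- all_sites$sites$mod_type == "6mA"
  if (any(is_a) && any(!is_a)) {
    modA <- build_design_matrix(all_sites, "modA")
    modC <- build_design_matrix(all_sites, "modC")
    expect_equal(ncol(modA$X) + ncol(modC$X), ncol(full$X))
    expect_true(all(modA$meta$mod_type == "6mA"))
  }
  # column order is (contig, pos, strand, mod_type) lexicographic
  expect_equal(order(full$meta$contig, full$meta$pos, full$meta$strand,
                     full$meta$mod_type), seq_len(ncol(full$X)))
})

test_that("a dataset variant with no sites is an explicit error", {
  recs <- rbind(rec_row(10, "m", "5mC", "10", 50),
                rec_row(10, "m", "5mC", "12", 80))
  sites <- reconcile_modtypes(recs, sample_ages = c("10" = 10, "12" = 12))
  covered <- filter_complete_coverage(sites, c(10, 12))
  covered$sites$gene <- "ND1"
  expect_error(build_design_matrix(covered, "modA"), "no aging sites")
})
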