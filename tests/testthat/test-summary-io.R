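test_that("well-formed tables round-trip through write and read", {
  rec <- make_records(3)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(rec, f)
  back <- read_summary_table(f)
  attr(back, "n_dropped") <- NULL
  expect_equal(back, rec)
  expect_equal(nrow(back), 3)
})

test_that("rows violating record invariants are dropped and counted", {
  rec <- make_records(4)
  rec$se[2] <- 0
  rec$pval[3] <- 0
  f <- withr::local_tempfile(fileext = ".tsv")
  write_summary_table(rec, f)
  expect_warning(back <- read_summary_table(f), "dropped 2")
  expect_equal(nrow(back), 2)
  expect_equal(attr(back, "n_dropped"), 2L)
  expect_equal(back$snp_id, rec$snp_id[c(1, 4)])  # order preserved
})

test_that("dialect headers are remapped via column_map", {
  rec <- make_records(3)
  alien <- rec
  names(alien) <- c("variant_id", "chromosome", "base_pair_location",
                    "ea", "oa", "effect_allele_frequency", "beta",
                    "standard_error", "p_value", "sample_size")
  f <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(alien, f, sep = "\t", quote = FALSE, row.names = FALSE)
  cmap <- c(snp_id = "variant_id", chrom = "chromosome",
            pos = "base_pair_location", effect_allele = "ea",
            other_allele = "oa", eaf = "effect_allele_frequency",
            se = "standard_error", pval = "p_value", n = "sample_size")
  back <- read_summary_table(f, column_map = cmap)
  attr(back, "n_dropped") <- NULL
  expect_equal(back, rec)
})

test_that("missing mandatory columns and empty files are handled", {
  f <- withr::local_tempfile(fileext = ".tsv")
  rec <- make_records(2)
  rec$se <- NULL
  utils::write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_summary_table(f), "se")

  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("snp_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n"),
                   collapse = "\t"), f2)
  expect_warning(empty <- read_summary_table(f2), "empty")
  expect_equal(nrow(empty), 0)
  expect_error(read_summary_table(tempfile()), "not found")
})

test_that("harmonization applies the orientation rules", {
  ex <- make_records(1, effect_allele = "A", other_allele = "G",
                     beta = 0.1, eaf = 0.25)
  # swapped alleles: outcome beta negated, eaf complemented
  ou <- make_records(1, effect_allele = "G", other_allele = "A",
                     beta = -0.05, eaf = 0.3)
  h <- harmonize(ex, ou)
  expect_equal(h$beta_outcome, 0.05)
  expect_equal(h$eaf_outcome, 0.7)
  expect_equal(attr(h, "n_flipped"), 1L)

  # identical alleles: unchanged
  ou2 <- make_records(1, effect_allele = "A", other_allele = "G",
                      beta = -0.05, eaf = 0.3)
  h2 <- harmonize(ex, ou2)
  expect_equal(h2$beta_outcome, -0.05)
  expect_equal(attr(h2, "n_flipped"), 0L)

  # strand flip: complement of T/C is A/G -> kept as-is
  ou3 <- make_records(1, effect_allele = "T", other_allele = "C",
                      beta = -0.05, eaf = 0.3)
  h3 <- harmonize(ex, ou3)
  expect_equal(h3$beta_outcome, -0.05)

  # strand flip plus swap: complement of C/T is G/A -> negated
  ou4 <- make_records(1, effect_allele = "C", other_allele = "T",
                      beta = -0.05, eaf = 0.3)
  h4 <- harmonize(ex, ou4)
  expect_equal(h4$beta_outcome, 0.05)

  # irreconcilable allele sets are dropped
  ou5 <- make_records(1, effect_allele = "A", other_allele = "C",
                      beta = -0.05, eaf = 0.3)
  h5 <- harmonize(ex, ou5)
  expect_equal(nrow(h5), 0)
  expect_equal(attr(h5, "n_dropped_mismatch"), 1L)
})

test_that("ambiguous palindromic SNPs are dropped, unambiguous ones oriented", {
  ex <- make_records(1, effect_allele = "A", other_allele = "T",
                     beta = 0.1, eaf = 0.49)
  ou <- make_records(1, effect_allele = "A", other_allele = "T",
                     beta = 0.05, eaf = 0.49)
  h <- harmonize(ex, ou, palindromic_eaf_window = 0.08)
  expect_equal(nrow(h), 0)
  expect_equal(attr(h, "n_dropped_palindromic"), 1L)

  # clear frequencies on the same side: retained as-is
  ex2 <- make_records(1, effect_allele = "A", other_allele = "T",
                      beta = 0.1, eaf = 0.2)
  ou2 <- make_records(1, effect_allele = "A", other_allele = "T",
                      beta = 0.05, eaf = 0.25)
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_outcome, 0.05)

  # frequencies on opposite sides: the reported letters sit on opposite
  # strands, so the effect flips to match the exposure orientation
  ou3 <- make_records(1, effect_allele = "A", other_allele = "T",
                      beta = 0.05, eaf = 0.8)
  h3 <- harmonize(ex2, ou3)
  expect_equal(h3$beta_outcome, -0.05)
  expect_equal(h3$eaf_outcome, 0.2)
})

test_that("duplicate snp ids are rejected with the offenders listed", {
  ex <- make_records(2, snp_id = c("rs001", "rs001"))
  ou <- make_records(2)
  expect_error(harmonize(ex, ou), "rs001")
})

test_that("harmonization is idempotent", {
  sim <- simulate_gwas_pair(synthetic_config(m_snps = 60, seed = 5,
                                             palindromic_frac = 0.2))
  h1 <- harmonize(sim$exposure, sim$outcome)
  # rebuild an outcome table already on the exposure orientation
  keep <- match(h1$snp_id, sim$outcome$snp_id)
  ou2 <- sim$outcome[keep, , drop = FALSE]
  ou2$beta <- h1$beta_outcome
  ou2$eaf <- h1$eaf_outcome
  ex2 <- sim$exposure[match(h1$snp_id, sim$exposure$snp_id), , drop = FALSE]
  h2 <- harmonize(ex2, ou2)
  expect_equal(h2$beta_outcome, h1$beta_outcome)
  expect_equal(h2$beta_exposure, h1$beta_exposure)
  expect_equal(attr(h2, "n_flipped"), 0L)
})

test_that("flipping every exposure effect allele only changes signs", {
  sim <- simulate_gwas_pair(synthetic_config(m_snps = 40, theta = 0.1,
                                             palindromic_frac = 0, seed = 8))
  h1 <- harmonize(sim$exposure, sim$outcome)
  flipped <- sim$exposure
  tmp <- flipped$effect_allele
  flipped$effect_allele <- flipped$other_allele
  flipped$other_allele <- tmp
  flipped$beta <- -flipped$beta
  flipped$eaf <- 1 - flipped$eaf
  h2 <- harmonize(flipped, sim$outcome)
  expect_equal(h2$beta_exposure, -h1$beta_exposure)
  expect_equal(h2$beta_outcome, -h1$beta_outcome)
  b1 <- mr_ivw(h1, model = "fixed")
  b2 <- mr_ivw(h2, model = "fixed")
  expect_equal(b2$b, b1$b)   # double negation cancels in the slope
  expect_equal(b2$se, b1$se)
})
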