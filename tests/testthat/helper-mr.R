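# Shorthand for a harmonized set built from aligned effect vectors.
make_h <- function(bx, by, sy, sx = rep(0.01, length(bx)), ...) {
  harmonized_set(beta_exposure = bx, se_exposure = sx,
                 beta_outcome = by, se_outcome = sy, ...)
}

# A canonical summary-statistics record table, with overridable fields.
make_records <- function(n = 3, ...) {
  rec <- data.frame(
    snp_id = sprintf("rs%03d", seq_len(n)),
    chrom = "1",
    pos = seq_len(n) * 2e7,
    effect_allele = rep_len(c("A", "C", "G"), n),
    other_allele = rep_len(c("G", "T", "A"), n),
    eaf = rep_len(c(0.2, 0.3, 0.4), n),
    beta = rep_len(c(0.05, -0.04, 0.06), n),
    se = 0.005,
    pval = rep_len(c(1e-20, 1e-15, 1e-12), n),
    n = 136016,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

# Simulate, harmonize, return the harmonized set (no instrument selection).
sim_h <- function(...) {
  sim <- simulate_gwas_pair(synthetic_config(...))
  harmonize(sim$exposure, sim$outcome)
}
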