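# Fixture builders shared across the test files. Everything is generated
# in code; nothing is read from disk except temp files written here.

# Write a summary-statistics data.frame to a temp file and read it back
# through the public reader.
sumstats_from_df <- function(df, label = "test", ...) {
  f <- tempfile(fileext = ".tsv")
  on.exit(unlink(f))
  write.table(df, f, sep = "\t", row.names = FALSE, quote = FALSE)
  read_sumstats(f, trait_label = label, ...)
}

# A small well-formed table: n non-palindromic SNPs on chromosomes 1..22.
toy_sumstats_df <- function(n = 10L, seed = 1L) {
  set.seed(seed)
  data.frame(
    SNP = sprintf("rs%d", seq_len(n)),
    CHR = rep(1:22, length.out = n),
    BP = seq_len(n) * 1000L,
    A1 = "A", A2 = "G",
    BETA = rnorm(n, 0, 0.05),
    SE = runif(n, 0.01, 0.03),
    P = runif(n),
    N = 10000L,
    stringsAsFactors = FALSE)
}

# Exposure/outcome GWAS tables on a panel, with the instruments placed at
# the first SNP of consecutive blocks (so clumping keeps them all) and a
# known causal effect theta of exposure on outcome. Null background SNPs
# fill a few more blocks.
mr_gwas_pair <- function(panel, n_inst = 15L, theta = 0.2,
                         beta_exp_sd = 0.04, se_exp = 0.004,
                         se_out = 0.01, n_null = 30L, seed = 1L,
                         covariate_beta_sd = 0) {
  set.seed(seed)
  first <- panel$snps[, .SD[1L], by = block]
  stopifnot(nrow(first) >= n_inst + n_null %/% 10L)
  inst <- first[seq_len(n_inst)]
  b_exp <- rnorm(n_inst, 0, beta_exp_sd)
  b_exp <- b_exp + sign(b_exp) * 0.03          # keep them genome-wide strong
  b_out <- theta * b_exp + rnorm(n_inst, 0, se_out)
  null_snps <- panel$snps[!snp %in% inst$snp][seq_len(n_null)]
  mk <- function(ids, chr, bp, beta, se, label) {
    z <- beta / se
    dt <- data.table::data.table(
      snp = ids, chr = chr, bp = bp, a1 = "A", a2 = "G",
      beta = beta, se = se, p = 2 * pnorm(-abs(z)), n = 1e5)
    crosstrait:::.new_sumstats(dt, label)
  }
  exposure <- mk(c(inst$snp, null_snps$snp), c(inst$chr, null_snps$chr),
                 c(inst$bp, null_snps$bp),
                 c(b_exp + rnorm(n_inst, 0, se_exp),
                   rnorm(n_null, 0, se_exp)),
                 rep(c(se_exp, se_exp), c(n_inst, n_null)), "exposure")
  outcome <- mk(c(inst$snp, null_snps$snp), c(inst$chr, null_snps$chr),
                c(inst$bp, null_snps$bp),
                c(b_out + rnorm(n_inst, 0, se_out),
                  rnorm(n_null, 0, se_out)),
                rep(c(se_out, se_out), c(n_inst, n_null)), "outcome")
  cov_beta <- rnorm(n_inst + n_null, 0, covariate_beta_sd)
  covariate <- mk(c(inst$snp, null_snps$snp), c(inst$chr, null_snps$chr),
                  c(inst$bp, null_snps$bp), cov_beta,
                  rep(se_exp, n_inst + n_null), "covariate")
  list(exposure = exposure, outcome = outcome, covariate = covariate,
       b_exp = b_exp, theta = theta, inst_snps = inst$snp)
}

# Harmonized set built directly from vectors (for exact-algebra tests).
hset <- function(beta_exp, se_exp, beta_out, se_out) {
  dt <- data.table::data.table(
    snp = sprintf("iv%02d", seq_along(beta_exp)),
    beta_exp = beta_exp, se_exp = se_exp,
    beta_out = beta_out, se_out = se_out)
  dt[, f_stat := (beta_exp / se_exp)^2]
  data.table::setattr(dt, "class", c("harmonized_set", class(dt)))
  dt
}

# Standard heterogeneous-LD panel used by the recovery tests.
het_panel <- function(n_blocks = 200L, block_size = 100L)
  simulate_ld_panel(n_blocks, block_size,
                    seq(0, 0.95, length.out = n_blocks))
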