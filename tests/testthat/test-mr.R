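test_that("select_instruments applies threshold, clumping and F filter", {
  panel <- simulate_ld_panel(5, 10, 0.9)
  snps <- panel$snps
  mk <- function(rows, beta, se) {
    dt <- data.table::data.table(
      snp = rows$snp, chr = rows$chr, bp = rows$bp, a1 = "A", a2 = "G",
      beta = beta, se = se, p = 2 * pnorm(-abs(beta / se)), n = 1e5)
    crosstrait:::.new_sumstats(dt, "exp")
  }
  # single strong SNP: retained
  one <- mk(snps[1], 0.1, 0.1 / sqrt(50))           # F = 50, p ~ 1.5e-12
  got <- select_instruments(one, panel)
  expect_equal(got$snp, snps$snp[1])

  # two SNPs in strong LD (adjacent, r2 = 0.81): smaller p wins
  two <- mk(snps[1:2], c(0.12, 0.11), 0.1 / sqrt(50))
  got2 <- select_instruments(two, panel)
  expect_equal(got2$snp, snps$snp[1])               # the 0.12 one

  # independent blocks are both kept
  far <- mk(snps[c(1, 11)], c(0.12, 0.11), 0.1 / sqrt(50))
  expect_equal(nrow(select_instruments(far, panel)), 2L)

  # nothing genome-wide: error
  weak <- mk(snps[1:3], 0.001, 0.01)
  expect_error(select_instruments(weak, panel), "no valid instruments")

  # strong p but weak F cannot happen with (beta/se)^2; force via exclusions
  expect_error(select_instruments(one, panel, exclusions = snps$snp[1]),
               "no valid instruments")
})

test_that("harmonize aligns, flips and audits", {
  mk <- function(snp, a1, a2, beta, eaf = NA_real_) {
    dt <- data.table::data.table(snp = snp, chr = 1L,
                                 bp = seq_along(snp) * 1e6,
                                 a1 = a1, a2 = a2, beta = beta, se = 0.01,
                                 p = 1e-10, n = 1e5, eaf = eaf)
    crosstrait:::.new_sumstats(dt, "t")
  }
  ex <- mk(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "G", "T"),
           c(0.1, 0.2, 0.3), c(0.3, 0.3, 0.2))
  oc_same <- mk(c("rs1", "rs2", "rs3"), c("A", "A", "A"), c("G", "G", "T"),
                c(0.01, 0.02, 0.03), c(0.31, 0.29, 0.21))
  h <- harmonize(ex, oc_same)
  expect_equal(h$beta_out, c(0.01, 0.02, 0.03))     # identity: unchanged

  oc_swap <- mk(c("rs1", "rs2", "rs3"), c("G", "A", "A"), c("A", "G", "T"),
                c(0.01, 0.02, 0.03), c(0.69, 0.29, 0.21))
  h2 <- harmonize(ex, oc_swap)
  expect_equal(h2[snp == "rs1"]$beta_out, -0.01)    # swapped: negated

  # palindromic with no frequency information: dropped with reason
  ex_noeaf <- mk(c("rs1", "rs3"), c("A", "A"), c("G", "T"), c(0.1, 0.3))
  oc_noeaf <- mk(c("rs1", "rs3"), c("A", "A"), c("G", "T"), c(0.01, 0.03))
  h3 <- harmonize(ex_noeaf, oc_noeaf)
  expect_equal(h3$snp, "rs1")
  aud <- attr(h3, "dropped")
  expect_equal(aud[snp == "rs3"]$reason, "palindromic-ambiguous")

  # palindromic with informative, opposite-side frequencies: strand flip
  ex_p <- mk("rs9", "A", "T", 0.1, eaf = 0.2)
  oc_p <- mk("rs9", "A", "T", 0.05, eaf = 0.8)
  h4 <- harmonize(ex_p, oc_p)
  expect_equal(h4$beta_out, -0.05)

  # mid-frequency palindrome is uninformative even with eaf present
  ex_m <- mk("rs8", "A", "T", 0.1, eaf = 0.5)
  oc_m <- mk("rs8", "A", "T", 0.05, eaf = 0.5)
  expect_error(harmonize(ex_m, oc_m), "empty harmonized set")
})

test_that("ivw equals the through-origin weighted regression oracle", {
  h <- hset(beta_exp = c(0.1, 0.2, 0.3), se_exp = 0.01,
            beta_out = c(0.05, 0.10, 0.15), se_out = c(0.01, 0.02, 0.01))
  est <- ivw(h)
  expect_equal(est$theta, 0.5, tolerance = 1e-12)   # exact ratio data
  expect_equal(est$or_, exp(0.5))

  set.seed(9)
  h2 <- hset(rnorm(10, 0, 0.05), runif(10, 0.003, 0.01),
             rnorm(10, 0, 0.05), runif(10, 0.005, 0.02))
  W <- diag(1 / h2$se_out^2)
  X <- matrix(h2$beta_exp)
  oracle <- solve(t(X) %*% W %*% X, t(X) %*% W %*% h2$beta_out)
  expect_equal(ivw(h2)$theta, drop(oracle), tolerance = 1e-10)

  expect_error(ivw(h2[1]), "at least 2")
})

test_that("OR confidence bounds are the exact exponential transform", {
  h <- simulate_mr_instruments(mr_sim_config(seed = 2))
  for (est in list(ivw(h), mr_egger(h)$estimate,
                   weighted_median(h, n_boot = 50, seed = 1))) {
    expect_equal(est$ci_low, exp(est$theta - 1.96 * est$se))
    expect_equal(est$ci_high, exp(est$theta + 1.96 * est$se))
    expect_equal(est$or_, exp(est$theta))
  }
})

test_that("mr_egger recovers an exact affine relationship", {
  b_exp <- c(0.05, 0.1, 0.15, 0.2, 0.3)
  h <- hset(b_exp, 0.005, 0.1 + 0.3 * b_exp, 0.01)
  eg <- mr_egger(h)
  expect_equal(eg$estimate$theta, 0.3, tolerance = 1e-10)
  expect_equal(eg$pleiotropy$egger_intercept, 0.1, tolerance = 1e-10)
  expect_error(mr_egger(h[1:2]), "at least 3")
})

test_that("weighted_median matches the plain median under equal weights", {
  # negligible se_exp makes the delta-method ratio weights exactly equal
  h <- hset(beta_exp = c(1, 1, 1), se_exp = 1e-12,
            beta_out = c(0.1, 0.2, 0.3), se_out = 0.01)
  wm <- weighted_median(h, n_boot = 100, seed = 1)
  expect_equal(wm$theta, 0.2, tolerance = 1e-6)
  # determinism of the bootstrap SE
  wm2 <- weighted_median(h, n_boot = 100, seed = 1)
  expect_identical(wm$se, wm2$se)

  # robust to 40% grossly invalid instruments
  set.seed(4)
  b_exp <- runif(10, 0.05, 0.2)
  b_out <- 0.3 * b_exp
  b_out[1:4] <- b_out[1:4] + 0.5
  h3 <- hset(b_exp, 0.002, b_out, 0.005)
  expect_equal(weighted_median(h3, n_boot = 200, seed = 2)$theta, 0.3,
               tolerance = 0.1)
})

test_that("cochran_q detects heterogeneity and not homogeneity", {
  b_exp <- c(0.1, 0.2, 0.4)
  h <- hset(b_exp, 0.005, 0.5 * b_exp, 0.01)
  q <- cochran_q(h)
  expect_equal(q$Q, 0, tolerance = 1e-20)
  expect_equal(q$p, 1)
  expect_equal(q$df, 2L)

  hits <- vapply(1:20, function(s) {
    h <- simulate_mr_instruments(mr_sim_config(theta = 0.2, n_outliers = 1,
                                               outlier_shift = 0.2,
                                               seed = 300 + s))
    cochran_q(h)$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("leave_one_out isolates a single outlier", {
  expect_equal(nrow(leave_one_out(hset(c(.1, .2, .3), .01,
                                       c(.05, .1, .15), .01))), 3L)
  h <- simulate_mr_instruments(mr_sim_config(theta = 0.2, n_outliers = 1,
                                             outlier_shift = 0.3, seed = 5))
  loo <- leave_one_out(h)
  full <- ivw(h)
  shift <- abs(loo$theta - full$theta)
  expect_equal(which.max(shift), attr(h, "outlier_idx"))
  # homogeneous set: every leave-out estimate stays within 1 SE
  h0 <- simulate_mr_instruments(mr_sim_config(theta = 0.2, seed = 6))
  loo0 <- leave_one_out(h0)
  expect_true(all(abs(loo0$theta - ivw(h0)$theta) < ivw(h0)$se))
})

test_that("mr_presso is deterministic and corrected equals IVW on keepers", {
  h <- simulate_mr_instruments(mr_sim_config(theta = 0.1, n_outliers = 1,
                                             seed = 7))
  # n_sim must exceed nIV / alpha for the Bonferroni outlier test to be
  # able to flag anything (min Monte-Carlo p is 1/(n_sim+1))
  pr <- mr_presso(h, n_sim = 1000, seed = 11)
  pr2 <- mr_presso(h, n_sim = 1000, seed = 11)
  expect_identical(pr$global_p, pr2$global_p)
  expect_true(length(pr$outlier_indices) >= 1)
  expect_equal(pr$corrected$theta, ivw(h[-pr$outlier_indices])$theta,
               tolerance = 1e-15)
  expect_false(is.na(pr$distortion_p))

  h0 <- simulate_mr_instruments(mr_sim_config(theta = 0.1, seed = 8))
  pr0 <- mr_presso(h0, n_sim = 400, seed = 12)
  expect_null(pr0$corrected)                        # no outliers, no correction
  expect_error(mr_presso(h0[1:3]), "insufficient instruments")
})

test_that("mvmr handles null and collinear covariates as specified", {
  panel <- simulate_ld_panel(60, 20, seq(0.1, 0.9, length.out = 60))
  gp <- mr_gwas_pair(panel, n_inst = 15, theta = 0.25, seed = 13,
                     covariate_beta_sd = 0)        # exact-zero covariate
  suppressWarnings(
    mv <- mvmr(list(gp$exposure, gp$covariate), gp$outcome, panel))
  uni <- ivw(harmonize(select_instruments(gp$exposure, panel), gp$outcome))
  expect_true(mv$rank_deficient || is.na(mv$estimates[[2]]$theta) ||
                abs(mv$estimates[[2]]$theta) < 1e-6)
  expect_equal(mv$estimates[[1]]$theta, uni$theta, tolerance = 0.05)

  # collinear exposures: flagged rank deficiency
  expect_warning(mv2 <- mvmr(list(gp$exposure, gp$exposure), gp$outcome,
                             panel), "rank-deficient")
  expect_true(mv2$rank_deficient)
})

test_that("run_bidirectional finds the simulated one-way causal effect", {
  panel <- simulate_ld_panel(60, 20, seq(0.1, 0.9, length.out = 60))
  gp <- mr_gwas_pair(panel, n_inst = 15, theta = 0.25, seed = 14)
  res <- run_bidirectional(gp$exposure, gp$outcome, panel,
                           n_traits_tested = 6L, seed = 14)
  expect_null(res$forward$error)
  expect_lt(res$forward$ivw$p, 0.05 / 6)
  expect_equal(res$forward$significance, "significant")
  expect_equal(res$forward$ivw$theta, 0.25, tolerance = 0.25)
  # reverse direction: outcome has no genome-wide instruments of its own
  expect_false(is.null(res$reverse$error) &&
                 res$reverse$ivw$p < 0.05 / 6)
})
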