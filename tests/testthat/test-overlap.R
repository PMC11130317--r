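gene_tbl <- function(genes, p) data.table::data.table(gene = genes, p = p)

test_that("count_overlap counts x, y, z over the shared universe", {
  g <- sprintf("G%03d", 1:100)
  t1 <- gene_tbl(g, c(rep(0.01, 20), rep(0.5, 80)))
  t2 <- gene_tbl(g, c(rep(0.01, 10), rep(0.5, 40), rep(0.02, 10),
                      rep(0.9, 40)))
  cnt <- count_overlap(t1, t2)
  expect_equal(cnt$total_genes, 100L)
  expect_equal(cnt$x, 20L)
  expect_equal(cnt$y, 20L)
  expect_equal(cnt$z, 10L)                            # overlap G001..G010

  expect_equal(count_overlap(t1, t1)$z, 20L)          # identical: z = x = y
  t3 <- gene_tbl(g, c(rep(0.5, 20), rep(0.01, 10), rep(0.5, 70)))
  expect_equal(count_overlap(t1, t3)$z, 0L)           # disjoint hit sets

  # the universe is the id intersection, and thresholds are strict
  t4 <- gene_tbl(c(g[1:50], "EXTRA"), c(rep(0.05, 50), 0.001))
  expect_equal(count_overlap(t1, t4)$total_genes, 50L)
  expect_equal(count_overlap(t1, t4)$y, 0L)           # p = 0.05 not < 0.05
})

test_that("binomial_overlap_test equals exhaustive tail enumeration", {
  enum_tail <- function(z, y, e)                      # independent oracle
    sum(choose(y, z:y) * e^(z:y) * (1 - e)^(y - (z:y)))
  for (y in c(1, 2, 5, 13, 27, 50)) {
    for (e in c(0.05, 0.285, 0.5, 0.9)) {
      for (z in unique(c(0, 1, y %/% 2, y))) {
        cnt <- structure(list(total_genes = 100L, x = 10L, y = y, z = z),
                         class = "overlap_counts")
        expect_equal(binomial_overlap_test(cnt, e_override = e)$p_binomial,
                     min(1, enum_tail(z, y, e)), tolerance = 1e-12)
      }
    }
  }
})

test_that("binomial_overlap_test edge cases and monotonicity", {
  mk <- function(z, y, x = 10L, tot = 100L)
    structure(list(total_genes = tot, x = x, y = y, z = z),
              class = "overlap_counts")
  expect_equal(binomial_overlap_test(mk(0, 10), e_override = 0.5)$p_binomial,
               1)
  expect_equal(binomial_overlap_test(mk(10, 10), e_override = 0.5)$p_binomial,
               0.5^10)
  expect_equal(binomial_overlap_test(mk(3, 5), e_override = 0.2)$p_binomial,
               sum(dbinom(3:5, 5, 0.2)), tolerance = 1e-14)
  # agreement with the stats::binom.test oracle
  expect_equal(binomial_overlap_test(mk(7, 30), e_override = 0.13)$p_binomial,
               binom.test(7, 30, 0.13, alternative = "greater")$p.value,
               tolerance = 1e-12)

  # non-increasing in z; non-decreasing in e
  ps_z <- vapply(0:20, function(z)
    binomial_overlap_test(mk(z, 20), e_override = 0.3)$p_binomial, numeric(1))
  expect_true(all(diff(ps_z) <= 1e-15))
  ps_e <- vapply(seq(0.05, 0.95, by = 0.05), function(e)
    binomial_overlap_test(mk(8, 20), e_override = e)$p_binomial, numeric(1))
  expect_true(all(diff(ps_e) >= -1e-15))

  expect_error(binomial_overlap_test(mk(1, 10), e_override = 0),
               "strictly in")
  # default expected proportion is the exact ratio x / total
  expect_equal(binomial_overlap_test(mk(3, 10, x = 25L, tot = 100L))$e, 0.25)
})

test_that("gws_threshold is alpha over the gene universe", {
  expect_equal(gws_threshold(0.05, 1), 0.05)
  expect_equal(signif(gws_threshold(0.05, 19105), 3), 2.62e-6)
  expect_equal(signif(gws_threshold(0.05, 6), 3), 8.33e-3)
})

test_that("fisher_combine matches the chi-square(4) survival oracle", {
  expect_equal(fisher_combine(1, 1), 1)
  set.seed(6)
  p1 <- runif(200); p2 <- runif(200)
  oracle <- pchisq(-2 * (log(p1) + log(p2)), df = 4, lower.tail = FALSE)
  expect_equal(fisher_combine(p1, p2), oracle, tolerance = 1e-12)
  expect_equal(fisher_combine(p1, p2), fisher_combine(p2, p1))
  expect_error(fisher_combine(0, 0.5), "must lie in")

  # combining a value with itself helps below ~0.28 and hurts near 1
  lo <- seq(0.001, 0.27, by = 0.01)
  expect_true(all(fisher_combine(lo, lo) < lo))
  hi <- seq(0.6, 0.99, by = 0.01)
  expect_true(all(fisher_combine(hi, hi) > hi))
})

test_that("classify_shared_genes partitions genes into the stated classes", {
  gws <- gws_threshold(0.05, 19105)
  tbl <- data.table::data.table(
    gene = c("a", "b", "c", "d", "e", "f"),
    p1 = c(1e-7, 1e-7, 0.03, 1e-4, 0.5, 1e-7),
    p2 = c(0.03, 1e-8, 1e-7, 1e-4, 0.01, 0.6))
  out <- classify_shared_genes(gene_tbl(tbl$gene, tbl$p1),
                               gene_tbl(tbl$gene, tbl$p2), gws)
  got <- out$category[match(tbl$gene, out$gene)]
  expect_equal(got[1], "1")                           # GWS t1, nominal t2
  expect_equal(got[2], "sentinel-shared")             # GWS in both
  expect_equal(got[3], "2")                           # GWS t2, nominal t1
  # (1e-4, 1e-4): X = -4 ln(1e-4) = 36.84, p_fcp < gws => category 3
  expect_equal(got[4], "3")
  expect_lt(out[gene == "d"]$p_fcp, gws)
  expect_equal(got[5], "none")
  expect_equal(got[6], "none")                        # t2 not even nominal

  # property: exhaustive and mutually exclusive on random tables
  set.seed(7)
  r1 <- 10^(-runif(500, 0, 8)); r2 <- 10^(-runif(500, 0, 8))
  g <- sprintf("g%03d", 1:500)
  rnd <- classify_shared_genes(gene_tbl(g, r1), gene_tbl(g, r2), gws)
  expect_equal(nrow(rnd), 500L)
  expect_true(all(rnd$category %in%
                    c("1", "2", "3", "sentinel-shared", "none")))
  # re-derive each class independently and compare
  chk <- with(rnd, ifelse(p1 < gws & p2 < gws, "sentinel-shared",
              ifelse(p1 < gws & p2 < 0.05, "1",
              ifelse(p2 < gws & p1 < 0.05, "2",
              ifelse(p1 >= gws & p1 < 0.05 & p2 >= gws & p2 < 0.05 &
                       p_fcp < gws, "3", "none")))))
  expect_equal(rnd$category, chk)
})

test_that("multi_trait_intersection recovers a constructed shared set", {
  gws <- 1e-4
  g <- sprintf("g%02d", 1:30)
  shared_all <- g[1:3]
  mk_pair <- function(extra) {
    hits <- c(shared_all, extra)
    data.table::data.table(gene = g, p1 = 0.5, p2 = 0.5,
                           p_fcp = ifelse(g %in% hits, 1e-6, 0.5),
                           category = ifelse(g %in% hits, "3", "none"))
  }
  res <- list(pud = mk_pair(g[4]), gerd = mk_pair(g[5]), ibs = mk_pair(g[4]))
  out <- multi_trait_intersection(res, gws = gws, mode = "fcp")
  expect_setequal(out$intersections$all, shared_all)
  out2 <- multi_trait_intersection(res, gws = gws, mode = "fcp",
                                   subsets = list(c("pud", "ibs")))
  expect_setequal(out2$intersections[[1]], c(shared_all, g[4]))
  # gene present in one pair only never appears in a >= 2-pair intersection
  expect_false(g[5] %in% out2$intersections[[1]])
  m <- out$membership
  expect_equal(m[gene == g[5]]$n_pairs, 1L)
  expect_equal(m[gene == g[1]]$n_pairs, 3L)
  # category mode agrees on this fixture
  out3 <- multi_trait_intersection(res, mode = "category")
  expect_setequal(out3$intersections$all, shared_all)
})

test_that("overlap test rejects at the nominal rate under independence", {
  # pi_shared = pi1 * pi2: gene hits are independent across traits
  rej <- vapply(1:200, function(s) {
    gg <- simulate_gene_pvalues(gene_sim_config(
      G = 2000L, pi1 = 0.2, pi2 = 0.2, pi_shared = 0.04,
      effect_scale = 3, seed = 7000 + s))
    binomial_overlap_test(count_overlap(gg[[1]], gg[[2]]))$p_binomial < 0.05
  }, logical(1))
  expect_lt(mean(rej), 0.35)
  expect_gt(mean(rej), 0.001)
})

test_that("overlap test has power when sharing is real", {
  hits <- vapply(1:50, function(s) {
    gg <- simulate_gene_pvalues(gene_sim_config(
      G = 2000L, pi1 = 0.1, pi2 = 0.1, pi_shared = 0.1, seed = 800 + s))
    binomial_overlap_test(count_overlap(gg[[1]], gg[[2]]))$p_binomial < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
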