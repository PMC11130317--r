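# Local (per-LD-block) genetic correlation: project per-locus z-statistics
# onto truncated principal components of the local LD matrix, estimate the
# local genetic covariance by method of moments with a cross-trait
# intercept correction, and obtain CIs / P values by seeded Monte Carlo.

#' Read a locus-definition file of semi-independent LD blocks
#'
#' Expects a delimited text file with columns `LOC CHR START STOP`
#' (case-insensitive). Coordinates are GRCh37, 1-based inclusive.
#' Overlapping loci on the same chromosome draw a warning but are kept.
#'
#' @param path File path.
#' @return data.table `locus, chr, start, stop`, sorted by (chr, start).
#' @export
read_locus_file <- function(path) {
  stopifnot(file.exists(path))
  raw <- data.table::fread(path, header = TRUE)
  nm <- tolower(names(raw))
  need <- c("loc", "chr", "start", "stop")
  if (!all(need %in% nm))
    stop("locus file must have columns LOC CHR START STOP; found: ",
         paste(names(raw), collapse = ", "))
  data.table::setnames(raw, names(raw), nm)
  out <- data.table::data.table(
    locus = suppressWarnings(as.integer(raw$loc)),
    chr = suppressWarnings(as.integer(raw$chr)),
    start = suppressWarnings(as.numeric(raw$start)),
    stop = suppressWarnings(as.numeric(raw$stop)))
  bad <- which(!stats::complete.cases(out) | out$start > out$stop)
  if (length(bad))
    stop("malformed locus row at line ", bad[1L] + 1L)
  if (anyDuplicated(out$locus)) stop("duplicate locus ids")
  data.table::setorder(out, chr, start)
  ov <- out[, any(start[-1L] <= head(stop, -1L)), by = chr]$V1
  if (any(ov)) warning("overlapping loci on the same chromosome; kept")
  out
}

#' Project per-locus z-statistics onto truncated LD principal components
#'
#' Eigendecomposes the local LD matrix `R`, retains the leading components
#' reaching `prop_var` (default 99%) cumulative variance, and returns
#' component scores `Lambda^(-1/2) Q' z`, which are i.i.d. standard normal
#' under the null of no local signal. A non-PSD `R` is projected to the
#' nearest PSD matrix (negative eigenvalues clamped to zero) with a
#' warning.
#'
#' @param z Per-SNP z-statistics in the locus.
#' @param R Local LD (correlation) matrix.
#' @param prop_var Cumulative-variance truncation point.
#' @return List: `scores` (length `K`), `K` (retained components),
#'   `eigenvalues` (all, descending).
#' @export
local_transform <- function(z, R, prop_var = 0.99) {
  stopifnot(length(z) >= 2L, nrow(R) == length(z), ncol(R) == length(z))
  e <- eigen(R, symmetric = TRUE)
  vals <- e$values
  if (any(vals < -1e-8)) {
    warning("local LD matrix not PSD; projecting to nearest PSD")
    vals <- pmax(vals, 0)
  }
  vals <- pmax(vals, 0)
  pos <- vals > 1e-10 * max(vals)
  cum <- cumsum(vals) / sum(vals)
  K <- min(which(cum >= prop_var - 1e-12))
  K <- min(K, sum(pos))
  scores <- drop(t(e$vectors[, seq_len(K), drop = FALSE]) %*% z) /
    sqrt(vals[seq_len(K)])
  list(scores = scores, K = K, eigenvalues = vals)
}

#' Univariate local association test
#'
#' Under the null the component scores are i.i.d. N(0, 1), so their sum of
#' squares is chi-square with `K` degrees of freedom. The observed-scale
#' local heritability estimate is `(sum(scores^2) - K) / N`.
#'
#' @param scores Component scores from [local_transform()].
#' @param K Number of retained components.
#' @param N GWAS sample size.
#' @return List: `local_h2_obs`, `p_uni`, `K`.
#' @export
local_univariate <- function(scores, K = length(scores), N) {
  T_obs <- sum(scores^2)
  list(local_h2_obs = (T_obs - K) / N,
       p_uni = pchisq(T_obs, df = K, lower.tail = FALSE),
       K = K)
}

#' Bivariate local genetic correlation at one locus
#'
#' Method-of-moments estimate: with component scores `s_t = a_t + e_t`
#' (genetic part plus unit-variance noise, noise correlated across traits
#' by the cross-trait intercept), the local genetic sums of squares are
#' `g_t = sum(s_t^2) - K` and the intercept-corrected cross product is
#' `g_12 = sum(s1 s2) - K * gcov_intercept`, giving
#' `rho = g12 / sqrt(g1 g2)` (clamped to `[-1, 1]`). The 95% CI is the
#' percentile interval of a seeded parametric Monte-Carlo sampling
#' distribution at the estimated parameters; `p_biv` compares the observed
#' `rho` against the same generator with local correlation forced to zero.
#' Explained variance `r2 = rho^2`; its CI squares the `rho` bounds when
#' the `rho` CI excludes zero, otherwise the lower bound is 0. A locus is
#' `completely_shared` when the upper `r2` bound reaches 1 within 5e-3.
#'
#' @param scores1,scores2 Component scores of the two traits (same
#'   components).
#' @param K Retained components (must be >= 2).
#' @param N1,N2 Sample sizes (used only for reporting scale).
#' @param gcov_intercept Cross-trait intercept accounting for sample
#'   overlap (0 = disjoint samples; 1 = same GWAS twice).
#' @param n_draws Monte-Carlo draws (default 5000).
#' @param seed Seed for the Monte-Carlo draws.
#' @return List of class `local_rg_result`: `rho, rho_lower, rho_upper,
#'   r2, r2_lower, r2_upper, p_biv, completely_shared, K`, or a skipped
#'   result with a `reason` when `K < 2` or a local heritability estimate
#'   is non-positive.
#' @export
local_bivariate <- function(scores1, scores2, K = length(scores1),
                            N1 = NA, N2 = NA, gcov_intercept = 0,
                            n_draws = 5000L, seed = 1L) {
  skip <- function(reason)
    structure(list(rho = NA_real_, rho_lower = NA_real_,
                   rho_upper = NA_real_, r2 = NA_real_,
                   r2_lower = NA_real_, r2_upper = NA_real_,
                   p_biv = NA_real_, completely_shared = NA, K = K,
                   reason = reason), class = "local_rg_result")
  if (K < 2L) return(skip("fewer than 2 retained components"))
  g1 <- sum(scores1^2) - K
  g2 <- sum(scores2^2) - K
  if (g1 <= 0 || g2 <= 0)
    return(skip("non-positive local heritability estimate"))
  g12 <- sum(scores1 * scores2) - K * gcov_intercept
  rho <- max(-1, min(1, g12 / sqrt(g1 * g2)))

  # parametric Monte Carlo of the estimator's sampling distribution
  c0 <- max(-0.999, min(0.999, gcov_intercept))
  draw_rho <- function(rho_g) {
    a1 <- matrix(rnorm(K * n_draws), K) * sqrt(g1 / K)
    u <- matrix(rnorm(K * n_draws), K)
    a2 <- (rho_g * a1 / sqrt(g1 / K) +
             sqrt(max(0, 1 - rho_g^2)) * u) * sqrt(g2 / K)
    e1 <- matrix(rnorm(K * n_draws), K)
    eu <- matrix(rnorm(K * n_draws), K)
    e2 <- c0 * e1 + sqrt(1 - c0^2) * eu
    s1 <- a1 + e1; s2 <- a2 + e2
    g1s <- colSums(s1^2) - K
    g2s <- colSums(s2^2) - K
    g12s <- colSums(s1 * s2) - K * gcov_intercept
    ok <- g1s > 0 & g2s > 0
    r <- rep(NA_real_, n_draws)
    r[ok] <- pmax(-1, pmin(1, g12s[ok] / sqrt(g1s[ok] * g2s[ok])))
    r[!ok] <- 0
    r
  }
  set.seed(seed)
  r_alt <- draw_rho(rho)
  r_null <- draw_rho(0)
  ci <- unname(quantile(r_alt, c(0.025, 0.975), na.rm = TRUE))
  rho_lower <- min(ci[1L], rho)
  rho_upper <- max(ci[2L], rho)
  p_biv <- (1 + sum(abs(r_null) >= abs(rho))) / (n_draws + 1)

  r2 <- rho^2
  if (rho_lower > 0 || rho_upper < 0) {
    b <- sort(c(rho_lower^2, rho_upper^2))
    r2_lower <- b[1L]; r2_upper <- b[2L]
  } else {
    r2_lower <- 0
    r2_upper <- max(rho_lower^2, rho_upper^2)
  }
  structure(list(rho = rho, rho_lower = rho_lower, rho_upper = rho_upper,
                 r2 = r2, r2_lower = r2_lower, r2_upper = r2_upper,
                 p_biv = p_biv,
                 completely_shared = r2_upper >= 1 - 5e-3, K = K,
                 reason = NA_character_),
            class = "local_rg_result")
}

#' Label local results for multiple testing
#'
#' Bonferroni over `n_tests` bivariate tests: `significant` below
#' `0.05 / n_tests`, `nominal` below 0.05, else `null`. With the maximum
#' of 33 tests the strict threshold is 1.52e-3.
#'
#' @param results data.table (or list coercible) with a `p_biv` column.
#' @param n_tests Bonferroni denominator.
#' @return Input with a `label` column added.
#' @export
filter_and_correct <- function(results, n_tests) {
  stopifnot(n_tests >= 1)
  dt <- data.table::as.data.table(results)
  lab <- label_significance(dt$p_biv, n_tests)
  dt[, label := ifelse(is.na(lab), NA_character_,
                       ifelse(lab == "ns", "null", lab))]
  dt
}

#' Run the full local genetic-correlation scan for one trait pair
#'
#' For each locus: subset the paired z-statistics, pull the local LD
#' matrix from the panel, transform to component scores, apply the
#' univariate filter (`p_uni < p_uni_threshold` required of both traits),
#' and run the bivariate test on the survivors.
#'
#' @param pair A `paired_sumstats` table.
#' @param panel An [simulate_ld_panel()] (supplies per-locus LD).
#' @param loci Locus table (default: the panel's own loci).
#' @param gcov_intercept Cross-trait intercept passed to
#'   [local_bivariate()].
#' @param p_uni_threshold Univariate progression filter (default 0.05).
#' @param n_draws,seed Monte-Carlo settings.
#' @param phen1,phen2 Trait labels for the output.
#' @return data.table with one row per locus: coordinates, univariate
#'   P values, and the bivariate estimate columns (`rho`, `rho_lower`,
#'   `rho_upper`, `r2`, `p_biv`, `completely_shared`, `status`).
#' @export
run_local_rg <- function(pair, panel, loci = NULL, gcov_intercept = 0,
                         p_uni_threshold = 0.05, n_draws = 5000L,
                         seed = 1L, phen1 = "trait1", phen2 = "trait2") {
  if (is.null(loci)) loci <- panel$loci
  snps <- panel$snps
  res <- vector("list", nrow(loci))
  for (i in seq_len(nrow(loci))) {
    lc <- loci[i]
    row <- data.table::data.table(
      locus = lc$locus, chr = lc$chr, start = lc$start, stop = lc$stop,
      phen1 = phen1, phen2 = phen2,
      p_uni_1 = NA_real_, p_uni_2 = NA_real_,
      rho = NA_real_, rho_lower = NA_real_, rho_upper = NA_real_,
      r2 = NA_real_, p_biv = NA_real_, completely_shared = NA,
      status = "no_snps")
    in_loc <- snps[chr == lc$chr & bp >= lc$start & bp <= lc$stop]
    d <- pair[match(in_loc$snp, pair$snp, nomatch = 0L)]
    in_loc <- in_loc[in_loc$snp %in% d$snp]
    if (nrow(d) >= 2L) {
      blk <- in_loc$block[1L]
      pos <- match(in_loc$snp, snps[block == blk]$snp)
      R <- panel$blocks[[blk]][pos, pos, drop = FALSE]
      tr1 <- local_transform(d$z1, R)
      tr2 <- local_transform(d$z2, R)
      K <- min(tr1$K, tr2$K)
      u1 <- local_univariate(tr1$scores[seq_len(K)], K, d$n1[1L])
      u2 <- local_univariate(tr2$scores[seq_len(K)], K, d$n2[1L])
      row[, `:=`(p_uni_1 = u1$p_uni, p_uni_2 = u2$p_uni)]
      if (u1$p_uni < p_uni_threshold && u2$p_uni < p_uni_threshold) {
        bv <- local_bivariate(tr1$scores[seq_len(K)],
                              tr2$scores[seq_len(K)], K,
                              d$n1[1L], d$n2[1L], gcov_intercept,
                              n_draws = n_draws,
                              seed = seed + lc$locus)
        row[, `:=`(rho = bv$rho, rho_lower = bv$rho_lower,
                   rho_upper = bv$rho_upper, r2 = bv$r2,
                   p_biv = bv$p_biv,
                   completely_shared = bv$completely_shared,
                   status = if (is.na(bv$rho)) bv$reason else "tested")]
      } else row[, status := "filtered_univariate"]
    }
    res[[i]] <- row
  }
  data.table::rbindlist(res)
}
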