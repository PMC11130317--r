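# Global SNP heritability and bivariate genetic correlation by LD score
# regression: weighted regression of z^2 (or z1*z2) on LD scores with a
# free intercept, two-step heteroscedasticity weights, and block-jackknife
# standard errors over contiguous genome-ordered SNP blocks.

# Weighted least squares of y on [1, x]; returns c(intercept, slope) plus
# the per-block partial sums needed for delete-one-block refits.
.wls_blocks <- function(y, x, w, block) {
  d <- data.table::data.table(
    sw = w, swx = w * x, swx2 = w * x^2, swy = w * y, swxy = w * x * y,
    block = block)
  bs <- d[, lapply(.SD, sum), by = block,
          .SDcols = c("sw", "swx", "swx2", "swy", "swxy")]
  tot <- colSums(bs[, -1L])
  solve2 <- function(s) {
    det <- s["sw"] * s["swx2"] - s["swx"]^2
    c(int = unname((s["swx2"] * s["swy"] - s["swx"] * s["swxy"]) / det),
      slope = unname((s["sw"] * s["swxy"] - s["swx"] * s["swy"]) / det))
  }
  loo <- t(apply(as.matrix(bs[, -1L]), 1L, function(b) solve2(tot - b)))
  list(full = solve2(tot), loo = loo)
}

.jackknife_se <- function(theta_b) {
  theta_b <- theta_b[is.finite(theta_b)]
  B <- length(theta_b)
  if (B < 2L) return(NA_real_)
  sqrt((B - 1) / B * sum((theta_b - mean(theta_b))^2))
}

.blocks_of <- function(n, n_blocks) {
  n_blocks <- min(n_blocks, n)
  as.integer(cut(seq_len(n), breaks = n_blocks, labels = FALSE))
}

# Core univariate fit on matched vectors; returns coefficients, per-block
# leave-one-out slopes, and the final weights (shared with the bivariate
# fit so that self-correlation is exactly 1).
.ldsc_uni <- function(z2, x, l, block) {
  w0 <- 1 / pmax(l, 1)
  f0 <- .wls_blocks(z2, x, w0, block)$full
  v <- f0["int"] + f0["slope"] * x       # fitted E[z^2]
  w <- 1 / (pmax(l, 1) * pmax(2 * v^2, 1e-6))
  fit <- .wls_blocks(z2, x, w, block)
  list(fit = fit, w = w, v = v)
}

#' Estimate SNP heritability by LD score regression
#'
#' Regresses `z^2` on `N * l / M` with a free intercept. Weights are the
#' canonical two-step scheme: `1/max(l, 1)` initially, then refit once
#' with the heteroscedasticity term `2 * (fitted E[z^2])^2` folded in.
#' The standard error comes from a delete-one-block jackknife over
#' `n_blocks` contiguous genome-ordered SNP blocks.
#'
#' @param tbl data.table with columns `snp`, `n`, and either `z` or
#'   `beta`/`se`; a munged `sumstats` table works directly.
#' @param ld LD-score table with columns `snp`, `l` (see [ld_scores()]).
#' @param M Number of SNPs the heritability is spread over (default: the
#'   number of matched SNPs).
#' @param n_blocks Jackknife blocks (default 200).
#' @return List of class `h2_estimate`: `h2, h2_se, intercept,
#'   intercept_se, M, n_snps`.
#' @export
estimate_h2 <- function(tbl, ld, M = NULL, n_blocks = 200L) {
  d <- .match_ld(tbl, ld)
  if (nrow(d) < n_blocks)
    stop("only ", nrow(d), " SNPs matched to LD scores; need >= ", n_blocks)
  if (is.null(M)) M <- nrow(d)
  blk <- .blocks_of(nrow(d), n_blocks)
  x <- d$n * d$l / M
  u <- .ldsc_uni(d$z^2, x, d$l, blk)
  structure(list(
    h2 = unname(u$fit$full["slope"]),
    h2_se = .jackknife_se(u$fit$loo[, "slope"]),
    intercept = unname(u$fit$full["int"]),
    intercept_se = .jackknife_se(u$fit$loo[, "int"]),
    M = M, n_snps = nrow(d)), class = "h2_estimate")
}

.match_ld <- function(tbl, ld) {
  dt <- data.table::as.data.table(tbl)
  if (!"z" %in% names(dt)) dt[, z := beta / se]
  d <- merge(dt[, .(snp, z, n = as.numeric(n),
                    chr = if ("chr" %in% names(dt)) chr else 0L,
                    bp = if ("bp" %in% names(dt)) bp else seq_len(.N))],
             data.table::as.data.table(ld)[, .(snp, l)], by = "snp")
  data.table::setorder(d, chr, bp)
  d
}

#' Estimate global genetic correlation by bivariate LD score regression
#'
#' The cross-trait regression of `z1 * z2` on `sqrt(N1 N2) * l / M` with a
#' free intercept yields the genetic covariance slope (`gcov`) and the
#' cross-trait intercept (`gcov_intercept`, which absorbs sample overlap
#' and shared confounding). Component heritabilities come from univariate
#' fits on the same SNPs; `rg = gcov / sqrt(h2_1 * h2_2)`. The standard
#' error of the full ratio is a delete-one-block jackknife (numerator and
#' both denominators refit per block), and `p` is a two-sided normal test
#' of `rg / se`. Estimates are not clipped; `|rg| > 1` draws a warning.
#' If either estimated heritability is non-positive, `rg` is `NA`
#' (flagged) but `gcov` and its jackknife P are still reported.
#'
#' @param pair A `paired_sumstats` table (see [align_pair()] or the
#'   simulators).
#' @param ld LD-score table (`snp`, `l`).
#' @param M SNP count for the polygenicity scaling (default: matched SNPs).
#' @param n_blocks Jackknife blocks (default 200).
#' @param n_traits_tested Number of target traits in the run; used only
#'   for the significance label (`0.05 / n_traits_tested`).
#' @return List of class `rg_estimate`: `rg, se, p, gcov, gcov_se,
#'   gcov_p, gcov_intercept, gcov_intercept_se, h2_1, h2_2, n_snps,
#'   significance`.
#' @export
estimate_rg <- function(pair, ld, M = NULL, n_blocks = 200L,
                        n_traits_tested = 1L) {
  d <- merge(data.table::as.data.table(pair),
             data.table::as.data.table(ld)[, .(snp, l)], by = "snp")
  d[, `:=`(n1 = as.numeric(n1), n2 = as.numeric(n2))]
  data.table::setorder(d, chr, bp)
  if (nrow(d) < n_blocks)
    stop("only ", nrow(d), " SNPs matched to LD scores; need >= ", n_blocks)
  if (is.null(M)) M <- nrow(d)
  blk <- .blocks_of(nrow(d), n_blocks)

  x1 <- d$n1 * d$l / M
  x2 <- d$n2 * d$l / M
  u1 <- .ldsc_uni(d$z1^2, x1, d$l, blk)
  u2 <- .ldsc_uni(d$z2^2, x2, d$l, blk)

  xc <- sqrt(d$n1 * d$n2) * d$l / M
  w0 <- 1 / pmax(d$l, 1)
  f0 <- .wls_blocks(d$z1 * d$z2, xc, w0, blk)$full
  cv <- f0["int"] + f0["slope"] * xc
  wc <- 1 / (pmax(d$l, 1) * pmax(u1$v * u2$v + cv^2, 1e-6))
  fc <- .wls_blocks(d$z1 * d$z2, xc, wc, blk)

  gcov <- unname(fc$full["slope"])
  h2_1 <- unname(u1$fit$full["slope"])
  h2_2 <- unname(u2$fit$full["slope"])

  rg_of <- function(g, a, b) {
    if (is.na(a) || is.na(b) || a <= 0 || b <= 0) return(NA_real_)
    g / sqrt(a * b)
  }
  rg <- rg_of(gcov, h2_1, h2_2)
  rg_loo <- mapply(rg_of, fc$loo[, "slope"],
                   u1$fit$loo[, "slope"], u2$fit$loo[, "slope"])
  se <- .jackknife_se(rg_loo)
  gcov_se <- .jackknife_se(fc$loo[, "slope"])
  p <- if (is.na(rg) || is.na(se) || se == 0) NA_real_ else
    2 * pnorm(-abs(rg / se))
  gcov_p <- if (is.na(gcov_se) || gcov_se == 0) NA_real_ else
    2 * pnorm(-abs(gcov / gcov_se))
  if (!is.na(rg) && abs(rg) > 1)
    warning("estimated |rg| exceeds 1 (", signif(rg, 3),
            "); reported unclipped")
  structure(list(
    rg = rg, se = se, p = p,
    gcov = gcov, gcov_se = gcov_se, gcov_p = gcov_p,
    gcov_intercept = unname(fc$full["int"]),
    gcov_intercept_se = .jackknife_se(fc$loo[, "int"]),
    h2_1 = h2_1, h2_2 = h2_2, n_snps = nrow(d),
    significance = label_significance(p, n_traits_tested)),
    class = "rg_estimate")
}

#' Bonferroni significance labels
#'
#' `"significant"` below `alpha / n_tests`, `"nominal"` below `alpha`,
#' otherwise `"ns"`. With six target traits the strict threshold is
#' 0.05/6 = 8.33e-3.
#'
#' @param p P value(s).
#' @param n_tests Bonferroni denominator.
#' @param alpha Family-wise level (default 0.05).
#' @return Character vector of labels.
#' @export
label_significance <- function(p, n_tests, alpha = 0.05) {
  out <- rep("ns", length(p))
  out[!is.na(p) & p < alpha] <- "nominal"
  out[!is.na(p) & p < alpha / n_tests] <- "significant"
  out[is.na(p)] <- NA_character_
  out
}

#' @export
print.rg_estimate <- function(x, ...) {
  cat(sprintf("rg = %.4g (se %.3g, p = %.3g) [%s]\n",
              x$rg, x$se, x$p, x$significance))
  cat(sprintf("  gcov = %.4g  intercept = %.4g  h2_1 = %.4g  h2_2 = %.4g  (%d SNPs)\n",
              x$gcov, x$gcov_intercept, x$h2_1, x$h2_2, x$n_snps))
  invisible(x)
}

#' @export
print.h2_estimate <- function(x, ...) {
  cat(sprintf("h2 = %.4g (se %.3g), intercept = %.4g (se %.3g), %d SNPs\n",
              x$h2, x$h2_se, x$intercept, x$intercept_se, x$n_snps))
  invisible(x)
}
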