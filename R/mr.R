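# Two-sample Mendelian randomisation: instrument selection by greedy LD
# clumping, allele harmonisation, the IVW / MR-Egger / weighted-median
# estimators with multiplicative random effects, Cochran's Q,
# leave-one-out, MR-PRESSO, and multivariable MR.

.new_mr_estimate <- function(method, theta, se, p, nIV) {
  structure(list(method = method, theta = theta, se = se,
                 or_ = exp(theta),
                 ci_low = exp(theta - 1.96 * se),
                 ci_high = exp(theta + 1.96 * se),
                 p = p, nIV = nIV), class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("%-16s OR %.3f (95%% CI %.3f-%.3f)  p = %.3g  nIV = %d\n",
              x$method, x$or_, x$ci_low, x$ci_high, x$p, x$nIV))
  invisible(x)
}

# squared allelic correlation between two panel SNPs (AR(1) within block,
# zero across blocks)
.panel_r2 <- function(panel, snp_a, snp_b) {
  m <- panel$snps[match(c(snp_a, snp_b), snp)]
  if (anyNA(m$block) || m$block[1L] != m$block[2L]) return(0)
  i <- panel$snps[block == m$block[1L], which(snp == snp_a)]
  j <- panel$snps[block == m$block[1L], which(snp == snp_b)]
  panel$rho_block[m$block[1L]]^(2 * abs(i - j))
}

#' Select LD-independent instruments for an exposure
#'
#' Keeps genome-wide significant SNPs (`p < p_threshold`), greedily clumps
#' them at `r2 < r2_threshold` within a `window` bp window (ascending P;
#' correlated neighbours of a kept index SNP are dropped), and requires
#' per-instrument strength `F = (beta/se)^2 > f_threshold`.
#'
#' @param exposure Munged `sumstats` table for the exposure.
#' @param panel [simulate_ld_panel()] supplying pairwise LD.
#' @param p_threshold Association threshold (default 5e-8).
#' @param r2_threshold Clumping threshold (default 0.001).
#' @param window Clumping window in bp (default 10 Mb).
#' @param f_threshold Weak-instrument cutoff (default 10).
#' @param exclusions Optional snp ids to remove up front (user-supplied
#'   list of suspected pleiotropic variants).
#' @return `sumstats` subset of selected instruments.
#' @export
select_instruments <- function(exposure, panel, p_threshold = 5e-8,
                               r2_threshold = 0.001, window = 1e7,
                               f_threshold = 10, exclusions = NULL) {
  cand <- data.table::as.data.table(exposure)[p < p_threshold]
  if (!is.null(exclusions)) cand <- cand[!snp %in% exclusions]
  if (nrow(cand) == 0L) stop("no valid instruments at p < ", p_threshold)
  data.table::setorder(cand, p)
  kept <- integer()
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (k in kept) {
      if (cand$chr[i] == cand$chr[k] &&
          abs(cand$bp[i] - cand$bp[k]) <= window &&
          .panel_r2(panel, cand$snp[i], cand$snp[k]) >= r2_threshold) {
        ok <- FALSE; break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  out <- cand[kept]
  out <- out[(beta / se)^2 > f_threshold]
  if (nrow(out) == 0L) stop("no valid instruments (all below F > ",
                            f_threshold, ")")
  data.table::setorder(out, chr, bp)
  .new_sumstats(data.table::copy(out), trait_label(exposure))
}

.new_harmonized <- function(dt, exposure_label, outcome_label, dropped) {
  dt[, f_stat := (beta_exp / se_exp)^2]
  data.table::setattr(dt, "exposure_label", exposure_label)
  data.table::setattr(dt, "outcome_label", outcome_label)
  data.table::setattr(dt, "dropped", dropped)
  data.table::setattr(dt, "class", c("harmonized_set", class(dt)))
  dt
}

#' Harmonise instruments against an outcome GWAS
#'
#' Aligns outcome effects to the exposure effect allele (sign-flipping
#' where the allele pair is swapped). Palindromic (A/T, C/G) instruments
#' are kept only when both effect-allele frequencies are present and
#' informative (both < 0.42 or both on the same side after flipping;
#' discordant or missing frequencies drop the SNP). Every drop is recorded
#' with its reason.
#'
#' @param instruments `sumstats` subset from [select_instruments()].
#' @param outcome Munged `sumstats` table for the outcome.
#' @param eaf_bounds Frequency window treated as uninformative for
#'   palindromes (default `c(0.42, 0.58)`).
#' @return A `harmonized_set`: data.table `snp, beta_exp, se_exp,
#'   beta_out, se_out, f_stat` with a `dropped` audit attribute.
#' @export
harmonize <- function(instruments, outcome, eaf_bounds = c(0.42, 0.58)) {
  stopifnot(nrow(instruments) > 0L)
  ex <- data.table::as.data.table(instruments)
  oc <- data.table::as.data.table(outcome)
  dropped <- list()
  rows <- list()
  for (i in seq_len(nrow(ex))) {
    s <- ex$snp[i]
    j <- match(s, oc$snp)
    if (is.na(j)) { dropped[[s]] <- "absent_from_outcome"; next }
    same <- oc$a1[j] == ex$a1[i] && oc$a2[j] == ex$a2[i]
    swapped <- oc$a1[j] == ex$a2[i] && oc$a2[j] == ex$a1[i]
    if (!same && !swapped) { dropped[[s]] <- "incompatible_alleles"; next }
    b_out <- if (swapped) -oc$beta[j] else oc$beta[j]
    if (.is_palindromic(ex$a1[i], ex$a2[i])) {
      eaf_e <- if ("eaf" %in% names(ex)) ex$eaf[i] else NA_real_
      eaf_o <- if ("eaf" %in% names(oc)) oc$eaf[j] else NA_real_
      if (swapped && !is.na(eaf_o)) eaf_o <- 1 - eaf_o
      inf_e <- !is.na(eaf_e) &&
        (eaf_e < eaf_bounds[1L] || eaf_e > eaf_bounds[2L])
      inf_o <- !is.na(eaf_o) &&
        (eaf_o < eaf_bounds[1L] || eaf_o > eaf_bounds[2L])
      if (!inf_e || !inf_o) {
        dropped[[s]] <- "palindromic-ambiguous"; next
      }
      # frequencies on opposite sides: the outcome is strand-flipped
      if ((eaf_e < 0.5) != (eaf_o < 0.5)) b_out <- -b_out
    }
    rows[[s]] <- data.table::data.table(
      snp = s, beta_exp = ex$beta[i], se_exp = ex$se[i],
      beta_out = b_out, se_out = oc$se[j])
  }
  if (!length(rows)) stop("empty harmonized set")
  audit <- data.table::data.table(snp = names(dropped),
                                  reason = unlist(dropped, use.names = FALSE))
  if (!length(dropped)) audit <- data.table::data.table(
    snp = character(), reason = character())
  .new_harmonized(data.table::rbindlist(rows),
                  trait_label(instruments) %||% "exposure",
                  trait_label(outcome) %||% "outcome", audit)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of `beta_out` on `beta_exp` through the origin with
#' weights `1/se_out^2`, with a multiplicative random-effects standard
#' error: the fixed-effects SE is inflated by `max(1, sqrt(Q/(nIV-1)))`
#' and never deflated. P value is two-sided normal. OR and CI by
#' exponentiation (`ci = exp(theta -/+ 1.96 se)`).
#'
#' @param h A `harmonized_set`.
#' @return An `mr_estimate`.
#' @export
ivw <- function(h) {
  n <- nrow(h)
  if (n < 2L) stop("IVW needs at least 2 instruments")
  w <- 1 / h$se_out^2
  sxx <- sum(w * h$beta_exp^2)
  theta <- sum(w * h$beta_exp * h$beta_out) / sxx
  Q <- sum(w * (h$beta_out - theta * h$beta_exp)^2)
  scale <- max(1, sqrt(Q / (n - 1)))
  se <- scale / sqrt(sxx)
  .new_mr_estimate("IVW", theta, se, 2 * pnorm(-abs(theta / se)), n)
}

#' MR-Egger regression and pleiotropy-intercept test
#'
#' Weighted regression of `beta_out` on `beta_exp` with a free intercept
#' and weights `1/se_out^2`. The slope is the pleiotropy-corrected causal
#' estimate; the intercept measures directional pleiotropy. Both use t
#' inference with `nIV - 2` df and the multiplicative random-effects
#' scale `max(1, sigma_hat)`.
#'
#' @param h A `harmonized_set`.
#' @return List: `estimate` (`mr_estimate`), `pleiotropy`
#'   (`egger_intercept`, `se`, `p`).
#' @export
mr_egger <- function(h) {
  n <- nrow(h)
  if (n < 3L) stop("MR-Egger needs at least 3 instruments")
  w <- 1 / h$se_out^2
  fit <- stats::lm(beta_out ~ beta_exp, data = h, weights = w)
  sm <- summary(fit)
  sigma <- sm$sigma
  adj <- max(1, sigma) / sigma
  slope <- sm$coefficients["beta_exp", ]
  inter <- sm$coefficients["(Intercept)", ]
  se_s <- slope["Std. Error"] * adj
  se_i <- inter["Std. Error"] * adj
  est <- .new_mr_estimate(
    "Egger", unname(slope["Estimate"]), unname(se_s),
    2 * stats::pt(-abs(slope["Estimate"] / se_s), df = n - 2L), n)
  pleio <- list(egger_intercept = unname(inter["Estimate"]),
                se = unname(se_i),
                p = unname(2 * stats::pt(-abs(inter["Estimate"] / se_i),
                                         df = n - 2L)))
  list(estimate = est, pleiotropy = pleio)
}

.ratio_stats <- function(h) {
  ratio <- h$beta_out / h$beta_exp
  se_ratio <- sqrt(h$se_out^2 / h$beta_exp^2 +
                     h$beta_out^2 * h$se_exp^2 / h$beta_exp^4)
  list(ratio = ratio, se = se_ratio)
}

.weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]; w <- w[o]
  p <- (cumsum(w) - 0.5 * w) / sum(w)
  if (p[1L] >= 0.5) return(ratio[1L])
  if (p[length(p)] <= 0.5) return(ratio[length(p)])
  stats::approx(p, ratio, xout = 0.5, ties = "ordered")$y
}

#' Weighted-median MR estimate
#'
#' Weighted median of the per-instrument ratio estimates
#' `beta_out/beta_exp` with inverse-variance weights from the first-order
#' delta-method ratio SE; consistent with up to 50% invalid instruments.
#' SE by seeded parametric bootstrap (resampling the observed effects at
#' their standard errors).
#'
#' @param h A `harmonized_set`.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed.
#' @return An `mr_estimate`.
#' @export
weighted_median <- function(h, n_boot = 1000L, seed = 1L) {
  keep <- h$beta_exp != 0
  if (any(!keep)) {
    warning(sum(!keep), " instrument(s) with beta_exp = 0 excluded")
    h <- h[keep]
  }
  n <- nrow(h)
  if (n < 3L) stop("weighted median needs at least 3 instruments")
  rs <- .ratio_stats(h)
  w <- 1 / rs$se^2
  theta <- .weighted_median_point(rs$ratio, w)
  set.seed(seed)
  boot <- replicate(n_boot, {
    be <- h$beta_exp + rnorm(n, 0, h$se_exp)
    bo <- h$beta_out + rnorm(n, 0, h$se_out)
    r <- bo / be
    sr <- sqrt(h$se_out^2 / be^2 + bo^2 * h$se_exp^2 / be^4)
    .weighted_median_point(r, 1 / sr^2)
  })
  se <- sd(boot)
  .new_mr_estimate("WeightedMedian", theta, se,
                   2 * pnorm(-abs(theta / se)), n)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum(w_i (ratio_i - theta)^2)` with IVW-equivalent ratio weights
#' `w_i = beta_exp_i^2 / se_out_i^2`, compared to chi-square with
#' `nIV - 1` df.
#'
#' @param h A `harmonized_set`.
#' @param theta Causal estimate to test around (default: IVW).
#' @return List: `Q`, `df`, `p`.
#' @export
cochran_q <- function(h, theta = NULL) {
  if (is.null(theta)) theta <- ivw(h)$theta
  w <- h$beta_exp^2 / h$se_out^2
  ratio <- h$beta_out / h$beta_exp
  Q <- sum(w * (ratio - theta)^2)
  df <- nrow(h) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Leave-one-out IVW analysis
#'
#' @param h A `harmonized_set` with at least 3 instruments.
#' @return data.table: `omitted, theta, se, or_, ci_low, ci_high, p`.
#' @export
leave_one_out <- function(h) {
  n <- nrow(h)
  if (n < 3L) stop("leave-one-out needs at least 3 instruments")
  out <- lapply(seq_len(n), function(i) {
    e <- ivw(h[-i])
    data.table::data.table(omitted = h$snp[i], theta = e$theta, se = e$se,
                           or_ = e$or_, ci_low = e$ci_low,
                           ci_high = e$ci_high, p = e$p)
  })
  data.table::rbindlist(out)
}

# leave-one-out IVW slopes for each column of a matrix of outcome effects
# (rows = instruments); vectorised across simulation replicates
.loo_theta_matrix <- function(beta_exp, B_out, w) {
  s1 <- colSums(w * beta_exp * B_out)
  s2 <- sum(w * beta_exp^2)
  num <- sweep(-(w * beta_exp) * B_out, 2L, s1, "+")
  den <- s2 - w * beta_exp^2
  num / den
}

#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' The global test compares the observed leave-one-out weighted residual
#' sum of squares `RSS = sum(w_i (beta_out_i - theta_(-i) beta_exp_i)^2)`
#' with a seeded parametric simulation of its null distribution (outcome
#' effects redrawn about the leave-one-out fitted values at their standard
#' errors). Per-instrument outlier P values come from each instrument's
#' own simulated residual distribution, Bonferroni-corrected over `nIV`.
#' When outliers are found, the corrected estimate is the IVW fit on the
#' remaining instruments, and the distortion test compares crude vs
#' corrected against the distribution obtained by removing random
#' instrument subsets of the same size.
#'
#' @param h A `harmonized_set` with at least 4 instruments.
#' @param n_sim Simulation replicates for the global and distortion nulls
#'   (default 1000).
#' @param seed Seed.
#' @param outlier_alpha Level of the Bonferroni outlier test (default
#'   0.05).
#' @return List of class `presso_result`: `global_rss`, `global_p`,
#'   `outlier_indices`, `outlier_p` (per instrument), `crude`
#'   (`mr_estimate`), `corrected` (`mr_estimate` or `NULL`),
#'   `distortion_p` (or `NA`).
#' @export
mr_presso <- function(h, n_sim = 1000L, seed = 1L, outlier_alpha = 0.05) {
  n <- nrow(h)
  if (n < 4L) stop("insufficient instruments for PRESSO (need >= 4)")
  w <- 1 / h$se_out^2
  set.seed(seed)

  theta_loo <- drop(.loo_theta_matrix(h$beta_exp, cbind(h$beta_out), w))
  resid_obs <- w * (h$beta_out - theta_loo * h$beta_exp)^2
  rss_obs <- sum(resid_obs)

  # parametric null: redraw outcome effects about the LOO fitted values
  B_sim <- matrix(rnorm(n * n_sim, mean = theta_loo * h$beta_exp,
                        sd = h$se_out), nrow = n)
  T_sim <- .loo_theta_matrix(h$beta_exp, B_sim, w)
  R_sim <- w * (B_sim - T_sim * h$beta_exp)^2
  rss_sim <- colSums(R_sim)
  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)

  outlier_p <- vapply(seq_len(n), function(i)
    (1 + sum(R_sim[i, ] >= resid_obs[i])) / (n_sim + 1), numeric(1))
  outlier_idx <- which(outlier_p * n < outlier_alpha)

  crude <- ivw(h)
  crude$method <- "PRESSO-crude"
  corrected <- NULL
  distortion_p <- NA_real_
  if (length(outlier_idx)) {
    corrected <- ivw(h[-outlier_idx])
    corrected$method <- "PRESSO-corrected"
    d_obs <- (crude$theta - corrected$theta) / abs(corrected$theta)
    keepers <- setdiff(seq_len(n), outlier_idx)
    d_sim <- replicate(n_sim, {
      drop_i <- sample(keepers, length(outlier_idx))
      th <- ivw(h[-drop_i])$theta
      (crude$theta - th) / abs(th)
    })
    distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_sim + 1)
  }
  structure(list(global_rss = rss_obs, global_p = global_p,
                 outlier_indices = outlier_idx, outlier_p = outlier_p,
                 crude = crude, corrected = corrected,
                 distortion_p = distortion_p),
            class = "presso_result")
}

#' Multivariable MR with several exposures
#'
#' Retrieves instruments for each exposure, pools and jointly clumps them,
#' re-extracts every clumped SNP from each exposure and the outcome,
#' harmonises all effects to the first exposure's allele orientation, and
#' fits the weighted multiple regression of outcome effects on all
#' exposure effects through the origin (weights `1/se_out^2`,
#' multiplicative random-effects SE). One conditional estimate per
#' exposure; an exposure whose effect column is degenerate (all zero or
#' collinear) is returned with an `NA` estimate and a rank-deficiency
#' flag.
#'
#' @param exposures List of munged `sumstats` tables (>= 2).
#' @param outcome Munged `sumstats` table.
#' @param panel LD panel for clumping.
#' @param labels Exposure labels (default: trait labels).
#' @param ... Passed to [select_instruments()].
#' @return List: `estimates` (list of `mr_estimate`, one per exposure;
#'   degenerate ones have `NA` theta), `nIV`, `rank_deficient` (logical).
#' @export
mvmr <- function(exposures, outcome, panel, labels = NULL, ...) {
  k <- length(exposures)
  stopifnot(k >= 2L)
  if (is.null(labels))
    labels <- vapply(seq_len(k), function(i)
      trait_label(exposures[[i]]) %||% paste0("exposure", i), character(1))
  cand <- unique(data.table::rbindlist(
    lapply(exposures, function(e)
      tryCatch(data.table::as.data.table(select_instruments(e, panel, ...)),
               error = function(err) NULL)),
    fill = TRUE), by = "snp")
  if (is.null(cand) || nrow(cand) == 0L) stop("no valid instruments")
  pool <- .new_sumstats(cand, "pooled")
  clumped <- select_instruments(pool, panel, p_threshold = 1, ...)

  ref <- exposures[[1L]]
  B <- matrix(NA_real_, nrow(clumped), k)
  keep <- rep(TRUE, nrow(clumped))
  bo <- seo <- rep(NA_real_, nrow(clumped))
  oc <- data.table::as.data.table(outcome)
  for (r in seq_len(nrow(clumped))) {
    s <- clumped$snp[r]
    a1 <- clumped$a1[r]; a2 <- clumped$a2[r]
    for (j in seq_len(k)) {
      e <- exposures[[j]]
      i <- match(s, e$snp)
      if (is.na(i)) { B[r, j] <- 0; next }  # no measurable effect recorded
      if (e$a1[i] == a1 && e$a2[i] == a2) B[r, j] <- e$beta[i]
      else if (e$a1[i] == a2 && e$a2[i] == a1) B[r, j] <- -e$beta[i]
      else keep[r] <- FALSE
    }
    i <- match(s, oc$snp)
    if (is.na(i)) { keep[r] <- FALSE; next }
    if (oc$a1[i] == a1 && oc$a2[i] == a2) bo[r] <- oc$beta[i]
    else if (oc$a1[i] == a2 && oc$a2[i] == a1) bo[r] <- -oc$beta[i]
    else keep[r] <- FALSE
    seo[r] <- oc$se[i]
  }
  B <- B[keep, , drop = FALSE]; bo <- bo[keep]; seo <- seo[keep]
  n <- length(bo)
  if (n <= k) stop("post-clump instrument count (", n,
                   ") must exceed the number of exposures (", k, ")")
  w <- 1 / seo^2
  fit <- stats::lm.wfit(B, bo, w)
  rank_def <- fit$rank < k
  coefs <- unname(fit$coefficients)
  rss <- sum(w * fit$residuals^2)
  sigma2 <- rss / (n - fit$rank)
  used <- !is.na(coefs)
  XtX <- crossprod(B[, used, drop = FALSE] * sqrt(w))
  vc <- diag(solve(XtX))
  scale <- max(1, sqrt(sigma2))
  ests <- vector("list", k)
  vi <- 1L
  for (j in seq_len(k)) {
    if (used[j]) {
      se_j <- sqrt(vc[vi]) * scale
      ests[[j]] <- .new_mr_estimate(paste0("MVMR:", labels[j]), coefs[j],
                                    se_j, 2 * pnorm(-abs(coefs[j] / se_j)),
                                    n)
      vi <- vi + 1L
    } else {
      ests[[j]] <- .new_mr_estimate(paste0("MVMR:", labels[j]),
                                    NA_real_, NA_real_, NA_real_, n)
    }
  }
  if (rank_def)
    warning("rank-deficient multivariable design; degenerate exposure(s) ",
            "returned with NA estimates")
  list(estimates = ests, nIV = n, rank_deficient = rank_def)
}

#' Bidirectional univariable MR with the full sensitivity suite
#'
#' Runs instrument selection, harmonisation, IVW, MR-Egger, weighted
#' median, Cochran's Q, leave-one-out and MR-PRESSO in both directions
#' (A as exposure of B, then B as exposure of A). A direction that fails
#' (e.g. no instruments) is reported with its error, not fatal to the
#' other direction. IVW P values are labelled at `0.05 / n_traits_tested`
#' and 0.05.
#'
#' @param traitA,traitB Munged `sumstats` tables.
#' @param panel LD panel for clumping.
#' @param n_traits_tested Bonferroni denominator for the significance
#'   label (default 6).
#' @param seed Seed for the stochastic components.
#' @param ... Passed to [select_instruments()].
#' @return List with elements `forward` and `reverse`, each either a list
#'   (`exposure`, `outcome`, `ivw`, `egger`, `pleiotropy`,
#'   `weighted_median`, `heterogeneity`, `leave_one_out`, `presso`,
#'   `significance`) or a list with an `error` message.
#' @export
run_bidirectional <- function(traitA, traitB, panel, n_traits_tested = 6L,
                              seed = 1L, ...) {
  run_dir <- function(exposure, outcome) {
    tryCatch({
      inst <- select_instruments(exposure, panel, ...)
      h <- harmonize(inst, outcome)
      est <- ivw(h)
      eg <- if (nrow(h) >= 3L) mr_egger(h) else NULL
      wm <- if (nrow(h) >= 3L) weighted_median(h, seed = seed) else NULL
      q <- cochran_q(h, est$theta)
      loo <- if (nrow(h) >= 3L) leave_one_out(h) else NULL
      pr <- if (nrow(h) >= 4L) mr_presso(h, seed = seed) else NULL
      list(exposure = trait_label(exposure), outcome = trait_label(outcome),
           nIV = nrow(h), ivw = est,
           egger = if (!is.null(eg)) eg$estimate else NULL,
           pleiotropy = if (!is.null(eg)) eg$pleiotropy else NULL,
           weighted_median = wm, heterogeneity = q, leave_one_out = loo,
           presso = pr,
           significance = label_significance(est$p, n_traits_tested))
    }, error = function(e) list(exposure = trait_label(exposure),
                                outcome = trait_label(outcome),
                                error = conditionMessage(e)))
  }
  list(forward = run_dir(traitA, traitB),
       reverse = run_dir(traitB, traitA))
}
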