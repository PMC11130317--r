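# Synthetic-data generators: every input the pipeline consumes can be
# produced here with known generative parameters, so each estimator is
# validated by parameter recovery rather than against external downloads.

#' Simulate a block-diagonal LD reference panel
#'
#' Blocks carry AR(1) correlation, `corr(i, j) = rho_block^|i-j|`, which is
#' symmetric positive-definite by construction for `0 <= rho_block < 1`.
#' Variants are laid out on consecutive chromosomes-worth of coordinates so
#' the panel doubles as a locus map: block `b` spans
#' `[(b-1)*block_span + 1, ...]` bp on a single synthetic chromosome per
#' 250 blocks.
#'
#' Per-block `rho_block` values may be supplied (recycled across blocks):
#' heterogeneous LD across blocks gives the spread of LD scores that real
#' panels have, which the LD score regression needs to separate slope
#' from intercept.
#'
#' @param n_blocks Number of LD blocks.
#' @param block_size SNPs per block.
#' @param rho_block AR(1) correlation parameter(s), each in `[0, 1)`;
#'   scalar or vector recycled to `n_blocks`.
#' @param seed Integer seed (reserved; the panel layout is deterministic).
#' @param block_span Base pairs spanned by one block (default 1 Mb).
#' @return An `ld_panel`: list with `snps` (data.table `snp, chr, bp,
#'   block`), `blocks` (list of correlation matrices) and `loci`
#'   (data.table `locus, chr, start, stop`).
#' @export
simulate_ld_panel <- function(n_blocks, block_size, rho_block, seed = 1L,
                              block_span = 1e6) {
  stopifnot(all(rho_block >= 0), all(rho_block < 1), n_blocks >= 1,
            block_size >= 1)
  rho_block <- rep_len(rho_block, n_blocks)
  lag <- abs(outer(seq_len(block_size), seq_len(block_size), "-"))
  blocks <- lapply(rho_block, function(r) r^lag)
  blk <- rep(seq_len(n_blocks), each = block_size)
  chr <- ((blk - 1L) %/% 250L) + 1L
  within_chr <- (blk - 1L) %% 250L
  bp <- within_chr * block_span +
    round(seq(1, block_span * 0.9, length.out = block_size))[
      rep(seq_len(block_size), times = n_blocks) ] +
    0
  snps <- data.table::data.table(
    snp = sprintf("rs%06d", seq_len(n_blocks * block_size)),
    chr = chr, bp = as.integer(bp), block = blk)
  loci <- snps[, .(chr = chr[1L], start = min(bp), stop = max(bp)),
               by = .(locus = block)]
  structure(list(snps = snps, blocks = blocks, loci = loci,
                 rho_block = rho_block, seed = seed),
            class = "ld_panel")
}

#' LD scores of a panel
#'
#' `l_j = sum_k r^2_jk` over SNP `j`'s block, including `j` itself
#' (so `l_j >= 1`).
#'
#' @param panel An [simulate_ld_panel()] result.
#' @return data.table with columns `snp, chr, bp, l`.
#' @export
ld_scores <- function(panel) {
  stopifnot(inherits(panel, "ld_panel"))
  l <- unlist(lapply(panel$blocks, function(R) colSums(R^2)),
              use.names = FALSE)
  out <- data.table::data.table(panel$snps[, .(snp, chr, bp)], l = l)
  out
}

#' Generative configuration for a pair of polygenic traits
#'
#' @param M Total SNPs.
#' @param N1,N2 GWAS sample sizes.
#' @param h2_1,h2_2 SNP heritabilities, in `[0, 1]`.
#' @param rg_true Genetic correlation in `[-1, 1]`; the genetic covariance
#'   is `gcov = rg_true * sqrt(h2_1 * h2_2)`.
#' @param rg_local Optional named numeric vector of per-locus genetic
#'   correlation overrides (names = locus ids) for effect-level simulation.
#' @param h2_local Optional named numeric vector giving the per-trait local
#'   heritability assigned to overridden loci (fraction of total h2 is
#'   unchanged elsewhere); used only by [simulate_pair_effect()].
#' @param Ns Number of overlapping samples (injects a cross-trait
#'   intercept `Ns * rho_p / sqrt(N1 * N2)` in moment-level simulation).
#' @param rho_p Phenotypic correlation within the overlapping samples.
#' @param seed Integer seed.
#' @return A `sim_pair_config` list.
#' @export
sim_pair_config <- function(M = 20000L, N1 = 50000, N2 = 50000,
                            h2_1 = 0.3, h2_2 = 0.2, rg_true = 0.3,
                            rg_local = NULL, h2_local = NULL,
                            Ns = 0, rho_p = 0, seed = 1L) {
  stopifnot(h2_1 >= 0, h2_1 <= 1, h2_2 >= 0, h2_2 <= 1,
            abs(rg_true) <= 1, Ns >= 0)
  gcov <- rg_true * sqrt(h2_1 * h2_2)
  structure(list(M = as.integer(M), N1 = N1, N2 = N2, h2_1 = h2_1,
                 h2_2 = h2_2, rg_true = rg_true, gcov = gcov,
                 rg_local = rg_local, h2_local = h2_local,
                 Ns = Ns, rho_p = rho_p, seed = as.integer(seed)),
            class = "sim_pair_config")
}

#' Moment-level simulation of paired GWAS z-statistics
#'
#' Draws `(z1j, z2j)` independently across SNPs from the bivariate normal
#' implied by the LD score regression moment structure:
#' `Var(z1j) = 1 + N1 h2_1 l_j / M`, `Var(z2j) = 1 + N2 h2_2 l_j / M`,
#' `Cov(z1j, z2j) = sqrt(N1 N2) gcov l_j / M + Ns rho_p / sqrt(N1 N2)`.
#' Cross-SNP correlation of z is ignored (fast mode for global-correlation
#' and calibration work); block-jackknife SEs computed downstream are
#' therefore approximate in exactly the way real LD makes them approximate.
#'
#' @param cfg A [sim_pair_config()].
#' @param ld LD-score table (`snp, l`; from [ld_scores()]); recycled or
#'   truncated to `cfg$M` SNPs.
#' @return A `paired_sumstats` data.table (`snp, chr, bp, z1, z2, n1, n2`).
#' @export
simulate_pair_moment <- function(cfg, ld) {
  stopifnot(inherits(cfg, "sim_pair_config"))
  M <- cfg$M
  if (nrow(ld) < M)
    ld <- ld[rep(seq_len(nrow(ld)), length.out = M)]
  ld <- ld[seq_len(M)]
  l <- ld$l
  v1 <- 1 + cfg$N1 * cfg$h2_1 * l / M
  v2 <- 1 + cfg$N2 * cfg$h2_2 * l / M
  cv <- sqrt(cfg$N1 * cfg$N2) * cfg$gcov * l / M +
    cfg$Ns * cfg$rho_p / sqrt(cfg$N1 * cfg$N2)
  bad <- which(cv^2 > v1 * v2)
  if (length(bad))
    stop("per-SNP covariance matrix not PSD at SNP index ", bad[1L])
  set.seed(cfg$seed)
  u1 <- rnorm(M); u2 <- rnorm(M)
  z1 <- sqrt(v1) * u1
  rho <- cv / sqrt(v1 * v2)
  z2 <- sqrt(v2) * (rho * u1 + sqrt(1 - rho^2) * u2)
  out <- data.table::data.table(
    snp = if ("snp" %in% names(ld)) ld$snp else sprintf("rs%06d", seq_len(M)),
    chr = if ("chr" %in% names(ld)) ld$chr else 1L,
    bp = if ("bp" %in% names(ld)) ld$bp else seq_len(M),
    z1 = z1, z2 = z2, n1 = cfg$N1, n2 = cfg$N2)
  data.table::setattr(out, "class", c("paired_sumstats", class(out)))
  out
}

#' Effect-level simulation of paired GWAS z-statistics with block LD
#'
#' Per LD block, joint standardised per-SNP effects `(d1, d2)` are drawn
#' i.i.d. bivariate normal with per-SNP variances `h2_t / M` and covariance
#' `gcov_b / M`, where `gcov_b` is the block's own genetic covariance
#' (globally `rg_true * sqrt(h2_1 h2_2)` or a per-locus override from
#' `cfg$rg_local` / `cfg$h2_local`). Marginal z-statistics follow
#' `z_t = sqrt(N_t) R d_t + e_t`, `e_t ~ MVN(0, R)`. Samples are assumed
#' disjoint in this mode (no intercept term).
#'
#' @param cfg A [sim_pair_config()]. If `cfg$h2_local` names a locus, both
#'   traits' per-SNP effect variance in that block is
#'   `h2_local[locus] / block_size` (a localised heritability concentration)
#'   instead of `h2_t / M`.
#' @param panel An [simulate_ld_panel()].
#' @return A `paired_sumstats` data.table.
#' @export
simulate_pair_effect <- function(cfg, panel) {
  stopifnot(inherits(cfg, "sim_pair_config"), inherits(panel, "ld_panel"))
  set.seed(cfg$seed)
  M <- nrow(panel$snps)
  zs <- vector("list", length(panel$blocks))
  for (b in seq_along(panel$blocks)) {
    R <- panel$blocks[[b]]
    k <- nrow(R)
    U <- chol(R)
    id <- as.character(b)
    rg_b <- if (!is.null(cfg$rg_local) && id %in% names(cfg$rg_local))
      cfg$rg_local[[id]] else cfg$rg_true
    if (!is.null(cfg$h2_local) && id %in% names(cfg$h2_local)) {
      s1 <- cfg$h2_local[[id]] / k
      s2 <- s1
    } else {
      s1 <- cfg$h2_1 / M
      s2 <- cfg$h2_2 / M
    }
    cv <- rg_b * sqrt(s1 * s2)
    if (cv^2 > s1 * s2 + 1e-12)
      stop("effect covariance not PSD in block ", b)
    u1 <- rnorm(k); u2 <- rnorm(k)
    d1 <- sqrt(s1) * u1
    rho <- if (s1 > 0 && s2 > 0) cv / sqrt(s1 * s2) else 0
    d2 <- sqrt(s2) * (rho * u1 + sqrt(pmax(0, 1 - rho^2)) * u2)
    e1 <- drop(crossprod(U, rnorm(k)))
    e2 <- drop(crossprod(U, rnorm(k)))
    z1 <- sqrt(cfg$N1) * drop(R %*% d1) + e1
    z2 <- sqrt(cfg$N2) * drop(R %*% d2) + e2
    zs[[b]] <- data.table::data.table(z1 = z1, z2 = z2)
  }
  zz <- data.table::rbindlist(zs)
  out <- data.table::data.table(panel$snps[, .(snp, chr, bp)],
                                z1 = zz$z1, z2 = zz$z2,
                                n1 = cfg$N1, n2 = cfg$N2)
  data.table::setattr(out, "class", c("paired_sumstats", class(out)))
  out
}

#' Generative configuration for paired gene-level P tables
#'
#' @param G Gene-universe size; default 18710, a realistic protein-coding
#'   universe after pairwise SNP intersection.
#' @param pi1,pi2 Marginal proportions of associated genes per trait.
#' @param pi_shared Proportion associated in both traits
#'   (`<= min(pi1, pi2)`).
#' @param effect_scale Mean of `-log10 P` for associated genes.
#' @param seed Integer seed.
#' @return A `gene_sim_config` list.
#' @export
gene_sim_config <- function(G = 18710L, pi1 = 0.1, pi2 = 0.1,
                            pi_shared = 0.05, effect_scale = 4,
                            seed = 1L) {
  stopifnot(pi_shared <= min(pi1, pi2) + 1e-12, pi1 <= 1, pi2 <= 1)
  structure(list(G = as.integer(G), pi1 = pi1, pi2 = pi2,
                 pi_shared = pi_shared, effect_scale = effect_scale,
                 seed = as.integer(seed)),
            class = "gene_sim_config")
}

#' Simulate a pair of gene-level association tables
#'
#' A configurable fraction of genes is associated in both traits
#' (`pi_shared`), in one only (to marginal rates `pi1`, `pi2`), or null.
#' Associated genes draw `-log10 P ~ Exp(mean = effect_scale)`; null genes
#' draw `P ~ Uniform(0, 1)`.
#'
#' @param cfg A [gene_sim_config()].
#' @return List of two data.tables (`gene, chr, start, stop, nsnps, p`)
#'   with attribute `truth` recording the membership of each gene
#'   (`"shared"`, `"t1"`, `"t2"`, `"null"`).
#' @export
simulate_gene_pvalues <- function(cfg) {
  stopifnot(inherits(cfg, "gene_sim_config"))
  set.seed(cfg$seed)
  G <- cfg$G
  n_sh <- round(G * cfg$pi_shared)
  n_1 <- round(G * (cfg$pi1 - cfg$pi_shared))
  n_2 <- round(G * (cfg$pi2 - cfg$pi_shared))
  lab <- rep("null", G)
  idx <- sample.int(G)
  lab[idx[seq_len(n_sh)]] <- "shared"
  if (n_1 > 0) lab[idx[n_sh + seq_len(n_1)]] <- "t1"
  if (n_2 > 0) lab[idx[n_sh + n_1 + seq_len(n_2)]] <- "t2"
  draw_p <- function(assoc) {
    p <- runif(G)
    k <- sum(assoc)
    if (k) p[assoc] <- 10^(-rexp(k, rate = 1 / cfg$effect_scale))
    pmin(pmax(p, .Machine$double.xmin), 1)
  }
  p1 <- draw_p(lab %in% c("shared", "t1"))
  p2 <- draw_p(lab %in% c("shared", "t2"))
  chr <- rep(1:22, length.out = G)
  start <- as.integer(seq_len(G)) * 50000L
  tmpl <- data.table::data.table(
    gene = sprintf("GENE%05d", seq_len(G)), chr = chr,
    start = start, stop = start + 20000L,
    nsnps = 10L)
  t1 <- data.table::copy(tmpl)[, p := p1]
  t2 <- data.table::copy(tmpl)[, p := p2]
  data.table::setattr(t1, "truth", lab)
  data.table::setattr(t2, "truth", lab)
  list(t1, t2)
}

#' Generative configuration for instrument-level MR data
#'
#' Defaults describe a well-powered two-sample setting: 30 instruments,
#' exposure effects with sd 0.04 measured with se 0.004 (median F well
#' above the conventional cutoff of 10), outcome se 0.01.
#'
#' @param n_inst Instrument count.
#' @param theta True causal effect (log-OR per SD of exposure).
#' @param pleiotropy_mode `"none"`, `"balanced"` or `"directional"`.
#' @param pleiotropy_sd SD of per-instrument pleiotropic effects.
#' @param pleiotropy_mean Mean pleiotropy under `"directional"`.
#' @param n_outliers Number of gross-outlier instruments.
#' @param outlier_shift Pleiotropic shift applied to each outlier.
#' @param beta_exp_sd SD of true exposure effects.
#' @param se_exp,se_out Standard errors of exposure and outcome estimates.
#' @param seed Integer seed.
#' @return An `mr_sim_config` list.
#' @export
mr_sim_config <- function(n_inst = 30L, theta = 0.1,
                          pleiotropy_mode = c("none", "balanced",
                                              "directional"),
                          pleiotropy_sd = 0.01, pleiotropy_mean = 0.02,
                          n_outliers = 0L, outlier_shift = 0.15,
                          beta_exp_sd = 0.04, se_exp = 0.004,
                          se_out = 0.01, seed = 1L) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_outliers < n_inst)
  structure(list(n_inst = as.integer(n_inst), theta = theta,
                 pleiotropy_mode = pleiotropy_mode,
                 pleiotropy_sd = pleiotropy_sd,
                 pleiotropy_mean = pleiotropy_mean,
                 n_outliers = as.integer(n_outliers),
                 outlier_shift = outlier_shift,
                 beta_exp_sd = beta_exp_sd, se_exp = se_exp,
                 se_out = se_out, seed = as.integer(seed)),
            class = "mr_sim_config")
}

#' Simulate a harmonised instrument set with known causal effect
#'
#' `beta_out_i = theta * beta_exp_i + alpha_i + noise` where `alpha_i` is
#' zero (`none`), zero-mean (`balanced`) or positive-mean (`directional`)
#' pleiotropy; `n_outliers` instruments additionally receive a gross
#' `outlier_shift`. Observed effects carry measurement noise at the
#' configured standard errors.
#'
#' @param cfg An [mr_sim_config()].
#' @return A `harmonized_set` (see [harmonize()]) with attribute
#'   `outlier_idx` recording which instruments were shifted.
#' @export
simulate_mr_instruments <- function(cfg) {
  stopifnot(inherits(cfg, "mr_sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_inst
  b_exp_true <- rnorm(n, 0, cfg$beta_exp_sd)
  alpha <- switch(cfg$pleiotropy_mode,
                  none = rep(0, n),
                  balanced = rnorm(n, 0, cfg$pleiotropy_sd),
                  directional = rnorm(n, cfg$pleiotropy_mean,
                                      cfg$pleiotropy_sd))
  outlier_idx <- integer()
  if (cfg$n_outliers > 0) {
    outlier_idx <- sample.int(n, cfg$n_outliers)
    alpha[outlier_idx] <- alpha[outlier_idx] +
      cfg$outlier_shift * sample(c(-1, 1), cfg$n_outliers, replace = TRUE)
  }
  b_out_true <- cfg$theta * b_exp_true + alpha
  h <- data.table::data.table(
    snp = sprintf("iv%03d", seq_len(n)),
    beta_exp = b_exp_true + rnorm(n, 0, cfg$se_exp),
    se_exp = cfg$se_exp,
    beta_out = b_out_true + rnorm(n, 0, cfg$se_out),
    se_out = cfg$se_out)
  h[, f_stat := (beta_exp / se_exp)^2]
  data.table::setattr(h, "exposure_label", "exposure")
  data.table::setattr(h, "outcome_label", "outcome")
  data.table::setattr(h, "dropped", data.table::data.table(
    snp = character(), reason = character()))
  data.table::setattr(h, "outlier_idx", outlier_idx)
  data.table::setattr(h, "class", c("harmonized_set", class(h)))
  h
}

#' Materialise a full synthetic study on disk
#'
#' Writes munged-format summary statistics for both traits, an LD-score
#' table (`SNP L2`), a locus-definition file (`LOC CHR START STOP`), the
#' pair of gene tables (`GENE CHR START STOP NSNPS P`) and a plain-text
#' truth file recording every generative parameter. Intended for CLI use
#' and end-to-end tests.
#'
#' @param dir Output directory (created if needed).
#' @param pair_cfg A [sim_pair_config()].
#' @param gene_cfg A [gene_sim_config()].
#' @param panel Optional [simulate_ld_panel()]; a small default panel is
#'   built when omitted.
#' @return Named list of file paths, invisibly.
#' @export
simulate_study <- function(dir, pair_cfg = sim_pair_config(),
                           gene_cfg = gene_sim_config(),
                           panel = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(panel)) {
    nb <- max(1L, pair_cfg$M %/% 100L)
    panel <- simulate_ld_panel(n_blocks = nb, block_size = 100L,
                               rho_block = seq(0, 0.95, length.out = nb),
                               seed = pair_cfg$seed)
  }
  ld <- ld_scores(panel)
  pair <- simulate_pair_moment(pair_cfg, ld)
  f <- function(...) file.path(dir, paste0(...))
  for (k in 1:2) {
    out <- data.table::data.table(
      SNP = pair$snp, CHR = pair$chr, BP = pair$bp, A1 = "A", A2 = "G",
      Z = if (k == 1) pair$z1 else pair$z2,
      N = if (k == 1) pair$n1 else pair$n2, P = 2 * pnorm(-abs(
        if (k == 1) pair$z1 else pair$z2)))
    data.table::fwrite(out, f("trait", k, ".sumstats.tsv"), sep = "\t")
  }
  data.table::fwrite(ld[, .(SNP = snp, L2 = l)], f("ldscores.tsv"),
                     sep = "\t")
  data.table::fwrite(panel$loci[, .(LOC = locus, CHR = chr, START = start,
                                    STOP = stop)],
                     f("loci.tsv"), sep = "\t")
  genes <- simulate_gene_pvalues(gene_cfg)
  for (k in 1:2)
    data.table::fwrite(
      genes[[k]][, .(GENE = gene, CHR = chr, START = start, STOP = stop,
                     NSNPS = nsnps, P = p)],
      f("genes", k, ".tsv"), sep = "\t")
  truth <- c(
    sprintf("# synthetic truth (seed %d)", pair_cfg$seed),
    sprintf("M: %d", pair_cfg$M),
    sprintf("N1: %g", pair_cfg$N1), sprintf("N2: %g", pair_cfg$N2),
    sprintf("h2_1: %g", pair_cfg$h2_1), sprintf("h2_2: %g", pair_cfg$h2_2),
    sprintf("rg_true: %g", pair_cfg$rg_true),
    sprintf("Ns: %g", pair_cfg$Ns), sprintf("rho_p: %g", pair_cfg$rho_p),
    sprintf("G: %d", gene_cfg$G),
    sprintf("pi1: %g", gene_cfg$pi1), sprintf("pi2: %g", gene_cfg$pi2),
    sprintf("pi_shared: %g", gene_cfg$pi_shared))
  writeLines(truth, f("truth.yaml"))
  invisible(list(sumstats1 = f("trait1.sumstats.tsv"),
                 sumstats2 = f("trait2.sumstats.tsv"),
                 ldscores = f("ldscores.tsv"), loci = f("loci.tsv"),
                 genes1 = f("genes1.tsv"), genes2 = f("genes2.tsv"),
                 truth = f("truth.yaml")))
}
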