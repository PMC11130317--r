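---
title: "Methods: cross-trait genetic correlation, Mendelian randomisation and gene-level overlap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-trait genetic correlation, Mendelian randomisation and gene-level overlap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosstrait)
```

# Scope

`crosstrait` implements a complete cross-trait analysis pipeline over GWAS
summary statistics for a pair (or small set) of complex traits -- the kind
of analysis used to dissect the shared genetics of, say, type 2 diabetes
and gastrointestinal disorders:

1. harmonisation and QC of per-variant summary records;
2. global genetic correlation by bivariate LD score regression;
3. local genetic correlation on semi-independent LD blocks;
4. bidirectional univariable and multivariable two-sample Mendelian
   randomisation with a full sensitivity suite;
5. gene-level overlap statistics: a one-sided exact binomial overlap test
   and Fisher's combined probability (FCP) classification of shared genes.

Every input the pipeline consumes can be generated by the synthetic-data
module, so each estimator is validated by parameter recovery on data with
known truth rather than against bundled reference downloads.

# Summary-statistics model and QC

A variant record carries (snp id, chromosome, GRCh37 position, effect and
other allele, effect size, SE, P, N, optional effect-allele frequency).
Odds ratios are converted to log-odds at read time so all downstream
algebra is on the log scale. Coordinates are 1-based and all interval
bounds (locus files, the MHC region) are inclusive at both ends.

Munging drops non-SNP alleles, strand-ambiguous palindromic variants
(A/T, C/G), and *all* copies of a duplicated id -- with summary data alone
there is no basis for adjudicating which duplicate is correct, so the
conservative choice is to remove the id entirely. The correlation stages
always drop palindromes; the MR harmoniser applies its own rule (below)
because allele frequencies can rescue palindromic instruments there.
Every filter reports its attrition count and the identity
`input rows = output rows + sum(drops)` is enforced and tested.

The default excluded MHC interval is chr6:28,477,797-33,448,354 (GRCh37),
with an extended chr6:25-34 Mb option, both ends inclusive.

# Global genetic correlation (LD score regression)

Under a polygenic model, the expected products of association
z-statistics follow

$$E[z_{1j} z_{2j}] = \frac{\sqrt{N_1 N_2}\,\rho_g}{M} \ell_j +
  \frac{N_s \rho_p}{\sqrt{N_1 N_2}},$$

where $\ell_j$ is SNP $j$'s LD score, $\rho_g$ the genetic covariance,
$M$ the number of SNPs, and the intercept absorbs sample overlap
($N_s$ overlapping samples with phenotypic correlation $\rho_p$) and
shared confounding. `estimate_h2()` and `estimate_rg()` fit these
regressions with **free intercepts always** (constraining them is not
offered), and

$$r_g = \hat\rho_g / \sqrt{\hat h^2_1 \hat h^2_2}.$$

Numerical choices:

* **Two-step weights.** Initial weights $1/\max(\ell_j, 1)$; one refit
  with the heteroscedasticity term from the fitted variance
  ($2 v_j^2$ univariate, $v_{1j} v_{2j} + c_j^2$ bivariate) folded in.
  This follows the canonical LD score regression scheme in spirit; it is
  an approximation and is validated by recovery, not by output-matching
  any particular published implementation. The univariate and bivariate
  weights are algebraically consistent, which makes
  `estimate_rg(align_pair(a, a))` return exactly 1.
* **Jackknife.** SEs come from a delete-one-block jackknife over 200
  contiguous genome-ordered SNP blocks (the conventional default). For
  $r_g$ the full ratio is recomputed per leave-out block. P values are
  two-sided normal on `rg/se`.
* **Degenerate heritability.** If an estimated $h^2 \le 0$, $r_g$ is
  reported as `NA` (not an imaginary number) while the covariance slope,
  its SE and P are still emitted. Estimates are never clipped; `|rg| > 1`
  logs a warning.
* **Significance labels** use `alpha/n_traits_tested` (0.05/6 = 8.33e-3
  when six target traits are run) and 0.05 for nominal.

# Local genetic correlation

Each locus (LD block) is analysed through a principal-component
transform of its LD matrix $R = Q \Lambda Q'$: component scores
$s = \Lambda^{-1/2} Q' z$ are i.i.d. standard normal under the null.
Components are truncated at 99% cumulative variance -- the standard
choice for local-covariance methods; the truncation point is exposed as
`prop_var`. A non-PSD input is projected to the nearest PSD matrix with
a warning.

The univariate filter refers $\sum s^2$ to $\chi^2_K$; only loci where
**both** traits pass `p_uni < 0.05` progress (whether the published
analyses filtered one or both traits is not stated; both-trait filtering
is the conservative reading and is what this package does). The
bivariate statistic is a method-of-moments correlation of the genetic
parts,

$$\hat\rho = \frac{\sum s_1 s_2 - K c_0}{\sqrt{(\sum s_1^2 - K)(\sum s_2^2 - K)}},$$

with $c_0$ the cross-trait intercept passed in from the global stage to
absorb sample overlap. The point estimate is clamped to $[-1, 1]$.

CIs and P values come from a seeded parametric Monte Carlo (default
5,000 draws) of the estimator's sampling distribution at the estimated
parameters (CI: percentile interval) and at $\rho = 0$ (P value),
rather than a closed form: the MC route is robust at small $K$ and is
exactly reproducible given the seed. Consequences worth knowing:

* the smallest attainable `p_biv` is `1/(n_draws + 1)`;
* the percentile CI is widened, if necessary, to contain the point
  estimate, preserving the `rho_lower <= rho <= rho_upper` invariant.

Explained variance is `r2 = rho^2` exactly (pre-rounding). Its CI
squares the `rho` bounds when the `rho` CI excludes zero; otherwise the
lower bound is 0 and the upper bound is the larger squared `rho` bound.
A locus is **completely shared** when the upper `r2` bound reaches 1
within 5e-3. Bonferroni labelling uses a configurable denominator
(0.05/33 = 1.52e-3 at the maximum of 33 tests, chosen for consistency
across pairs).

# Mendelian randomisation

Instrument selection keeps exposure SNPs at `p < 5e-8`, greedily clumped
at `r^2 < 0.001` within a 10 Mb window (the conventional companion
window for that threshold; the window is configurable), each with
`F = (beta/se)^2 > 10`. A user-supplied exclusion list stands in for
manual removal of suspected pleiotropic variants.

Harmonisation aligns outcome effects to the exposure effect allele.
Palindromic instruments are kept only when both effect-allele
frequencies are informative (outside 0.42-0.58); frequencies on opposite
sides imply a strand flip, concordant informative frequencies imply
matched strands, anything else drops the SNP with reason
`palindromic-ambiguous`.

Estimators:

* **IVW**: weighted through-origin regression, weights `1/se_out^2`,
  with a *multiplicative random-effects* SE -- the fixed-effects SE
  scaled by `max(1, sqrt(Q/(nIV-1)))`, never deflated. Wald P two-sided
  normal.
* **MR-Egger**: weighted regression with free intercept; slope and
  intercept use t inference with `nIV - 2` df and the same
  never-deflate scale rule. The intercept is the pleiotropy test.
* **Weighted median** of per-instrument ratios with first-order
  delta-method ratio SEs as weights; SE by seeded parametric bootstrap
  (default 1,000 replicates).
* **Cochran's Q** with IVW-equivalent ratio weights, `nIV - 1` df.
* **Leave-one-out** IVW per omitted instrument.
* **MR-PRESSO**: the global statistic is the weighted leave-one-out
  residual sum of squares; its null is a seeded parametric simulation
  (outcome effects redrawn about leave-one-out fitted values). Outlier
  P values are per-instrument tail probabilities under the same
  simulation, Bonferroni-corrected over `nIV`. The corrected estimate is
  IVW on the non-outliers -- *exactly*, which is tested. The distortion
  test resamples same-size random subsets. PRESSO internals differ
  across published implementations; this package's definitions are fixed
  as above and validated by calibration. Note a resolution constraint:
  with `n_sim` simulations the smallest Monte-Carlo P is
  `1/(n_sim + 1)`, so the Bonferroni outlier test can only ever flag
  anything when `n_sim > nIV/0.05`; the default `n_sim = 1000` is
  adequate for typical instrument counts.
* **Multivariable MR** pools per-exposure instruments, jointly clumps,
  re-extracts each exposure and the outcome, and fits a weighted
  multiple regression through the origin. Degenerate designs
  (an all-zero or collinear exposure column) are flagged as
  rank-deficient and that exposure's estimate is `NA`; the remaining
  conditional estimates are still returned, and with a null covariate
  the primary exposure's estimate reduces to its univariable IVW.

ORs and CIs are exact exponential transforms of the log-odds estimate
(`exp(theta +/- 1.96 se)`). `run_bidirectional()` executes the full
suite in both directions; a failed direction (e.g. no genome-wide
instruments for the reverse exposure) is reported as an error object
without aborting the other direction.

# Gene-level overlap

With a discovery and a target gene table restricted to their shared
universe of size $G$: $x$ and $y$ are the per-trait gene counts at
`p < 0.05` (strict `<` at every threshold, matching the convention the
statistics were defined with), $z$ the count below threshold in both.
The expected overlap proportion is $e = x/G$, the observed one
$O_{obs} = z/y$, and the one-sided exact binomial upper tail

$$P = \sum_{k=z}^{y} \binom{y}{k} e^k (1-e)^{y-k}$$

is accumulated in log space. By default $e$ is the full-precision ratio;
`e_override` exists solely to reproduce published calls that used a
rounded $e$. FCP is $X = -2(\ln p_1 + \ln p_2)$ referred to
$\chi^2_4$, computed via the closed-form survival function
$e^{-X/2}(1 + X/2)$; dependence between the two gene P values is
ignored (a documented caveat shared with the approach this reproduces).
Shared genes are classified as GWS-in-trait-1 + nominal-in-trait-2,
the converse, both-GWS ("sentinel-shared"), or nominal-in-both with
`p_fcp` reaching GWS (putatively novel); the printed condition
"0.05 < P > GWS" in the source material is read as `GWS <= P < 0.05`,
the only internally consistent interpretation. The gene universe size is
always an input (it varies by pair), never hard-coded.

# The synthetic-data world

The generators state a fixed world; their defaults are not tuning knobs.

* **LD panels** are block-diagonal AR(1) correlation matrices --
  closed-form, always positive-definite, no external reference needed.
  `rho_block` may vary per block (recycled vector). This matters: with a
  single rho all LD scores are nearly equal and the LD score regression
  cannot separate slope from intercept, so recovery simulations use
  per-block rho spanning 0-0.95, giving LD scores spanning roughly 1-19
  -- qualitatively the heterogeneity real panels have.
* **Moment-mode** paired z-statistics draw each SNP independently from
  the bivariate normal implied by the regression moments, with the
  sample-overlap intercept `Ns*rho_p/sqrt(N1*N2)` injected into the
  cross-covariance. Fast, used for global-rg and calibration work;
  because cross-SNP LD correlation of z is ignored, block-jackknife SEs
  are approximate in this mode (documented, and empirically adequate:
  coverage is checked in the acceptance suite).
* **Effect-mode** draws per-block standardised effects with the block's
  own genetic covariance (global or per-locus override) and builds
  `z = sqrt(N) R delta + MVN(0, R)`. Used for local-rg testing; assumes
  disjoint samples (no intercept), matching a setting with no
  substantial GWAS overlap.
* **Gene tables** assign shared/trait-specific/null labels and draw
  `-log10 P ~ Exp(mean = effect_scale)` for associated genes, uniform P
  for nulls. The default universe of 18,710 genes mirrors a realistic
  protein-coding universe after pairwise SNP intersection.
* **MR instruments**: `beta_out = theta*beta_exp + alpha + noise`, with
  balanced or directional pleiotropy and optional gross outliers.
  Default SEs (0.004 exposure, 0.01 outcome) and effect spread (sd 0.04)
  describe a well-powered two-sample setting where the median F is
  comfortably above 10.

What a green test does **not** establish: bit-compatibility with the
published LDSC/LAVA/TwoSampleMR/MR-PRESSO tools (estimators of the same
form are validated by recovery, not parity); behaviour under realistic
MAF spectra, annotation-stratified architectures, imputation error or
cross-ancestry LD (not modelled); robustness of moment-mode jackknife
SEs under strong long-range LD (moment mode has none).

# Determinism and seeds

Every stochastic routine takes an explicit seed and is bit-reproducible
given (configuration, seed): the generators, the local-rg Monte Carlo,
the weighted-median bootstrap, and both PRESSO resampling tests. The
acceptance script derives all of its streams from a single `--seed`.

# Known limitations

* The jackknife assumes exchangeable contiguous blocks; with fewer SNPs
  than blocks the fit aborts rather than silently degrade.
* The local-rg Monte Carlo CI is a sampling-distribution percentile
  interval, not a profile-likelihood interval; near `|rho| = 1` it is
  conservative on the inside edge.
* MVMR assumes the instrument effect matrix is measured without error
  (no weak-instrument correction for the covariate).
* No liftover, no VCF/BGEN parsing, no partitioned heritability, no
  constrained-intercept mode, no pathway enrichment against annotation
  services -- all deliberately out of scope.
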