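# crosstrait

Cross-trait statistical genetics from GWAS summary statistics: global and
local genetic correlation, bidirectional (multivariable) Mendelian
randomisation, and gene-level overlap statistics — the toolkit used to ask
whether two complex diseases (e.g. a metabolic and a gastrointestinal
disorder) share genetic aetiology, whether one causes the other, and which
genes they share.

## Who this is for

Statistical geneticists and epidemiologists with per-variant GWAS summary
statistics (no individual-level data) for two or more traits who want a
single tested pipeline for:

* **Global genetic correlation** `r_g` by bivariate LD score regression.
  With LD score `l_j`, the cross-trait regression is
  `E[z1_j z2_j] = sqrt(N1 N2) * rho_g * l_j / M + intercept`, the free
  intercept absorbing sample overlap and shared confounding;
  `r_g = rho_g / sqrt(h2_1 h2_2)`, with SEs from a 200-block jackknife.
* **Local genetic correlation** per semi-independent LD block, via
  truncated principal components of the local LD matrix, with seeded
  Monte-Carlo CIs, explained variance `r2 = rho^2` and a
  "completely shared" criterion (the 95% CI of `r2` includes 1).
* **Two-sample MR**: instrument selection (`p < 5e-8`, clumping at
  `r^2 < 0.001`, `F > 10`), harmonisation, IVW with multiplicative
  random effects, MR-Egger with pleiotropy-intercept test, weighted
  median, Cochran's Q, leave-one-out, MR-PRESSO
  (global / outlier / distortion tests), and multivariable MR adjusting
  for a second exposure such as BMI.
* **Gene-level overlap**: with `x` discovery hits, `y` target hits and
  `z` joint hits at `P_gene < 0.05` over a shared universe of `G` genes,
  the expected overlap proportion is `e = x/G`, the observed one `z/y`,
  compared by a one-sided exact binomial tail; plus Fisher's combined
  probability (`-2(ln p1 + ln p2) ~ chi^2_4`) classification of shared
  genes and multi-trait intersections.

A synthetic-data module generates LD panels, paired summary statistics
with known global/local genetic covariance and sample overlap, gene P
tables and MR instrument sets, so the whole pipeline is testable offline.

## Worked example

```r
library(crosstrait)

## a synthetic pair of traits with known rg = 0.3
panel <- simulate_ld_panel(200, 100, seq(0, 0.95, length.out = 200))
ld    <- ld_scores(panel)
cfg   <- sim_pair_config(M = 20000L, N1 = 50000, N2 = 50000,
                         h2_1 = 0.3, h2_2 = 0.2, rg_true = 0.3, seed = 42)
pair  <- simulate_pair_moment(cfg, ld)
estimate_rg(pair, ld, n_traits_tested = 6)
#> rg = 0.3013 (se 0.0261, p = 6.47e-31) [significant]
#>   gcov = 0.07501  intercept = 0.002198  h2_1 = 0.3077  h2_2 = 0.2014  (20000 SNPs)
```

The estimate recovers the simulated truth (0.3) within one jackknife SE;
the near-zero cross-trait intercept reflects the disjoint samples, and
"significant" means `p < 0.05/6` with six target traits.

```r
## gene-level overlap, counts as published for a diabetes-ulcer pair
cnt <- structure(list(total_genes = 18710L, x = 5359L, y = 1541L,
                      z = 517L), class = "overlap_counts")
binomial_overlap_test(cnt, e_override = 0.285)
#> e = 0.285, observed = 0.335 (33.5%), one-sided binomial P = 8.65e-06
```

33.5% of the target trait's associated genes are also discovery-trait
hits versus 28.5% expected by chance: far more overlap than chance
(P = 8.65e-6, exact upper binomial tail).

```r
## MR with 30 simulated instruments, true causal log-OR 0.1
h <- simulate_mr_instruments(mr_sim_config(n_inst = 30, theta = 0.1,
                                           seed = 42))
ivw(h); mr_egger(h)$estimate; weighted_median(h, seed = 1)
#> IVW              OR 1.081 (95% CI 1.004-1.163)  p = 0.0386  nIV = 30
#> Egger            OR 1.078 (95% CI 1.002-1.161)  p = 0.0536  nIV = 30
#> WeightedMedian   OR 1.071 (95% CI 0.966-1.187)  p = 0.192  nIV = 30
cochran_q(h)
#> Cochran Q = 19.12 (df 29), p = 0.92
```

All three estimators bracket the true OR `exp(0.1) = 1.105`; Q shows no
heterogeneity, as simulated.

## Command line

A multi-command entry point ships in `inst/cli/`:

```sh
CLI=$(Rscript -e 'cat(system.file("cli","crosstrait.R",package="crosstrait"))')
Rscript $CLI simulate --out-dir study --m 20000 --seed 3
Rscript $CLI rg --sumstats1 study/trait1.sumstats.tsv \
                --sumstats2 study/trait2.sumstats.tsv \
                --ldscores study/ldscores.tsv --n-traits-tested 6
Rscript $CLI overlap --discovery study/genes1.tsv --target study/genes2.tsv
```

Subcommands: `munge`, `simulate`, `rg`, `localrg`, `mr`, `overlap`.

## Documentation

`vignettes/crosstrait-methods.Rmd` documents the models, the weighting and
jackknife choices, the Monte-Carlo machinery, what the synthetic world
does and does not emulate, and known limitations.
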