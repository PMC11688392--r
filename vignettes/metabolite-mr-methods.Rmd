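---
title: "Methods: two-sample MR for metabolic biomarker panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR for metabolic biomarker panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabomr)
```

# The model

Two-sample Mendelian randomization estimates the causal effect $\theta$ of
an exposure (here, a circulating metabolic biomarker) on an outcome (here,
breast cancer liability on the log-odds scale) from two independent GWAS:
one giving per-SNP exposure associations $\hat\beta^x_j \pm s^x_j$, one
giving outcome associations $\hat\beta^y_j \pm s^y_j$. Under the three
instrumental-variable assumptions — the instruments are (1) associated with
the exposure, (2) independent of confounders, and (3) affect the outcome
only through the exposure — each variant provides a Wald ratio
$\hat\beta^y_j / \hat\beta^x_j$ estimating $\theta$, and the
inverse-variance weighted (IVW) estimator combines them:

$$\hat\theta_{IVW} = \frac{\sum_j w_j \hat\beta^x_j \hat\beta^y_j}
                          {\sum_j w_j (\hat\beta^x_j)^2},
  \qquad w_j = 1/(s^y_j)^2,$$

with fixed-effect standard error $(\sum_j w_j (\hat\beta^x_j)^2)^{-1/2}$.
This is exactly weighted regression of $\hat\beta^y$ on $\hat\beta^x$
through the origin, and equivalently the precision-weighted mean of the
Wald ratios with weights $(\hat\beta^x_j / s^y_j)^2$ — an identity the test
suite exploits as an independent oracle.

Because assumption (3) fails when a variant acts on the outcome through
other pathways (horizontal pleiotropy), three complementary estimators are
computed for every pair: MR-Egger regression (unconstrained intercept; the
slope is consistent under the InSIDE assumption even with directional
pleiotropy, and the intercept estimates its average), the weighted median
(consistent when at least half the weight is valid), and the weighted mode
(consistent when the largest homogeneous cluster is valid). All report
log-odds effects, converted to odds ratios with
$\mathrm{OR} = e^b$, CI $= e^{b \pm z_{0.975} s}$, and two-sided normal
p-values $2\Phi(-|b/s|)$. The normal (not $t$) reference was verified to
reproduce, to all printed digits, the odds-ratio and p-value columns of the
published breast-cancer tables shipped in `inst/extdata/`.

# Instrument selection

Instruments must pass, in order:

1. **Relevance**: exposure association $p < 10^{-8}$ (strictly below; the
   threshold is configurable — some panels use the conventional
   $5\times10^{-8}$).
2. **Independence**: greedy clumping — sort by p-value (ties broken
   lexicographically by SNP id, for determinism), take the best remaining
   SNP, discard same-chromosome SNPs within 10,000 kb whose pairwise
   $r^2 \ge 0.001$. The LD table is user-supplied (3 columns:
   `snp_a`, `snp_b`, `r2`); absent pairs count as $r^2 = 0$. Computing LD
   from a reference panel is out of scope.
3. **Strength**: per-SNP $R^2 = 2\,\mathrm{MAF}(1-\mathrm{MAF})\beta^2$
   (frequencies folded at 0.5) and $F = R^2 (N-2)/(1-R^2)$ with the
   exposure GWAS $N$; variants with $F < 10$ are excluded, the boundary
   $F = 10$ retained. The $R^2$ formula presumes standardized exposure
   units; records lacking a frequency cannot be assessed and are retained
   for estimation with a warning rather than silently discarded.

# Harmonization policy

Outcome records are aligned to the exposure's effect allele: identical
allele pairs pass unchanged; swapped pairs negate the outcome beta and
complement its frequency; complementary (strand-flipped) pairs are
complemented first; anything irreconcilable is dropped and counted.
Palindromic variants (A/T, C/G) are strand-ambiguous, so letters cannot
orient them; they are kept only when both allele frequencies fall on the
same side of 0.5 and outside $0.5 \pm 0.08$ (window configurable), with the
orientation inferred from frequency. The 0.08 default mirrors common
two-sample MR practice; source GWAS rarely document strand conventions, so
this policy is a package decision, not a data fact. Coordinates are 1-based
throughout, which matters because clumping does position arithmetic.

# Sensitivity analyses

- **Cochran's Q** at the IVW slope, $\chi^2_{k-1}$ reference. The model
  rule is strict: Q p-value $< 0.05$ selects the multiplicative
  random-effects IVW (standard error scaled by
  $\max(1, \sqrt{Q/(k-1)})$), otherwise fixed effects. The floor at 1
  prevents under-dispersion from shrinking errors below the fixed-effect
  ones; the same floor applies to the Egger residual scale.
- **MR-Egger intercept test**: directional pleiotropy is flagged at
  intercept $p \le 0.05$. Rows are pre-oriented to $\hat\beta^x_j \ge 0$
  because Egger regression is not invariant to allele orientation.
- **MR-PRESSO**: the observed residual sum of squares uses leave-one-out
  IVW slopes; its null distribution comes from parametric resimulation of
  both effect vectors (1000 draws by default, seed mandatory). Per-SNP
  contributions give Bonferroni-adjusted outlier p-values; the distortion
  test compares the estimate shift after outlier removal against removals
  of equally many random instruments. Empirical p-values use the
  $(1 + \#\{\cdot\})/(n_{sim}+1)$ convention, so they are never zero.
- **Steiger directionality**: summed instrument $R^2$ on each trait's own
  scale, compared through Fisher's z with the two sample sizes. The
  direction flag and the difference p-value are reported separately;
  "direction supported" requires *both* more variance explained in the
  exposure *and* a small p-value. (Prose summaries of this test are often
  ambiguous about which inequality "supports" the direction; keeping the
  two components separate avoids baking that ambiguity in.)
- **Leave-one-out** IVW, flagged unstable if any reduced-set estimate
  changes sign or its CI excludes the full estimate; **funnel data**
  (ratio vs precision) are emitted as plain tables — plotting is left to
  the user.

# Panel orchestration and multiplicity

`run_mr()` analyzes every exposure–outcome pair, then applies
Benjamini–Hochberg FDR (via `stats::p.adjust`) to the IVW p-values per
outcome, the family being all exposures analyzed against that outcome —
the IVW estimate is the primary method, and FDR-adjusted p-values are
reported for it alone. Significant effects are classified protective
(OR < 1) or risk (OR > 1). A nominal mode (`fdr_gate = FALSE`) gates
classification on raw p-values instead, matching the convention used for
subtype analyses whose findings are reported at nominal significance when
they do not survive multiplicity correction; Bonferroni can be emulated by
passing a larger family size to `bh_fdr()`-style pre-adjustment if wanted.
Pairs with fewer than two surviving instruments are skipped and logged, not
fatal. All per-pair randomness (bootstrap, PRESSO) is seeded
deterministically from the config seed, making full reruns byte-identical.

The package's functions, YAML-driven `run_config()`/`read_run_config()`,
and the scripts are the intended interface; the workflow is an R analysis,
not a shell tool, so no separate command-line binary is provided.

# The synthetic generator

`simulate_gwas_pair()` draws, per SNP: MAF $p_j \sim U(0.05, 0.5)$; true
instrument effect $\gamma_j \sim N(0, \sigma_\gamma^2)$ on a standardized
exposure scale; optional direct outcome effects $\alpha_j$ (balanced,
directional, confined to a fraction of SNPs, or correlated with $\gamma_j$
to break InSIDE); outcome truth $\Gamma_j = \theta\gamma_j + \alpha_j$; and
estimates with sampling errors $s^x_j = (2p_j(1-p_j)n_x)^{-1/2}$ and
$s^y_j = (2p_j(1-p_j)n_{eff})^{-1/2}$, where
$n_{eff} = 4/(1/n_{cases} + 1/n_{controls})$ is the standard effective
sample size for a log-odds-scale case-control GWAS (the outcome variance
model is a package choice; source publications typically leave it
implicit). Reverse causation is modeled by letting direct outcome effects
feed back into the exposure with coefficient `reverse_theta`. Positions are
spaced 20,000 kb apart so the default clumping window never merges SNPs,
and a configurable fraction (default 0.1) of allele pairs is palindromic to
exercise the harmonization policy.

Defaults emulate the motivating study's cohorts: $n_x = 136{,}016$
(metabolite GWAS) and $122{,}977$ cases / $105{,}974$ controls (breast
cancer). The default $\sigma_\gamma = 0.05$ gives per-SNP $F$ in the
hundreds — typical of genome-wide-significant metabolite loci, where single
variants commonly explain 0.05–0.3% of variance. Exposure effects are
assumed standardized (source units are predominantly mmol/l but vary by
biomarker); this makes the $R^2$ and standard-error formulas closed in the
reported columns and is documented rather than configurable.

What the generator does *not* emulate: LD between instruments (clumping is
exercised through a user-style pairwise $r^2$ table), frequency differences
between cohorts, sample overlap, population stratification, and
winner's-curse selection into the exposure GWAS. Passing tests therefore
validate the estimators and diagnostics under their own assumptions, not
robustness to every artifact of real summary statistics.

# Numerical choices and validation conditions

Problem sizes for the simulation-based checks were chosen so each property
is measured with useful precision while the whole suite stays quick on one
CPU:

- *Calibration*: 1000 replicates, 50 SNPs, $\theta = 0$. IVW rejects at
  $0.05 \pm 0.02$. The Egger intercept test is checked under modest
  balanced pleiotropy ($\alpha_j \sim N(0, 0.002^2)$, about half the
  outcome sampling SD); with constant-variance pleiotropy the
  multiplicative scaling is slightly mis-specified and the normal reference
  ignores the $t_{k-2}$ correction, so mild inflation (a rejection rate
  nearer 0.06) is expected and grows with the pleiotropy magnitude.
- *Recovery*: $\theta = 0.1$, 500 replicates, 50 strong instruments. For
  "strong" to mean what the check requires — regression-dilution
  attenuation (of order $\bar{s^x}^2/\sigma_\gamma^2$) negligible against
  Monte-Carlo noise — this scenario uses $\sigma_\gamma = 0.1$, i.e.
  $F \gtrsim 500$; at the generator default 0.05 the attenuation
  ($\approx 0.8\%$ of $\theta$) is of the same order as the Monte-Carlo
  standard error of the mean.
- *Robustness*: 20% of SNPs carry directional pleiotropy
  $\alpha = 0.02$ (about four outcome sampling SDs); the weighted median's
  mean absolute error beats IVW's.
- *PRESSO*: 100 replicates of 20 SNPs; an injected 10-SD outlier must be
  caught in at least 95%, clean data rejected in at most 7%.

Per-replicate seeds are drawn from a single master stream
(`sample.int` after one `set.seed`): linearly spaced seed sequences produce
subtly correlated Mersenne–Twister streams, which we observed as
several-MC-SE shifts in replicate means. Degenerate inputs are handled
explicitly: a single instrument degrades IVW to the Wald ratio with a
warning; identical ratios give the weighted mode a zero bandwidth and the
input ratio is returned; weighted-median/mode standard errors come from a
seeded parametric bootstrap (default 1000 draws) because no closed form is
standard; clumping ties break lexicographically.

# Known limitations

MR-Egger is reported without SIMEX correction; multivariable MR,
contamination-mixture and Bayesian estimators, radial MR and the Rucker
framework are out of scope. LD clumping requires a user-supplied $r^2$
table rather than a genotype reference panel. The binary-outcome standard
errors use the effective-sample-size approximation, adequate for
common-disease GWAS but not for rare outcomes. The Steiger test treats the
outcome $R^2$ on the observed log-odds scale, a common approximation.
Reverse-direction analyses are performed by re-running the pipeline with
the exposure and outcome roles swapped — that is what "reverse MR" denotes
procedurally — rather than by a separate algorithm.
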