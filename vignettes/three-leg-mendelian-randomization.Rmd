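---
title: "Three-leg two-sample Mendelian randomization with mediation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Three-leg two-sample Mendelian randomization with mediation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triomr)
```

## The question the package addresses

Inflammatory bowel disease (IBD) is accompanied, at elevated rates, by
extraintestinal manifestations (EIMs) — sarcoidosis, iridocyclitis,
ankylosing spondylitis, psoriatic arthropathies, primary sclerosing and
primary biliary cholangitis, and others. The gut microbiota is a
plausible intermediary: IBD perturbs the microbial community, and the
community in turn influences immune-mediated disease elsewhere. Whether
the microbiota *mediates* the IBD-to-EIM effects, rather than merely
co-varying with them, is a causal question that observational cohorts
cannot settle.

Two-sample Mendelian randomization (MR) approaches it with genetics:
variants associated with an exposure act as randomized instruments, and
the ratio of SNP-outcome to SNP-exposure associations estimates the
causal effect, using only published GWAS summary statistics from two
different study samples. `triomr` implements the full three-leg design:

1. IBD → each EIM (the total effects),
2. IBD → each gut-microbial taxon,
3. each taxon → each EIM,

followed by a product-of-coefficients mediation decomposition for taxa
implicated in both microbiota legs.

## Models and estimators

For instrument $j$, let $\hat\gamma_j$ (se $\sigma_{xj}$) be the
SNP-exposure association and $\hat\Gamma_j$ (se $\sigma_{yj}$) the
SNP-outcome association, both per effect allele on the log-odds scale
for binary traits. The per-SNP Wald ratio is
$\hat\theta_j = \hat\Gamma_j / \hat\gamma_j$ with first-order standard
error $\sigma_{yj} / |\hat\gamma_j|$ (exposure-side uncertainty ignored,
the convention of standard summary-data MR tooling; a second-order
version sits behind a flag in `wald_ratio()`).

**IVW.** With weights $w_j = 1/\mathrm{se}(\hat\theta_j)^2$, the
fixed-effects estimate is $\hat\theta = \sum w_j \hat\theta_j / \sum
w_j$, $\mathrm{se} = (\sum w_j)^{-1/2}$ — algebraically the
zero-intercept weighted regression of $\hat\Gamma$ on $\hat\gamma$.
Cochran's $Q = \sum w_j (\hat\theta_j - \hat\theta)^2$ on $k-1$ df tests
heterogeneity; when $Q$ is significant at $p < 0.05$ the multiplicative
random-effects model is used, which inflates the standard error by
$\sqrt{\max(1, Q/(k-1))}$, and otherwise the fixed-effects model — the
selection rule `mr_ivw(model = "auto")` applies. Both variants are
always reported so their sign agreement can be checked mechanically.
Additive (DerSimonian–Laird) random effects are deliberately not
implemented.

**MR-Egger.** Weighted least squares of $\hat\Gamma_j$ on
$\hat\gamma_j$ with weights $1/\sigma_{yj}^2$ and a free intercept,
after orienting every SNP so $\hat\gamma_j \ge 0$. The intercept
estimates average directional pleiotropy; the slope is the
pleiotropy-adjusted effect. Both use a $t$ reference on $k - 2$ df —
honest at the small instrument counts microbiome exposures yield.

**Weighted median.** Ratios are sorted; the estimate interpolates the
standardized cumulative weight function at 0.5. It is consistent while
at least half the weight comes from valid instruments. Its standard
error is a seeded parametric bootstrap (default 1000 resamples) that
re-draws each ratio from $N(\hat\theta_j, \mathrm{se}_j)$ with the
weights held fixed.

**MR-PRESSO.** The observed residual sum of squares weighs each SNP's
outcome effect against the prediction of the IVW fit *excluding that
SNP*; the null distribution comes from parametric draws of both summary
statistics under the fitted no-pleiotropy model (default 1000
simulations, global p floored at $1/(n_{sim}+1)$). Per-SNP outlier
p-values are each residual's rank in its own simulated distribution,
Bonferroni-adjusted. The distortion test compares the estimate shift
caused by removing the detected outliers against removals of random SNP
sets of the same size (1000 seeded draws).

**Leave-one-out.** The auto-model IVW is refit excluding each SNP in
turn; a nominally significant association is *dominated* when any
single exclusion lifts its p-value above the nominal level or flips the
sign. The narrative criterion is codified exactly this way because no
formula is conventional.

**Steiger directionality.** Instrument variance explained is summed per
side using the regression-$t$ identity $R^2 = t^2/(t^2 + n - 2)$ (no
allele frequency needed; the same estimator on both sides), and the
difference tested by a z-test on Fisher-transformed $\sqrt{R^2}$ with
the respective sample sizes. The assumed direction is supported when
the instruments explain more variance in the exposure.

**Mediation.** For a taxon significant in both microbiota legs, the
mediated effect is $\beta_i = \beta_1 \beta_2 / \beta$: leg-1 effect
times leg-2 effect over the total effect, all taken from the auto-model
IVW of each leg. The decomposition is only coherent when
$\beta_1\beta_2$ and $\beta$ share a sign; `mediation_effect()` returns
that check as the `consistent` flag rather than suppressing the value.
No confidence interval for $\beta_i$ is attempted.

```{r mediation}
mediation_effect(beta1 = log(1.035), beta2 = log(0.488),
                 beta_total = log(1.266))
```

## Instrument processing rules

`run_grid()` applies, per exposure-outcome pair and in this order:

* **p-value selection** — strictly below the threshold; 1e-5 for
  microbiota exposures (genome-wide significance leaves too few
  instruments for 16S-scale GWAS), 5e-8 for disease exposures.
* **LD clumping** — greedy by ascending p-value (ties broken
  lexicographically by SNP id for determinism): keep the best SNP, drop
  everything with $r^2 \ge 0.001$ within 10,000 kb, recurse. Without
  positions only the $r^2$ rule applies; SNPs missing from the LD
  matrix count as independent, with a warning.
* **Instrument strength** — $F = R^2(n-k-1)/(k(1-R^2))$; per-SNP
  filtering uses $k = 1$, under which $F = t^2$ exactly, and retains
  $F > 10$ (strictly). Joint-set $F$ is available through
  `f_statistic()` with $k$ set to the instrument count.
* **MAF** — $\min(\mathrm{eaf}, 1-\mathrm{eaf}) \ge 0.01$, applied to
  the exposure side (which side the convention intends is ambiguous;
  the exposure side is where instruments are defined). Records without
  an allele frequency pass with a warning.
* **Harmonization** — outcome records aligned to the exposure's effect
  allele: swapped alleles negate the outcome beta and complement the
  frequency; a strand flip is rescued before declaring a mismatch —
  except for palindromic (A/T, C/G) SNPs, where flips are
  indistinguishable from swaps, so they are dropped unconditionally by
  default rather than rescued by frequency. Exposure-side statistics
  are never modified, and every drop carries a machine-readable reason.

Unnamed taxa (`name == "unknown"`) are removed from the trait panel
before analysis — on the reference 211-taxon panel this leaves 196
traits. Bonferroni thresholds are computed per taxonomic rank as
$0.05/m$ with $m$ counted from the taxonomy actually analysed
(reference counts: 131 genera, 35 families, 20 orders, 16 classes, 9
phyla). Note $0.05/9 = 5.56\times10^{-3}$, which we report exactly even
where $5.5\times10^{-3}$ circulates as a rounded value.

**Classification.** *Nominal*: IVW $p < 0.05$. *Stable*: nominal, and
Egger intercept $p > 0.05$, and MR-PRESSO clean (global $p > 0.05$, or
a sign-concordant corrected estimate with distortion $p \ge 0.05$), and
not leave-one-out dominated, and Steiger direction correct. *Strong*:
stable and IVW $p$ below the rank threshold. The classes are nested by
construction; "stable" has no canonical formula, so this codification
is an interpretation and each ingredient is reported separately in the
grid output so readers can re-weigh it.

## The synthetic-data generator

Real consortium GWAS downloads are out of scope, so every stage is
exercised on simulated summary statistics with known truth
(`simulate_pair()`):

$$\hat\gamma_j = \gamma_j + \varepsilon_{xj}, \qquad
  \hat\Gamma_j = \theta\,\gamma_j + \alpha_j + \varepsilon_{yj},$$

with $\mathrm{se} \approx 1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$
so instrument strength responds to sample size as in a real GWAS.
Defaults, chosen once as the study conditions:

* `n_exp = 18340` (a microbiome-GWAS-scale exposure study) and
  `n_out = 50000`;
* $\gamma_j \sim N(0.1, 0.05)$ truncated positive. The truncation makes
  effect alleles consistently trait-increasing (harmonization tests
  scramble alleles separately); the coefficient of variation of 0.5
  gives the heterogeneous instrument strengths real panels show. This
  heterogeneity is not cosmetic: MR-Egger is identified only through
  spread in $\gamma$, and a near-constant panel puts the estimator in
  an ill-conditioned errors-in-variables regime no implementation can
  rescue;
* minor-allele frequencies uniform on (0.05, 0.5), the post-QC common
  variant range;
* pleiotropy: balanced ($\alpha_j \sim N(0, \tau)$), directional (mean
  $\mu$), an InSIDE-violating component coupling $\alpha_j$ to centred
  $\gamma_j$, and an outlier fraction given direct effects of at least
  ten times the pleiotropy scale — all off by default;
* `simulate_triangle()` wires three independent systems with effects
  $a$, $b$, and $\mathrm{direct} + ab$ for mediation recovery tests.

What the generator does **not** emulate: linkage disequilibrium among
the generated SNPs (LD matrices are supplied separately to exercise
clumping), case/control liability-threshold sampling (binary outcomes
are approximated linearly on the log-odds scale — the generator's
largest idealization), sample overlap between the two studies, winner's
curse in instrument discovery, and realistic allele-frequency spectra.
Passing tests therefore certify the estimators and decision rules under
the standard linear summary-statistics model, not robustness to those
real-data complications.

## Numerical choices

* All threshold comparisons that the conventions state as strict
  ("$P < 10^{-5}$", "F greater than 10", "MAF less than 0.01
  excluded") are implemented strictly; boundary cases are pinned by
  tests.
* Degenerate inputs: a single instrument reduces IVW to the Wald ratio
  with Q flagged undefined; Egger and the weighted median refuse fewer
  than 3 SNPs; MR-PRESSO refuses fewer than 4; a zero total effect is a
  hard error in the mediation formula; pairs with no surviving
  instruments appear in the grid report with reason `no_instruments`
  rather than vanishing.
* Seeds: every stochastic component (bootstrap, PRESSO simulations,
  distortion null, the generator) takes an explicit integer seed and
  restores the caller's RNG state; `run_grid()` derives per-pair seeds
  deterministically, so a whole study report is byte-identical under a
  fixed seed.
* P-values are floored at the smallest positive double rather than
  printed as 0; PRESSO Monte-Carlo p-values use the $(1+\#)/(n+1)$
  form.

## Test problem sizes

The suite validates estimator arithmetic against independent
closed-form oracles (100 random instances at 1e-10), and calibration by
Monte-Carlo at sizes chosen to keep the whole suite around a minute on
one core while leaving the binomial noise well inside the asserted
bands: 500 replicates of 150 instruments for coverage and bias, 100–200
replicates for type-I error, PRESSO null calibration and outlier
detection, and 20–60 replicates for the slower comparative properties.

## Known limitations

* The linear log-odds approximation for binary traits means simulated
  "odds ratios" are internally consistent but not generated from
  individual-level disease models.
* Egger remains attenuated when instrument strengths are nearly
  homogeneous (low $I^2_{GX}$); the package reports, but does not
  SIMEX-correct, that regime.
* No proxy-SNP lookup for instruments missing in the outcome study, no
  reference-panel LD computation, no multivariable MR, and no
  confidence interval for the mediated proportion — matching the
  design's scope.
* The "stable" class encodes a narrative convention; alternative
  readings (e.g. requiring only the Bonferroni pass for "strong") are
  one `classify_association()` call away since all ingredients are in
  the report.
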