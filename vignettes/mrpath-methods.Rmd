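---
title: "Methods: summary-level MR and mediation for the hepato-ovarian axis"
author: "mrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: summary-level MR and mediation for the hepato-ovarian axis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The estimation problem

mrpath estimates causal effects between traits from pairs of GWAS
summary-statistic tables — the two-sample Mendelian randomization design.
Each instrument j contributes an exposure association
$\hat\beta_{Xj} \sim N(\beta_{Xj}, \sigma_{Xj}^2)$ from one sample and an
outcome association $\hat\beta_{Yj} \sim N(\beta_{Yj}, \sigma_{Yj}^2)$
from another. If the instrument is valid (relevant, unconfounded, and
acting on the outcome only through the exposure),
$\beta_{Yj} = \theta\,\beta_{Xj}$ and each ratio
$\hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect $\theta$.
Binary traits enter on the log-odds scale, continuous traits in SD units;
estimates are labelled with their outcome scale and an odds-ratio view is
provided only for log-odds outcomes.

The motivating application is the chain from non-alcoholic fatty liver
disease (NAFLD) to polycystic ovary syndrome (PCOS): a direct effect
$\theta_1$ plus indirect pathways through fasting insulin
($\theta_6$ into insulin, $\theta_2$ from insulin to PCOS) and onward
through SHBG and bioavailable testosterone
($\theta_5, \theta_4, \theta_3$). The total effect decomposes as
$\theta_1 + \theta_2\theta_6 + \theta_3\theta_4\theta_5\theta_6$.

## Instrument selection and harmonization

Selection keeps variants with $p < 5\times10^{-8}$ (strict inequality),
minor allele frequency strictly above 0.01, and removes palindromic (A/T,
C/G) variants whose effect-allele frequency falls inside the ambiguity
band around 0.5. The band spans 0.42–0.58 and is *open*: a frequency
exactly at a band edge is kept. That boundary convention is forced by the
data the pipeline is meant to reproduce, which retains an A/T instrument
at EAF 0.420 while excluding one with EAF ≈ 0.5.

Clumping is greedy: candidates are ranked by ascending p (ties: larger
$|\hat\beta/\sigma|$, then lexicographic rsID — the output is fully
deterministic), the best is kept, and anything within ±10 Mb (symmetric,
inclusive, same chromosome) with $r^2 \ge 0.001$ is discarded; repeat.
Candidates absent from the LD reference are treated as unlinked and kept,
with a warning. The LD reference is a local correlation matrix plus a
coordinate side-car; no external service is queried.

Harmonization aligns outcome records to the exposure's effect allele:
swapped alleles flip the outcome beta and reflect its EAF; opposite-strand
records are complemented first. For palindromic variants strand is
unresolvable from alleles, so the two readings are distinguished by
frequency concordance when both EAFs are outside the ambiguity band,
otherwise the variant is dropped (a `palindromicPolicy = "drop"` switch
drops all of them, since it is not documented practice everywhere to infer
strand from frequency). Rows whose EAFs disagree by more than 0.2 are kept
but flagged. Instruments missing from the outcome table can be replaced by
the highest-$r^2$ proxy within ±1 Mb at $r^2 \ge 0.8$ (ties: closest,
then lexicographic).

## Estimators

**IVW.** $\hat\theta = \sum w_j \hat\beta_{Yj}\hat\beta_{Xj} /
\sum w_j \hat\beta_{Xj}^2$ with $w_j = 1/\sigma_{Yj}^2$; fixed-effects
SE $1/\sqrt{\sum \hat\beta_{Xj}^2/\sigma_{Yj}^2}$. Heterogeneity uses
Cochran's $Q = \sum (\hat\beta_{Xj}/\sigma_{Yj})^2 (r_j - \hat\theta)^2$
on $k-1$ df. The random-effects variant is the multiplicative
over-dispersion model: the fixed SE is inflated by
$\max(1, \sqrt{Q/(k-1)})$, never deflated. `mode = "auto"` uses fixed
effects for $k \le 3$ and random effects otherwise.

**Wald ratio SE.** First-order, $\sigma_{Yj}/|\hat\beta_{Xj}|$, by
default; the second-order form is available behind a flag. A Monte-Carlo
check in the test suite shows the two differ by well under 1% at the
instrument strengths this pipeline requires ($F > 10$), which is why
first-order is the default.

**MR-Egger.** Weighted least squares of $\hat\beta_Y$ on $\hat\beta_X$
with a free intercept after orienting all exposure betas non-negative, so
results are invariant to allele-coding sign conventions. The intercept
estimates average directional pleiotropy under InSIDE; its two-sided
normal test is the directional-pleiotropy test. SEs carry the same
floored multiplicative inflation as IVW (equivalently, the model SE is
divided by $\min(\hat\sigma, 1)$).

**Weighted median.** Ratios are sorted; with normalized inverse-variance
weights $p_j$ the cumulative midpoints are $s_j = \sum_{i\le j} p_i -
p_j/2$ and the estimate interpolates ratio against $s$ at 0.5. The SE is
the SD over seeded parametric-bootstrap resamples (default 1000; the same
seed gives a bit-identical SE).

**MR-PRESSO.** Observed statistic
$\mathrm{RSS} = \sum_j (\hat\beta_{Yj} - \hat\theta_{(-j)}
\hat\beta_{Xj})^2/\sigma_{Yj}^2$ with leave-one-out IVW slopes
$\hat\theta_{(-j)}$. The null distribution simulates
$\beta_{Yj}^* \sim N(\hat\theta_{(-j)}\hat\beta_{Xj}, \sigma_{Yj}^2)$ and
$\beta_{Xj}^* \sim N(\hat\beta_{Xj}, \sigma_{Xj}^2)$ (exposure SEs
missing: $\beta_X$ held fixed, a documented degraded mode) and recomputes
the statistic; the global p is the plus-one empirical tail
$(1 + \#\{RSS^* \ge RSS\})/(1 + n_{sim})$, never zero. Per-SNP outlier
p-values use each instrument's own simulated squared-residual
distribution, Bonferroni-adjusted over k; the corrected estimate is the
auto-mode IVW of the unflagged rows, and the distortion p compares the
corrected-minus-original slope shift against its simulated distribution.
One structural caveat, verified during design: an outlier that dominates
the weights (SE an order of magnitude smaller than its peers)
contaminates every leave-one-out slope, so the simulated null reproduces
the outlier's own residual and no RSS-simulation test of this family can
flag it. The shipped detection fixtures therefore plant an outlier with a
moderately smaller SE, where detection is essentially certain.

**Multivariable MR.** Weighted regression (no intercept, weights
$1/\sigma_{Yj}^2$) of outcome associations on the $L$ exposure
association columns; coefficient $j$ is the direct effect of exposure $j$
conditional on the others, SEs from the weighted normal-equations
covariance with the same floored inflation (for $L = 1$ this reduces
exactly to random-effects IVW). Conditional instrument strength for
exposure $x$ regresses its associations on the other exposures'
(weights $1/\sigma_{xj}^2$), takes the weighted residual sum of squares
$Q_x$, and reports $F_x = Q_x/(k - L)$; for $L = 1$ this is
$\sum (\hat\beta/\sigma)^2/(k-1)$. Cross-exposure sampling covariances
(overlapping samples between the glycemic and the hormone GWASs) are set
to zero — no published covariances exist to plug in — which is a known
limitation of the conditional-F convention chosen here; the convention is
pinned by oracle tests rather than by matching unpublished values.

**Mediation.** A pathway is an ordered chain of stage effects on the
additive scale (odds-ratio stages entered as logs; the constructor checks
that stages compose head-to-tail). The indirect effect is the product of
stage estimates; its SE is the first-order multivariate delta form
$\sqrt{\sum_i \sigma_i^2 \prod_{j\ne i}\theta_j^2}$, computed in the
expanded sum-of-products form so zero stages are harmless, symmetric
under stage permutation, and assuming independent stages (they come from
separate fits in a two-sample design). Stage SEs can be backed out of
printed CIs as $(u-\ell)/(2z)$ with $z = 1.959964$ (the 0.975 normal
quantile — not 1.96 — used everywhere in the package). Proportions
mediated divide by the obesity-SNP-excluded total effect: this is the
denominator under which the published four-stage proportion (2.2%) is
recovered from printed inputs, and it is the more defensible estimand
because the same pleiotropy filter was applied to every stage. The
insulin-only proportion computed from printed rounded inputs is 15.2%
against a published 14.9% — the difference is rounding of unprinted
intermediate estimates, and the tests assert the value the printed inputs
actually give. Evidence grading follows the five-exposure Bonferroni
policy: p < 0.01 strong, 0.01–0.05 suggestive, else none.

**Meta-analysis.** Fixed-effects inverse-variance pooling on a common
outcome scale; the published pooled estimate is not exactly recoverable
from two printed component estimates (rounding), so the operation is
validated by closed form and by an independent package cross-check.

## LD-score regression

Per-SNP association chi-squares follow
$E[\chi^2_j] = a + N h^2 \ell_j / M$ where $\ell_j$ is the LD score, M
the number of SNPs behind the scores, and $a$ an intercept near 1 absent
confounding. The fit is two-pass: an unweighted pass gives a provisional
$h^2$ for heteroskedasticity weights $1/(1 + N h^2 \ell_j/M)^2$, then the
weighted fit is reported — a simplified version of the canonical
iterated weighting. Cross-trait products $z_{1j}z_{2j}$ regressed on
$\ell_j$ give the genetic covariance via slope $\cdot M/\sqrt{N_1N_2}$,
and $r_g = \widehat{\mathrm{cov}}_g/\sqrt{h_1^2 h_2^2}$. Uncertainty is
the delete-one-block jackknife over contiguous blocks in SNP order
(default 200 blocks); for $r_g$ all three regressions share one weight
family and one set of block deletions so the jackknifed ratio is
internally consistent — in design-stage calibration runs this
consistency was what brought the null-$r_g$ two-SE coverage to its
nominal level. Heritability is reported on the observed scale only; no
sample-overlap intercept is modeled for cross-trait pairs (a
`fixedIntercept` argument lets a known value be pinned instead).

## The synthetic-data generator

`simConfig()`/`simulateDagTruth()`/`simulateSummaryStudy()` emulate the
study's data situation with exact ground truth. Structural equations on
the liability scale, with an unmeasured adiposity factor U:

* NAFLD $= \sum_j \gamma_j G_j + c_N U$
* insulin $= \theta_6\,\mathrm{NAFLD} + c_F U$
* SHBG $= \theta_5\,\mathrm{insulin} + c_S U$
* testosterone $= \theta_4\,\mathrm{SHBG} + c_B U$
* PCOS $= \theta_1\,\mathrm{NAFLD} + \theta_2\,\mathrm{insulin} +
  \theta_3\,\mathrm{testosterone} + c_P U + \sum_j \alpha_j G_j$

Fasting glucose is included as a null node (own instruments, confounder
loading, no causal edges) so the multivariable null checks have defined
truth. Marginal per-SNP effects on every trait follow by exact linear
propagation, and the generator records them all; summary statistics are
then drawn at the coefficient level,
$\hat\beta_j \sim N(\mathrm{marginal}_j, 1/(2 n p_j(1-p_j)))$ — the
standardized-scale SE, applied on the log-odds scale for the binary
traits as the usual small-effect liability/log-odds approximation.
Estimation errors are independent across disjoint GWAS samples and share
a common factor with variance equal to the overlap fraction otherwise.

Defaults are the study's conditions: 2000 SNPs in AR(1) LD blocks of 10
(within-block correlation 0.5), 20 exposure instruments placed one per
block, chain coefficients $\theta_1 = 0.10$, $\theta_2 = 1.1$,
$\theta_3 = 0.64$, $\theta_4 = -0.93$, $\theta_5 = -0.28$,
$\theta_6 = 0.015$ (the magnitudes of the fitted chain), no pleiotropy,
and GWAS sample sizes of 200&nbsp;000 per trait. Instrument effect sizes
draw $|\gamma| \sim U(0.08, 0.25)$ with random sign — strong instruments
($F \gg 10$), matching the published instrument strength. Directional
pleiotropy is defined *relative to the exposure-increasing allele*
($\alpha_j$ multiplied by $\mathrm{sign}(\gamma_j)$): with randomly
signed $\gamma$, a fixed-sign $\alpha$ would cancel in ratio space and
bias nothing, whereas the orientation-relative definition is what the
Egger intercept actually estimates. `pleioMean` may be a vector, recycled
across invalid instruments, giving mixed-direction contamination: equal
invalid weight on both sides of the truth but nonzero net pleiotropy.
That construction is used for the robustness split in the acceptance
tests because strictly one-sided contamination provably shifts the
weighted median to an off-centre quantile of the valid ratio
distribution — a bias that scales with the same $\sigma$ as its
Monte-Carlo SE and therefore cannot be "unbiased to 2 MC SEs" at any
sample size — while the mixed construction leaves the weighted quantile
0.5 inside the valid cluster and still biases IVW through the net term.

What the generator does **not** emulate: real human LD maps and allele
frequency spectra, winner's-curse at marginal instrument strength,
sex-specific effects (a limitation it shares with the sex-combined
exposure GWASs it mimics), non-collapsibility of the odds ratio (effects
are generated directly on the log-odds scale), and case/control
imbalance. Green tests therefore certify the estimators and their
calibration under the stated model, not the correctness of any real-data
conclusion.

For LD-score test beds, `simulateLdscInputs()` draws the within-block
correlation per block from $U(0, 0.95)$ so the LD scores span a realistic
range — with a single block correlation the scores are nearly constant
and the regression slope is unidentifiable in noisy mode.

## Numerical and testing choices

* Threshold comparisons that the data conventions fix: significance strict
  (<), MAF strict (>), palindrome band open, clump window inclusive.
* Empirical p-values use plus-one correction; all parametric p-values are
  two-sided normal.
* All randomness is seeded; seeded internals restore the caller's RNG
  state (`withSeed()`), and pipeline artifacts embed the seed so any run
  can be reproduced bit-identically.
* Degenerate inputs: zero exposure beta is an error for a Wald ratio;
  collinear exposure columns raise an error naming the offending
  exposures; an MR-PRESSO request with fewer than four instruments raises
  a typed `pressoNotApplicable` condition rather than a silent skip.
* Problem sizes in the test suite are chosen to keep the full run around
  a minute while leaving calibration checks statistically meaningful:
  replicate counts of 50 (parameter recovery and robustness), 500 (Egger
  null calibration), 100 (outlier detection, null-$r_g$ coverage), LDSC
  fixtures of 1000 SNPs with 50 jackknife blocks, and a
  reduced-instrument generator for per-replicate speed where LD handling
  is not under test. The delta-method SE is checked against a
  $10^6$-draw Monte-Carlo reference.

## Known limitations

* Conditional F uses one pinned convention; published conditional-F
  values from other conventions (or with nonzero cross-exposure error
  covariance) will differ.
* LDSC here is the minimal two-pass flavour: no partitioned heritability,
  no liability-scale conversion, no cross-trait intercept estimation
  under sample overlap.
* The weighted-median SE is bootstrap-based and therefore stochastic
  (seeded); analytic alternatives exist but are not implemented.
* The generator's binary-trait approximation degrades for large
  per-allele effects; its validity range is small effects, which is where
  the shipped defaults live.
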