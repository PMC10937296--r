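---
title: "Modelling carry-over effects of brood size on post-fledging DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling carry-over effects of brood size on post-fledging DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broodmethyl)
```

## The scientific setting

Brood size manipulation in hole-nesting passerines is a classic tool for
imposing nutritional stress during early development: within a cross-foster
(CF) pair of broods matched on hatch date, nestlings are partially swapped
and one brood is enlarged by three nestlings while the other is reduced by
three. Nestlings raised in enlarged broods fledge lighter and less
developed. The question this package addresses is what happens *after*
fledging: whether birds from enlarged broods catch up in weight, wing
development (third primary length, P3) and exploratory behaviour as days
since fledging accumulate, and whether those carry-over effects are
mirrored by erythrocyte DNA methylation at individual CpG sites measured by
reduced-representation bisulfite sequencing.

The statistical signature of a carry-over effect is an **interaction
between treatment and days since fledging**: a trait (or a CpG's
methylation level) changing with time at a different rate in the two
treatments.

## The per-CpG screening model

For CpG site $s$ and individual $i$, the data are a methylated read count
$m_{si}$ out of a coverage $n_{si}$. The site-level model is a binomial
generalized linear mixed model with a logit link:

$$
m_{si} \sim \mathrm{Binomial}(n_{si},\, p_{si}),\qquad
\operatorname{logit} p_{si} =
\beta_0 + \beta_T T_i + \beta_D D_i + \beta_{TD} T_i D_i
+ u_{o(i)} + u_{r(i)},
$$

where $T_i$ indicates the enlarged treatment (reduced is the reference
level), $D_i$ is days since fledging, and $u_{o}$, $u_{r}$ are
brood-of-origin and brood-of-rearing random intercepts, each nested within
CF pair (implemented by pair-qualified grouping labels, one variance
component per factor). For every site two models are fitted — a null model
with treatment only, and the full model above — and compared by a
likelihood-ratio test with 2 degrees of freedom (days + interaction).
Screening then proceeds:

1. sites whose fits error or separate are omitted (fits whose only issue is
   a singular variance component are kept and flagged);
2. sites whose full-model Pearson dispersion falls outside the 95% highest
   density interval (HDI) of the empirical dispersion distribution are
   removed — an overdispersion guard;
3. Benjamini–Hochberg FDR is applied to the remaining likelihood-ratio
   p-values at q ≤ 0.05;
4. for the significant ("days-dependent DMS") sites, per-treatment slopes
   $\beta_D$ (reduced) and $\beta_D + \beta_{TD}$ (enlarged) are tested by
   normal-reference z-tests with their own BH pool, and each site is
   assigned one of six interaction categories: opposing slopes (up or down
   in the enlarged group), an enlarged-only slope (up/down), or a
   reduced-only slope (up/down). Anything else — including both slopes
   significant with the same sign — is reported as `unclassified`.

### The estimation engine

`fit_binomial_glmm()` is a purpose-built Laplace engine rather than a
wrapper, because the screening stage fits two mixed models at every one of
thousands of CpGs and general-purpose formula machinery dominates the run
time at that granularity. For fixed log standard deviations $\theta$ the
fixed effects and spherical random effects are driven to their joint
penalized mode by iteratively reweighted least squares with step halving;
the Laplace objective adds $-\tfrac12 u^\top u$ and
$-\tfrac12 \log\det(\Lambda^\top Z^\top W Z \Lambda + I)$ (the u-block
only, the standard one-quadrature-point convention), and $\theta$ is
optimised on the log scale by `nlminb` with a relative tolerance of
`1e-10`, bounds $[-8, 3]$, and at most 500 outer iterations. The
fixed-effect covariance is the corresponding block of the inverse penalized
information at the optimum. A random-effect standard deviation below
`1e-4` flags the fit singular (kept); non-convergence and complete
separation flag it for omission.

Two independent routes check the engine in the test suite: `lme4::glmer`
(the same Laplace approximation, independently implemented) agrees with it
to a few times $10^{-3}$ in log-likelihood on shared fits, and a
hand-written 25-node adaptive Gauss–Hermite oracle — nodes from the
Golub–Welsch eigenproblem, each group's integral centred at its conditional
mode — bounds the total error. The quadrature comparison uses
deep-coverage toys (totals near 2000 reads): the Laplace approximation
error itself scales as the inverse of the per-group information, so at
study-like 30× coverage the *approximation* gap (about $10^{-2}$ in
log-likelihood, identical in glmer) would mask any *implementation* error,
which is the thing the check is for.

### Numerical and procedural choices

* **Dispersion statistic.** Pearson $\sum (m - n\hat p)^2 / (n \hat p (1 -
  \hat p))$ over residual degrees of freedom $n_{obs} - p_{fixed}$, with
  $\hat p$ at the joint mode (predicted random effects included), fitted
  probabilities floored at $10^{-10}$. Because the random intercepts absorb
  brood-level variation, the statistic centres below 1; the HDI filter acts
  on the empirical distribution, so only its tails matter.
* **HDI.** The shortest contiguous window of the sorted values containing
  $\lceil 0.95 N \rceil$ observations, first window on ties; it requires at
  least 20 finite values, below which the interval is unstable.
* **FDR universe.** BH is applied to the sites that actually reached a
  test (survived omission and the HDI filter); `fdr_universe =
  "all_filtered"` instead counts every filtered site as a test, the more
  conservative reading.
* **Post-hoc pool.** The slope z-tests of all significant sites are
  BH-corrected jointly (2 × n tests); `posthoc_pool = "per_site"` switches
  to within-site correction. "Stable" methylation in one treatment is
  operationalised as a non-significant slope after FDR; no equivalence test
  is attempted.
* **LRT guard.** Numerically negative statistics within $-10^{-6}$ are
  clamped to zero; larger negative values warn.

### Calibration at the study size

With roughly 55 recaptured individuals the 2-df likelihood-ratio statistic
carries the classic Bartlett-type finite-sample inflation of order
$1 + k/n \approx 1.06$: across thousands of simulated null sites its mean
sits near 2.1 rather than 2.0, in exact agreement with `glmer` on the same
data. The null p-values still pass a Kolmogorov–Smirnov uniformity check at
the 1% level at 2000 sites, and BH keeps the realised false discovery
proportion controlled — in the all-null configuration, 20 of 20 pinned
seeds yield zero discoveries. This inflation is a property of the method at
this sample size, not of the implementation.

## Filtering

Four rules are applied in a fixed order, each with strict inequalities,
and the report telescopes (sites in → removed → out per stage):

1. per-cell coverage: cells below 10× are set missing, as are cells above
   the sample's own 99.9th coverage percentile (per-sample, matching
   common RRBS practice; whether the original rule was per-sample or
   global is not determinable from the text). The percentile is the
   inverse-ECDF order statistic, so the cut is an observed coverage value;
   since a re-estimated cut would trim a new tail on every pass, this
   upper cut is a one-shot trim and the idempotence of the pipeline is
   stated (and tested) with the upper cut saturated;
2. sites left with no covered cells are dropped;
3. a site must be covered in at least 15 individuals in *both* treatments;
4. the site's mean methylation fraction across covered individuals must
   lie within (0.05, 0.95).

Cells removed by the coverage rule become missing, never zero, so the
presence rule counts post-coverage data. Coordinates are 1-based,
anchored at the plus-strand cytosine of the merged CpG dinucleotide
(complementary-strand counts at position p+1 are summed into p); BED
output is 0-based half-open.

At the scale of the original study these rules reduce about 4.0 million
raw CpGs to roughly 116 thousand; reproducing those counts requires the
unreleased per-sample methylation calls, so they are documentation here,
not a test target.

## Annotation

Genes are read from GFF3 (`rtracklayer`); the transcription start is the
strand-aware 5′ end of the gene (per gene, not per transcript, since the
analysis annotates genes). Windows: TSS region 300 bp upstream to 50 bp
downstream; promoter 2000 bp upstream to 200 bp downstream; gene body;
5′/3′ UTRs from the annotation; 10-kbp flanks either side. A CpG
overlapping several windows takes the highest-priority class; within a
class, characterised genes beat `LOC` (uncharacterised) genes and then the
shortest edge-to-site distance to the gene body wins — the stated
tie-break for flanks, applied uniformly. The published priority places the
gene body above the UTR classes; because UTRs lie inside gene bodies this
makes UTR labels unreachable, which is consistent with no UTR counts being
reported. That literal order is the default; `utr_before_body = TRUE`
ranks UTRs above the gene body for users who want UTR-resolved labels.
Upstream/downstream for flank hits follows the winning gene's strand.

## The phenotype stage

Four responses — post-fledging weight, Δweight (post-fledging minus day-14
weight), P3 length and the exploration score — are analysed with Gaussian
mixed models (ML), brood-of-origin and brood-of-rearing random intercepts
(pair-qualified), and backward elimination of fixed effects: at each step
the least-significant removable term with p ≥ 0.05 in the type III
Satterthwaite table is dropped, interactions before their main effects,
the squared hatch-date term before the linear one, ties broken in favour
of the later model term, and treatment never removed. Δweight starts from
treatment, hatch date, hatch date squared, their treatment interactions,
and the days terms; hatch date enters as the raw April day and its square
(uncentered), with the caveat that type III tests with polynomials are
sensitive to centering. Per-treatment slopes use `emmeans::emtrends` with
Bonferroni correction (two contrasts), the same machinery the original
analysis used. These are ordinary Gaussian mixed models, so the stage
stands on `lme4`/`lmerTest`/`emmeans` behind the package's function
surface; the elimination logic, exploration scoring and Spearman design
checks are the package's own.

The exploration score corrects the 2-minute novel-environment movement
count for test date by linear residualisation across the cohort, with the
grand mean added back to keep the original scale; the reference procedure
is cited but not specified in detail, so plain linear residualisation is
the implemented reading, skipped with a warning when only one distinct
test date exists. `spearman_check()` (average ranks, t-approximation)
covers the design checks between days since fledging, hatch date and test
date.

## What the simulator emulates — and what it does not

`simulate_design()` reproduces the experimental skeleton: 16 CF pairs, a
base brood of 9 manipulated by ±3 (so 12 versus 6 nestlings), partial
cross-fostering by random reassignment within the pair (about half of each
rearing brood moved), hatch dates spread over April days 20–40, fledging
20 days later, and Bernoulli recapture at the study's realised rates —
30.51% for reduced-brood and 16.43% for enlarged-brood birds — which is
also the only way selective disappearance enters the generator. Days since
fledging are Uniform(28, 110): recapture began four weeks after fledging
and ran to the end of the field season, and the realised distribution is
not printed, so the uniform keeps the interaction identifiable without
inventing structure. One global seed drives three fixed-offset streams
(design, phenotypes, methylation), so each stage is independently
reproducible.

`simulate_methylation()` draws per-cell coverage from a negative binomial
(mean 30, size 5 — overdispersed, as RRBS coverage is, which gives the
99.9th-percentile filter something to cut), a per-site baseline from a
two-component logit-normal mixture centred at ±1.5 (hypo- and
hyper-methylated modes, so the 0.05/0.95 mean-methylation filter has
realistic bite), brood random intercepts with sd 0.3 on the logit scale,
and binomial counts whose logits carry the planted treatment-specific
slopes (±0.025 logit/day in the benchmark categories). Per-observation
Gaussian logit noise is available (`obs_overdispersion_sd`) but defaults
to zero, matching the fitted model's assumption; the overdispersion tests
switch it on.

What the generator does **not** emulate: read-level artefacts (bisulfite
conversion error, PCR clones, alignment bias), linkage between neighbouring
CpGs, sex effects, condition-dependent survival, or any coupling between a
bird's phenotype and its methylation. Passing recovery tests therefore
demonstrates that the pipeline finds the interaction structure it is
designed for at realistic sample sizes and coverage — not that real data
meet the model's assumptions.

## Problem sizes used by the tests

The acceptance-level checks run at the simulated study size (about 55–60
recaptured individuals): 2000 sites for null calibration and for the
recovery benchmark (600 planted across the six categories, 1400 null), 20
seeds of 400 all-null sites for FDR control, 20 deep-coverage toys for the
quadrature comparison, and 100 seeds for phenotype-slope recovery. These
sizes give stable pass/fail behaviour while keeping a full run in the
minutes range on one core.

## Known limitations

* Laplace only — no quadrature fitting path (the oracle lives in the
  tests), no random slopes, no REML for the screening engine, and the
  binomial family only: the source analysis describes a cbind-response
  logit binomial model, and that is what is implemented.
* The LRT's finite-sample inflation at n ≈ 55 (above) means q-values very
  near the threshold should not be over-read.
* The dispersion statistic's centring depends on the random-effect
  shrinkage convention; only its empirical tails are used.
* Paper-scale genome-wide counts are not reproducible without the original
  per-sample calls; the package documents them and tests everything else.
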