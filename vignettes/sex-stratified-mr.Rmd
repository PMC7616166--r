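---
title: "Methods: sex-stratified two-sample Mendelian randomization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sex-stratified two-sample Mendelian randomization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsexdiff)
```

## The scientific question and the design

Aneurysmal subarachnoid haemorrhage (aSAH) is markedly more common in
women, yet which causal risk factors differ between the sexes is unclear.
Two-sample Mendelian randomization (MR) addresses this with summary
statistics only: SNP-exposure associations from one GWAS and SNP-outcome
associations from another are combined into a causal estimate, assuming
each instrument affects the outcome only through the exposure. Running the
whole pipeline separately per sex — sex-specific instruments where a
sex-stratified exposure GWAS exists, sex-combined instruments applied to
both sexes' outcome data otherwise — yields a woman's and a man's estimate
per exposure-outcome pair, and a two-group Cochran's Q test decides whether
they differ beyond sampling error.

This package implements that design end to end, plus a synthetic
summary-statistics generator with known ground truth so that every stage is
verifiable without access to consortium data.

## Instrument selection

* **Significance**: instruments must reach `p ≤ 5e-8` (inclusive at the
  boundary). `filter_pvalue()`.
* **Frequency**: variants with minor-allele frequency below 5% are
  excluded: `min(eaf, 1−eaf) ≥ min_maf`. `filter_maf()`.
* **Independence**: greedy LD clumping on a SNP×SNP correlation panel:
  candidates are ranked by ascending p (ties broken by ascending rsid, which
  makes the output a deterministic function of the candidate *set*), the
  best remaining SNP is kept and every candidate with `r² > 0.001` against
  it is pruned. There is no physical-distance window: the panel is the sole
  arbiter of dependence, which keeps the operation exactly reproducible at
  desk scale; SNPs absent from the panel are dropped with a warning rather
  than assumed independent. `clump()`.
* **Strength**: the per-SNP F-statistic is the squared Wald ratio
  `(β/σ)²` — the standard one-parameter approximation — and the mean over
  instruments is compared against the conventional bar of 10; a typed
  warning (`weak_instruments_warning`) is raised at or below it.

## Harmonization

Allele harmonization is standard two-sample MR plumbing rather than part of
the estimators, but it determines the sign of every outcome effect, so the
rules are explicit. For each variant shared by the two studies:

1. identical allele labels: keep;
2. swapped labels: negate the outcome beta, reflect its frequency;
3. strand-complemented labels (A↔T, C↔G): complement, then rule 1 or 2;
4. palindromic variants (A/T, G/C) carry no label information, so they are
   oriented by allele frequency alone: dropped as ambiguous when the MAF in
   either study exceeds `0.5 − window` (default window 0.08, i.e. drop when
   MAF > 0.42, a common community default), otherwise flipped when the two
   studies' effect-allele frequencies sit on opposite sides of 0.5;
5. irreconcilable allele sets are dropped.

Exposure effects are never altered, and every shared variant is accounted
for either in the retained set or in the dropped table — a partition the
test suite asserts on corrupted synthetic data, where harmonization must
recover the generated outcome effects *exactly* for all non-ambiguous
variants.

## Estimators

All estimators work on the log-odds scale; odds ratios and 95% CIs use the
exact normal quantile `qnorm(0.975) = 1.959964…`, not 1.96, and two-sided
normal p-values (the summary-data MR convention, not t).

**IVW** is the primary analysis: weighted regression through the origin
with weights `1/σ_Y²`. The error model is multiplicative random effects by
default — the fixed-effect SE times `max(1, √(Q/(J−1)))` — so
heterogeneity widens but never narrows the interval; this matches the
default behaviour of the analysis software ecosystem this design comes
from. A single-SNP analysis falls back to the Wald ratio with a warning.

**MR-Egger** frees the intercept after orienting all SNPs to non-negative
exposure effects; the intercept, its SE and p form the directional
pleiotropy test, with the same multiplicative inflation (denominator
`J−2`). The orientation step presumes *selected* instruments: applied to
unselected near-null SNPs, the observed-sign flip correlates with noise and
sign-flips part of the pleiotropy, biasing the intercept toward zero. The
pipeline never does this — estimation always sits downstream of the
significance filter — and the recovery tests reproduce that stage order.

**Median estimators** interpolate the weight-ordered per-SNP Wald ratios at
cumulative midpoint 0.5 (weights `ratio_se^-2`; equal weights give the
simple median). The SE is a parametric bootstrap (default 10,000 resamples,
explicit seed mandatory): effects are redrawn from normals at the observed
values and SEs and the median recomputed. SNPs are canonically oriented to
`β_X ≥ 0` first, which leaves ratios and weights unchanged but makes the
bootstrap bit-reproducible under per-SNP sign flips.

**MR-PRESSO** computes leave-one-out IVW slopes with fixed-effect weights,
sums the squared per-SNP residuals, and compares against `n_sim`
parametric replicates (default 5000, minimum 1000). All Monte-Carlo
p-values use `(b+1)/(n_sim+1)`, so they are never exactly zero. Per-SNP
p-values are Bonferroni-corrected; outliers at `α = 0.05` trigger the
distortion test, whose null removes equally many SNPs resampled (with
replacement) from the non-outlier set.

**Between-sex test**: two-group Cochran's Q with df 1, algebraically the
squared z statistic `(θ̂_W − θ̂_M)²/(se_W² + se_M²)`. `ci_to_log()` feeds it
from published OR + CI pairs when only printed numbers are available. The
published non-HDL-C → aSAH row illustrates the limit of that path: printed
2-decimal ORs recompute to p ≈ 0.049 against the published 0.044 — an
arithmetic artefact of rounding, which is why the worked-example tolerance
for that row is ±0.01 while the smoking rows (robust to rounding at 3
decimals) are matched exactly.

By design the sex-difference table tests IVW estimates only (the primary
analysis); other estimators can be requested explicitly. No multiplicity
correction is applied across exposure-outcome pairs, matching the source
design; the number of tests performed is recorded in the provenance block.

## The synthetic generator

`generate_pair()` simulates at the level the analysis consumes — summary
statistics — rather than genotypes: per-SNP true exposure effects, observed
effects with GWAS-scale sampling noise, and outcome effects
`θ·b + α + noise`, with `α` zero, balanced (zero-mean normal) or
directional. Choices worth stating:

* **Sample sizes** default to 250,000 (exposure) and 80,000 (outcome),
  emulating a consortium-scale exposure GWAS and a large case-control
  outcome GWAS; with `beta_x_sd = 0.025` the implied mean F is ≈ 65,
  inside the 37–245 range reported for real sex-specific cardiometabolic
  instruments. Standard errors follow `(2·eaf(1−eaf)·n)^-1/2`, so they
  shrink as `n^-1/2` and the mean F grows accordingly (a tested property).
* **Effect-magnitude model**: true effects are half-normal, i.e. the effect
  allele is coded as the exposure-increasing allele. This is the natural
  convention for instrument panels and keeps directional pleiotropy
  meaningful under the Egger orientation; a signed-effect model would make
  "directional" pleiotropy partially self-cancelling after orientation.
* **Corruption knobs** (`allele_swap_rate`, `strand_flip_rate`,
  `palindrome_rate`) change only the *representation* of the outcome file,
  never the data, so harmonization must invert them exactly; this is the
  package's strongest harmonization oracle.
* **LD** is block-diagonal equicorrelation via `generate_ld_panel()`
  (non-positive-definite requests error); within-block effects are drawn
  independently, which is unrealistic biologically but exactly what the
  clumping tests need — the expected clump output is one index SNP per
  block.
* **No sample overlap** between the exposure and outcome draws, mirroring a
  design that excluded overlapping cohorts from the outcome GWAS.

What the generator does *not* emulate: realistic allele-frequency spectra,
LD-induced correlation among effect estimates, case-control imbalance in
the outcome SE model, population stratification, or winner's curse beyond
the significance filter itself. Passing tests therefore demonstrate the
statistical machinery, not robustness to those real-data pathologies.

## Numerical and reproducibility choices

* Deterministic tie-breaks everywhere (clumping by `(p, rsid)`); clump
  output is invariant to input row order, asserted by permutation tests.
* Seeds are mandatory wherever randomness enters (median bootstrap,
  MR-PRESSO, the generator); `run_analysis()` derives per-unit streams from
  one master seed, so plan + seed determine every output byte.
* Monte-Carlo p-values are `(b+1)/(n+1)`-corrected, never 0.
* Rendering follows the source presentation: ORs/CIs to 2 decimals,
  p-values to 3, round half away from zero, `<0.001` below a thousandth.
* Degenerate inputs: `β_X = 0` SNPs are excluded from ratio-based methods
  with a warning; Egger errors when the oriented exposure effects have no
  spread; all-outlier MR-PRESSO errors ("no reference set"); an empty
  instrument set is a typed `no_instruments_error` that the pipeline
  records as a failed unit without aborting the study.

The test suite runs its simulations at deliberately desk-sized problem
sizes — e.g. 500 replicates of J ≈ 150 for IVW coverage, 2000 null
replicates for the sex-difference type-I error, 200 replicates at
`n_sim = 2000` for the MR-PRESSO planted-outlier recovery — chosen as the
smallest sizes at which the binomial bands on the assessed rates are
informative.

## Limitations

The package deliberately stops at summary-level two-sample MR: no
individual-level models, no multivariable MR, no Steiger filtering, no
proxy-SNP lookup, no liftover, and no genotype-derived LD. The between-sex
test covers exactly two groups; meta-regression over more strata is out of
scope. Real consortium results depend on data acquisition and cohort
overlap logistics that no synthetic fixture reproduces; the published
worked examples recomputed here are those derivable from printed odds
ratios alone.
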