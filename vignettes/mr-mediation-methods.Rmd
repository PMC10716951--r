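---
title: "Methods: two-sample MR estimation and two-step mediation in mrpath"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimation and two-step mediation in mrpath}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrpath)
```

## The causal model and its assumptions

`mrpath` implements two-sample Mendelian randomization: genetic variants
are used as instrumental variables for an exposure, with the SNP-exposure
associations (γ̂ⱼ, σ̂γⱼ) and SNP-outcome associations (Γ̂ⱼ, σ̂Γⱼ) taken
from two separate GWAS. Causal interpretation rests on the three
instrumental-variable assumptions: relevance (the SNP associates with the
exposure), exchangeability (no confounding of SNP and outcome), and
exclusion (no effect on the outcome except through the exposure). No
single estimator is robust to all violations, which is why the package
treats the sensitivity battery — not any single method — as the unit of
analysis (`mr_fit()`).

Effects on binary outcomes are handled on the log-odds scale throughout;
exponentiation to odds ratios happens only in the reporting layer, and a
report-level sign flip is available for presentations phrased per unit
*decrease* of the exposure.

## Estimators and their numerical conventions

**Wald ratio and IVW.** The per-SNP ratio is β̂ⱼ = Γ̂ⱼ/γ̂ⱼ. Its default
standard error is first order, σ̂Γⱼ/|γ̂ⱼ| (a second-order version that
propagates exposure-side noise is available by flag but does not feed the
default weights). IVW pools ratios with weights wⱼ = 1/se(β̂ⱼ)², which is
algebraically a weighted regression of Γ̂ on γ̂ through the origin. The
random-effects flavour is multiplicative over-dispersion: the
fixed-effect SE is inflated by max(1, √(Q/(J−1))). This matches the
dominant convention in two-sample MR software; additive random effects
are deliberately out of scope. All beta p-values are two-sided normal
(not t): estimator asymptotics here are large-J, and the choice keeps
p-values consistent across methods (the t vs normal difference is below
1% for the panel sizes the package targets).

**MR-Egger.** Weighted regression with free intercept after orienting
every SNP so γ̂ⱼ ≥ 0 — Egger regression is not orientation-invariant and
this is the canonical convention. Both slope and intercept SEs carry the
max(1, √(Q/(J−2))) inflation. The fit itself is explicit QR-based
weighted least squares; generic WLS routines are reserved for the test
suite, where they serve as an independent oracle.

**Weighted median.** The sorted ratios are interpolated at normalized
cumulative weight 0.5 using the midpoint convention (cumulative weight
minus half the SNP's own weight). With more than half the total weight
concentrated on SNPs sharing one ratio, and that run covering the 0.5
point of the midpoint grid, the estimate equals that ratio exactly.

**Mode-based estimators.** The ratios are smoothed with a normal kernel
of bandwidth φ·0.9·mad(β̂)·J^(−1/5) — a modified Silverman rule on the
median-absolute-deviation scale, robust to outlying ratios — and the
density (equal kernel weights for the simple mode, inverse-variance
weights for the weighted mode) is maximized over a fixed 512-point grid
spanning the ratios ± 3 bandwidths. The fixed grid makes the estimator
exactly reproducible and testable against a dense-grid oracle; φ
defaults to 1. If all ratios coincide the bandwidth degenerates and that
common ratio is returned.

**Bootstrap SEs.** Median and mode SEs come from a parametric bootstrap:
per-SNP effects are redrawn from normal distributions centred at the
observed values with the reported SEs and the estimator is recomputed
(default 1000 draws; below 100 draws a warning is issued; 0 draws skips
the bootstrap for simulation studies that need only point estimates). A
seed is mandatory everywhere randomness enters — there is no silent
clock seeding anywhere in the package.

**MR-PRESSO.** The observed residual sum of squares
Σⱼ wⱼ(Γ̂ⱼ − β̂₍₋ⱼ₎γ̂ⱼ)², with leave-one-out IVW estimates β̂₍₋ⱼ₎ and
wⱼ = σ̂Γⱼ⁻², is compared against a null distribution built by redrawing
both γ̂* and Γ̂* from their sampling distributions (default 5000
simulations). Per-SNP contributions yield outlier p-values with the
add-one estimator (lower bound 1/(n_sim+1)); SNPs with
Bonferroni-adjusted p < 0.05 are flagged, and a multiplicative
random-effects IVW on the remainder is the corrected estimate. The
distortion test (significance of the raw-vs-corrected shift) is not
implemented. SNPs are put in canonical identifier order before any
random draw, so results are independent of input row order; the
implementation is single-threaded and fully vectorised from one seeded
stream, making equal seeds bitwise-reproducible by construction.

## Harmonization, clumping and instrument selection

Outcome effects are aligned to the exposure's effect allele, recognising
both swapped-allele and opposite-strand codings. Palindromic SNPs (A/T,
C/G) cannot be strand-resolved from alleles alone; the default policy
`drop_ambiguous` drops them all (conservative), while `infer_by_eaf`
orients them by allele frequency and drops only those with either
frequency inside [0.5 − w, 0.5 + w] (default w = 0.08, i.e. ambiguous =
eaf in [0.42, 0.58]) or missing. Every exclusion is logged with a reason
(`allele_mismatch`, `palindromic_ambiguous`, `missing_in_outcome`) —
never silently, and never as an exception.

LD clumping is greedy: SNPs ranked by ascending p-value (ties broken
lexicographically on the identifier, for cross-platform determinism) are
accepted iff their r² with every already-accepted SNP on the same
chromosome within the window is strictly below the threshold (defaults
r² < 0.001 within 10,000 kb). Positions are 1-based and the window is
inclusive (|posᵢ − posⱼ| ≤ window). A pair absent from the supplied LD
records counts as r² = 0: absent evidence of correlation should not
discard instruments, and remote reference-panel lookups are deliberately
out of scope (proxy variants must be pre-resolved in the input, with an
optional rename map). For multivariable MR the instrument set is the
union of SNPs genome-wide significant in any exposure, clumped on the
smallest p-value across exposures — union-then-clump rather than
concatenating per-trait clumped lists, so the joint set is itself
approximately independent.

## Two-step mediation

Step 1 estimates β₁ (exposure → mediator) by univariable IVW; step 2
estimates β₂ (mediator → outcome, adjusted for the exposure) by MV-IVW.
The indirect effect is the product β₁β₂ with first-order delta SE
√(β₁²se₂² + β₂²se₁²) — without the se₁²se₂² cross term, the dominant
convention in two-step MR. The mediation proportion is indirect/total
with a ratio delta SE that treats the two as independent (the two-sample
setting estimates them from partially disjoint data; the shared
outcome-GWAS noise between β₂ and the total effect is a known
approximation, noted under limitations). Negative raw proportions are
truncated to 0% and flagged — 0% is the lowest value at which a
mediation proportion is meaningful — and the SE always describes the
untruncated ratio. For binary mediators β₁ is on the log-odds scale and
the proportion inherits mixed units; the implementation computes on
whatever scale the inputs carry and preserves the unit annotations.

Screening applies three criteria: (1) the exposure is causally
associated with the mediator, operationalised as an evidence grade of at
least "suggestive" with FDR computed across the full candidate battery
as one family per exposure-outcome pair (per-candidate families would be
anti-conservative); (2) the mediator has a direct effect on the outcome
(step-2 p < 0.05); (3) the mediated and total effects share a sign.
Benjamini-Hochberg is the FDR method (delegated to `stats::p.adjust`
behind a validating wrapper); evidence grading follows the rule: IVW
p < 0.05 with q < 0.05 and at least one same-direction significant
sensitivity estimate is "causal", IVW p < 0.05 otherwise "suggestive",
else "none". P-values that underflow to zero at extreme z-statistics are
clamped to the smallest positive double before FDR.

## The synthetic-data generator

The generator emulates the summary statistics such a study consumes,
without individual-level genotypes: per SNP, a minor-allele frequency
from U(0.1, 0.4); a true per-allele instrument effect from N(0.05, 0.01)
in exposure-SD units — the strong-instrument regime of genome-wide
significant, stringently clumped loci, giving mean F around 280; and
observed effects drawn from Normal(truth, se²) with
se = 1/√(2·maf·(1−maf)·n), the variance of a per-allele coefficient for
a standardized trait, which reproduces realistic weight heterogeneity
across frequencies. Default sample sizes mirror consortium scale
(exposure 297,356; mediator 450,243; outcome 638,000). The causal chain
defaults to β(exposure→mediator) = 0.5, β(mediator→outcome) = 0.168 and
a direct effect of 0.252, so the total effect is log(1.40) = 0.336 on
the log-odds scale with a true mediated proportion of 25%. Exposure
instruments are partitioned into fetal-only (41%), maternal-only (23%)
and shared (36%) genome-of-origin classes, with the orthogonal path
effect exactly zero by construction. Pleiotropy can be balanced
(mean-zero, InSIDE-satisfying by independence) or directional, applied
to a configurable fraction of instruments; outliers are planted by
displacing outcome effects a stated number of SEs. Mediator-specific
instruments (default 80) are generated alongside, because step-2
multivariable MR is unidentified without them; a battery variant
produces several candidate mediators over one shared panel for
screening-specificity studies.

What the generator does **not** emulate — and what recovery tests
therefore cannot certify on real data: sample overlap between the two
GWAS, winner's-curse inflation of selected instruments, population
stratification, real LD structure (the block simulator generates
stylised Beta-distributed within-block r² only), and non-linear or
interacting effects.

## Validation design and problem sizes

The study-scale test suite validates: exact agreement (≤ 1e-10) of IVW,
MR-Egger, MV-IVW and MVMR-Egger with a generic weighted-least-squares
oracle on 50 random instances up to J = 200, K = 4; parameter recovery
over 500 replicates at the default conditions (J = 120, true effect
0.336); Egger intercept calibration and power over 1000 replicates under
balanced (sd 0.003, about 1.5× the outcome sampling SE) and directional
(mean = 2·sd) pleiotropy; robustness ordering of the weighted median
versus IVW with 40% invalid instruments (500 replicates); MR-PRESSO
outlier detection and null calibration (200 and 500 replicates,
n_sim = 1000) with the planted-outlier panel sized at J = 8 so that a
single 10σ outlier displaces IVW by about 3.5 sampling SDs — on large
panels a lone outlier is diluted below the estimator's own noise and
removing it cannot systematically improve the estimate; mediation
recovery of the 25% proportion (500 replicates); screening specificity
on 6-candidate batteries (200 replicates); exhaustive small-instance
oracles for clumping, BH-FDR and the weighted median; and bitwise
determinism of every stochastic routine under fixed seeds.

## Known limitations

* **Weak-instrument attenuation.** Because the exposure associations
  carry sampling error, every ratio-based estimator is multiplicatively
  attenuated by roughly F̄/(F̄+1); at the default mean F ≈ 280 this is a
  ~0.4% shrinkage of the causal estimate. It is a property of the
  estimators, not of this implementation, and it is visible in
  high-replicate recovery studies whose Monte-Carlo resolution is finer
  than the attenuation; CI coverage dips correspondingly a point or two
  below nominal.
* **Egger intercept under imperfect instrument precision.** The same
  exposure-side noise attenuates the Egger slope and thereby displaces
  the intercept by β·mean(γ)·(1 − I²GX); at I²GX ≈ 92% (the default
  generator regime) the intercept test over-rejects a null of no
  directional pleiotropy. SIMEX-style corrections are out of scope.
* The mediation-proportion SE assumes independence of the indirect and
  total effects and omits the delta cross term; a covariance-aware
  variant is noted as an open refinement.
* Proportions are per-mediator and non-additive across mediators;
  exposure-mediator interactions are not modelled.
* No Steiger filtering, contamination-mixture or correlated-instrument
  (generalized) IVW estimators; no remote LD or proxy lookups; no
  genome-build liftover.

## Interface notes

The package is organised in the classic modelling idiom — fitting
functions returning classed objects with `print`/`summary`/`coef`/
`confint`/`plot` methods — because its users work interactively in R, as
with the established MR packages; the two-phase pipeline is exposed as
plain functions (`run_phase1()`, `run_phase2()`) driven by a JSON
configuration rather than a shell entry point. Every report cell
originates from an estimate object that is also serialized to a JSON
side-car with the seed and configuration, so each number in a table is
traceable to a machine-readable record.
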