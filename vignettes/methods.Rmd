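---
title: "Models and methods behind fieldevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fieldevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fieldevol` implements the quantitative pipeline of a multi-generation field
experimental-evolution study in which resynthesized hybrid plant lineages and
a non-hybrid control lineage evolve *in situ* and are then phenotyped in a
final common garden. This vignette describes the statistical models, the
tunable parameters that matter, the synthetic world the generators emulate,
and the numerical choices made where the design was genuinely open. It states
no empirical result that the package's tests and acceptance script do not
themselves compute.

## The trend model

The central model regresses a standardized trait (or fitness) value $y_i$ on
generation $x_i$ with a separate intercept and slope per group $j$ (treatment
or lineage):

$$y_i = \beta_{0j} + \beta_j x_i + \epsilon_i,$$

with $\beta_{0j}, \beta_j \sim N(0, 1)$ and the noise precision
$\tau = 1/\sigma^2_\epsilon \sim \mathrm{Gamma}(1, 1)$. Because traits are
z-scored before fitting, the unit-variance prior is weakly informative on the
natural scale of the data, and the Gamma(1, 1) prior on the *precision* is
the convention of BUGS-family samplers for this model class ("shape and scale
one" is unambiguous at these values since shape equals rate equals scale).

The sampler (`gibbs_linear_model()`, compiled core in `src/gibbs.cpp`) is a
pure conjugate Gibbs alternation: the coefficient vector given $\tau$ is
jointly multivariate normal, and $\tau$ given the coefficients is gamma.
There is no tuning, and the joint coefficient update makes successive draws
nearly independent — which is why the test suite can run short chains
(2 × 6,000) and retain the inferential content of the default regime
(5 chains × 100,000 iterations, 25,000 burn-in, thinning 25). The default
regime yields 15,000 saved draws, which conflicts with the commonly quoted
10,000; the package resolves this by evenly subsampling pooled draws down to
`save_target = 10000`. Each chain draws from its own stream seeded
`seed + chain`. With zero rows the posterior correctly collapses to the
prior. Convergence is monitored with the classic Gelman–Rubin statistic
$\hat R = \sqrt{((n-1)/n \cdot W + B/n)/W}$; $\hat R > 1.01$ attaches a
warning rather than failing, matching common practice of flagging, then
inspecting.

Support classification uses equal-tailed empirical quantile intervals
(linear interpolation): **strong** support when the 95% interval excludes
zero, **moderate** when only the 80% interval does. Quantile (not HPD)
intervals were chosen because BUGS-family summaries are quantile-based and
the credible-interval rule in the source analysis was stated in those terms.

### Slope-magnitude comparisons

Whether hybrids evolve *faster* is asked of the paired-draw distribution
$|\beta_{hybrid}| - |\beta_{control}|$, draws paired by pooled index (both
posteriors are exchangeable draws, so index pairing is valid and preserves
draw-count accounting; mismatched counts are an error, never silently
resampled). The folded-difference direction — take absolute values, then
subtract — is used because it is sign-informative about *which* lineage is
steeper; the opposite order of operations discards that information.

### Fitness contrasts within a generation

Per-generation treatment contrasts use a small hierarchical model:
$y_i = \eta_{t(i)} + u_{\ell(i)} + \epsilon_i$ with Normal(0, 100) priors on
the treatment cell means, lineage random intercepts
$u_\ell \sim N(0, \sigma_u^2)$, a half-Normal(0, 10) hyperprior on
$\sigma_u$, and Gamma(1, 1) on the noise precision. All conditionals are
conjugate except $\sigma_u$, which takes a random-walk Metropolis step on
$\log \sigma_u$ (Gibbs-within-Metropolis). One deliberate choice: the
reported contrast is the difference of *fitted treatment means including the
lineage effects*. With a single lineage per treatment — the actual design of
such experiments, which have one control lineage — the fixed effect and its
lineage intercept are individually confounded, but their sum is identified;
contrasting the sums keeps the posterior centred on the true group
difference regardless of how the model splits it internally.

## Evolutionary rates in haldanes

The two-endpoint haldane is
$H = \left((\bar y_{late} - \bar y_{early})/s_p\right)/g$ with means on the
natural-log scale and $s_p$ the pooled standard deviation
($n-1$ weighting). $g$ defaults to 7 (generations 1 through 8). Traits with
nonpositive values (carbon-isotope ratios, zero damage fractions) cannot be
log-transformed; rather than adding an arbitrary offset — any offset choice
changes $H$ — the rate falls back to the raw scale and every report carries
the `log_transform_applied` flag.

Counts of significantly evolving (or faster-evolving) traits in two lineages
are compared by a 1-df goodness-of-fit test with equal expected frequencies,
$X^2 = (a-b)^2/(a+b)$, no continuity correction. This specific construction
was adopted because it is the unique standard test that reproduces the
cross-checkable published statistics for such comparisons; a 2×2 contingency
variant is available behind `method = "contingency"` for sensitivity checks.

## Phenotypic selection analysis

Selection on a standardized trait $z_k$ is measured two ways, in the
Lande–Arnold framework: the selection *differential*
$s'_k = \mathrm{cov}(z_k, w)$ (total selection) with $w$ the relative
fitness (fitness over within-treatment mean fitness, so $\bar w = 1$
exactly per treatment), and the selection *gradient* $\beta_k$, the partial
regression coefficient of $w$ on all traits jointly (direct selection). For
uncorrelated traits the two coincide, a property the tests verify on an
exactly orthogonal design. Standardization for this analysis is
within-treatment, independent of the global standardization used by the
trend models — the two analyses answer different questions on different
reference populations. Normality transforms for predictors are a
user-supplied per-trait hook (`transforms =`), not automatic, because no
defensible default set of transforms exists.

Confidence intervals come from case bootstrap resampling, 10,000 replicates
by default, with bias-corrected-and-accelerated (BCa) endpoints: bias
correction $z_0$ from the fraction of replicate statistics below the point
estimate and acceleration $a$ from jackknife skewness. "Bias-corrected" in
bootstrap software can mean plain BC or full BCa; the package implements the
stronger reading as default with `"bc"` and `"percentile"` switchable. All
statistics of one treatment share a single set of resamples, so the
differentials and gradients of a bootstrap replicate describe the same
resampled population. A replicate on which a statistic is undefined is
redrawn and counted. Significance means the 95% interval excludes zero.

A trait's evolution is called **adaptive** when its generational trend and
its generation-1 selection gradient are both supported and share a sign.
The default evolution threshold is strong-or-moderate (80% credible level or
better), configurable to strong-only. Traits absent from the selection
analysis are "not assessable", never silently dropped.

## Distance predicts rate

For each trait the signed distance from a lineage's generation-1 mean to the
locally adapted reference mean (both on the shared standardized scale) is
regressed against the Bayesian slope estimate by OLS, with a two-sided
t-test ($n-2$ df) on the coefficient. Distance is *signed* — reference minus
initial — so a positive coefficient means evolution proceeds toward the
local phenotype; an absolute-value mode exists behind `absolute = TRUE` for
users who only care about speed, not direction.

## Gene-flow detection

A backcross-founded (BC1) population is genetically closed: every allele in
later generations must already segregate among the founders. The detector
builds a catalogue of all alleles carried by BC1 genotypes at sites called
in at least 20 founders (sites below the threshold are unreliable and
dropped), then scores each later sample for the percentage of its called
allele observations absent from the catalogue. The unit is allele
observations — a heterozygous novel call contributes 1 of 2 — because it is
the finest-grained count; a per-site variant unit is switchable. Samples at
or above 0.5% novel alleles are classified admixed; the threshold is the
boundary below which samples are empirically indistinguishable from
founder-only ancestry, and is configurable. Control populations are not
scored: their founding allelic diversity is too high for novel alleles to be
identifiable, which the API reflects by requiring an explicit founder set.

## The synthetic world

The generators exist so every stage is testable without the undeposited
field data. Their defaults are a fixed stated world, not tuning dials:

* **Phenotypes** (`simulate_experiment`): control and one hybrid lineage at
  generations 1 and 5–8, a second hybrid lineage at generations 1 and 8
  (the final common-garden planting design), 60 plants in endpoint
  generations and 30 in intermediate ones. Trait value = lineage intercept +
  slope × generation + Normal(0, 1); per-trait slopes default to the
  published per-trait haldane rates (standardized units per generation),
  fitness slopes to the published 0.001 / 0.154 / 0.115 with hybrid
  intercepts 0.3 SD below controls (hybrids start worse). Fitness is
  truncated at zero — seed counts cannot be negative — while the linear
  model is still fit to the truncated values, mirroring the normal-likelihood
  simplification of the original analysis. The reference cohort's trait
  means default to (LBJ slope)/0.12, emulating a world in which lineages
  approach the local phenotype at a rate proportional to distance, with the
  distance–rate coefficient at the magnitude the study reported.
* **Selection cohort** (`simulate_selection_generation`): standard-normal
  traits (optionally correlated), relative fitness
  $w = 1 + \sum_k \beta_k z_k + N(0, 0.3)$ truncated at zero, default
  gradients of magnitude 0.2–0.3 on three traits, 200 plants per treatment.
* **Genotypes** (`simulate_genotypes`): 1,000 biallelic sites at BC1
  alternate-allele frequencies 25/50/75% (weights 0.5/0.25/0.25 — backcross
  segregation makes the 25% class the most common), 90 genotyped founders, a
  breeding population of 250, 45 genotyped samples per later generation.
  Migration acts at the gamete level: each offspring gamete is, with
  probability $m$, a migrant haplotype carrying an outside-private allele at
  10% of sites. This is the simplest mechanism that produces
  rising-then-plateauing admixture trajectories; no mechanistic model was
  given for the real system. Missing calls at 5%.

What a green test does *not* establish: the phenotype generator has
independent traits, homoskedastic normal residuals and exactly linear
trends, so passing recovery tests does not validate behaviour under trait
correlations, heteroskedasticity or nonlinear trajectories. The genotype
simulator has free recombination, no linkage map, no selfing genetics and no
selection, so admixture trajectories are calibration checks of the detector,
not population-genetic predictions.

## Numerical choices and degenerate inputs

* Sample statistics use $n-1$ denominators throughout (SD, covariance,
  pooled SD).
* The longevity exclusion is strict: a plant living exactly 75 days is kept.
  Exclusion rules apply in a fixed order and a plant matching several is
  attributed to the first, so report counts partition the removals.
* Zero seeds scored makes damage fractions missing, never zero; a plant with
  heads but no bagged head has missing fitness with a warning; zero heads is
  fitness zero.
* Constant trait columns are a hard standardization error naming the trait;
  missing cells propagate and are deleted casewise per analysis, never
  imputed.
* Degenerate bootstrap distributions (all replicates equal) return a point
  interval; $z_0$ would otherwise be infinite.
* $\hat R$ over chains with zero internal variance is undefined and returned
  as flagged `NA` rather than 1.
* All generators and samplers are deterministic under a fixed seed, with
  chain seeds derived as master + chain index.

## Known limitations

Only linear selection gradients (no quadratic/correlational selection); only
two-endpoint haldanes (no multi-generation rate estimators); the hierarchical
model is intentionally small (no crossed random effects); VCF support is
GT-only; and the published per-trait rate table shipped with the package is
an input for recomputing summary statistics, not a substitute for raw data —
per-plant slope estimates of the original study cannot be reproduced without
the undeposited field measurements.
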