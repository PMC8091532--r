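---
title: "Simulating genetic trait architectures and estimating association power"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating genetic trait architectures and estimating association power}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phenosim)
```

# The problem

Before a genetic association study is mounted, its design must be
evaluated: at genome-wide significance, what is the probability of
detecting a causal SNP of a given effect size? Closed-form answers exist
only for the simplest Gaussian models, while real phenotypes are binary
diagnoses, ordered disease stages, counts, skewed positive quantities, or
correlated family measurements. `phenosim` therefore estimates power by
brute-force simulation: draw many phenotype replicates from the assumed
generative model, analyze each exactly as the eventual study would, and
count rejections.

This vignette records the models, the numerical choices, and the limits
of what the package's own tests demonstrate.

# Genotype substrate

Genotypes are biallelic SNP dosages. Internally they live in a packed
SNP-major 2-bit buffer — the same byte layout as the body of a PLINK 1.9
`.bed` file (codes 00/10/11 for 0/1/2 copies of allele2, 01 for missing,
four samples per byte, zero pad bits) — so a matrix of n samples by S
SNPs costs S·⌈n/4⌉ bytes and round-trips to disk losslessly.

Two conventions are fixed at construction time:

* **Minor-allele orientation.** Dosages always count the minor allele.
  If allele2's frequency among non-missing calls exceeds 0.5, the SNP is
  flipped (dosage ↦ 2 − dosage) and its allele labels swapped; the swap
  is recorded in `snp_info$swapped` so output filesets are reproducible.
  A frequency of exactly 0.5 is left unflipped.
* **Missing data.** Allele frequencies are computed over non-missing
  calls only. During GRM estimation, a missing genotype is imputed as
  the most likely genotype under Hardy–Weinberg equilibrium given the
  SNP's MAF: the mode of ((1−p)², 2p(1−p), p²), i.e. 0 for p < 1/3 and
  1 for p ≥ 1/3. The exact tie at p = 1/3 is resolved to the lower
  dosage, making the imputation a deterministic step function.

## The genetic relationship matrix

Realized relatedness is estimated by the standard formula

$$\hat\Phi_{ij} \;=\; \frac{1}{2S}\sum_{k=1}^{S}
  \frac{(G_{ik}-2p_k)(G_{jk}-2p_k)}{2p_k(1-p_k)},$$

after excluding SNPs with undefined MAF or MAF ≤ `maf_threshold`
(default 0.01; monomorphic SNPs are thereby dropped automatically). On
this scale an unrelated non-inbred individual has expected diagonal 1/2
and unrelated pairs expect 0 — kinship-coefficient scale. The additive
model convention, in which the residual covariance of relatives is the
additive variance times *twice* the kinship coefficient, wants the matrix
at twice this scale; both conventions circulate, so `compute_grm()`
exposes `scale = "kinship"` (the formula exactly as above, the default)
and `scale = "relationship"` (twice it). The two differ only by the
factor of two, and the variance-component machinery accepts either as
long as the interpretation of σ_A follows along.

# Trait models

One polymorphic `simulate()` entry point (the base-R generic) dispatches
on the model class. All models share the linear predictor
η = Xβ + Gγ. Every simulate path is a pure function of (model, seed).

**GLM traits.** `glm_trait()` supports normal, Bernoulli, binomial,
Poisson, negative binomial, gamma and exponential responses. Family/link
pairings are validated against an explicit table; anything unlisted is
rejected at construction so an inverse link can never silently produce a
mean outside the family's domain. Parameterizations the literature
leaves open are fixed as: normal carries a residual standard deviation
`sd`; binomial carries `trials` with the link acting on the per-trial
success probability (mean = trials·p); negative binomial uses
(mean μ, dispersion r) with variance μ + μ²/r; gamma carries `shape` α
with rate α/μ; exponential has mean 1/rate.

**Ordinal traits.** `ordinal_trait()` implements the cumulative-link
model g(Pr(y ≤ j)) = θ_j − η with nondecreasing intercepts θ₁ ≤ … ≤
θ_{J−1} and a logit (proportional odds), probit, or complementary
log-log (proportional hazards) link. On the logit link e^γ is the
per-allele cumulative odds ratio. `simulate(..., logistic = TRUE,
cutoff = c)` dichotomizes the *same* underlying draws at category c —
the indicator [y > c] — so a case/control trait is exactly the cut
ordinal trait, replicate for replicate. The strict inequality means
categories above the cutoff form the case group (cutoff 2 with J = 4
makes {3, 4} cases).

**Variance-component traits.** `vcm_trait()` draws
Y = XB + GΓ + Σ_c E_c with cov(vec E_c) = Σ⁽ᶜ⁾ ⊗ V⁽ᶜ⁾. `vec` stacks
columns (traits), so V acts on individuals. Each component is sampled as
L_V Z L_Σ', with L the PSD square roots of V and Σ — the nd × nd
Kronecker matrix is never assembled, which is what makes biobank-scale n
feasible. Factors are computed once at `variance_component()`
construction and cached, so repeated simulation from one model (the
power loop's hot path) never refactors an n × n matrix.

**GLMM traits.** `glmm_trait()` adds a correlated normal random effect
u ~ N(0, Σ_c σ⁽ᶜ⁾V⁽ᶜ⁾) to the linear predictor of a univariate GLM,
then draws conditionally independent responses. Random effects enter on
the linear-predictor scale, the standard GLMM convention.

Numerical tolerances: covariance matrices must be symmetric to 1e-10
(relative) and eigenvalues ≥ −1e-8 (relative); small negative
eigenvalues are clipped to zero before factorization, anything more
negative raises an error naming the offending matrix. A component with
Σ = 0 contributes exactly zero and skips both the factorization of its V
and the random-number draws.

One caveat worth stating: for a *Bernoulli* GLMM with independent
per-individual random effects, the marginal variance equals the
Bernoulli variance at the marginal mean identically (law of total
variance with a binary outcome), so overdispersion is only visible in
grouped structures — shared random intercepts or count responses. The
test suite demonstrates it with binomial counts and with block-shared
Bernoulli intercepts.

# Synthetic genotypes

The built-in generators make the package self-contained — no external
data is needed to exercise any code path, and the test suite builds all
of its fixtures from them.

* `generate_unrelated(n, maf, missing_rate)`: independent
  Binomial(2, p) dosages per SNP (Hardy–Weinberg equilibrium), with
  independent missingness.
* `generate_sibships(n_families, sibs_per_family, maf)`: per family,
  two founders receive independent Bernoulli(p) alleles; each sib
  inherits one uniformly chosen allele from each parent per SNP. This is
  single-generation gene dropping with unlinked SNPs. The theoretical
  kinship matrix (diagonal 1/2, full sibs 1/4, parent–offspring 1/4,
  founders unrelated) is returned alongside.

What the generators deliberately do **not** emulate: linkage
disequilibrium, recombination maps, multi-generation pedigrees,
population structure or admixture, and ethnicity-specific frequency
spectra. Passing tests therefore certify the statistical machinery —
formulas, samplers, fitters, the power loop — under idealized genotype
structure; they do not certify robustness to LD or stratification in
real data. Defaults used throughout the tests mirror the study
conditions the package targets: sibships of four, MAF 0.23 for the
focal SNP, variance split σ_A = 0.4 / σ_E = 0.6 on unit total variance,
four ordered disease categories with θ = (−1, 0, 1).

# Analysis engines

The power loop needs fast, reliable maximum-likelihood fits of the two
analysis models, plus the likelihood-ratio test.

**Ordinal fitter.** `fit_ordinal()` maximizes the multinomial
log-likelihood by Newton iterations with step-halving on the
reparameterized scale (θ₁, log(θ₂−θ₁), …, β), which keeps the
intercepts strictly ordered without constraints. The gradient is
analytic; the Hessian is a central finite difference of that gradient
(cheap at these dimensions and link-agnostic). Starting values take θ
from the link-transformed empirical cumulative frequencies and β = 0.
Convergence is a gradient max-norm below 1e-8, capped at 100 iterations;
non-convergence is reported, never silently accepted. Standard errors
come from the inverse observed information at the MLE (skippable in
tight loops). The suite cross-checks estimates and log-likelihoods
against an independent implementation (`MASS::polr`).

**Variance-component fitter.** `fit_vcm_univariate()` fits
y ~ N(Xβ, σ_A Φ + σ_E I) by full ML — not REML, because the power loop
compares models that differ in their *fixed* effects, for which ML
likelihoods are the coherent choice. With the one-time eigendecomposition
Φ = U D U', rotation by U' makes the covariance diagonal
(σ_A d_i + σ_E). β is then profiled out by weighted least squares and
the total variance σ² = σ_A + σ_E analytically, leaving a

one-dimensional search over the heritability ratio h = σ_A/σ² ∈ [0, 1]:
a coarse grid scan (step 0.02) brackets the optimum, golden-section
refinement (tolerance 1e-10) polishes it, and the boundaries h ∈ {0, 1}
are checked explicitly, so σ_A = 0 is handled exactly rather than
through a log-scale parameterization that cannot reach it. Profiling
two of the three parameters makes the search immune to the boundary and
ridge pathologies that a joint (log σ_A, log σ_E) search must dodge with
multi-starts. `vcm_rotation()` exposes the eigendecomposition so that
replicate loops against a fixed Φ pay the O(n³) cost once; this is the
dominant cost at large n, exactly as in production variance-component
analyses.

**LRT.** `lrt_pvalue()` returns the upper-tail χ²(df) probability of
2(ℓ_A − ℓ₀), clipping negative statistics within 1e-8 to zero and
refusing larger ones (a sign of non-nested models or a failed fit).
Significance of γ is always assessed by LRT, refitting both the null and
the alternative model on every replicate.

# The power procedure

`power_study_config()` freezes a study: a template model lacking only γ,
an effect-size grid, the replicate count, α, and a root seed. For each
grid value, `estimate_power()` completes the template, simulates
`n_reps` phenotype replicates, analyzes each (null fit without the SNP
column, alternative fit with it), and reports the rejection proportion
with a Wilson 95% interval. Replicates whose fits fail to converge are
excluded from the denominator and counted; more than 5% triggers a
warning in the result.

Two deliberate design choices:

* **Common random numbers across the grid.** Replicate substreams are
  pre-drawn integer seeds derived from the root seed and the replicate
  index only — not the grid position. Each grid point's result is
  therefore unchanged by adding or removing other grid points, and the
  Monte Carlo noise in power *differences* along the curve largely
  cancels, which sharpens monotonicity comparisons at no cost.
* **Desk-scale α in the tests.** The config default is the genome-wide
  α = 5 × 10⁻⁸, but no desk-scale replicate count can estimate a
  rejection rate that small, so the test suite and acceptance script
  work at α ∈ {0.05, 0.01}, where level and power are estimable from
  hundreds-to-thousands of replicates; calibration further into the tail
  is covered by the Kolmogorov–Smirnov uniformity check on null
  p-values.

The x-axis transforms of the two case-study figures are attached to the
result: e^γ (odds ratio) for ordinal models, and for variance-component
models the proportion of variance explained, PVE = γ²·2p(1−p)/σ²_total
with σ²_total defaulting to σ_A + σ_E + γ²·2p(1−p).

# Problem sizes used in validation

The package validates itself at sizes chosen to finish in minutes on one
core while leaving Monte Carlo bands tight enough to be meaningful: GRM
moment checks use 500 unrelateds (and 500 sibships of four) × 5000 SNPs;
the Kronecker covariance law is verified at n = 3, d = 2 against the
explicitly assembled 6 × 6 matrix over 200 000 draws; ordinal LRT
calibration uses n = 2000 samples × 2000 null replicates;
variance-component recovery uses 500 sibships of four × 200 replicates;
the power curve demonstration uses n = 1000 and 500 replicates per grid
point. The corresponding published-scale analyses (n ≈ 2 × 10⁴–2 × 10⁵,
1000 replicates at α = 5 × 10⁻⁸) are the same code paths at larger n —
nothing in the implementation is specific to the desk scale, and the
O(n³) eigendecomposition plus O(n) per replicate cost structure matches
standard variance-component practice.

# Known limitations

* Multivariate (d > 1) variance-component *fitting* is out of scope; the
  simulator is fully multivariate, but bivariate power studies must
  analyze each trait univariately or supply a custom analyzer hook.
* GLMM *fitting* (integral approximation) is likewise out of scope — the
  package simulates from GLMMs but does not analyze under them.
* No LD, recombination, or multi-generation pedigrees in the synthetic
  generators (above).
* The ordinal analyzer assumes every category is observed in every
  replicate; with extreme intercepts and small n this can fail, which
  surfaces through the flagged-replicate mechanism rather than a crash.
* PLINK 2 formats, dosage/BGEN data and multi-allelic variants are not
  read; PCA and LD pruning are not provided.
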