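---
title: "Models and methods behind gpcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gpcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(gpcomp)
```

`gpcomp` compares seven genomic prediction models — GBLUP, single-step
GBLUP, and five Bayesian marker-effect regressions — on simulated
pedigreed populations, together with the surrounding machinery a real
comparison needs: marker quality control, density panels, fixed-effect
phenotype correction, REML heritability estimation, and cross-validated
accuracy and bias. This vignette documents the models, the tunable
parameters, the synthetic-data generator's assumptions, and the numerical
choices, in enough detail that every result the package produces can be
traced back to a formula and a decision stated here.

## The two-stage analysis scheme

Raw records are first adjusted for categorical fixed effects (sex, farm,
birth batch analogs) by ordinary least squares with reference-level dummy
coding; the corrected phenotype is the residual plus the fitted
intercept, `y_c = y - X b_hat + b0`, which keeps `y_c` on the grand-mean
scale so the overall mean `mu` in downstream models remains meaningful.
All prediction models then use `y_c` with an intercept-only fixed design.

Two properties follow from the OLS projection and are enforced by tests:
`var(y_c) <= var(y)`, and the mean of `y_c` is equal across the levels of
every fitted effect. Correction is computed once on the full dataset by
default — the same two-stage order a field study uses, where correction
precedes cross-validation. This leaks a small amount of fixed-effect
information across CV folds; `correct_phenotypes(fit_on = )` offers a
within-training-fold alternative for sensitivity analyses (an unseen
factor level in the application set is then an error, never a silent
`NA`).

## Relationship structures

**Genomic.** `compute_G()` implements the VanRaden matrix
`G = M M' / (2 sum p_i (1 - p_i))` with `M` the dosage matrix centered by
`2 p_i`. Two conventions deserve a note:

- The centering frequency is the *counted-allele* frequency by default.
  Centering at the literal minor-allele frequency (offered as
  `freq_convention = "minor"` for sensitivity checks) breaks `E(M) = 0`
  whenever the counted allele is the major one, which distorts the
  relationship scale; the counted-allele convention is what makes the
  denominator equal the expected marker heterozygosity.
- With frequencies observed from the data, the centered columns each sum
  to zero, so `G` annihilates the all-ones vector and is *always
  singular*. Any use of `G^-1` therefore requires either blending,
  `G* = (1 - eps) G + eps A22` with `eps = 0.05` by default
  (`blend_G()`), or externally supplied centering frequencies
  (`compute_G(freq = )`). Monomorphic markers are excluded from numerator
  and denominator alike.

**Pedigree.** `compute_A()` is the recursive tabular method (founders
unrelated and non-inbred); `compute_A_inverse()` applies Henderson's
rules with inbreeding, taking the inbreeding coefficients from the
tabular diagonal — exact at the package's desk scale, O(n^2) but never
the bottleneck.

**Single-step.** `assemble_H_inverse()` forms
`H^-1 = A^-1 + [0 0; 0 G^-1 - A22^-1]` with no tau/omega scaling weights
and no mean/diagonal tuning of G toward A22 — the plain single-step
combination. `compute_H_inverse()` wraps the whole construction
(A, sparse A-inverse, A22, blending, inversion, assembly) and refuses a
singular G with advice to blend.

## REML and heritability

`estimate_reml()` maximizes the restricted likelihood of
`y_c = mu + g + e`, `g ~ N(0, K sigma_g2)`, on the eigendecomposition of
K: rotating by the eigenvectors makes V diagonal, so every likelihood,
score and average-information evaluation is O(n) after a one-time O(n^3)
decomposition. The iteration is average-information REML; when an AI step
would leave the parameter space it falls back to the EM update
`sigma^2 <- sigma^2 + sigma^4 (y'PKPy - tr(PK)) / n`, and each accepted
step must not decrease the likelihood (step halving otherwise). Because
AI/EM iterations creep when the optimum sits at a variance boundary, a
final polish maximizes the 1-D profile of the same restricted likelihood
over the heritability ratio (cheap in the rotated representation) and
adopts the result only if it improves the objective; boundary estimates
are reported with `h2 = 0` and flagged. Standard errors come from the
inverse AI matrix, `SE(h2)` by the delta method. Non-convergence is a
flagged result with a warning, never silent.

`heritability()` is the ratio `sigma_g2 / (sigma_g2 + sigma_e2)`.

## BLUP solvers

`solve_gblup()` and `solve_ssgblup()` build and solve the mixed-model
equations directly (dense factorization — exact at desk scale, and the
contract is the residual norm of the solved system, which is reported).
Individuals absent from `y` receive GEBVs through their relationships;
under `H^-1` that includes ungenotyped pedigree members.
`solve_snp_blup()` is the ridge marker-effect solver with a jointly
estimated (absorbed) intercept, evaluated in the m- or n-dimensional
form, whichever is smaller. With `G = WW'/c` from the same centering and
`k_marker = k c`, SNP-BLUP reproduces GBLUP GEBVs to machine precision —
the package keeps this classical equivalence as a permanent test of both
solvers.

The variance ratio `k` is re-estimated by REML on each training fold by
default (no leakage); the predictor factories accept a fixed `k` to
mirror the cheaper estimate-once design.

## The Gibbs engine

One compiled sampler (`run_mcmc()`) covers the five Bayesian models via
single-site Gibbs sweeps over `mu`, every marker effect, the effect
variances and `sigma_e2`, with incremental residual maintenance (the
residual vector is adjusted on every effect update, making a sweep O(nm)).
Genotypes are column-centered for stability; the centering constants are
stored and reused when predicting new individuals, shifting all GEBVs by
a constant that correlations and regression slopes ignore.

Priors follow the standard formulations, with scales solved from an
assumed marker-variance share `R2 = 0.5` of `var(y)` (defaults of the
reference software the field uses for these models):

- *BayesA*: per-marker `g_i ~ N(0, sigma_i^2)`,
  `sigma_i^2 ~` scaled-inv-chi-square(df 4.2, scale from R2).
- *BayesB*: spike at zero with probability `Pi` (default 0.95 —
  explicitly an arbitrary choice, exposed as `pi0`), BayesA slab
  otherwise; the indicator is sampled from the marginal likelihood ratio.
- *BayesC*: common slab variance; `Pi` updated from its
  Beta(#zero + 1, #nonzero + 1) full conditional, i.e. a uniform prior.
  `update_pi = FALSE` holds `Pi` fixed, which at `pi0 = 0` reproduces
  BayesA-style shrinkage (a tested degeneracy).
- *Bayesian LASSO*: `g_i ~ N(0, tau_i^2 sigma_e2)` with
  `tau_i^2 ~ Exp(lambda^2 / 2)`; `1/tau_i^2` has an inverse-Gaussian full
  conditional and `lambda^2` a Gamma(1.1, rate solved from R2) update.
- *BayesR*: four-component normal mixture with variances
  `(0, 0.0001, 0.001, 0.01) x sigma_g2`, Dirichlet(1,1,1,1) on the
  proportions. The scale `sigma_g2` is itself sampled (scaled-inverse-
  chi-square from the component-standardized sum of squares) — the
  standard resolution of the fact that the mixture definition leaves
  `sigma_g2` unspecified.

Chain defaults are 12,000 iterations with 2,000 burn-in; the desk-scale
experiment presets shrink this to 3,000/500, which the planted-QTL and
degeneracy tests show is ample at a few hundred markers. Seeds make full
traces bit-identical. Monte Carlo standard errors for `mu` and `sigma_e2`
come from non-overlapping batch means; multi-chain diagnostics are out of
scope. A collapsed residual variance with nonzero residuals is flagged as
divergent.

`gebv_from_effects()` computes `GEBV = X g_bar` — posterior-mean effects
only, the overall mean excluded.

## The synthetic-data generator

`simulate_population()` emulates the data-generating situation the
analysis assumes, not any particular real population:

- **Pedigree**: founders, then discrete generations of random pair
  matings without selfing; parents always precede offspring. Defaults:
  3 generations, 4 offspring per mating, founder count chosen so the
  final generation is the requested cohort size.
- **Genotypes**: founder haplotypes drawn per marker from
  `U(0.05, 0.5)` allele frequencies; descendants by gene dropping with
  Haldane recombination (Poisson crossovers, no interference) over 10
  chromosomes of 1 Morgan. A quarter of markers carry an INDEL class
  label that is statistically inert — panels are compared, mechanisms are
  not modeled.
- **Traits**: polygenic (all markers), sparse (n_qtl markers), or a
  four-component mixture mirroring the BayesR prior. The residual SD is
  calibrated to the *realized* genetic variance so the in-sample
  heritability equals the target exactly — this is what makes
  parameter-recovery tests sharp instead of confounded with architecture
  sampling noise. Fixed-effect level values are drawn `N(0, sd^2)` per
  configured effect.

What the generator does *not* emulate: genotyping error and missingness
(injected separately, only to exercise QC), selection, mutation,
breed structure of multi-way crosses (one admixed pedigree exercises
every estimator equally), and LD calibrated to any real population — no
public LD or MAF summaries exist for the emulated cohort, so passing
tests demonstrate estimator correctness under the stated conditions, not
transferability to a specific breed.

**Information-content calibration.** The heritability-recovery
experiments run at a 300-marker polygenic architecture (cohort 1000).
With the pedigree depth above, a few hundred markers give the realized
relationships enough contrast that `SE(h2) ~ 0.02` — matching the
precision a commercial cohort of ~1500 animals shows in practice; much
denser panels at the same shallow pedigree wash out the per-marker
relationship deviations and roughly double the SE. Panel and density
experiments use denser defaults (1500–3000 markers) where LD structure,
not REML precision, is the object of study.

## Cross-validation design

`make_folds()` partitions individuals randomly into folds differing by
at most one in size; each round re-randomizes. The default plan is
5 folds x 5 rounds = 25 validation fits. Accuracy is the raw Pearson
correlation between GEBV and `y_c` in the validation fold — deliberately
*not* divided by `sqrt(h2)`; bias is the OLS slope of `y_c` on GEBV.
Undefined cases (constant vectors) yield `NA` with a warning and are
excluded from aggregation.

For the single-step comparison, ungenotyped phenotyped relatives stay in
every training set (`ssgblup_predictor(y_extra = )`) and validation folds
are drawn from the genotyped individuals only. This is the design under
which the single-step claim is even testable: the two models are scored
on identical validation sets and differ only in whether the relatives'
phenotypes inform training. Validating on ungenotyped individuals would
instead measure pedigree-only prediction and reverse the comparison for
an uninteresting reason.

`run_experiment_grid()` executes the factorial design (models x panels x
fold counts), deriving per-cell seeds reproducibly from a master seed; a
failing cell is recorded with its message and the grid continues.
`run_pipeline()` adds the surrounding stages (simulation, QC, correction,
panel construction, per-panel REML, result tables, config snapshot) and
is byte-reproducible from its YAML snapshot. The exported functions and
YAML configuration are the package's interface; there is no shell
executable.

## Numerical choices and degenerate inputs

- QC order is individuals -> marker call rate -> MAF -> autosomes, with
  strict (`>`) thresholds; retained counts depend on this order, so it is
  fixed and documented. MAF uses observed genotypes only; QC never
  imputes. An emptied panel is an error, not an empty object.
- Thinning is a uniform draw without replacement, genome order kept,
  deterministic under its seed.
- G blending default `eps = 0.05`; the CV predictors stabilize an
  observed-frequency G with a `1e-6` diagonal ridge instead, which
  perturbs GEBVs far below measurement noise.
- The MME are solved by dense factorization; the reported relative
  residual norm is the solver contract (an iterative solver could replace
  it without touching any test).
- Ties in spike/mixture indicator draws are resolved by the sampled
  uniform itself; monomorphic (zero-variance) marker columns are skipped
  with zero effect.
- Degenerate inputs error early and explicitly: fewer than 2 founders,
  `target_h2` outside (0,1), zero realized genetic variance, constant
  phenotypes, missing dosages in G or MCMC, rank-deficient fixed-effect
  designs (naming the aliased columns), pedigree records out of order.

## Problem sizes

The shipped tests and the acceptance script run, per quantity, at the
sizes the package's own experiments use: cohorts of 400–2000 with
300–3000 markers, 8–20 replicates per directional claim, and MCMC chains
of 1,500–3,000 iterations. These sizes were chosen so each claim is
decided by its signal rather than by replicate noise while the whole
suite stays desk-scale; the full-size settings (12,000-iteration chains,
eight-density grids) remain available through the exported configuration
objects.

## Known limitations

- Single-trait models only; no repeated records, no GxE, no dominance or
  epistatic kinships, no metafounders or APY approximations.
- The simulator's LD is whatever three generations of gene dropping
  produce; it is not matched to any real genome map.
- Bayesian model comparison at desk scale cannot reproduce the small
  between-model differences a 1500-animal, 45K-marker study resolves;
  the package's claims about model ranking are directional and tested as
  such.
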