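---
title: "Models and methods: simulating and analysing bidirectional size selection in medaka"
author: "medakasel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The experiment this package models

`medakasel` implements, end to end, the statistical machinery of a
laboratory harvest-selection experiment on medaka (*Oryzias latipes*):
three lines (Control, Small, Large) are propagated for six selection
episodes (generations F1–F7) under two-stage truncation selection —
families are ranked by mean standard length at 60 days posthatch (dph),
then mature individuals are selected by length at 75 dph — with pedigrees
tracked throughout, pair matings that exclude full sibs and minimize the
median offspring inbreeding coefficient, and fourteen phenotypic,
life-history and endocrine traits measured each generation.

The package has two halves:

1. a **pedigree-explicit generative simulator** of the whole experiment
   (`run_experiment()`), so every downstream analysis can be exercised and
   validated on data whose ground truth is known; and
2. the **analysis suite**: eight hierarchical Bayesian trait models fitted
   by MCMC, probabilistic maturation reaction norms (PMRNs),
   natural-selection fitness regressions, RT-qPCR relative quantification,
   and a Bonferroni-controlled effect-size report.

# Pedigree, kinship, inbreeding, and effective size

Kinship is computed by the recursive tabular method on Wright's numerator
relationship matrix A over a topological order of the pedigree:
`A[i,j] = (A[sire_i,j] + A[dam_i,j])/2` for earlier `j` and
`A[i,i] = 1 + A[sire_i,dam_i]/2`; founders are unrelated and non-inbred.
An individual's inbreeding coefficient is `F = 2k − 1` with `k = A[i,i]/2`
its self-kinship — equivalently the kinship of its parents. This is exact
and O(n²), comfortably fast for the few thousand individuals of one
experiment.

Pair assignment (`propose_pairs()`) mirrors the experiment's resampling
procedure: among `n_resamples` random pairings that avoid full-sib matings
(half-sib exclusion is available but off by default, matching the
procedure's stated rule), it returns the pairing whose hypothetical
offspring have the smallest **median** inbreeding coefficient.
Feasibility is decided exactly by maximum bipartite matching, so an
instance where only sib matings exist fails with a diagnosis rather than
by exhaustion. The original resampling effort is not recorded anywhere;
the default is 100 resamples, and a sensitivity scan (5–100 resamples)
moves the realized F7 inbreeding by well under half a point, so the
choice is benign.

Effective population size uses the inbreeding effective number: with
per-generation rates `dF_t = (F_t − F_{t−1})/(1 − F_{t−1})`,
`Ne = 1/(2·mean(dF))`.

## Founder relatedness

A subtle but load-bearing modelling choice: the selection-line founders
(F1) are *assumed non-inbred* but are **not unrelated**. They descend from
a single wild-caught stock (modelled as 100 unrelated wild founders)
through two pond generations of mass spawning (random parentage within a
cohort of 300), a transfer of ~60 adults to the laboratory, and two
random-mating laboratory generations of 54 and 56 pairs. The simulator
reproduces that history and initializes the F1 relationship matrix from
it, resetting only the diagonal (founder F = 0). Without this pre-phase,
inbreeding cannot accumulate during the first two selection generations
and the simulated trajectory undershoots the design's published
~9.6% mean inbreeding at F7 (Ne ≈ 30) by several points; with it, the
simulator lands at ~8.7–9.0% with Ne ≈ 32 across seeds. The pond-phase
depth (2 generations) follows the stock's two-year pond residence; the
pond cohort size is inconsequential because founder kinship is driven by
the numbers of breeding parents, not cohort census.

# The generative trait architecture

All generative parameters live in `trait_architecture()`. Defaults are
calibrated once to the experiment's published Control-line anchor points
and then frozen; they are not tuned per analysis.

* **Growth** is von Bertalanffy: mean length
  `L(a) = hatch + L∞(1 − e^{−ka})` with `hatch = 4.5 mm`,
  `L∞ = 20.6 mm`, `k = 0.02/day`, giving ~20.5 mm at 75 dph (Control).
  No growth law is prescribed by the study itself; any monotone
  saturating curve matching the printed lengths would do, and the PMRN
  machinery accepts user-supplied trajectories to bypass this choice.
  Additive-genetic and permanent-environment deviations scale with the
  curve's growth fraction so that heritability applies at the 75 dph
  scale (`h² = 0.3`, phenotypic sd 1.5 mm — typical values for fish body
  length). Breeding values are transmitted as the mid-parent value plus
  Mendelian segregation noise of variance `σ²_A/2` (inbreeding-induced
  reduction of segregation variance is ignored; at F ≤ 0.1 this
  understates drift in genetic variance by a few percent at most).
* **Maturation** is a daily hazard whose logit is linear in age and
  length — exactly the structure the maturity ogive model assumes, so
  ogive fitting is well-specified. The intercept (−14.7, with slopes
  0.42/mm and 0.063/day) was calibrated numerically so that ~86% of fish
  are mature at 75 dph under the default growth parameters, the
  experiment's published maturity level. Sexes are assigned 50:50 at
  maturation; immature fish keep the code `I`.
* **Phenotyping ages** vary by family (~75 ± 4 dph, clipped to 65–87),
  as in the real measurement campaign; whole sibling families share one
  age.
* **Reproduction** is a two-part (zero-inflated) process: a pair is
  infertile with probability 0.1, otherwise daily egg counts are Poisson
  around a family rate with log-normal overdispersion (sd 0.3), a
  reference rate of 12 eggs/day at 20 mm, and a log-linear mother-length
  effect (+0.05/mm) so that natural selection on parental size has
  something to act on. Egg perimeter is Gaussian (3.5 mm ± 0.15) with a
  +0.02 mm/mm mother-length slope; incubation is Gaussian (8 ± 1 days);
  hatching is Binomial with stage survival given below.
* **Survival** acts per family and stage (egg→0, 0→15, 15→60,
  60→75 dph) on the logit scale with family-level overdispersion
  (sd 0.3); stage logits (1.4, 2.2, 2.6, 3.0) give survivals of roughly
  0.80, 0.90, 0.93, 0.95.
* **Hormones** (pituitary LHβ, FSHβ, GH as ln gene/actin ratios) are
  trivariate normal per line with residual sd 0.8 and residual
  correlation 0.6 (the experiment found the three axes strongly
  positively correlated). The default line means encode the published
  corrected effect sizes as generative truth — notably the Small-line GH
  shift of +0.44 — so recovery tests have a documented target.
* **Density control**: family aquaria are stocked at ~19.6 ± 1.6 larvae
  and thinned to 17 at 15 dph by random removal of the overflow; the
  thinning rule is not recorded in the source procedure, and random
  removal avoids inadvertent size selection.

What the generator deliberately does **not** emulate: maternal effects
beyond the parental-length terms, genotype–environment interaction,
selection-induced linkage disequilibrium (Bulmer effect), measurement
error distinct from permanent environment, and tank effects separate from
family effects (the two are confounded in the real design too). Passing
tests on these data therefore validate the statistical machinery, not the
biology of any particular real population.

# The eight trait models

Every model is expressed as a declarative `model_spec` (JAGS code plus
data and monitors) built from a design matrix with treatment contrasts —
reference levels Control line and female sex — so line coefficients are
contrasts against Control. Continuous covariates are centered (centers
stored in the spec). Generations are pooled with a Gaussian random
intercept; the analysis scripts pool F3–F7 as the original analysis did.

1. **Length at 75 dph** — normal; line + sex + age (continuous dph) +
   individual inbreeding.
2. **Maturity ogive** — Bernoulli-logit; line intercepts plus
   line-specific length and age slopes and a common inbreeding slope.
3. **Stage survival** — Binomial per family and transition; line +
   mother/father inbreeding + observation-level overdispersion (no
   generation effect, four separate transition fits).
4. **Fecundity** — zero-inflated Poisson per pair: logit zero part and
   log count part, both with line, parental inbreeding, and linear +
   quadratic mean-parental-length terms; log collection days as offset;
   generation intercepts in both parts; overdispersion in the count
   part.
5. **Egg perimeter**, 6. **incubation time**, 7. **hatch length** —
   normal with the model-specific covariate sets (mother length and
   parental inbreeding for 5–6; mean parental length and own inbreeding
   for 7).
8. **Hormones** — trivariate normal with per-gene fixed effects and a
   line-specific covariance matrix under an inverse-Wishart prior (scale
   matrix `diag(3)·3`, 3 degrees of freedom).

**Zero-inflation construction.** The published notation
`F ~ Pois((1−π)λ)` is read as the standard latent-indicator mixture (a
structural zero with probability π, else Poisson(λ)) — the construction
every JAGS implementation of "zero-inflated Poisson" uses — rather than a
Poisson whose mean is literally deflated. Both constructions are
implemented (`build_zip_fecundity_model(construction=)`); the mixture is
the default. The overdispersion term is hierarchically centered (the
latent log rate is drawn around the linear predictor) because the
non-centered form mixes an order of magnitude worse under Gibbs sampling.

**Priors.** The original analysis states only "weakly informative
priors". Defaults here: Normal(0, sd 100) for fixed effects and
half-Cauchy(scale 5) for standard deviations, declared in one place
(`.prior_fixed`, `.prior_sd`) and visible in every generated model
string.

# MCMC estimation and diagnostics

`fit_model()` runs three independent JAGS chains thinned at a period of
5, each chain's RNG seeded deterministically from the user seed, and
computes the Gelman–Rubin potential scale reduction factor for every
monitored scalar. The convergence threshold is R̂ ≤ 1.1 (the original
analysis assessed convergence without printing a cutoff); exceeding it
raises a typed error (`mcmc_convergence_error`) naming the offending
parameters, downgradable to a warning for bulk runs.

Two bespoke p-values:

* **MCMC p-value** — twice the posterior mass on the side opposite the
  posterior mean's sign, capped at 1; zeros never count as opposite, and
  an all-zero sample is defined as p = 1 (flagged). It is invariant to
  positive rescaling of the draws.
* **Bayesian (posterior predictive) p-value** — for each retained draw a
  replicate dataset is simulated from the fitted likelihood and compared
  with the observed data through a discrepancy; the p-value is the
  proportion of replicates whose discrepancy is at least the observed
  one. The discrepancy is the sum of squared Pearson residuals (the
  original choice is unrecorded); it sits behind the `ppp` closure
  interface of `model_spec`, so alternatives are pluggable. For models
  with observation-level overdispersion the Pearson standardization uses
  the linear predictor without the overdispersion draw for both observed
  and replicated data — a symmetric choice that preserves calibration.

# PMRN estimation

The maturity ogive `o(a, s)` from Model 2 is converted into per-increment
maturation probabilities `m(a_τ, s_τ) = (o_τ − o_{τ−1})/(1 − o_{τ−1})`
along simulated slow/median/fast growth trajectories (the 0.1/0.5/0.9
per-age length quantiles, smoothed by von Bertalanffy fits), and the PMRN
midpoint is the first crossing of `1 − ∏(1 − m) = 0.5` over 200 equal
increments between 0 and 87 dph, with linear interpolation between the
bracketing increments (only the increment resolution is prescribed by the
method; interpolation removes most of the residual grid dependence, and
crossings computed at 200 vs 2,000 increments agree within one coarse
increment). Non-monotone ogive values along a trajectory (possible when
an age slope is negative) are clipped into [0, 1] with the clipped
fraction reported; ogive values are capped at 1 − 2·10⁻³ before the
increment formula, just below the guard that rejects a division by
(numerically) zero. Uncertainty is propagated by recomputing the
crossing for every retained MCMC draw of the ogive parameters; the curve
reports the posterior median and 2.5/97.5% quantiles, the proportion of
draws with no crossing, and an unreliability flag when that proportion
exceeds one half. Ogives are evaluated at the generation-typical level
(random intercept 0) and mean inbreeding.

# Natural selection and the effect-size report

Fitness components (fecundity, hatch rate, progeny reaching 75 dph,
progeny kept as breeders) are regressed on centered mean parental length
with linear and quadratic terms: zero-inflated Poisson for counts (with
overdispersion for fecundity only) and Binomial for hatch rate.
`fitness_prediction_grid()` emits the Figure-style predicted-fitness
curves with credible bands as CSV.

The effect-size table reports, for 14 traits × 2 selected lines, the raw
line contrast (mean difference against Control on each trait's reporting
scale: plain differences for lengths, egg size, incubation and ln hormone
ratios; logit differences of pooled proportions for maturity, survival
and fertility; log differences of mean daily fecundity) next to the
covariate-corrected effect: the posterior mean of the model's line
coefficient, i.e. the contrast at reference levels and centered
covariates. Because no model carries a line-by-sex interaction, the
corrected effect is common to the sexes ("averaged across sexes" is the
identity here). The fertility row flips the sign of the zero-part
coefficient so that positive means more fertile. Significance uses the
Bonferroni cutoff α = 0.05/28 ≈ 0.0018 (printed as 0.002 at table
precision).

# RT-qPCR quantification

Gene-specific standard curves are least-squares lines of Cq on log10
calibrator volume over a 7-point dilution series; the amplification
efficiency is `E = 10^(−1/slope) − 1`. Sample expressions are the
inverted curve values; duplicate technical measurements are averaged on
the Cq scale (the averaging scale is unrecorded in the source protocol;
Cq-scale averaging corresponds to geometric-mean expression, the common
convention); inter-run noise is removed by an additive Cq shift
equalizing each run's calibrator with the reference run, and a blank
amplifying below Cq 35 triggers a contamination warning. The reported
quantity is `ln([gene]/[actin-β])` per fish. `hormones_to_cq()` is the
generative inverse, and the noise-free round trip (simulated ratios → Cq
→ ratios) is exact to 10⁻⁹.

# Problem sizes and numerical choices in the test-suite

The validation suite runs every stage at desk scale, chosen so the whole
suite completes in well under half an hour on one core:

* breeding-design inbreeding: 20 full 7-generation experiments;
* model recovery: 20 seeded replicates per model at reduced n (400–600
  observations for the Gaussian and ogive models, 150–300
  families/pairs/fish for survival, fecundity and hormones), three
  chains of 1,000 post-adaptation iterations thinned at 5; coverage of
  the 95% credible intervals is assessed pooled over parameters and
  seeds against a 90% floor;
* null-effect reports: 10 full experiments with no true line differences
  (zero heritability, identical hormone means, random selection in all
  lines), each pushed through all eight models and the 28-test report;
* PMRN: closed-form, fine-grid (20,000 increments) and
  resolution-invariance oracles.

A parameterization note: the zero-inflated Poisson count part uses
hierarchically centered overdispersion (the latent log rate drawn around
its linear predictor), which mixes far better under Gibbs sampling than
the additive form. The Binomial survival models instead keep the additive
(non-centered) form: there the fixed effects — the quantities the report
tests — gain several-fold effective sample size, at the price of slow
mixing of the nuisance overdispersion sd, whose Gelman–Rubin statistic
can exceed the threshold in full-length fits (the analysis drivers
therefore downgrade convergence failures to warnings and report the
figures per model).

# Known limitations

* The simulator's growth and maturation laws are structural choices
  consistent with, but not derivable from, the published phenotypes;
  PMRN and ogive inferences on *real* data should treat the trajectory
  model as an input, not a fact.
* Kinship is pedigree-based; marker-based (genomic) relatedness and
  pedigree-error correction are out of scope.
* The Wishart degrees of freedom (ρ = 3, the minimum proper value) make
  the hormone covariance prior weakly informative at n below a few
  dozen fish per line.
* MCMC p-values near the Bonferroni cutoff require enough retained draws
  (p can only fall below 1/draws in steps of 2/draws); the defaults
  retain 1,500 draws, ample for α = 0.002 decisions at the reported
  effect sizes, but bulk scaled-down runs retain 600 and should not be
  used to adjudicate borderline significance.
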