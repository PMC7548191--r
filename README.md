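# medakasel

Simulation and Bayesian analysis of bidirectional size-selection
experiments in medaka (*Oryzias latipes*).

Laboratory harvest-selection experiments impose truncation selection on
body size — against large fish (a "Small" line, mimicking fishing),
against small fish ("Large" line), or at random ("Control") — across
several generations, while tracking pedigrees, maturation, survival,
fecundity, egg traits and pituitary hormone expression. This package is
for quantitative geneticists and fisheries-evolution researchers who want
that whole pipeline as reusable, tested code: a pedigree-explicit
generative simulator of the experiment, and the full Bayesian analysis
suite that such experiments report.

## What it computes

**Pedigree machinery** — Wright's numerator relationship matrix by the
recursive tabular method; individual inbreeding `F = 2k − 1` (k =
self-kinship); breeding-pair proposals that exclude full-sib matings and
minimize the median offspring inbreeding over a resampling search;
inbreeding effective size `Ne = 1/(2·mean ΔF)` with
`ΔF_t = (F_t − F_{t−1})/(1 − F_{t−1})`.

**Experiment simulator** — `run_experiment()` iterates, per line and
generation: pair reproduction (zero-inflated daily fecundity, egg
perimeters, incubation, hatching), family aquaria with density thinning,
stage-wise survival, von Bertalanffy growth with additive genetics
(`h² = 0.3` by default), hazard-based maturation (~86% mature at 75 dph),
two-stage truncation selection (families at 60 dph, mature individuals at
75 dph), and pedigree-aware pairing. Output: fish/clutch/egg/survival/
hormone tables, the realized pedigree, selection differentials, and the
inbreeding trajectory — byte-identical under a fixed seed.

**Trait models 1–8** — hierarchical Bayesian models fitted by MCMC
(JAGS, three chains, thin 5, Gelman–Rubin diagnostics): normal models for
length at 75 dph, egg perimeter, incubation time and hatch length;
a Bernoulli-logit maturity ogive with line-specific length and age
slopes; Binomial stage-survival models with overdispersion; a
zero-inflated Poisson fecundity model with a log collection-days offset
and quadratic parental-length terms; and a trivariate-normal hormone
model (ln LHβ/actin, FSHβ/actin, GH/actin) with line-specific covariance
under an inverse-Wishart prior. Effects are tested with the MCMC p-value
(twice the posterior mass opposite the mean's sign) and model fit with a
posterior predictive (Bayesian) p-value.

**PMRN** — probabilistic maturation reaction norms: per-increment
maturation probability `m(a,s) = (o_t − o_{t−1})/(1 − o_{t−1})` from the
fitted ogive along slow/median/fast growth trajectories, the 50% crossing
of `1 − ∏(1 − m)` over 200 increments between 0 and 87 dph, with full
posterior envelopes.

**Natural selection & report** — quadratic (Lande–Arnold style) fitness
regressions on mean parental length, and the 14-trait × 2-line
effect-size table (raw line contrasts next to covariate-corrected model
effects) under a Bonferroni cutoff of `0.05/28 ≈ 0.002`.

**RT-qPCR** — calibrator standard curves (`E = 10^(−1/slope) − 1`),
Cq-to-expression inversion, inter-run calibrator adjustment, and
ln gene/actin ratios, with an exact generative round trip.

## Worked example

```r
library(medakasel)

ex <- run_experiment(simulation_config(seed = 1))
ex
#> Synthetic size-selection experiment
#>   lines: Control, Small, Large
#>   generations: 7
#>   fish: 4635  clutches: 353
#>   mean inbreeding at final generation: 0.092
```

The realized per-generation selection differentials and final mature
lengths for this seed:

```r
aggregate(delta_length ~ line, ex$differentials, mean)
#>      line delta_length
#> 1 Control    0.0720076
#> 2   Large    1.7771535
#> 3   Small   -1.1944547

fish <- ex$tables$fish
aggregate(length_75 ~ line, fish[fish$generation == 7 & fish$mature_75 == 1, ], mean)
#>      line length_75
#> 1 Control  20.98013
#> 2   Large  22.53955
#> 3   Small  18.94768
```

Selection is strongly directional (+1.78 mm/generation in the Large
line, −1.19 in the Small line) and the lines diverge accordingly. Note
that with a purely additive genetic architecture the simulated Small
line responds symmetrically; the real experiment's hallmark *asymmetry*
(no Small-line response) is a biological finding about evolvability, not
something an additive simulator reproduces.

Fitting the length-at-75-dph model (generations F3–F7 pooled, generation
as a random effect; coefficients are contrasts against the Control line
and female sex, age and inbreeding centered):

```r
fit <- fit_model(build_gaussian_model(1, ex$tables, generations = 3:7), seed = 1)
posterior_summary(fit)[6:12, c("parameter", "mean", "sd", "q2.5", "q97.5", "mcmc_p")]
#>    parameter     mean      sd    q2.5   q97.5 mcmc_p
#> 6    beta[1] 20.78051 0.06659 20.6484 20.9123 0.0000   # intercept
#> 7    beta[2] -1.09389 0.06024 -1.2115 -0.9755 0.0000   # lineSmall
#> 8    beta[3]  1.00191 0.05806  0.8873  1.1121 0.0000   # lineLarge
#> 9    beta[4] -0.00191 0.05492 -0.1069  0.1058 0.9493   # sexM
#> 10   beta[5] -1.44764 0.07499 -1.5968 -1.3011 0.0000   # sexI
#> 11   beta[6]  0.07621 0.00578  0.0644  0.0872 0.0000   # age (per dph)
#> 12   beta[7]  2.07665 0.92498  0.1493  3.7316 0.0333   # inbreeding

posterior_predictive_p(fit, seed = 1)
#> [1] 0.5
```

The corrected Large-line effect is +1.00 mm (MCMC p-value 0.000) for this
simulated experiment, and a Bayesian p-value of 0.5 indicates the model
reproduces its own data's dispersion exactly — as it should on
well-specified input.

The numbered drivers under `analysis/` chain the full workflow on a
simulated experiment — `01_simulate.R` (tables + pedigree),
`02_selection_differentials.R`, `03_fit_models.R` (all eight models with
diagnostics and the qPCR round trip), `04_pmrn.R`, `05_report.R` (effect
sizes and fitness regressions) — writing their outputs under `results/`.

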