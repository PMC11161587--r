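---
title: "Models and methods behind kdtlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind kdtlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`kdtlab` implements the analytics of a serious-game decision-making
assessment: a virtual environment (the Kalliste Decision Task, KDT) in
which participants maximize virtual money by collecting coins, opening risk
and ambiguous boxes, banking, and buying watches and shields, while the
game logs 18 behavioral count variables across two theoretical dimensions
(performance and risk behavior). The package provides everything needed to
exercise that analysis pipeline end to end on synthetic cohorts: choice
models for the classical instruments, screening statistics, behavioral
phenotyping, and group comparisons. This vignette documents the models, the
tunable parameters, and the design decisions.

## The prospect-theory choice model

The mixed gamble task presents 64 fifty-fifty gambles crossing gains
100-380 (step 40) with losses 50-190 (step 20). Utilities follow the
standard power/loss-aversion form

$$u(x) = x^\rho \ (x \ge 0), \qquad u(x) = -\lambda\,(-x)^\rho \ (x < 0),$$

and a gamble is accepted with softmax probability
$P = 1/(1 + e^{-\mu\,\Delta U})$, where
$\Delta U = 0.5\,u(\text{gain}) + 0.5\,u(-\text{loss})$ against a
status-quo utility of zero. The task endowment is treated as framing and
does not enter the utilities, consistent with the model family this task
comes from. Parameters and bounds: risk attitude $\rho \in (0, 2]$
($1$ = risk neutral), loss aversion $\lambda \in (0, 5]$ ($1$ = gains and
losses weighted equally), consistency $\mu \in (0, 10]$ (softmax inverse
temperature on the raw utility-difference scale; published "consistency"
values are reported on an unstated scale, and we adopt this reading).

### Identifiability: the rho-mu ridge

A structural feature dominates everything about estimating this model from
64 binary choices: lowering $\rho$ shrinks every utility by roughly
$S^{\Delta\rho}$, where $S \approx 200$ is the typical stake, and the
softmax temperature $\mu$ can absorb that rescaling almost exactly (with a
smaller compensation by $\lambda$ through the gain/loss stake ratio). The
log-likelihood is therefore nearly flat along a long curved ridge in
$(\rho, \lambda, \mu)$; at one subject and 64 trials the ridge is flat to
well under one log-likelihood unit over $\rho$ ranges of $\pm 0.15$. Three
consequences shape the implementation:

* **Maximum likelihood** (`fit_pt_mle`) uses a deterministic grid of starts
  spanning the ridge, Nelder-Mead search, and a bounded quasi-Newton
  polish; single-start gradient optimization stalls on the plateau or runs
  into a bound. $\rho$ and $\lambda$ recover well from long datasets, but
  $\mu$ is only determined up to its position on the ridge.
* **Hierarchical estimation** (`fit_pt_hierarchical`) samples on the
  coordinates $(\rho, \log\lambda, \log\kappa)$ with
  $\kappa = \mu S^{\rho}$, the softmax scale at the typical stake. In these
  coordinates the data-identified quantities are the coordinates
  themselves, the compensation laws are linear, and the weak direction is
  straight rather than banana-shaped.
* **Recovery precision is information-limited.** Even with 39 subjects
  completing the full matrix (2,496 choices), the cohort-level posterior
  along the ridge retains a standard deviation near 0.1 in $\rho$; recovery
  of a generative group mean is unbiased but carries sampling noise of that
  order from the data themselves. Tests and the acceptance analysis are
  interpreted with this in mind.

### The hierarchical model and sampler

Subject coordinates $z_i$ follow normal group distributions
$z_{ip} \sim N(m_p, s_p^2)$. Priors: $m_\rho \sim N(1, 2^2)$ (risk-neutral
center), $m_{\log\lambda} \sim N(0, 4^2)$ and
$m_{\log\kappa} \sim N(\log S, 4^2)$ — deliberately wide, because the
posterior position along the weak direction is sensitive to the location
priors and their centers are arbitrary reference points — and half-normal
scales $s_\rho \sim HN(0.2)$, $s_{\log\lambda} \sim HN(0.3)$,
$s_{\log\kappa} \sim HN(0.5)$. The tight scale priors matter most: they
enforce the partial pooling that lets the cohort-aggregate likelihood,
rather than per-subject noise, locate the weakly identified direction.

The sampler is Metropolis-within-Gibbs assembled from moves chosen for this
posterior's geometry:

* per-subject adaptive random-walk updates per coordinate (tuned to 44%
  acceptance during burn-in, frozen afterwards);
* exact conjugate Gibbs draws for the group locations $m_p$;
* random-walk Metropolis on $\log s_p$, plus a non-centered companion move
  that rescales all subject deviations together with $s_p$ (this sidesteps
  the funnel coupling between the scale and the spread of subject values);
* population translation moves that shift all subjects and the group
  location together, per coordinate and along a joint proposal whose
  covariance is learned from the group-mean history during burn-in
  (adaptive Metropolis, frozen after burn-in) - under tight pooling the
  collective shift is the slow mode, since individual moves away from the
  group mean are vetoed by the prior;
* a stepping-out slice move along the leading eigenvector of that learned
  covariance, which crosses the flat stretch of the weak direction in one
  update instead of diffusing along it.

Initialization uses per-subject maximum-likelihood estimates (clamped to
the interior) plus chain-specific overdispersed offsets; starting all
subjects from a common point lets the scale update collapse and pin the
cohort to the group mean (the funnel trap).

Two scale presets ship with the package (`pt_sampler_scales()`): `desk`
(3 chains x 2,000 retained draws, 5,000 burn-in, thinning 6; several
minutes on one CPU for 39 subjects) and `paper` (3 chains x 40,000 retained
after 23,333 burn-in each - 120,000 retained draws in total), matching the
published analysis configuration. The desk preset deviates from an earlier
plan of 1,000 burn-in with no thinning because the weak posterior direction
mixes slowly; the longer adaptation and thinning buy effective sample size
per retained draw and bring the split-chain Gelman-Rubin statistic to 1.0
at one decimal. Convergence is monitored with a split-chain
potential-scale-reduction factor (`gelman_rubin`), rank-normalization off.

Group-level natural-scale summaries are posterior means of the
across-subject average of subject-level parameters, which targets the
cohort mean directly and is robust to the nonlinearity of the transforms.

## Synthetic cohorts

`generate_profiles()` draws the 18 behavioral counts per participant
independently per variable from normals at published cluster means/SDs
(three profiles of sizes 39/21/21: risk-avoidant, useless risk, useful
risk), rounded half-to-even and floored at zero. Published tables report
marginal moments only, so no inter-variable correlation is imposed; an
important consequence is that synthetic cohorts are somewhat *easier* to
cluster than real data with correlated noise would be, and passing recovery
tests demonstrates pipeline correctness, not field performance. The same
limitation applies to the questionnaire totals (uniform-ish draws within
the legal ranges, optionally shifted per cluster) and to the Iowa-gambling
agent: a delta-rule expectancy learner with softmax choice
(`exploration` is a temperature in currency units; 0 = greedy) over the
classic four-deck schedule (A/B large gains, net -250 per 10 cards; C/D
small gains, net +250; the published task prints no schedule, so the
classic structure is the default). The agent exists to generate plausible
choice sequences; only the IG index (advantageous minus disadvantageous
picks) is analyzed downstream.

## The abstract game environment

`build_environment()` / `run_episode()` provide a second, mechanistic route
to behavioral profiles: a token-level discrete abstraction of the game.
Time is discretized (one event per step; the 20-minute session becomes a
600-step budget, the 10-second shield a 5-step window; watches add 20
steps). Zones alternate in segments; dangerous zones are
negative-expectation by construction (boxes preconfigured to lose, guarded
coins, larger danger losses) while safe zones are positive-expectation, so
the adaptive strategy is to take risks only in safe regions. Agents are
parametric policies (approach, acceptance, deposit, purchase propensities)
with a delta-rule zone-value learner gating engagement through a logistic
of the learned zone value; a zone-blind agent (learning rate 0) keeps a
0.5 gate everywhere. Banks retain exactly 50% of carried money; the exact
ledger `gains - losses - purchases - commissions = banked + carried` holds
by construction and is enforced in tests. The real game's token counts,
probabilities and payoffs are unpublished; this simulator is an
abstraction for exercising the pipeline, not a clone.

## Screening statistics

* Outliers: the 3-standard-deviation rule around the sample mean.
* Normality: Kolmogorov-Smirnov with Lilliefors correction (mean and SD
  estimated), p-value by Monte Carlo under the null (default 5,000
  simulated normal samples; the null distribution depends only on n, so a
  precomputed table can be reused). Monte Carlo removes the interpolation
  ambiguity of printed tables; the seed is an explicit argument.
* Q-Q diagnostics: correlation between sample and theoretical normal
  quantiles.
* Association: partial Pearson correlation by residualization on covariates
  (with intercept) and `df = n - 2 - #covariates`; the source analyses say
  only "controlled for", so residualization-then-correlation is our
  declared mechanism. Gender enters as a binary indicator and videogame
  ability as an ordinal integer treated as numeric. No multiple-comparison
  correction is applied in the correlation table, mirroring the source
  analysis' exploratory stance.

## Phenotyping and group comparisons

The 18 variables are z-scored before clustering (their ranges differ by two
orders of magnitude, so unscaled squared-Euclidean distances would be
dominated by the big counts; the source does not state its scaling).
Ward-linkage agglomeration runs on squared Euclidean distances via the
Lance-Williams recurrence (heights reported as the within-cluster SSE
increase, verified against an exhaustive-search oracle); k is chosen by
mean silhouette (Euclidean, standardized space) over k = 2-6 from the
dendrogram cuts, with seeded K-means (25 restarts) as confirmation.
Clusters are named by rules on their mean profiles: lowest box engagement
is "risk-avoidant"; among the rest, highest total losses is "useless risk"
and the remainder "useful risk"; ties break on the total-gains mean with a
warning.

Between-cluster inference uses Pillai's trace (robust default; the source
names only "MANOVA") from a model-comparison MANOVA with covariates entered
before the group factor, so the group effect is tested on
covariate-adjusted cross-products - whether the original analysis entered
covariates multivariately is unstated, and this is our declared choice.
Per-outcome follow-ups report F, p and partial eta squared
$SS_{effect}/(SS_{effect}+SS_{error})$; pairwise post hocs are
pooled-variance t tests with Bonferroni multiplication (capped at 1) and a
compact letter display assigned greedily from the lowest-mean group.

## Problem sizes and calibration checks

The shipped tests run the full pipeline at the published cohort size
(n = 81), the hierarchical recovery at 39 subjects x 64 trials with the
desk-scale sampler, and the type-I-error calibrations (Lilliefors and
MANCOVA at alpha = 0.05) over 2,000 null replicates at n = 81 each - sizes
chosen so the whole suite exercises every claim at realistic scale while
staying comfortable on a single CPU. Known limitations: synthetic profiles
lack inter-variable correlation; the mu parameter of the choice model is
reported on a scale that the data constrain only through the ridge; and the
environment simulator's payoff magnitudes are package defaults, not
published game constants.
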