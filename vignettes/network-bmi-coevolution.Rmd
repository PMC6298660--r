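---
title: "Modeling the co-evolution of friendship networks and BMI categories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling the co-evolution of friendship networks and BMI categories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netcoev)
```

## The scientific problem

When college students who live together gain weight over an academic year,
two social mechanisms can produce correlated BMI among friends: *selection*
(students befriend peers with particular BMI levels) and *influence*
(students' BMI drifts toward that of their friends).  Cross-sectional
correlation cannot separate the two.  `netcoev` implements a stochastic
actor-oriented model (SAOM) that separates them by jointly modeling the
dynamics of a directed friendship network and an ordinal BMI category
observed over several panel waves.

## The model

**State.**  At any moment the state is a binary directed network $x$ (tie
$x_{ij}=1$ when actor $i$ names $j$ a friend; no self-ties) and an integer
BMI category $z_i \in \{1,\dots,11\}$ per actor.  Measured BMI (kg/m²) maps
onto the categories with cut points $19, 20, \dots, 26, 28, 31$: category 1
below 19, integer-truncated BMI for 19–25.99, then 26–27.99, 28–30.99 and
$\ge 31$.  Categories are mean-centered with a single constant pooled over
all non-missing actor–wave observations; with the study's distribution the
centered values span $-5.25$ to $4.75$, and the behavior *range* (max minus
min observed code, 10 here) scales the similarity statistic below.

**Dynamics.**  Observed waves are snapshots of a continuous-time Markov
process that moves through *ministeps*.  Over an observation period
(rescaled to unit length), actors receive change opportunities from
independent exponential clocks: network opportunities at rate
$\lambda^{net}_m$ and behavior opportunities at rate $\lambda^{beh}_m$ per
actor in period $m$.  At a network opportunity, actor $i$ chooses among
keeping the network or toggling one outgoing tie, with multinomial-logit
probabilities $\propto \exp f^{net}_i(x')$; at a behavior opportunity $i$
chooses among $z_i - 1$, $z_i$, $z_i + 1$ (restricted to the category
range) with probabilities $\propto \exp f^{beh}_i(z')$.

**Evaluation functions.**  Each function is a linear combination
$f_i = \sum_k \beta_k s_{ik}$ of effect statistics.  The network function
uses: out-degree, reciprocity, transitive triplets (ordered pairs $(j,h)$
with $i\to j$, $i\to h$, $h\to j$), transitive reciprocated triplets,
out-degree activity (out-degree squared), in-degree activity (out-degree
times in-degree), and covariate effects — alter, alter squared, ego, ego
squared, ego × alter and "same" (indicator match) — where the covariate may
be a fixed attribute or the dynamic centered BMI itself.  The behavior
function uses linear and quadratic shape terms and *average similarity*
$\frac{1}{x_{i+}}\sum_j x_{ij}\,(\mathrm{sim}_{ij} - c)$ with
$\mathrm{sim}_{ij} = 1 - |z_i - z_j|/\mathrm{range}$, the peer-influence
term.  An actor with no outgoing ties contributes 0 to average similarity.

## Estimation

Parameters (one rate per function per period plus one coefficient per
effect) are estimated by the method of moments: the expected simulated
statistics must equal the observed targets.  Targets are the per-period
amount of change for rates (network Hamming distance over dyads whose ego
is observed at both ends; summed $|\Delta z|$ over actors observed at both
ends) and, for each coefficient, the effect-statistic sum over each
period's observed end wave.  The moment equations are solved by
Robbins–Monro stochastic approximation in three phases:

1. *Derivative.*  The Jacobian $D = \partial E[\text{stats}]/\partial\theta$
   is estimated with the likelihood-ratio (score-function) identity
   $D_{kl} = \mathrm{cov}(\text{stat}_k, \text{score}_l)$, where the score
   accumulates $\Delta s_k(\text{chosen}) - E_p[\Delta s_k]$ over ministeps
   for coefficients and $-n_{act} + M/\lambda$ for rates.  A
   finite-difference estimator with common random numbers is available for
   cross-checking (`deriv = "fd"`).
2. *Search.*  $\theta \leftarrow \theta - a\,D^{-1}(\text{sim} -
   \text{target})$ with one simulation per iteration, over `n_sub`
   subphases whose iteration counts grow geometrically from `n2start` and
   whose gain $a$ halves each subphase; each subphase restarts from the
   average of the previous subphase's iterates (Polyak averaging).  By
   default the whole phase-1/phase-2 cycle runs twice (`restarts = 2`),
   the second pass starting from the first answer — in our experiments a
   single pass regularly leaves convergence ratios just above threshold on
   models with 15+ parameters, and a second pass resolves this.  For
   stability the update matrix blends $D$ with its diagonal
   (`diagonalize = 0.2`), steps are capped at `max_step`, rates are floored
   at 0.01, and a non-positive diagonal entry of $D$ (possible under Monte
   Carlo noise for a weakly identified parameter) is replaced by a positive
   proxy with a warning rather than aborting.
3. *Diagnostics.*  `n3` simulations at the solution give the per-statistic
   convergence t-ratios (mean deviation over its SD; $|t| < 0.1$ is the
   conventional pass), the overall convergence ratio (the Mahalanobis norm
   $\sqrt{\bar d^\top \Sigma^{-1} \bar d}$, threshold 0.25), and the
   parameter covariance $D^{-1}\Sigma D^{-\top}$ with standard errors from
   its diagonal.  Wald $z = \hat\theta/\mathrm{se}$ with two-sided normal
   p-values.

Estimation is unconditional (it does not condition on the observed total
amount of change); the rate parameters absorb the observed change through
their own moment equations.  Missing data are handled the way the
reference tradition does: behavior codes are imputed
last-observation-carried-forward (then backward for a missing first wave)
and a non-participant's outgoing tie row is imputed by its last observed
row (zero before the first observation, which coincides with the recorded
data).  All actors remain active in simulation — the latent process does
not pause for non-response — but imputation cannot masquerade as observed
change: the ego sums of every target are restricted to actors observed at
both ends of the period, and the simulated values at unobserved
actor-waves are reset to the imputed values before statistics are
computed, so unobserved entries cancel identically from the two sides of
each moment equation.

One bias channel remains open by construction: egos *react* to imputed
alter rows (through reciprocity, transitivity and similarity), so when a
substantial share of rows is hidden the imputation error feeds back into
the dynamics and shifts the moment balance — the participation-rate bias
the field cautions about, and the reason the original study retained only
its highest-compliance residence hall.  The estimator-correctness tests in
this package therefore run on full-participation panels; fits to panels
with study-level missingness carry this additional design-induced
uncertainty on top of the reported standard errors.

The dyadic similarity centering constant $c$ defaults to the mean observed
dyadic similarity over all ordered pairs at all waves (`sim_center =
"data"`), which only shifts the similarity statistic's baseline; 0 is used
in toy examples and in the generator, where the true coefficients are
specified directly.

## Interpretation layer

Coefficients exponentiate into odds ratios.  For tie-selection effects,
`or_from_coefficient` reports $e^\beta$ (displayed to 1 decimal).  The
*alter-selection curve* $g(v) = \beta_{alt} v + \beta_{alt^2} v^2$ over
centered categories locates the BMI level most attractive in nominations;
with the published coefficients $(0.014, -0.020)$ its vertex sits at
centered $+0.35$, inside the 22–26 kg/m² band.  `ego_alter_table` evaluates
the full quadratic-plus-interaction selection surface on a grid.

For behavior change, `behavior_change_or` contrasts the odds of a
one-category step (versus staying) between two ego-and-friends scenarios.
The canonical contrast compares an ego whose friends all sit one category
*above* with an ego whose friends sit one category *below*.  The reference
is the lower side of "same or lower" deliberately: with friends exactly at
the ego's category the up- and down-step similarity changes are equal
($-1/\mathrm{range}$ each) and every contrast degenerates to 1, whereas the
above-vs-below contrast gives $e^{2\beta_{sim}/\mathrm{range}}$ for the up
step and its exact inverse for the down step — reproducing all published
values (2.85 and 0.35 for $\beta_{sim} = 5.233$; 2.83 for 5.205).  Because
the shape terms cancel and similarity is linear in the friend offset, the
up-step value is identical to what a friends-at-ego reference would give;
only the down step distinguishes them.  `own_category_or` reports
$e^{2\beta_{quad}}$, the per-unit-of-own-category factor the shape terms
contribute to the increase-vs-stay odds (1.09 at $\beta_{quad} = 0.041$).

Confidence intervals for any scalar functional of the parameters come from
`mc_bootstrap_ci`: draws from the multivariate normal at
$(\hat\theta, \widehat{\mathrm{cov}})$ are pushed through the functional
and the 2.5th/97.5th percentiles reported (default $10^5$ draws).

## The synthetic-study generator

`gen_study` emulates the study design so the full pipeline is testable
without the original data: 276 actors, four waves spanning an academic
year, wave participation 239/241/218/192, 71% female, race fractions
0.49/0.105/0.272/0.134 (White/Black/Hispanic/Other), 93.1% first-year.
Floors are assigned uniformly across 6 floors — a typical residence-hall
layout; the source reports no floor count.  The first-wave network draws
each unordered pair from a four-state distribution (null / asymmetric /
mutual) with a tie odds weight calibrated by root finding to a mean
out-degree of 3.3, doubled within floors (odds multiplier 2, of the order
implied by the published same-floor selection effect) and with a mutual-dyad
boost of 5 (friendship nominations reciprocate far above chance).  First-wave
BMI categories are drawn from the study's first-wave frequency table.
Subsequent waves are simulated forward under the published no-demographics
coefficients as the default truth.  Missingness is completely at random
subject to exact per-wave counts and every actor remaining observed at
two or more waves, matching the study's inclusion rule; the generator does
not reproduce the study's demographic participation differences.

One convention difference is worth knowing: the generator centers the
behavior scale on its first-wave codes (later waves do not exist yet when
simulation starts) and uses a zero similarity-centering constant, while
estimation pools all waves and centers similarity on the data.  The two
parameterizations describe the same model family — a centering shift is
absorbed into the linear shape term and the linear ego/alter selection
terms — so recovered coefficients are compared to the generating values
after that (numerically small) reparameterization, which the quadratic,
similarity and structural coefficients do not feel.

What passing tests on generated panels do *not* show: the generator's
first wave is a simple inhomogeneous Bernoulli draw, not a SAOM
equilibrium, and real nomination data are top-5-ranked, so degree
distributions, missingness mechanisms and measurement error in real panels
are all simpler here than in the field.

## Numerical choices and problem sizes

Choice probabilities subtract the maximum objective before exponentiating.
Change statistics are computed incrementally in compiled code and are
tested to equal full recomputation exactly (exhaustively over all 3-actor
digraphs and on random graphs up to n = 6).  The test suite exercises
parameter recovery on a generated study of 100 actors over 3 periods with
the 15-parameter structural-plus-shape model (each recovered parameter
within 3 reported standard errors; convergence t-ratios within threshold),
a scale at which the full estimate runs in well under a minute; larger
studies (the full 276-actor design) estimate in a few minutes with the
same code path.  Monte Carlo test bounds (binomial/multinomial 99% bands,
Poisson dispersion bands, 0.03 on bootstrap quantiles at $10^5$ draws) are
fixed from the corresponding exact distributions.

## Known limitations

- Evaluation-function (selection-only) parameterization: no separate
  creation/endowment effects, matching the published model.
- Unconditional estimation only; the reference tradition's option of
  conditioning on observed change counts is not implemented.
- No time-heterogeneity tests and no goodness-of-fit auxiliary statistics.
- The multinomial network choice set is the full actor set; very large
  panels (thousands of actors) would need candidate subsampling, which
  this study design does not require.

## A worked example

```{r example, eval = FALSE}
library(netcoev)

# generate a study-like panel and estimate the published specification
st <- gen_study(study_config(), seed = 1)
spec <- bmi_effect_spec()
fit <- saom_estimate(st$panel, spec, options = list(seed = 2))
print(fit)

# interpret: influence odds ratio with a bootstrap CI
scale <- fit$scale
or_hat <- behavior_change_or(
  c(avg_similarity = unname(fit$theta["beh.avg_similarity"])),
  scenario_contrast(step = 1), scale)
ci <- mc_bootstrap_ci(fit$theta, fit$covariance, function(th)
  behavior_change_or(c(avg_similarity = unname(th["beh.avg_similarity"])),
                     scenario_contrast(step = 1), scale),
  n_draws = 1e5, seed = 3)
round(c(or = or_hat, lo = ci[1], hi = ci[2]), 2)
```
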