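---
title: "Methods: performance-based allocation, Shapley benchmarks and zero-one-inflated beta models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: performance-based allocation, Shapley benchmarks and zero-one-inflated beta models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(allocbias)
```

## The scientific problem

When two people earn a joint reward through a collective task, how
should — and how do — they split it? `allocbias` implements a complete,
simulation-backed pipeline for studying *self-allocation bias* in
performance-based reward division: the tendency to allocate more to
oneself, and to rely less on one's own objective performance, when the
allocation concerns oneself rather than two third parties.

The task it models is a modified dictator game built on a prime-number
judgement cover task. On each trial a decision maker sees two players'
correct-response counts ($p_1$, $p_2$), a collective criterion, and the
resulting joint outcome, then divides the pot between the players with a
slider. Three collective criteria structure how performance causes the
reward:

* **simple** — the pot scales with the total number of correct
  responses; there is no threshold;
* **additive** — the pot is won if and only if $p_1 + p_2 \ge T$;
* **disjunctive** — the pot is won if and only if
  $\max(p_1, p_2) \ge T$.

Threshold comparisons are inclusive ($\ge$): the worked example with
performances 2 and 3 against a threshold of 5 wins the pot.

## Shapley benchmarks and contribution structure

Each reward trial induces a two-player coalitional game: $v(S)$ is the
amount coalition $S$ would have earned alone under the trial's
criterion, with $v(\emptyset) = 0$ by the standard normalization. The
Shapley value divides the joint outcome by average marginal
contribution over the two possible orders of coalition formation,

$$\phi_1 = \tfrac12 v(\{1\}) + \tfrac12\big(v(\{1,2\}) - v(\{2\})\big),$$

and symmetrically for player 2. It is efficient
($\phi_1 + \phi_2 = v(\{1,2\})$), symmetric, and assigns dummy players
zero. For threshold criteria the ratio $\phi_1 / (\phi_1 + \phi_2)$ can
only take the values 1, 0.5 or 0, which classifies every reward trial
into a *contribution structure*: `player1_only`, `both`, or
`player2_only` — who was causally necessary for the reward. Simple
trials are all `both` (no threshold gates the reward). Money is carried
internally in integer cents, so the efficiency identity holds exactly
for threshold games rather than to floating-point tolerance.

## The task generator

`generate_stimulus_list()` produces the trial lists the generator
presents to simulated allocators. Layouts mirror the three experiment
designs: 384 trials in 4 sessions (two conditions, `exp1`), 216 trials
in 6 sessions (`exp2`), and a crossed source $\times$ recipient design
with four conditions (`exp3`) whose cell sizes mirror `exp2`. Every
(condition $\times$ criterion) cell receives an equal trial count, and
the same stimuli (identical `stimulus_id`, performances, threshold,
pot) appear in every condition so that trial-wise matching across
conditions is exact.

Design choices where the task description leaves the numbers open (all
configurable through `perf_config()`):

* per-player performance values are drawn from the grid 1–8 — the scale
  of the worked examples — then **mirrored**: each sampled pair
  $(p_1, p_2)$ is accompanied by its swap $(p_2, p_1)$, which makes the
  multiset of pairs exactly exchange-symmetric and forces the mean
  relative performance of player 1 over reward trials to equal 0.5
  exactly, not merely in expectation;
* thresholds come from the grid 3–8 and are sampled jointly with the
  performances so that every reward trial actually satisfies its
  criterion and the three contribution structures all occur (the
  sampler cycles through them);
* pots are ¥6/8/10/12 for threshold criteria; simple-trial pots are
  ¥1 per correct response;
* 20% of mirrored stimulus pairs are flagged as loss trials (negative
  pot). Flagging whole pairs keeps the reward subset exactly
  symmetric. Loss trials are generated, carried in the tables, and
  excluded from every analysis;
* block structure: each session contains one mini-block per cell in
  seeded random order, labelled "no goal" / "mutual reach" /
  "one reaches"; decision time limits (8 s / 6 s) are metadata only.

## The synthetic cohort

No individual-level generative account of the participants' decision
process exists; the agent model is this package's own design
commitment, validated by qualitative pattern reproduction and parameter
recovery, never claimed to be the participants' mechanism. An agent
allocates around the latent mean

$$\operatorname{logit}(\mu) = \operatorname{logit}\!\big(w r + (1 - w)\,0.5\big) + \underbrace{\big(b_0 + b_{\mathrm{svo}} z + b_{\mathrm{contrib}}\,[\text{player2\_only}]\big)\,[\text{self recipient}]}_{\text{self-bias}},$$

where $r$ is relative performance, $w = w_{\mathrm{other}} -
\Delta w_{\mathrm{self}}\,[\text{self recipient}]$ is the performance
weight, and $z$ is the cohort-standardized SVO angle. Putting the bias
on the log-odds scale matches the logit link of the analysis model,
which makes parameter recovery well-posed. The bias is gated by the
*allocation recipient*, not the performance source (a `gate` switch
allows source-gating for sensitivity runs). Blend values at the
boundary are clipped into $(10^{-6}, 1 - 10^{-6})$ before the logit.

Responses are zero-one-inflated beta draws around $\mu$ (boundary
probability `zoi`, conditional one-probability `coi`, precision
$\phi$), converted to money at the trial's pot and rounded to the
¥0.1 slider step while preserving the pot sum. A small fraction of
trials (0.12% for `exp1`-like runs, 0.96% otherwise) is flagged as
missed and dropped before analysis.

Population defaults are calibrated once to the qualitative effect
regime of interest and are not tuned thereafter: $b_0 = 0.19$ log-odds
(an odds ratio near 1.2 for the self-relevance contrast),
$b_{\mathrm{svo}} = -0.16$ per SD of SVO (individualistic agents more
biased), $w_{\mathrm{other}} = 0.6$ with
$\Delta w_{\mathrm{self}} = 0.14$ (noticeably weaker reliance on
performance for self-directed allocations), $b_{\mathrm{contrib}} =
0.15$ (extra bias when only the partner was causally necessary), SVO
angles $\sim N(25^\circ, 15^\circ)$ (a mostly prosocial population with
an individualistic tail, as slider studies typically find), $\phi =
30$, `zoi` $= 0.1$, `coi` $= 0.5$. With every bias parameter at zero
(`null_population()`) the generative process is exchangeable in player
identity, which the calibration tests exploit.

One consequence worth knowing: because the performance down-weighting
also *shrinks* self-relevant allocations toward an even split, the net
trial-level bias in `player1_only` cells (where $r$ is high) can be
small or even slightly negative at these defaults, while `player2_only`
cells (low $r$, plus $b_{\mathrm{contrib}}$) show the largest bias —
the ordering the analyses target.

## The statistical engine

Relative allocations live on $[0,1]$ with genuine point masses at the
boundaries, so the engine is a hierarchical **zero-one-inflated beta**
regression: a boundary response occurs with probability `zoi` and
equals 1 with conditional probability `coi`; interior responses follow
$\mathrm{Beta}(\mu\phi, (1-\mu)\phi)$ with

$$\operatorname{logit}(\mu_{ij}) = x_{ij}^\top\beta + u_j, \qquad u_j \sim N(0, \sigma^2).$$

`zoi` and `coi` are intercept-only (the model formulas condition only
$\mu$), which factorizes the likelihood: boundary counts inform the
inflation parameters, interior values inform the beta regression.
Formulas use standard Wilkinson notation with one `(1 | group)` term.
Reference levels follow the reporting conventions: `self_irrelevant`
and `simple` first.

**Priors** (declared and fixed; a sensitivity test verifies they barely
move estimates on informative data): $N(0, 2.5)$ on fixed effects
(logit scale), half-$N(0,1)$ on $\sigma$, $\mathrm{Gamma}(2, 0.1)$ on
$\phi$, $N(0, 2.5)$ on the inflation logits.

**Estimation.** The default engine is MAP + Laplace. A subtlety: the
joint posterior mode over $(\beta, u, \sigma)$ is degenerate — as
$\sigma \to 0$ with $u \to 0$ the joint density diverges (the usual
funnel), which wrecks naive joint optimization precisely in the
near-null settings the calibration tests need. The engine therefore
holds $\sigma$ fixed during the inner optimization over
$(\beta, u, \log\phi, \operatorname{logit} zoi, \operatorname{logit}
coi)$ (analytic gradients, `nlminb`) and updates $\sigma$ by an
EM-type step on the Laplace approximation,
$\sigma^2 \leftarrow$ the half-normal-penalized root of
$\sigma^4/s^2 + J\sigma^2 = \sum_j (u_j^{*2} + 1/H_j)$, where $H_j$ is
the per-group curvature. Posterior draws come from the Gaussian
approximation at the mode, conditional on the estimated $\sigma$ —
adequate for the fixed-effect contrasts the analyses need. The
`"mcmc"` engine runs adaptive random-walk Metropolis chains (proposal
from the Laplace covariance, Robbins–Monro tuned to 23% acceptance
during warmup) and reports split R-hat per parameter; defaults mirror
the 8-chain, 3000-iteration schedule but with 1000 warmup iterations
rather than a token burn-in. Optimizer failure, a non-positive-definite
Hessian, or R-hat > 1.05 flags the fit as non-converged — never a
silent success.

**Contrasts.** `marginal_means()` averages the linear predictor on the
link scale over unrequested factors (equal weights, covariates at
training means), reports cell means on the response scale, and forms
pairwise contrasts on the logit scale, exponentiated to odds ratios.
`marginal_slopes()` is the trend analogue; because the predictor is
linear in the covariate, the ±0.5 finite difference is the exact
derivative. All intervals are 95% highest-density intervals (shortest
interval over sorted draws; ties broken by the lower bound). Interval
coverage of HPD intervals is computed on the reported scale (odds
ratios after exponentiation).

**Model comparison.** `compare_models()` estimates the difference in
expected log pointwise predictive density by importance-sampling
leave-one-out on the stored draws, with raw ratios truncated at
$\bar r \sqrt{S}$ — a light-weight stabilization in the spirit of
Pareto smoothing. The standard error comes from the pointwise
differences. Exact replication of any particular sampler's LOO output
is a non-goal.

**The bias response.** The trial-matched self-allocation bias — the
difference in relative allocation between a self-relevant trial and
its stimulus-matched self-irrelevant twin — lives on $[-1, 1]$, which
a zero-one-inflated beta cannot host. `bias_table()` maps it affinely
onto $[0,1]$ (`bias01 = (bias + 1) / 2`) before fitting and results
are read back through `2x - 1`; 0.5 on the transformed scale is bias
zero. For the crossed `exp3` design, `self_allocation_bias()` exposes
the recipient difference (XforS − XforO) and the source difference
(SforX − OforX) separately and labels them; neither is privileged as
"the" bias.

## Validation design and problem sizes

The test suite validates each layer against independent oracles: the
closed-form Shapley value against brute-force enumeration over
orderings on ≥1000 random monotone games (with exact efficiency,
symmetry and dummy checks); the mixture density against numerical
quadrature (normalization to $10^{-6}$ over 100 random parameter
sets); the fitting engine against data simulated from known
coefficients, against its own MCMC engine (agreement within 0.1
posterior SD), and against null cohorts (type-I calibration of the
headline bias estimates).

The parameter-recovery harness simulates 20 replicate cohorts of 40
participants each under the `exp2` layout at the default population,
and requires at least 18 of 20 replicates to reproduce each of the
four headline patterns: (i) a self-relevant vs self-irrelevant odds
ratio above 1 with the 95% HPD excluding 1, (ii) a negative SVO slope
in self-relevant cells only, (iii) a lower performance slope when the
self receives, and (iv) the largest bias in the `player2_only`
category. Cohorts of 40 with ~170 reward trials per participant give
each Laplace fit a few seconds on one CPU; the harness is the
dominant cost of the suite by design, not an accident of scale.

## Limitations

The synthetic cohort emulates the *statistical* structure of the task
— symmetric stimuli, matched conditions, boundary-inflated slider
responses, SVO-linked heterogeneity — not the participants' cognition:
no reaction times, no learning across trials, no believability
dynamics, no neural quantities. Passing recovery tests shows the
pipeline can detect effects of the posited form at realistic sizes; it
cannot show that human data were generated this way. The Laplace
posterior conditions on the estimated random-intercept SD, so the SD's
own uncertainty is not propagated into the contrasts; the MCMC engine
is available where that matters. The LOO approximation uses truncated
rather than Pareto-smoothed importance weights and has no per-point
reliability diagnostic.
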