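---
title: "Models and methods in rleam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in rleam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rleam)
```

This vignette documents the models the package implements, the choices made
where the design was genuinely open, the numerical machinery, and what the
synthetic-data generators do and do not emulate.

## The model family

All models share one learning rule. Each stimulus set (a pair or triplet of
options presented together) carries a vector of Q-values — running estimates
of each option's expected reward, coded on [0, 1]. After feedback the chosen
option's value moves toward the observed outcome by the delta rule

$$Q_{i,t+1} = Q_{i,t} + \alpha\,(r_t - Q_{i,t}),$$

with learning rate $\alpha \in (0, 1)$; unchosen options are untouched and
sets are learned independently. Decisions on a trial are driven by the
values *as they stood when the stimulus appeared* (feedback arrives after
the response), which is why `q_trajectory()` returns pre-feedback values
and why the likelihood uses them. Initial values start at 0; estimating
them freely adds nothing in practice, and the package keeps `q0 = 0` as a
configurable default. Rewards of "+100 points" are coded 1 and "0 points"
coded 0: with that coding the canonical decision weights produce drift
rates of the size actually observed, and Q-values live on the same [0, 1]
scale as reward probabilities.

The decision architectures differ in how Q-values become a response and a
response time (RT = decision time + non-decision time $t_0$; within-trial
noise SD is fixed at 1 everywhere, since it only sets the scale of evidence
units):

* **Soft-max** (`softmax`): choice-only baseline,
  $P_i \propto \exp(\beta Q_i)$; no RTs. Useful as a floor in model
  comparison.
* **RL-DDM** (`rl_ddm`): one diffusion between boundaries $+a$ and $-a$
  with unbiased start and drift $v = w (Q_1 - Q_2)$. Variants add a
  saturating link $v = 2 v_{max}/(1 + e^{-w \Delta Q}) - v_{max}$,
  proportional drift variability ($sv$: trial drift
  $\sim N(v, (|v| sv)^2)$, keeping $v/sv$ constant), uniform start-point
  variability ($sz$, expressed as a fraction of the full boundary range),
  and uniform non-decision variability ($st_0$).
* **RL-RD** (`rl_rd`): one single-boundary diffusion per option racing to a
  common threshold $a$, $v_i = V_0 + w Q_i$. $V_0$ is an urgency input:
  it speeds every accumulator regardless of evidence.
* **RL-lARD / RL-ARD** (`rl_lard`, `rl_ard`): the advantage race,
  $v_1 = V_0 + w_d (Q_1 - Q_2) + w_s (Q_1 + Q_2)$ (and symmetrically for
  accumulator 2). The difference weight $w_d$ carries the discriminative
  evidence; the sum weight $w_s$ makes both accumulators faster when total
  available reward is high. `rl_lard` fixes $w_s = 0$. The equivalent
  excitation/inhibition form $v_i = V_0 + w_e Q_{own} - w_i Q_{other}$
  with $w_e = w_d + w_s$, $w_i = w_d - w_s$ is available as
  `drift_ard2_ei()`.
* **Win-All RL-ARD** (`rl_ard_winall`): for three options, six directional
  pairwise accumulators ($v_{i\text{-}j} = V_0 + w_d(Q_i - Q_j) +
  w_s(Q_i + Q_j)$) share one threshold and the five decision parameters.
  An option is chosen once *both* of its accumulators have finished while
  each rival still has at least one unfinished accumulator; the slower of
  the two winning accumulators sets the decision time. Removing an option
  recovers the two-choice model exactly, so the generalization costs no
  extra parameters.

Free-parameter counts of the baseline models: RL-DDM 4 ($\alpha, a, t_0,
w$), RL-RD 5, RL-lARD 5, RL-ARD 6, Win-All RL-ARD 6.

## Likelihoods

Race likelihoods build on the Wald (inverse-Gaussian) first-passage law of
a single-boundary diffusion. `dwald()`/`pwald()` extend it to zero and
negative drifts, where the distribution is *defective*: the boundary is
reached only with probability $e^{2va}$ for $v < 0$. Negative drifts arise
naturally after reward reversals (a large value disadvantage), so the race
densities use the defective CDF in their survivor terms; the summed choice
probabilities then fall below one, the mass of "stalled" races in which no
accumulator ever finishes. The two-choice density is the winner's Wald
density times the survivor function of the loser; the Win-All density
multiplies the density of the slower of the chosen option's two
accumulators with, for each rival, the probability that at least one of
its accumulators is unfinished.

The diffusion density uses the classical small-time/large-time series for
the Wiener first-passage problem, switching per evaluation point to
whichever series needs fewer terms at truncation error $10^{-8}$.
Proportional drift variability integrates in closed form (the drift enters
the density only through an exponential prefactor, so its normal mixture
is Gaussian); start-point variability uses 16-node and non-decision
variability 32-node Gauss–Legendre quadrature. Internally the paper-style
$\pm a$ bounds map to the boundary-separation form (separation $2a$,
relative start 0.5); the user-facing convention is $\pm a$ throughout.

Per-trial densities are floored at $10^{-10}$: an RT at or below $t_0$
degrades the fit instead of crashing the sampler. Trials without a
recorded response (missed deadlines with no response, stalled races)
contribute no density but *do* update Q-values, because the outcome is
shown to the learner even on late trials; the likelihood applies no
censoring for responses after the deadline (all recorded responses
contribute — a flagless default chosen because the estimation target is
the response process, not the payoff rule).

Two open details were resolved as follows. The saturating value link is
oriented so drift increases with the value difference (the alternative
orientation makes learning slow responses down, which contradicts the
phenomenon the model describes). The start-point range $sz$ is *relative*
(fraction of the full boundary separation), so that $sz = 1$ means "the
entire range between the boundaries" and the prior truncation at 0.5 means
"at most half the range"; an absolute parametrization would make the
truncation bound depend on $a$.

## Task paradigms and simulation

`make_design()` instantiates four paradigms: (1) baseline two-alternative
learning — four pairs with reward probabilities .8/.2, .7/.3, .65/.35,
.6/.4, each 52 presentations, 208 uniformly interleaved trials, 2 s
deadline (one report of this task gives 2.5 s; 2.0 s is the default and
the deadline is an argument); (2) speed–accuracy cueing — three pairs, 324
trials in three blocks, SPD/ACC cues randomly interleaved and balanced
within block, 0.6 s deadline under SPD; (3) reversal learning — four
blocks of 128 trials, two pairs, with the pair probabilities swapped from
a per-block reversal trial drawn uniformly from block trials 61–68;
(4) three-alternative choice — three blocks of 144 trials, four triplets
crossing difficulty with reward magnitude. Option 1 is always the
(pre-reversal) best option. Interleaving is uniform-random per block (the
randomization scheme is otherwise unconstrained) and cue frequencies are
balanced; inter-event jitters of the cued task are not simulated because
they never enter the model.

`simulate_experiment()` runs the closed decide–feedback–learn loop, using
exact inverse-Gaussian sampling for the races (an Euler path simulator with
continuity-corrected barrier exists purely as a cross-check oracle in the
test suite) and numerical inversion of the analytic density for the
diffusion. Late responses keep their outcome but forfeit the reward;
learning uses the outcome. Under speed cues, selected parameters scale
proportionally, e.g. $a_{spd} = (1 + m_a)\,a_{acc}$ with $m > -1$.

What the generator emulates is the *model's* data-generating process under
the canonical parameter tables (`default_group_params()`, across-subject
means and SDs typical of healthy young adults in these paradigms). What it
does not emulate: working-memory contributions that push early-trial
accuracy above what feedback learning allows, block-order or fatigue
effects, and any RT contamination (anticipations, lapses). Passing tests
therefore show internal consistency of likelihoods, samplers and
summaries — not that real data obey the model.

## Hierarchical estimation

`run_sampler()` estimates subject- and group-level parameters jointly.
Populations are independent truncated normals per parameter (truncation
shared with the prior support: thresholds positive, $t_0 \in [0.025, 1]$ s,
$sz \in [0, 0.5]$, multipliers $> -1$); learning rates are sampled on the
probit scale. Priors: $\alpha \sim \Phi(N(-1.6, 5))$, $a \sim N(3,5)$
truncated at 0, $t_0 \sim N(0.3, 0.5)$ on [0.025, 1], $w \sim N(2,5)$
(diffusion) or $N(9,5)$ (race), $w_d \sim N(9,5)$, $w_s \sim N(0,3)$,
group SDs $\sim \Gamma(1,1)$. The urgency prior is not pinned down by the
sources the defaults were taken from; the package uses $V_0 \sim N(2, 5)$
truncated at 0, vague on the scale of the canonical estimates.

Sampling is differential-evolution MCMC: $D = 3 \times$ (number of free
parameters) chains; proposals $\theta' = \theta + \gamma(\theta_m -
\theta_n) + \epsilon$ with $\gamma = 2.38/\sqrt{2d}$ and uniform jitter
$\epsilon$. Within an iteration every subject's parameter block and then
each parameter's group-level $(\mu, \sigma)$ pair is updated by
Metropolis–Hastings. Three implementation details matter:

* **Frozen-half updates.** Chains update in two blocks, each proposing
  with difference vectors drawn from the *other, frozen* block. Updating
  all chains simultaneously from one snapshot lets co-moving chains
  contract the population and demonstrably biases posterior spread; the
  two-block scheme keeps every update a valid MH kernel while preserving
  vectorized likelihood evaluation across chains. (The per-coordinate
  "cross-over probability" of some DE-MCMC software is not reproduced;
  full-vector proposals with the standard $\gamma$ serve the same role.)
* **Staged initialization.** Each subject is first fit independently for
  `n_init` iterations against likelihood × prior; the hierarchy starts
  from those states with $(\mu, \sigma)$ taken from the across-subject
  spread. Starting all subjects from one shrunk prior cluster instead
  lets the group-level SDs collapse onto that cluster (the hierarchical
  funnel) and recovery of between-subject differences fails. Non-decision
  chains additionally initialize below the subject's fastest RT.
* **Migration and unsticking.** With probability 0.05 per burn-in
  iteration a random subset of chains ring-copies full states
  (Metropolis-accepted); at the end of burn-in, chains stranded far below
  the population's typical posterior density (> 50 log units under the
  median) are replaced by copies of healthy chains. Both run before
  sampling only, so the retained draws come from untouched MH kernels.

Defaults are 500 burn-in and 1000 retained iterations with automatic
extension (previous draws become burn-in) while the Gelman–Rubin statistic
exceeds 1.03, up to `max_extend` times. `gelman_rubin()` implements the
df-adjusted univariate PSRF and the multivariate version exactly as the
standard R reference implementation does (the test suite pins this to
`coda` at $10^{-8}$).

Model comparison uses the Bayesian predictive information criterion,
$\mathrm{BPIC} = \bar D + 2 p_D$ with $p_D = \bar D - D(\bar\theta)$,
deviance $-2\log L$ at the posterior mean of the subject-level parameters
— the stronger-penalty analogue of the DIC. $p_D$ is meaningful only for
converged chains; badly mixed fits can make it negative, which the
unsticking pass above largely prevents.

## Assessment layer

`bin_summaries()` splits each subject's trials into 10 equal-count bins
(remainder to the earliest bins), computes accuracy and the 10th/50th/90th
RT percentiles separately for correct and error responses, then averages
over subjects; error percentiles from fewer than 3 error trials are
reported missing rather than as unstable estimates. Correctness means
choosing the option with the currently highest reward probability, so in
reversal designs it tracks the post-reversal contingency, while
`reversal_align()` additionally labels `choice_a` relative to the fixed
*pre*-reversal best option — both views are needed to reproduce the
standard figures. `posterior_predict()` simulates the full design once per
joint posterior draw (default 100) and reports 2.5–97.5% envelopes of the
subject-averaged summaries. `exclusion_screen()` applies the conventional
accuracy cutoffs for these paradigms (0.55 two-alternative at ~200 trials,
0.37 three-alternative at ~430) or an exact one-sided binomial test; the
printed conventions and the exact test agree only approximately, which is
why both modes exist and the cutoff mode is the fidelity default.

## Problem sizes

The package's own studies are desk-scale by choice: the recovery study
fits 20 simulated subjects on the 208-trial two-alternative design
(rank correlations ≥ 0.7 for $\alpha, a, t_0, V_0, w_d$; the threshold's
correlation ceiling is set by its posterior width relative to the modest
between-subject spread, as thresholds trade off against urgency and
non-decision time within subject), and the model-selection study uses 20
simulated data sets of 2 subjects with shortened chains, checking only the
direction of the BPIC difference. Scaling subjects or iterations up
sharpens both, at proportional cost.

## Known limitations

Only two- and three-alternative architectures are exercised; the Win-All
machinery generalizes but is untested beyond $N = 3$. The sampler assumes
independent normal populations — no parameter correlations at the group
level. Collapsing bounds, within-trial urgency signals, dual learning
rates and eligibility traces are out of scope. The linear ballistic
accumulator variant of the advantage framework is deliberately not
implemented.
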