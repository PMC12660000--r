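---
title: "Multi-state survival modelling of action-log data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-state survival modelling of action-log data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msmlog)
```

## The problem

Computer-based assessments log every interface action a respondent takes —
button clicks, page switches, tool uses — with a timestamp. These *process
data* carry information that the final right/wrong score discards: not just
*what* respondents did, but *how fast* they moved between actions, and
whether the pace differs between people who eventually answered correctly
and people who did not. `msmlog` models the timestamped action sequence as
a realisation of a continuous-time multi-state process in which each
distinct action is a state, and asks where, and for whom, transitions
between states are faster or slower.

## The model

For respondent $i$ in correctness group $g_i \in \{0, 1\}$ (1 = correct),
the instantaneous rate of moving from action $m$ to action $l$ is

$$
h_i(m, l) \;=\; \lambda_{mlg_i}\; \theta_i\;
\exp\!\big(x_i^\top \beta \;+\; \gamma_{1 g_i}\, \mathbf 1[m \in K]
\;+\; \gamma_{2 g_i}\, \mathbf 1[l \in K]\big),
$$

with

* $\lambda_{mlg} > 0$: group-specific baseline hazard of the $m \to l$
  transition, in events per minute;
* $\theta_i > 0$: an individual overall speed factor, scaling all of
  respondent $i$'s rates;
* $\beta$: covariate effects, shared across groups and transitions — a
  positive coefficient means individuals high on that background variable
  transition faster everywhere;
* $\gamma_{1g}, \gamma_{2g}$: additional log-rate effects when the start
  (resp. end) action belongs to the key-action set $K$, allowed to differ
  between the correct and incorrect groups.

Hazards are constant in time (time-homogeneous Markov assumption): the
future depends on the current action only, and sojourn times in a state
are exponential with rate equal to the total outgoing hazard. Under that
assumption the *embedded-chain transition probability* — the chance that
the next action is $l$ given the current action is $m$ — is

$$
P_i(m, l) = \frac{h_i(m, l)}{\sum_{l'} h_i(m, l')}.
$$

Because $\theta_i$, $\exp(x_i^\top\beta)$ and the $\gamma_1$ start-action
term are common to every destination in a row, they cancel in this ratio:
transition *probabilities* depend only on the group's baseline hazards and
$\gamma_2$. The package keeps the speed and covariate arguments in the
probability interfaces for fidelity, and the cancellation is verified by a
property test that evaluates the matrix at two covariate settings.

### Likelihood

Each consecutive event pair contributes one observed transition and one
fully observed sojourn; the interval from the last event to the total
solution time $T_i$ is a right-censored sojourn in the final state. Time
before the first event is not modelled — a respondent enters the state of
their first action at that action's timestamp (an optional virtual start
state was considered and deliberately left out: the data carry no
information about a "pre-first-action" process under this design). With
transition counts $d_{iml}$ and state exposures $e_{im}$ (censored tail
included), the log-likelihood is

$$
\ell = \sum_i \Big[ \sum_{(m,l)} d_{iml} \log h_i(m,l)
\;-\; \sum_m e_{im} \sum_{l} h_i(m,l) \Big].
$$

`compute_sufficient_statistics()` reduces a dataset to $(d, e)$ once; a
brute-force test re-derives $\ell$ by scanning the raw event list and
agrees to $10^{-9}$.

**Support.** With $E$ actions the full hazard space has $E(E-1)$ (or
$E^2$, counting repeat events) parameters per group, most of which carry
no data in real logs. By default each group's support is the set of
ordered pairs observed at least once in that group (`support =
"observed"`); pairs outside it are structural zeros. `support = "full"`
enables every ordered pair and is the right choice for simulation studies
in which every transition is possible. Repeated identical consecutive
events are kept as observable self-transitions by default — they are log
events, not state changes — and `collapse_repeats()` provides the
classical multi-state view.

### Priors and identifiability

Defaults: $\beta_k, \gamma \sim N(0, 2^2)$ and
$\lambda, \theta \sim \mathrm{Gamma}(1, 1)$ (shape, scale; prior mean 1).
The normal scale 2 sits at the lower edge of the regime where the prior
sensitivity sweep (`sensitivity_sweep()`, grids in `sensitivity_grid()`)
shows posterior means to be stable; the Gamma(1, 1) choice matches the
canonical sensitivity grid in which every (shape, scale) combination has
prior mean one.

The likelihood is exactly invariant under $\lambda \mapsto c\lambda$,
$\theta \mapsto \theta/c$: only the $\theta$ prior, centred at one, pins
the common scale. The same holds direction-wise for the covariate
coefficients ($\beta_k \mapsto \beta_k + \delta$ compensated by
$\theta_i \mapsto \theta_i e^{-x_{ik}\delta}$) and for the key-action
effects (compensated by the key-row or key-column hazards). These *soft
ridges* shape both the interpretation — reported $\lambda$ and $\theta$
are identified relative to the prior centring, and
`renormalize_scale()` moves the common scale into the hazards for
reporting — and the sampler design below.

## Estimation

`msmlog()` runs a fully Bayesian Metropolis-within-Gibbs sampler:

* every scalar parameter is its own Metropolis block; $\lambda$ and
  $\theta$ use Gaussian random walks on the log scale (Jacobian included),
  $\beta$ and $\gamma$ on the natural scale;
* given the rest of the state, the $\lambda$'s are mutually conditionally
  independent, as are the $\theta$'s, so those blocks are proposed and
  accepted element-wise in one vectorised sweep — same kernel, no R-level
  loop;
* each cycle additionally proposes *ridge moves*: likelihood-invariant
  reparameterisations along the soft directions above (global
  $\lambda\!\leftrightarrow\!\theta$ rescaling; each $\beta_k$ shifted with
  compensating $\theta$ rescaling; each $\gamma$ shifted with compensating
  key-row hazards). Because the likelihood cancels exactly, the acceptance
  ratio is the prior ratio times the transformation Jacobian. Without
  them, single-site updates diffuse slowly along the ridges and
  between-chain convergence of $\beta$ can stall; with them the
  Gelman-Rubin statistics of all parameters drop close to one. This is
  the one place the implementation goes beyond plain single-site updates,
  and it changes the kernel, not the posterior;
* proposal scales adapt only during burn-in, every `adapt_interval`
  iterations: multiply by 1.5 if the block's running acceptance exceeds
  0.5, by 0.67 if below 0.2. Kernels are frozen after burn-in, so the
  retained draws target the exact posterior. Post-burn-in acceptance
  rates per block are stored in the fit;
* chains are seeded `seed + chain - 1` and run independently;
  `gelman_rubin()` computes the classic $\hat R$ and `hpd_interval()` the
  shortest interval holding the stated mass. An effect is reported
  *significant* when its 95% HPD interval excludes zero.

Initial values are empirical: $\lambda$ at pooled rates
$d_{+mlg}/e_{+mg}$ floored at $10^{-3}$, $\theta = 1$,
$\beta = \gamma = 0$. The default `msm_control()` (20,000 iterations,
5,000 burn-in, thin 5, 5 chains) is sized for interactive use; the
`"paper"` preset mirrors the large-scale setting of 300,000 iterations
with 100,000 burn-in and thinning by 10.

### Conditional-distribution check

The primary sampler-correctness test exploits conjugacy: with everything
fixed except one $\lambda$ carrying $d$ events and exposure $e$ under a
$\mathrm{Gamma}(a, s)$ prior, the exact posterior is
$\mathrm{Gamma}(a + d,\; s/(1 + s e))$. The test suite compares the
sampled marginal's mean and variance against this closed form within
three batch-means Monte-Carlo standard errors.

## Key-action extraction

`chi_square_scores()` implements TF–ISF-weighted chi-square feature
scoring. For action $i$: $ISF_i = \ln(N / n_i)$ with $n_i$ the number of
sequences containing the action (the document-frequency reading; a total
occurrence-count variant is switchable), $TF_{ij}$ the count of action $i$
in respondent $j$'s sequence, and $w_{ij} = TF_{ij} \times ISF_i$. The
weighted frequencies are summed by correctness group into a per-action
2×2 table against the remaining group totals, and the chi-square statistic
of independence is computed directly on the weighted (non-integer) counts,
with no continuity correction and no p-value — scores only rank actions.
An action is *correct-representative* when its weighted occurrence
proportion is higher in the correct group.

`select_key_actions()` defaults to elbow selection on the descending score
curve: the elbow is the rank maximising the perpendicular distance to the
chord joining the first and last points, and the selection is the
correct-representative actions with scores *strictly above* the elbow
action's score (the elbow itself is excluded). Ties in the ranking break
alphabetically, so output is deterministic. Degenerate inputs fail
loudly: a single-action table has no chord, and an all-equal score curve
has no elbow; both errors point to the explicit `top_k` / `min_score`
overrides.

## Group comparison

`transition_difference()` evaluates, for every stored posterior draw, both
groups' embedded-chain matrices (speed set to one — exactly neutral by the
cancellation property) and summarises the correct-minus-incorrect
difference per ordered pair with its posterior mean and HPD interval.
Pairs supported in only one group are excluded and listed rather than
imputed — imputing would compare data against prior. No multiplicity
correction is applied across pairs; the per-pair 95% HPD rule is the
reported criterion, and the `level` argument can tighten it.
`export_heatmap()` writes the $E \times E$ signed-difference matrix with
non-significant cells zeroed plus a significance mask;
`export_edge_list()` writes the significant pairs as a directed edge list
sorted by absolute difference.

## The simulator

`make_scenario()` / `simulate_logs()` generate data from exactly the
model above, for testing and parameter-recovery studies. Reference
design: 400 individuals, 50 actions of which the first 10 are key
actions, five covariates i.i.d. $N(0, 4)$, and sequence lengths from a
negative binomial truncated at two. The four presets differ in group
heterogeneity: S1 — no group differences and no key effects but nonzero
$\beta$; S2 — key-action effects shared by both groups; S3 — a fraction
of baseline hazards (default 30%) multiplied by 2 in the correct group;
S4 — hazard heterogeneity *and* group-specific key effects. The scenario
table in the source material is not machine-readable, so these presets
are reconstructions of the described design, and every knob is
overridable.

Choices the design left open, fixed once here: negative-binomial
parameters $r = 5$, $p = 0.15$ (mean ≈ 28, variance well above the mean,
resembling real item logs); true baseline hazards drawn log-uniform on
$[0.5, 2]$ under a fixed construction seed separate from the data seed,
so "truth" is reproducible while datasets vary; initial state uniform;
group assignment Bernoulli(0.5); true speeds drawn from the Gamma(1, 1)
prior (set `theta_fixed = TRUE` for unit speeds). Data generation follows
the continuous-time mechanism — exponential sojourns at the total
outgoing rate, embedded-chain next states — with one extra sojourn after
the last action setting the total time, so the final exposure is censored
exactly as the model assumes.

`run_replications()` repeats generate → fit → score: per individual, the
plug-in (posterior-mean) transition matrix is compared to the truth by the
mean squared difference over all $E^2$ entries, individual MSEs are
averaged into one value per run, and runs are summarised boxplot-style.
The plug-in convention (posterior means of parameters, not per-draw
matrix averaging) is deliberate and switchable via
`predict(fit, type = "draw_mean")`.

**What the simulator does not emulate.** Real interfaces constrain which
transitions are physically possible; the simulator allows all off-diagonal
transitions. Real logs contain repeated identical events, action
vocabularies in the hundreds, missing or truncated sessions, and
covariates that are neither normal nor independent. Passing recovery
tests on simulated data therefore demonstrates the estimator is
consistent with its own generative assumptions — not that those
assumptions hold for any particular assessment item.

## Numerical choices and degenerate inputs

* Weighted 2×2 tables with a zero margin get chi-square 0 rather than NaN.
* Tied timestamps within a respondent keep file order (stable sort); the
  source logs do not specify a rule, and determinism matters more than the
  choice.
* The HPD window size is $\lceil \text{level} \cdot n \rceil$ sorted draws;
  at least 20 draws are required.
* $\hat R$ for a parameter with zero variance everywhere (a fixed block)
  is `NA`, not 1.
* Hazard initialisation floors empirical rates at $10^{-3}$ so pairs with
  zero counts start at a finite log.
* Exposure bookkeeping is exact: $\sum_m e_{im} = T_i - t_{i1}$ to
  floating-point accuracy, asserted on every simulated dataset.
* Fits are byte-reproducible under a fixed seed; all randomness flows
  from the `seed` in `msm_control()` and the scenario seed.

## Scale of the built-in checks

The bundled checks run at desk scale: convergence and acceptance-window
checks use one scenario-S1 dataset with 100 individuals, 10 actions (2
key) and 2 covariates, fitted with 5 chains of 5,000 iterations (2,000
burn-in, thin 5); recovery uses 20 replications at that size plus 10 at
N = 50 with single short chains; the sampler-correctness check uses a
two-state dataset and 15,000 iterations. These sizes were chosen so the
whole suite runs in a couple of minutes while leaving every conclusion
qualitative-stable under larger runs; the `"paper"` preset in
`msm_control()` is the faithful large-scale setting.

## Known limitations

* Time-homogeneity is assumed, not tested; semi-Markov or
  time-inhomogeneous variants are out of scope.
* $\beta$ is shared across groups and transitions by design.
* Baseline hazards and speeds are identified jointly only up to the prior
  centring (see the ridge discussion); compare products or renormalized
  draws across fits, not raw scales.
* No model-fit criterion (WAIC, posterior predictive p-values) is built
  in; `simulate()` on a fit provides raw material for posterior
  predictive checks.
* The per-pair HPD significance rule makes no multiplicity adjustment;
  with many supported pairs, expect the nominal share of false flags
  under group equality (this rate is itself checked in the test suite).
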