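---
title: "Modelling panic-buying contagion and social interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling panic-buying contagion and social interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(panicabm)
library(dplyr)
```

## The model

`panicabm` simulates how panic buying of essential goods spreads through a
population during a sudden crisis, and how five kinds of social intervention
suppress it. It is a discrete-time, agent-based Monte Carlo model: `N`
agents sit on a fixed Barabási–Albert (BA) scale-free network, the natural
choice for a social-interaction substrate because a few well-connected
individuals (designated *opinion leaders*, the top 5% by degree) reach a
disproportionate share of the population.

Each agent `i` carries:

* a **material need** $M_i(t) \in [0,1]$ and a constant **safety need**
  $S_i \in [0,1]$ (safety information comes from official news and is not
  updated by the model),
* a **panic emotion** $E_i(t) = \alpha M_i(t) + \beta S_i + F_i(t)$, where
  $F_i(t) = \frac{NI_i(t-1)}{N_i(t-1)}\,Con(i)$ is herd pressure: the
  fraction of `i`'s neighbours who bought last tick, scaled by `i`'s
  conformity,
* a **buying attitude**
  $A_i(t) = \theta_1\,(\alpha M_i + \beta(1 - S_i)) + \theta_2\,E_i$ with
  emotion-derived weights $\theta_1 = |1-E_i|$, $\theta_2 = |E_i|$: the more
  panicked an agent, the less the rational need term counts,
* a binary **buying state**, `1` exactly when $A_i(t) \ge d_A$. The state
  is memoryless — agents drop out of buying as soon as their attitude falls
  back below the threshold.

A shared **material stock** starts at $Q(1) = 1$ (one unit satisfies the
whole population's basic purchases once) and each buyer consumes $1/N$ per
tick. Buyers reach the shelves in a uniformly random order; the `k`-th
buyer perceives $Q_i = Q(t-1) - k/N$ and translates scarcity into need via
the *self experience* $\mu\,(d_{SD} - Q_i)$: shelves below the
supply–demand threshold $d_{SD}$ push the buyer's need up, full shelves
relax it. Non-buyers instead absorb their buying neighbours' posts: the
trust-weighted mean attitude excess $\sum_j (A_j - d_A)\,TR(j) / NI_i$.

### Interventions

Five mechanisms are independently switchable; a disabled mechanism
contributes exactly zero to every update:

* **Supply monitoring** (offline): whenever the depleted stock falls below
  $d_{SD}$, `q_move` units are moved in; events are counted per run.
* **Information review + guidance** (bundled, since review is the
  prerequisite of guidance): a buyer's post is classified as truth when the
  poster's buying tendency is consistent with actual scarcity
  ($(A_j - d_A)(d_{SD} - Q) \ge 0$), as rumor otherwise. Guidance multiplies
  the post's influence by $+\gamma$ (truth) or $-\gamma$ (rumor), and the
  whole influence lands `t_exam` ticks later than it otherwise would.
* **Official response**: a persistent, trust-scaled reduction of material
  need, $\lambda_1\, Gov \cdot TR_{gov}$ per tick after onset.
* **Psychological counseling**: the emotional counterpart, subtracting
  $\lambda_2\, Str_{PR} \cdot TR_{ol}$ from panic emotion after onset.

The printed form of the counseling-modified emotion update omits the
$PR(t)$ factor after $\lambda_2$; the surrounding definitions make clear
the intended term is $-\lambda_2 PR(t)$, which is what the package
implements.

**Onset convention.** The disturbance starts at tick 1, and a mechanism
with delay `d` first acts at tick `1 + d + 1` — the first update that can
use it — then persists every tick. Persistence (rather than a one-shot
effect) is the only reading consistent with the sustained decay of buyer
counts that the delayed-response and low-trust experiments show.

### Tick pipeline

Updates are synchronous. Per tick `t ≥ 2`: deplete the stock by the
previous tick's buyers; replenish if supply monitoring is on; draw random
purchase orders among previous buyers; previous buyers compute perceived
stock and self experience while previous non-buyers receive matured
neighbour information; update material need (minus any official effect);
compute herd pressure from previous-tick states; update emotion (minus any
counseling effect); recompute weights, attitude, and buying state. Buyers
then publish posts consumed `1 + t_exam` ticks later. Tick 1 records the
initialized population: needs and conformity drawn from normals clipped to
$[0,1]$, emotion and attitude evaluated with no herd pressure (there is no
prior tick), and full stock.

## Default parameters

| Parameter | Default | Meaning |
|---|---|---|
| `N` | 1000 | population (network nodes) |
| `m_attach` | 3 | BA attachment edges per node (mean degree ≈ 6) |
| `leader_fraction` | 0.05 | top-degree share flagged opinion leaders |
| `alpha`, `beta` | 0.6, 0.4 | material vs safety weight (`alpha > beta`: physiological needs dominate) |
| `mu` | 0.2 | self-experience influence |
| `d_SD`, `d_A` | 0.65, 0.6 | supply–demand and buying thresholds |
| `gamma` | 1 | authenticity influence under review |
| `lambda1`, `lambda2` | 0.2, 0.2 | official / counseling influence |
| need levels | 0.2 / 0.5 / 0.8 | low / medium / high means, sd 0.15 |

`m_attach` is a free choice; 3 is the standard BA density giving mean
degree ≈ 6 at `N = 1000`, and it is exposed in `network_params()`. Trust
defaults are 1 for both roles in the generic experiments; the case presets
override `tr_ol = 0.8` (and the UK cases `tr_gov = 0.5`). The review delay
`t_exam` defaults to 1 tick wherever the review mechanism participates in a
combined strategy, since only the dedicated review study varies it.

## What the generator emulates — and what it does not

The synthetic population *is* the study design: initial needs and
conformity are independent clipped normals, the network is regenerated per
replicate seed, and every random ingredient (network growth, initial
draws, purchase orders, posting) runs on an independent derived stream so
that toggling one mechanism never perturbs another's randomness. What this
does **not** capture about real crises: correlated needs within households
or districts, heterogeneous trust, price dynamics, media shocks arriving
mid-run, or agents leaving the market after hoarding. Passing tests
therefore validate the mechanism arithmetic and the qualitative
intervention orderings, not forecasts for any real event.

## Numerical choices

* All state variables are clamped to $[0,1]$ after each update and the
  stock floored at 0; the raw recursions can exit these declared ranges.
* The buying threshold is inclusive ($A \ge d_A$ buys) and ties at the
  opinion-leader degree cutoff break by ascending node id.
* An agent with no buying neighbours has zero neighbour influence (the
  0/0 guard) and an isolated agent zero herd pressure.
* Buyers perceive the *previous* tick's recorded stock; a config switch
  (`perceive_current_stock`) lets them see the current post-replenishment
  stock instead, for sensitivity analysis.
* The official strength may exceed its nominal $(0,1)$ range (the China
  case uses 10); the constructor warns but accepts.
* Replicate `r` runs at seed `base + r`; identical configuration and seed
  give byte-identical CSV output.

## Worked example

```{r example}
cfg <- simulation_config(
  network = network_params(n_agents = 500),
  needs = needs_spec(m0_mean = 0.8, s0_mean = 0.2),
  interventions = intervention_config(supply_enabled = TRUE, q_move = 2),
  horizon = 20, seed = 42
)
sim <- run_simulation(cfg)
glance(sim)
```

```{r replicates}
reps <- run_replicates(cfg, replicates = 5)
glance(reps)
```

```{r plot, fig.width = 6, fig.height = 5}
autoplot(sim)
```

The experiment harness reproduces the study designs directly:
`scenario_library()` lists every preset (need grids, single-intervention
studies, the ten combination strategies, the comprehensive plan, and the
China/UK case parameterizations); `combination_study()` returns the 12-row
strategy table; `needs_sweep()` draws random initial need means and records
final buyer counts under three intervention regimes.

## Problem sizes

The shipped tests and the acceptance script use the full `N = 1000`
population with horizons of 20–30 ticks for single studies, 30 replicates
for aggregate statistics, and the 100-run sweep at horizon 100 — a few
seconds to a couple of minutes on one CPU. Unit tests exercise the same
code paths at `N = 100`–`300` for speed.

## Known limitations and model behaviour

Two structural properties of the update equations are worth knowing before
interpreting single simulated realizations:

* **High initial uptake.** With the tick-1 initialization
  ($E = \alpha M + \beta S$, no herd pressure), a low-safety/high-material
  population already has mean attitude ≈ 0.67 > $d_A$, so most agents buy
  at tick 1. Interventions, which can first act at tick 2 or later, cannot
  reduce the *peak* much in that regime — they shorten the outbreak
  instead.
* **Strong herd amplification.** The herd term adds up to `Con(i)` to
  emotion, and with emotion-weighted attitudes this feedback is
  self-reinforcing: at medium needs an initial ~15% uptake amplifies
  toward saturation within a few ticks unless a persistent intervention
  drains material need. Consequently intermediate, slowly-decaying buyer
  counts are rare: runs tend to either die out or saturate, and
  replenishment-event counts under supply monitoring are correspondingly
  high while buying persists.

Within those dynamics the qualitative intervention findings hold and are
covered by tests: supply-containing strategies stop the outbreak while the
comprehensive plan ends every run of the random-needs sweep; higher
material need weakly increases replicate-mean peaks; supply monitoring
weakly shortens stop times when combined with an official response; and
the information+psychology combination (no stock or need drain) never
stops on its own.

The forgetting of past experience, heterogeneous per-agent need weights,
agent birth/death, and dynamic network growth are outside the model's
scope.
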