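---
title: "Coupled snowdrift / prisoner's dilemma dynamics under social influence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled snowdrift / prisoner's dilemma dynamics under social influence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Two square `L x L` lattices with von Neumann (4-neighbor) interactions and
periodic boundaries are coupled point-to-point: every player has exactly one
partner at the same coordinates of the other layer. One layer plays the
snowdrift game, the other the prisoner's dilemma. Both 2x2 games use
temptation `T = b`, reward `R = 1` and sucker's payoff `S = 0`; the
punishment alone distinguishes them, `P = 0.2` in the PD layer (ranking
`T > R > P > S`, mutual defection is the unique equilibrium) and `P = -0.2`
in the SD layer (ranking `T > R > S > P`, which favors mixed C-D pairs).
Keeping `S` shared and moving only `P` is the minimal change that switches
between the two rankings, and `1 < b <= 2` preserves both.

Dynamics are asynchronous random-sequential Monte Carlo. One elementary
update draws a layer (uniformly), a site (uniformly among `L^2`), and then a
branch:

* with probability `s` (**social influence**), the player looks at its
  *partner group* on the other layer — the partner plus the partner's four
  neighbors, five members in all — and adopts the group's majority strategy
  (3-of-5; no ties are possible). With probability 0.1 the draw is
  *conformity noise* instead of strict majority learning (next section);
* with probability `1 - s` (**Fermi imitation**), the player picks one of
  its four same-layer neighbors uniformly, both accumulate payoffs by
  playing all four of their neighbors, and the focal player adopts the
  neighbor's strategy with probability
  `W = 1 / (1 + exp((P_x - P_y) / K))`, `K = 0.1`. Payoffs are recomputed
  fresh at every imitation event; nothing is cached across updates.

A full MC step performs `2 L^2` elementary updates, so each player across
both layers is selected once on average. `s = 0` reduces the system to two
independent single-lattice games (verified in the test suite against a
separately written single-lattice implementation); `s = 1` removes payoffs
from the dynamics entirely.

## The conformity-noise convention

"With probability 0.1 the player chooses a strategy at random" admits
several readings, and they are *not* equivalent. The package implements four
(argument `noise_mode` of `game_params()`):

* `"set"` (default): a uniform choice among the **distinct strategies
  present in the partner group**. A mixed group yields a fair coin; a
  unanimous group offers only its own strategy.
* `"uniform"`: a fair coin between C and D regardless of the group.
* `"member"`: copy one uniformly chosen group member (proportional rather
  than uniform over the distinct strategies).
* `"abstain"`: keep the current strategy.

The modes differ in one decisive respect: whether noise can inject a
strategy into a region where it is extinct. Under `"uniform"`, a fraction
`s * 0.1 / 2` of all updates plants a lone defector inside cooperating
territory (and vice versa). A lone defector surrounded by four cooperators
earns `4b`, the largest payoff in the entire system, so every such seed is
an aggressive nucleus of invasion; at `b = 1.1` this sustained seeding
destroys any cooperator-dominated state at *every* influence strength — no
amount of conformity can repair blisters as fast as they are planted and
expanded. Unanimous dominance of either strategy, and with it the abrupt
defection-to-cooperation outbreak that is the model's signature, exists only
under the injection-free readings, where unanimous configurations are
absorbing. Among those, `"set"` noise is the strongest interface
perturbation (a fair coin wherever the group is mixed), `"member"` is
proportional and milder, `"abstain"` removes noise from the strategy space
altogether. The outbreak threshold moves accordingly: near `s ≈ 0.38` for
`"abstain"`/`"member"` and near `s ≈ 0.46` for `"set"` at the package's
default protocol. `"set"` is the default because it is the reading that
keeps noise meaningful (it acts wherever there is local disagreement)
without granting it the unphysical power to resurrect extinct strategies,
and because the resulting regime structure — coexistence, extinction window,
outbreak near 0.47, absorbing full dominance — is the documented behavior of
this class of model. The `"uniform"` reading remains available and is
exercised by the validation oracle; under it the all-defector state is not
absorbing (a cooperator appears per update with probability `s * 0.05`).

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `b` | 1.1 | shared temptation; dimensionless payoff |
| `s` | 0.5 | social influence strength, in [0, 1] |
| `K` | 0.1 | Fermi uncertainty; smaller = more deterministic imitation |
| `P_pd`, `P_sd` | 0.2, -0.2 | layer punishments (set the two rankings) |
| `noise_prob` | 0.1 | conformity-noise probability inside the social-influence branch |
| `L` | 100 | lattice linear size |
| `relax`, `avg` | 20000, 2000 | relaxation and averaging MC steps |
| `runs` | 10 | replicate seeds per parameter point |

The steady-state protocol (`L = 100`, `2e4 + 2e3` MC steps, 10 replicates)
is the package's desk-scale default: it resolves the outbreak threshold to
the grid spacing 0.01 in a few minutes of CPU time, while every experiment
driver accepts larger `L` and longer runs for higher-precision studies. The
observables per point are time averages over the final `avg` steps,
replicate-averaged with a standard error across seeds.

## Observables and phase classification

Per state the package records the cooperation frequency of each layer
(`f_c`, fraction of cooperators; the system value is the mean of the two
layers) and the interlayer pair frequencies: C-C and D-D (identical partner
pairs), C-D (cooperator in SD over defector in PD) and D-C (the reverse).
The four pair categories partition the `L^2` partner pairs, so
`f_cc + f_dd + f_cd + f_dc = 1`, `f_c(SD) = f_cc + f_cd` and
`f_c(PD) = f_cc + f_dc` hold exactly; the test suite asserts them on every
recorded state. The synchronization index `f_cc + f_dd` quantifies how far
the two layers have coordinated (1 = identical grids, 0.5 = independent).

A time-averaged `f_c` is classified as phase `D` below `epsilon = 0.01`,
`C` above `1 - epsilon`, else `C+D`. The tolerance exists because finite
runs near a transition need not have absorbed yet; 0.01 sits well below any
genuine coexistence level observed at small `s` (a few percent at least)
and well above the floating noise of an averaged absorbed trajectory (zero
under the default noise mode). Replicate phase labels are combined by
majority; the (rare) ties resolve toward the defection-leaning label so
that threshold brackets err conservatively.

## Threshold detection

The outbreak threshold `s_o` is located in two stages: a sweep over an `s`
grid records majority phase labels, the *last* D -> C label change along
increasing `s` gives the initial bracket, and bisection on fresh replicated
probe runs narrows the bracket to 0.005. Bisection on the *label* (rather
than on `f_c` values) is appropriate because the transition is
first-order-like: trajectories commit to one absorbing state, so the label
is a robust binary observable. The same machinery detects the vanishing
threshold `s_v` (last non-D -> D change along `s`) and the critical
temptation `b_c` (same rule along `b`). If the scanned grid does not
bracket the change, the driver extends the grid rather than failing, and
reports `bracketed = FALSE` only when no change exists in the admissible
range.

Near the threshold the dynamics are metastable: individual replicates at,
say, `s = 0.45` occasionally outbreak at `L = 100` while the majority go
extinct. This is why points are classified by replicate-majority label, and
why reported thresholds carry their bracket rather than a standalone point.

## Initial conditions

Two initial-state generators cover the experiments. `random_initial()`
assigns C/D independently with probability 1/2 per site per layer — the
standard disordered start for steady-state measurements; at `L = 100` its
per-layer `f_c` lies within [0.45, 0.55] except with probability below
`1e-3`, and the layers are independent (synchronization ≈ 0.5).
`block_initial()` places a centered `L/2 x L/2` cooperator square at the
same position on both layers; it is a constructed, synthetic preparation
(the geometry is not uniquely determined by the phenomenon it illustrates)
used to visualize how a compact cooperative domain splits, dies or expands
under the different regimes. Conclusions in the test suite rest on the
random starts; block starts feed only the snapshot machinery.

These generators emulate idealized conditions: no empirical system supplies
50/50 random strategy assignments or perfect square domains. Passing tests
therefore demonstrate internal consistency of the model and reproduction of
its published phenomenology, not predictions about any empirical social or
biological population.

## Numerical choices

* The Fermi exponent is clamped to ±500 before exponentiation; at `b = 2`
  and `K = 0.1` the true exponent magnitude reaches 96, so the clamp is
  inert in admissible parameter ranges and exists purely as overflow
  armor. Clamped probabilities are 0/1 to machine precision.
* The engine uses a dedicated xoshiro256++ generator seeded via splitmix64
  from the run's integer seed, consuming draws in a fixed documented order
  (layer+site+branch from one 64-bit word; branch-specific draws from the
  next). Identical seed and configuration give bit-identical trajectories,
  independent of R's RNG state. Replicate `k` of a point uses consecutive
  seeds from the point's base seed; initial states draw from R's RNG seeded
  with the same integer.
* Under injection-free noise modes, unanimous two-layer states are
  absorbing; the engine detects them after each MC step and short-circuits
  the remaining steps with the (exactly constant) trajectory. This is a
  pure optimization: recorded observables are identical to full simulation.
* Fermi adoption probabilities are precomputed for all 200 local
  configurations (layer x strategy x neighbor counts squared), so the inner
  loop is exp-free.
* The single-run standard error reported by `steady_state_average()` treats
  recorded steps as independent, which underestimates the error on
  autocorrelated stretches; across-replicate standard errors (the default
  for every sweep) do not have this problem and are what the experiment
  drivers report.
* The exact-enumeration oracle treats the Fermi adoption as a two-outcome
  branch with its closed-form probability and never samples; the engine is
  validated against it by chi-square on 1e5 sampled updates per instance,
  with expected counts below 5 pooled.

## Known limitations

* Square lattices with von Neumann neighborhoods only; no other topologies,
  degree heterogeneity, or more than two layers.
* No finite-size scaling analysis: thresholds are reported at the protocol's
  `L` with their bracket, not extrapolated to the thermodynamic limit. The
  critical temptation `b_c` is detectable but has no external reference
  value to compare against.
* The sweep drivers run replicates sequentially on one core.
* Negative sucker's payoffs are admitted by the parameter validation (the
  rankings still hold for small `|S|`) but no experiment exercises them.
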