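---
title: "The ant-trail traffic model: dynamics, communication states, and measurement"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ant-trail traffic model: dynamics, communication states, and measurement}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anttrail)
```

## The model

`anttrail` simulates unidirectional ant traffic on a periodic
one-dimensional trail of `L` cells, each holding at most one ant
(hard-core exclusion, no overtaking, no backward motion). Ants are agents
with a continuous position `p` in `[0, L)` and a continuous velocity `v`
in `{0} ∪ [vmin, vmin + a·σsat]` cells per step; the cell an ant occupies
is `floor(p)`. Each cell carries a pheromone concentration `σ` in
`[0, σsat]` — the communication medium. The trail is the blackboard of a
stigmergic system: ants write by depositing pheromone and read by sensing
the concentration one cell ahead.

Each time step has two stages.

**Stage I — motion.** Every ant's velocity is computed in parallel from
the time-`t` occupancy and pheromone of the cell ahead:

1. cell ahead occupied → `v = 0` (exclusion);
2. cell ahead empty, `σ < 1` (below the differentiable level): with
   probability `P` the ant slows to `max(v_prev − 0.1, vmin)`, otherwise
   it keeps `v_prev` (an ant coming out of a block carries `vmin`);
3. cell ahead empty, `1 ≤ σ < σsat`: deterministic chemotaxis
   `v = vmin + a·σ`;
4. cell ahead empty, `σ ≥ σsat`: the antenna saturates,
   `v = vmin + a·σsat`.

All positions then advance by `p ← (p + v) mod L`. Because
`vmin + a·σsat ≤ 1` is enforced, an ant crosses at most one cell boundary
per step, and only the unique ant immediately behind an empty cell can
enter it — the parallel update can never produce a collision.

**Stage II — pheromone.** Every cell first evaporates,
`σ ← σ·(1 − re)`, then occupied cells deposit `τ` units, clamped at
`σsat`. Occupancy and velocities are those of the start of the step.

After Stage II a new ant is injected at cell 0 (position `0.0`, velocity
`vmin`, id `N`) with probability `inflow` whenever the entry cell is
empty. A run starts from a single ant on a pheromone-free trail and
sweeps slowly through every density until the trail is full, so the
per-step record of density, mean velocity and flow (`f = d·v_avg`) traces
out the full fundamental diagram in a single run.

### Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `L` | 1000 | cells | trail length (periodic) |
| `re` | 0.02 | fraction/step | pheromone evaporation rate |
| `tau` | 1 | units/step | deposit per occupied cell per step |
| `sigma_sat` | 80 | units/cell | antenna saturation |
| `vmin` | 0.15 | cells/step | velocity with no readable signal |
| `a` | 0.01 | cells/step/unit | chemotaxis gain (`a·σsat = 0.8`) |
| `P` | 0.7 | — | slowdown probability in the meager case |
| `inflow` | 0.001 | — | injection probability per step |

The defaults are the reference conditions of the model: the top speed is
`vmin + a·σsat = 0.95 < 1`, and the slow inflow (`≪ 1`) gives traffic
time to establish at every density, which is why the fundamental-diagram
binning applies no burn-in by default (`burn_in` remains available as a
knob).

## The deposit rule

The model description states the per-case pheromone update with a
"deposit only if the ant moved this step" condition. We expose both
readings as `atm_params(deposit = )` and default to deposition by *every*
occupied cell, for two reasons.

First, the model's own aggregation theory requires it. The closed-form
concentration behind a platoon, `σ(M) = τ·Σ_{k=1..M}(1−re)^k`, counts one
deposit for every step a tightly packed platoon occupies the cell — and
under exclusion the members of a tightly packed platoon are necessarily
blocked most of the time. If blocked ants deposited nothing, the series
would have no deposits to sum.

Second, the headline traffic phenomenology depends on it. With
deposition by occupied cells, standing platoons saturate their own cells,
so a freed follower accelerates sharply ("slow in, fast out"); the
free-flow phase then extends to high density, the average velocity
spikes just before the jamming phase (the "rise-up"), and the critical
density at `re = 0.02` lands near 0.8 on the reference trail. Under the
literal moved-only rule (`deposit = "moving"`), jammed regions leave no
signal: we measure the flow peak at ≈ 0.575 with no rise-up at all.
Tests cover both rules; all fundamental-diagram results in this package
use the default.

## The pheromone calculus and the three communication states

The analytics module carries the closed forms, all per-cell:

* **finite aggregation** `finite_aggregation(tau, re, M)` =
  `τ·Σ_{k=1..M}(1−re)^k` — the concentration a cell reads after a platoon
  has streamed through it for `M` steps. The reading is taken after each
  step's evaporation (the value the *next* arriving ant can sense), which
  is why the sum starts at `k = 1`: in the simulator this corresponds to
  reading the cell one evaporation after the `M`-th deposit. The
  deterministic single-cell trace `aggregation_fixture()` reproduces it
  term for term.
* **converged aggregation** `converged_aggregation(tau, re, sigma_sat)` =
  `min(τ(1−re)/re, σsat)` — the infinite-platoon limit, the highest
  concentration any cell ever approaches.
* **depletion time** `depletion_time(sigma0, re)` =
  `max(0, −ln σ0 / ln(1−re))` — steps of pure evaporation until the
  signal falls below the differentiable level 1.
* **boundaries.** The channel saturates (and stops carrying local
  information) when the converged aggregation reaches `σsat`:
  `re = τ/(σsat + τ)` (`inactive_state_boundary`, 0.0123 ≈ 0.012 at the
  defaults). The signal dies before the closest possible follower — one
  cell behind, travelling at `vmin` — can read it when the converged
  aggregation decays below 1 within `D = 1/vmin` steps (≈ 6.67, printed
  6.66 at two-decimal truncation): the root of
  `τ(1−re)/re·(1−re)^{1/vmin} = 1` (`minimal_state_boundary`, 0.1932 ≈
  0.19). The inverse of the first relation gives the emission rate that
  first saturates a trail, `saturation_tau(re, sigma_sat)` =
  `σsat·re/(1−re)` (1.63 at `re = 0.02`).

`classify_state()` labels an evaporation rate **minimal** (`re` above the
minimal boundary: information is discarded before it can be read, ants
fall back to `vmin` and exclusion only), **active** (between the
boundaries: the concentration encodes the flow through the cell in the
recent past, the regime that produces platoons and congestion-free
traffic), or **inactive** (below the inactive boundary: the channel
saturates and carries no local information). Boundaries are compared at
the precision at which the analysis quotes them (two decimals for the
minimal boundary, three for the inactive one; `digits = c(Inf, Inf)`
compares the raw roots), and the boundaries themselves belong to the
active state.

In the minimal-boundary equation we use the exact `D = 1/vmin = 6.667`
rather than the truncated 6.66; the difference does not move the
two-decimal root. The root is found by bisection on
`(10⁻⁶, 1 − 10⁻⁶)` to absolute tolerance `10⁻⁸` — the residual is
strictly decreasing, so bisection is unconditionally safe; tests
cross-check it against `stats::uniroot` and a dense-grid scan.

## Measurement conventions

The model analysis reads critical densities off fundamental diagrams
without giving a formula, so the estimator here is a declared
convention: bin the per-step metrics by density (default width 0.005),
average flow per bin, smooth with a centered moving average (default 5
bins, shrinking at the edges), and take the bin center with maximal
smoothed flow, breaking ties toward lower density. The convention is
validated against the reference value ≈ 0.8 at `re = 0.02` and behaves
consistently in all three regimes, including the rise-up case where the
flow peak *is* the free-flow/jamming junction.

Platoons (`detect_platoons()`) are maximal runs of ants separated by at
most `gap_threshold` empty cells on the ring (default 2, configurable
and reported with results) — the analysis gives no operational
definition, so the threshold is a convention, not a claim.

## Numerical and design choices

* Cells are indexed 0..L−1 internally; an ant occupies `floor(p)`;
  "ahead" means `(floor(p)+1) mod L`.
* The initial ant and every injected ant start at velocity `vmin` (the
  natural resting value given the meager-case floor; the description is
  silent), positioned at the left edge of the entry cell. Injection
  happens after Stage II against post-update occupancy; any fixed order
  would do, this one is simplest.
* A blocked ant (`v = 0`) that frees into a meager-pheromone cell
  carries `vmin` as its remembered velocity — with `v_prev = 0` the
  keep-branch of the meager case would otherwise be ill-defined.
* One seeded generator drives everything, consumed in a fixed documented
  order (per ant in ascending id when and only when the meager case
  applies, then one draw per step for injection), so whole runs are
  bit-reproducible. The optimized C++ stepper and the naive R reference
  stepper consume R's own RNG identically and produce bit-identical
  trajectories — an invariant under test.
* Runs stop at density 1 or at `max_steps` (default 5·10⁶) to bound
  runtime at extreme parameters; truncated runs are flagged.
* `inflow = 0` is allowed (a closed ring), used by the deterministic
  two-ant exclusion fixture.

## Problem sizes used in the tests

The full reference protocol (`L = 1000`, `inflow = 0.001`, run to
density 1) takes a few million steps per run with the compiled stepper.
The reference-scale checks cap runs at 4·10⁶ steps, which truncates the
hole-limited crawl from density ≈ 0.98 to gridlock — the flow peak sits
far below that, so the critical-density estimate is unaffected while the
runtime drops by roughly a third. The acceptance checks run that capped
reference protocol with three seeds, and run the evaporation-rate sweep
(`re ∈ {0.005, 0.01, 0.02, 0.05, 0.1}`, three seeds each) on the
proportionally scaled trail `L = 200`, `inflow = 0.005`.
Regime-signature checks use the same scaled trail. Property and
equivalence tests use rings of 30–50 cells.

## What the simulations do and do not show

The generator emulates the idealized trail of the model: homogeneous
cells (no per-cell resistance), a single lane, periodic boundary, one
pheromone species with linear evaporation and saturating additive
deposition, and slow recruitment at a single entry point. Real ant
trails are open systems with heterogeneous substrate, bidirectional
traffic, multiple recruitment mechanisms and receptor dynamics (the
response-threshold side of the pheromone channel is not modelled at
all). Passing tests therefore validate the model's internal consistency
and its agreement with the closed-form pheromone calculus — not
quantitative claims about living colonies.

Two further caveats. The rise-up is a property of the model's
information dynamics at densities real trails avoid; it should be read
as a diagnostic of the communication mechanism, not a prediction. And
the location of the optimum evaporation rate is scale-dependent in this
implementation: on the scaled trail (`L = 200`, `inflow = 0.005`) the
sweep of critical density against evaporation rate peaks at
`re = 0.02` (≈ 0.68, with ≈ 0.63 at `re = 0.01` and a collapse to
≈ 0.46 at `re = 0.005`), while at the reference scale (`L = 1000`)
`re = 0.01` edges slightly ahead (≈ 0.80 against ≈ 0.77 at
`re = 0.02`). On a short ring an ant re-encounters its own decaying
trail sooner, which punishes the near-inactive rates much harder; the
rise-and-fall shape of the sweep is robust across scales, the exact
ranking of the two adjacent grid points near the optimum is not.

## A worked example

```{r example, eval = FALSE}
library(anttrail)

params <- atm_params(L = 200, inflow = 0.005, re = 0.02, seed = 1)
run <- atm_run(params)
fd <- bin_fundamental_diagram(run$metrics)
critical_density(fd)

classify_state(re = 0.02)
analytics_report(re = 0.02)

detect_platoons(run$final$positions, L = params$L, gap_threshold = 2)
```
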