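---
title: "The replicells model: protocell reproducers and genetic-element replicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The replicells model: protocell reproducers and genetic-element replicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(replicells)
```

## The model

`replicells` simulates the coevolution of two kinds of propagating entities:
*reproducers* — protocells that grow by acquiring resources and propagate by
dividing their whole organization — and *replicators* — genetic elements
(GE) that are copied from a template inside a host protocell. The central
question the model addresses is under which conditions element-carrying
protocells outcompete element-less ones, i.e. when a primordial
reproducer–replicator symbiosis can become established.

### Protocell level: discrete resource-supply rounds

Time is discrete; one round is one resource-supply cycle. A fixed supply of
`R` resource units enters a well-mixed volume each round, and each protocell
can acquire **at most one unit per round**. When the population size `N`
exceeds `R`, a uniformly random subset of `R` cells is fed (the cell list is
randomly permuted and the first `R` cells in the permuted order each gain one
unit); leftover supply is discarded, never carried over. Every cell then pays
a housekeeping cost `dE` and is removed if its balance `B` is no longer
positive (`B - dE <= 0`, boundary inclusive).

A cell whose balance has reached the reproduction threshold `Etr` attempts
division once per round: with probability `p` it is replaced by two
daughters; with probability `1 - p` it dies, losing all resources and
elements. For element-less cells `p = p0`. The round schedule is

1. permuted feeding,
2. housekeeping and culling,
3. intracellular element phase (element-carrying cells only),
4. reproduction attempts (`B >= Etr`, evaluated once, after the element
   phase),
5. stochastic death with probability `nu` per cell, daughters included.

Newborn daughters first act in the following round: rounds are defined by
supply events, so a cell born mid-round has had no opportunity to feed. The
element phase sits between culling and reproduction so that the
reproduction probability sees the element counts *after* this round's
replication; the schedule is isolated in one place (`step_round()` and the
compiled loop behind `run_rounds()`) so this choice can be revisited.

For a single population the stationary size is approximated by the
resource-balance argument implemented in `equilibrium_estimate()`:

$$N^\* \approx \frac{R\,(1 + p)}{2\,\Delta E},$$

valid for `p > 1/2` and `dE` well below 1. The approximation takes the mean
cell balance as `Etr / 2`; under symmetric resource division the realized
mean balance is slightly larger, so the simulated population sits slightly
above the estimate — both behaviors are exercised in the test suite. Along
the slope `neutral_tradeoff_slope(p0, dE0) = (1 + p0) / dE0` a joint
increment `(dp, de)` leaves `N*` unchanged, which is the axis against which
the trade-off experiments (`run_tradeoff_grid()`) measure the asymmetry
between raising the reproduction probability and paying for it.

```{r equilibrium}
equilibrium_estimate(R = 30, p = 0.6, dE = 0.3)
st <- population_state(30, protocell_params(p0 = 0.6, dE = 0.3, Etr = 5,
                                            division_mode = "random"),
                       R = 30)
st <- run_rounds(st, 3000, record_every = 1)
mean(st$history$n1[st$history$round >= 2000])
```

### Element level: propensity-sampled birth-death events

Inside a carrying cell, autonomous elements (A) replicate through the
interaction of two A copies (one acting as replicase, one as template);
nonautonomous elements (N) replicate only through interaction with an A
copy. Replication requires resources: the capacity `li = floor(B / Ec)`
counts how many replications the host balance can still fund, and each
replication charges `Ec` to the host. The four elementary processes have
propensities

| process | propensity | effect |
|---|---|---|
| A birth | `rA * li * mA * (mA - 1) / 2` | `mA + 1`, `B - Ec` |
| N birth | `rN * mN * mA * li` | `mN + 1`, `B - Ec` |
| A death | `dA * mA` | `mA - 1` |
| N death | `dN * mN` | `mN - 1` |

Each round, **exactly `K` events** are sampled per carrying cell with
probability proportional to propensity; waiting times are discarded (the
element process is assumed fast relative to the round scale, and `K` is the
coupling knob between the two timescales). `li` is recomputed before every
draw, so a birth can disable further births within the same round, and the
per-round drawdown is bounded by `K * Ec`. A zero-total-propensity draw
consumes one of the `K` events as a no-op, keeping "exactly `K` events"
literal. A balance driven to zero by replication does not kill the cell
mid-round; mortality is checked only at the housekeeping step.

### The compartment-free limit

With elements evolving in a well-mixed volume with resource supply rate
`r`, the deterministic (mass-action) limit implemented in `ge_ode_rhs()` is

$$\dot S = r - r_A S A^2 - r_N S A N,\quad
  \dot A = r_A S A^2 - d_A A,\quad
  \dot N = r_N S A N - d_N N.$$

The stochastic pair factor `mA (mA - 1) / 2` is absorbed into `rA` (the
regime classification is invariant to that constant rescaling, but note
that when comparing a *stochastic* run against the rule, the effective
autonomous rate is `rA / 2`). `classify_equilibrium()` applies the
closed-form condition: both classes collapse when `rN / rA > dN / dA`
(parasites overtake, suppress the replicase supply, then die without it);
the reversed inequality leaves the autonomous class alone; coexistence
requires the fine-tuned equality. The `"ode"` method cross-validates the
rule by integration (`deSolve::lsoda`, absolute tolerance `1e-10`; the
horizon doubles from 2000 until the state moves less than `1e-6` over its
final 10%, and a class counts as extinct below `1e-6`).

`simulate_ge_stochastic()` adapts the event sampler to the same
compartment-free setting. Two structural caveats, established while
validating it: with a fixed event budget per round, births are capped by
supply and deaths fill the remaining budget, so the *total* abundance
performs a neutral random walk — the regimes are visible in the
*composition* (which class vanishes first), robustly so at large
abundances; and the fine-tuned coexistence line is structurally unstable
to drift, so only the two strict regimes are asserted stochastically.

### Coupling: feedback between elements and host

Mutualist elements raise the host's reproduction success
(`reproduction_probability()`):

$$p(m_A, m_N) = \min\!\big(p_0\,(1 + f),\, 1\big),$$

with `f` the mutualist fraction among the cell's elements (autonomous
count by default; the swapped variant, `mutualist_class =
"nonautonomous"`, models mutualists that cannot replicate themselves).
Parasite-only and element-less cells reproduce at the bare `p0`, so
parasites hurt twice: they consume `Ec` per copy and dilute `f`.

Three division scenarios allocate the mother's resources and elements
(`divide_ge_random()`, `divide_ge_binomial()`, `divide_ge_symmetric()`);
all conserve `B`, `mA`, `mN` exactly:

* **uniform counts, proportional resources** — each class's count for
  daughter 1 is discrete-uniform on `{0, ..., m}` (endpoints included),
  resources proportional to total counts. A daughter can receive zero
  elements and zero balance; it is then culled at its first housekeeping
  step unless fed — division stays a pure allocation rule, mortality is
  handled in one place.
* **uniform resources, binomial counts** — daughter 1's share `B1` is
  uniform on `(0, B)` and every element goes to it independently with
  probability `B1 / B` (recomputed per division).
* **symmetric** — counts halved (integer part to daughter 1), resources
  proportional to counts.

The chance that a fixed daughter is *mutualist-only* (at least two
mutualists — the minimum self-replicating complement — and no parasites)
has closed forms, tested against independent oracles (exhaustive
enumeration, numerical integration, and Monte-Carlo through the operators
themselves):

```{r partition}
p_mutualist_only_random(3, 2)    # uniform-count rule
p_mutualist_only_binomial(3, 2)  # always smaller for mA > 1, mN >= 1
```

Under symmetric division a mutualist-only daughter is impossible whenever
the mother carries more than one parasite, which is why symmetric division
is the losing scenario throughout the phase diagrams: the stochastic
appearance of mutualist-only cells is the engine of element fixation.

### Seeding

`seed_initial_population()` starts a run with `Ng0` carrying and `No0`
element-less cells. The total element count per carrying cell is
Poisson(`mu`); by default one shared draw per simulation (so only the
mutualist fraction varies between cells), with independent per-cell draws
available behind `per_cell_draw = TRUE` — the two readings of the seeding
rule are both plausible, the shared draw is the more literal one and is
the default. The mutualist count is uniform on `{0, ..., m0}` inclusive,
giving a mean initial mutualist fraction of one half. Founding balances
default to independent Uniform(0, `Etr`) draws, which avoids synchronized
division artifacts; a fixed value is available via `init_B = "fixed"`.

## Default parameters

All defaults (`default_config()`, and the constructors' defaults) are the
standard competition setup: `R = 30`, `p0 = 0.6`, `dE = 0.3`, `Etr = 5`,
`nu = 0`, `rA = 0.01`, `rN = 1`, `dA = dN = 0.01`, `Ec = 0.01`, `K = 1`,
`mu = 100`, `Ng0 = No0 = 30`. Units: resources are the per-round feeding
unit (a cell ingests at most 1 per round); rates are per event-weight
unit; probabilities are per round. The founding sizes for the coupled runs
are not uniquely determined by the scenario; we mirror the two-population
convention (30 + 30) and expose both as configuration. The element-less
competitor divides by the plain random rule by default (`geless_division`),
matching the random-division baseline of the protocell-only model.

## Experiments

```{r fig3, eval = FALSE}
pc <- protocell_params(p0 = 0.6, dE = 0.3, Etr = 5)
res1 <- run_ge_competition(pc, ge_params(K = 1), seeding_spec(),
                           division = "ge_random",
                           spec = ensemble_spec(M = 30, T = 3000,
                                                base_seed = 1))
res1$gamma_mean   # ~0.97: element-carrying cells win at K = 1
```

`run_ge_competition()` tracks the counts of carrying (`ng`) and
element-less (`no`) cells — a carrying cell that loses its last element
*joins the element-less population* for all statistics, with no explicit
type change — together with the population-wide element fractions
(`ge_fractions()`). The final relative abundance
`gamma = ng / (ng + no)` is averaged over the ensemble; replicates in
which both populations are extinct are recorded as missing, excluded from
the mean, and counted in `n_double_extinct`. `run_phase_diagram()` sweeps
`(K, Etr)` lattices per division scenario, and `run_tradeoff_grid()`
sweeps `(dp, de)` increments for the element-less trade-off heatmaps,
whose winning boundary is summarized by `minimal_winning_dp()` (the raw
ensemble mean is always reported; thresholding at 1/2 is a presentation
choice, not part of the statistic).

Reproducibility: replicate `k` of an ensemble runs under
`base_seed + k`, so ensembles are bit-for-bit reproducible and
parallelizable in principle; every written summary embeds the exact
configuration and seed that produced it.

## Numerical choices

* Balances are real-valued (feeding adds integer 1; `dE` and `Ec` may be
  fractional). The capacity `floor(B / Ec)` is computed with a `1e-9`
  guard against binary round-off in repeatedly incremented balances.
* The round loop is implemented once, in compiled code; the exported
  per-phase operations are thin wrappers over the same internals, and the
  test suite asserts that stepping round-by-round and running the
  compiled multi-round loop produce *identical* states under the same
  seed.
* All randomness flows through R's global generator, including inside the
  compiled code, so `set.seed()` governs everything.
* ODE integration: `lsoda`, `atol = 1e-10`, `rtol = 1e-8`, horizon
  doubling with a steady-state check (above).

## Problem sizes used in the shipped checks

The test suite and the acceptance script run the full 3000-round horizon
throughout, with ensembles of 20–30 replicates for trajectory experiments
(the published heatmaps use 100) and 10 replicates per cell on a 6×6,
step-0.03 trade-off grid covering the same increment range as the
published 18×18, step-0.01 grid. These sizes give comfortable
signal-to-noise for every qualitative claim while keeping the whole suite
in the tens of seconds.

## Known limitations

* No spatial structure, no resource carry-over, no mutation between
  element classes, and no within-run evolution of `p0` or `dE` — all
  deliberate simplifications of the modeled scenario.
* The early-transient claim that carrying cells outgrow element-less
  cells before the contest resolves is sensitive to the founding
  conditions: with equal founding sizes sharing `R = 30`, the per-cell
  intake is about half a unit per round and a large `K * Ec` surcharge
  can cancel the mutualist boost (at `K = 15` the transient does not
  materialize). It holds robustly in the coupled regime (`K = 1`).
* The synthetic populations are ideal realizations of the model's own
  assumptions; passing tests demonstrate internal correctness and the
  model's qualitative claims, not fidelity to any experimental
  protocell system.
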