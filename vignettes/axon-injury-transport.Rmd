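---
title: "Modelling dual-kinesin transport on injured axonal microtubule bundles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dual-kinesin transport on injured axonal microtubule bundles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinlattice)
```

## The model

`kinlattice` simulates two kinesin species moving unidirectionally along a
bundle of parallel microtubules (MTs), each MT a one-dimensional lattice
of 8 nm binding sites. The dynamics are a totally asymmetric simple
exclusion process (TASEP) extended with multi-site hops, lateral lane
changes, and Langmuir-kinetics (LK) exchange with finite,
position-anchored reservoirs. Every iteration (40 ms of real time) runs
four phases in order:

1. **Influx.** Arrivals are drawn per species with Gaussian inter-arrival
   times and queue FIFO at the minus end; each waiting motor loads onto
   site 1 of a uniformly chosen accessible lane whose loading site is
   free. At most one motor can load per lane per iteration, so the
   lattice absorbs at most `n_lanes / dt` motors/s — a hard entry
   bottleneck once staggering channelises loading onto a single lane.
2. **Stepping sweep.** Each bound motor, visited once, either exits (its
   hop would overshoot the plus end and the remaining path is empty),
   hops forward by its full speed `v` if the gap ahead allows, side-steps
   to site `i + v` of an adjacent lane, or detaches into the reservoir at
   its current site. No partial hops are taken; a motor whose cumulative
   run since attachment reaches its processivity detaches obligatorily.
   If the local reservoir is full the motor stalls in place — motors are
   never destroyed.
3. **Reservoir kinetics.** Each non-empty reservoir, in deterministic
   site order, considers only its FIFO head per iteration: the head leaks
   (is lost to a non-productive pool) once its residence exceeds the
   species lifetime; otherwise it reattaches to a uniformly chosen free
   cell of the 3 x 3 neighbourhood around its anchor, provided any
   ATP-depletion waiting time on the anchor has elapsed. Reattachment
   resets the run length.
4. **Accounting.** Deliveries are appended to the segment's junction
   reservoir (which feeds the next segment in linked axons), and every
   event is logged by position, species and cause.

### Sweep order

The only genuinely free scheduling choice is the order in which bound
motors are visited within an iteration, and it matters: it controls
whether congestion can form. We visit sites minus-end-first (ascending),
with a stamp guard so a motor that has already moved is not stepped again.
A trailing motor therefore sees its leader where it stood at the start of
the iteration, exactly as in the sequential traversal loop of the
heuristic this engine implements, and platoons compress — which is what
produces crowding-induced detachment of the fast species behind the slow
one, the slow species' response to severe channelisation, and the slower
clearance of intermittent injuries. The alternatives are available as
`update_order = "descending"` (plus-end-first: vacancies propagate
backwards within one iteration, platoons glide, and the lattice almost
never jams — under it the slow species shows *no* crowding response in
any proximal-injury scenario and intermittent and continuous injuries
clear pulses equally fast) and `"shuffle"` (random motor order, the
common choice for Monte-Carlo exclusion processes). We treat these as
sensitivity switches, not defaults, for the reason above.

### Parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `n_lanes` | 3 | — | parallel MTs per bundle segment |
| `mt_length_nm` | 4000 | nm | segment length (500 sites of 8 nm) |
| `dt_s` | 0.04 | s | one iteration |
| fast species | 1350 nm/s, 6240 nm | — | 7 steps/iteration, 780 sites processivity |
| slow species | 620 nm/s, 1070 nm | — | 3 steps/iteration, 130 sites processivity |
| `lifetime_s` | 60 | s | reservoir residence before leakage (1500 iterations) |
| `reservoir_capacity` | 50 | motors | per-site productive reservoir |
| `atp_wait_s` | 10 | s | minimum residence in ATP-depleted zones |
| influx | 10 or 15 | motors/s per species | study conditions |
| horizon | 600 | s | observation window (15 000 iterations) |

The slow species' processivity is kept at the canonical 130 lattice sites
rather than the half-up-rounded conversion of 1070 nm (134); the
conversion helpers themselves always round half-up, which also fixes the
staggered-run lengths (12.5 % of 500 sites = 63 blocked sites).

### Injury scenarios

Scenarios 1 and 2 are fully accessible lattices with and without lateral
movement. Scenarios 3–5 block the first 12.5 / 25 / 50 % of sites on
every lane except the middle (channel) lane; scenarios 6–8 block the same
fractions at the plus end. Blocked sites are a single boolean mask —
staggering, damage and occluding proteins are not distinguished. Segments
chain into multi-segment axons (`multi_mmls_spec("1-4P-7D")`) through
unlimited-capacity FIFO junction reservoirs; downstream segments draw
from their junction at the combined configured influx rate with the same
queue-retry loading.

## What the generator emulates — and what it does not

The influx scheduler and the optional "sprinkled" initial state are the
synthetic data of this package: they define the study conditions
(continuous 10/15 motors/s per species; 15 s pulses; 10 % residual
occupancy with an even species split). Inter-arrival gaps are Gaussian
with mean `1/(rate * dt)` iterations and standard deviation a third of
the mean, truncated to at least one iteration — a "normalised Gaussian"
reading; the truncation biases realised rates low by well under 1 %.
Real axons differ in ways the lattice does not capture: cylindrical
13-protofilament MT geometry (we model one protofilament per MT),
retrograde dynein traffic and tug-of-war, cargo identity, actin rings
and neurofilaments, and any regulation of kinesin activity. Passing
tests therefore certify the exclusion-process mechanics and their
emergent traffic phenomenology, not quantitative agreement with live
axons.

## Numerical and design choices

- **Determinism.** All randomness — schedules, lane choices, lateral and
  reattachment tie-breaks — draws from R's session RNG; `set.seed(seed)`
  (or the `seed` argument) makes runs bit-for-bit reproducible. We use
  one stream rather than per-module substreams; toggling a feature may
  therefore shift downstream draws, which the tests accept.
- **Blocked arrivals queue** rather than being dropped, so pulse
  experiments conserve motor counts; `drop_blocked_arrivals = TRUE`
  restores the literal drop-on-collision behaviour.
- **Delivery requires a clear path out**: a motor whose hop overshoots
  the plus end exits only if every remaining site is free, so motors
  cannot tunnel through blockers at the lattice edge.
- **Head-only reservoir release** (one event per reservoir per
  iteration) prevents a single vacancy from draining a whole queue
  instantly and bounds leak + reattach events by the number of non-empty
  reservoirs.
- **Lateral ties** between two available adjacent lanes break uniformly
  at random; `lateral_target = "nearest"` switches the lane-change target
  from site `i + v` to sites `i ± 1` for sensitivity analysis.
- **Mean-field integrator.** The single- and two-lane master equations
  under mean-field factorisation are integrated by explicit Euler with
  step `0.1 / (1 + max rate)`, which provably keeps densities in
  `[0, 1]`; densities leaving the interval raise an error rather than
  being clipped. The two-lane equations use the symmetric lane-exchange
  coupling; the asymmetric printed form is available via
  `printed_form = TRUE`. The full two-species coupled equations are
  evaluated term-by-term (`two_species_rhs()`) for algebraic checking
  only — their interdependencies make them intractable to integrate,
  which is why the stochastic engine exists.
- **Validation limit.** With one species, unit steps, no lateral moves,
  no processivity limit and detachment disabled, the engine reduces to an
  open-boundary exclusion process whose low-density bulk density must
  equal the entry rate; the acceptance suite checks engine and integrator
  against that closed form at `alpha = 0.2`, `beta = 0.8` on 200 sites.
  Because the engine's detachment is event-conditional rather than a free
  Langmuir rate, the engine-integrator comparison is confined to this
  zero-LK limit.

## Problem sizes

Test and acceptance runs use the full default lattice (3 x 500 sites,
15 000 iterations) where the claim concerns the study conditions, and
30–150-site lattices for mechanistic unit tests. Stochastic claims
average 10 seeds (20 for pulse accounting); the TASEP validation uses
2.2 x 10^5 iterations after a 2 x 10^4-iteration burn-in.

## Known limitations

- The fast species' detachment rate grows almost linearly with the
  blocked-run length, so the fold change from 12.5 % to 25 % staggering
  sits near the blocked-site ratio (~2) and the 25 → 50 % change near 4;
  configurations in which the 25 % scenario already triples the normal
  rate, or in which the slow species' rate grows an order of magnitude,
  were not found under any documented scheduler or influx setting.
- Throughput is conserved (no motor loss at default lifetimes), so
  steady-state outflow tracks the configured influx; it does not fall
  with longer (8 um) segments.
- Clearance-time ordering between intermittent and continuous injury
  chains is reproduced from an empty start; with a sprinkled start the
  ordering is within noise for the 25 % chains.
- Iteration granularity (40 ms) quantises speeds to whole steps per
  iteration; any positive speed is clamped to at least one step.
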