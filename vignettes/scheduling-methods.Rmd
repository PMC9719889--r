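---
title: "Dynamic scheduling of liquid-handling operations: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic scheduling of liquid-handling operations: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lhsched)
```

## The problem

A 48-fold parallel mL-scale stirred-tank bioreactor system integrated into a
liquid handling station (LHS) needs substrate additions, pH titration,
multi-stage sampling and induction — all through one shared pipetting
resource. Fixed sequential execution makes the realized feeding interval an
accident of whatever else is on the worklist. `lhsched` implements dynamic
scheduling instead: every task continuously recomputes a priority from
real-time per-reactor data under user-declared constraints, and a greedy,
non-preemptive dispatcher sends the highest-priority task to the LHS
whenever it is available. A digital twin of the LHS and a synthetic
fed-batch plant model close the loop so that complete experiments run, and
are verified, entirely in silico.

## Constraints and the priority calculus

A constraint bounds one quantity — requested volume (uL), elapsed time
since a position was last serviced (s), absolute clock time (s), or reactor
fill level (uL) — from below or above, per reactor position. *Hard*
constraints prohibit execution: a violating position drops out of the
affected set. *Soft* constraints may be violated and escalate priority. A
position is *affected* when it has nonzero demand and passes every hard
constraint; `n_aff` counts affected positions and `n_all` the active fleet
(malfunctioning positions are excluded permanently and shrink `n_all`).

Each task owns a baseline priority $p_{base}$ and a critical priority
$p_{crit}$; no priority exceeds $p_{crit}$, and a task that needs no
execution (or whose every demand-bearing position is hard-blocked) has
priority zero. Four algorithms are provided:

* **step** — $0$ / $p_{base}$ / $p_{crit}$ on hard violation / no
  violation / soft violation;
* **step specific** — the same, scaled by the affected share: $p_{base}
  \frac{n_{aff}}{n_{all}}$, and $p_{base} + (p_{crit} - p_{base})
  \frac{n_{aff}}{n_{all}}$ under soft violation;
* **dynamic volume** — $p_{base} + \frac{p_{crit}-p_{base}}{n_{all}}
  \sum_{i=1}^{n_{aff}} \frac{v_i - v_{i,lim,lower}}{\Delta v_{i,lim}}$,
  linear in how far each affected position's requested volume has moved
  through its allowed span $[v_{lim,lower}, v_{lim,upper}]$;
* **dynamic time** — the same form with $t_i$, the time since the
  position's last service, against its time window.

Numerical choices the formulas leave open, resolved once here: each
dynamic summand is clamped to $[0, 1]$ before summation and the total is
capped at $p_{crit}$, so positions past their soft bound cannot produce
unbounded terms; hard violation on a strict subset of positions removes
those positions rather than zeroing the task; and a soft violation is
carried with its extent (native units, clamped at $\ge 0$) rather than
folded into the dynamic value. Whether a soft violation should escalate
the dynamic algorithms beyond the cap is not decidable from the formulas'
stated branches; we cap at $p_{crit}$ and record soft violations
separately in the evaluation. Priorities are dimensionless, default
$p_{base} = 10$, $p_{crit} = 100$, and comparable only within one
experiment; $p_{base}/p_{crit}$ are per-task, not per-reactor.

## Tasks and demand models

Demand is what turns sensor data into work: an exponential feed bolus
$v(t) = v_0 e^{\mu_{set} t}$ (intermittent feeding is the only feeding
mode an LHS supports); one-sided proportional titration $v = g \cdot
\max(0, pH_{set} - \delta - pH_i)$ with NaOH only (no acid line on the
deck), zero inside the deadband $\delta$; and binary time-triggers for
sampling stages, induction and abort. Sampling is modeled as five chained
stages (withdraw, prepare/dilute, transport to reader, read, wash); stage
$k+1$ becomes demandable per reactor once stage $k$ has completed for that
reactor more recently than stage $k+1$ itself. A DO-control task is
deliberately absent. pH control services only positions with nonzero
clamped demand, not the whole fleet. Volumes are clamped to the channel's
pipettable range; demands below the minimum pipettable volume are
hard-blocked (you cannot titrate 2 uL with a 5 uL-minimum channel — the
position waits until its demand has grown).

## The scheduler

One tick (default 10 s of simulated time) performs, in order: completion
of a due execution (bookkeeping at the exact end time; liquid reaches the
plant at this processing moment, a lag of at most one tick), a plant step,
exclusion of freshly malfunctioning reactors, a sensor sweep on its own
interval (default 60 s), a priority report from every non-executing task
(an executing task retains its last value — dispatch is non-preemptive),
and, if the LHS is idle and some priority is positive, dispatch of the
argmax task. Ties break by (1) value, (2) older earliest per-reactor last
execution, (3) declaration order — deterministic and starvation-averse.
The ordering matters: priorities are logged *before* the dispatch
decision, which is what makes the run exactly replayable.

The termination sequence (stop task runtimes, close the availability
stream, persist the cause, close the datastore) runs on normal completion,
on a scheduled abort task, and — via a guard around the run loop — on any
unexpected main-loop failure. The natural end of the simulated horizon is
recorded with cause `api_abort` (the controlled-stop case); the cause
vocabulary has no separate "completed" value.

`evaluateConstraints` returns full-length vectors over declared positions
with inactive entries false/zero, rather than vectors re-indexed to the
active fleet; `n_all` is the active count. This avoids re-indexing every
exclusion and keeps reactor indices stable in logs. Reactor positions are
1-based throughout, the natural convention in R; deck position names
(`R01` … `R48`, `MTP01` …) are opaque strings mapped by the profile's
deck sequences.

## The LHS twin

The twin merges the broker and the simulator: it receives the minimal
dispatch message (method name, ordered volumes, target and optional source
sequence), validates it — unknown methods or positions, per-channel volume
outside `[min, max]` (zero volumes mark transport-only steps and pass),
length mismatches are *blocking*; a feed volume that disagrees with what
the configured feed profile prescribes at dispatch time is recorded as a
`miscalculated feeding volume` finding but does not block — and emulates
the execution time as

$$ d = \text{overhead}(method) + \lceil n_{targets} / n_{channels} \rceil
\cdot d_{cycle}, $$

optionally scaled by a seeded lognormal jitter. Published vendor timing
data does not exist, so the overheads (30–120 s) and cycle time (30 s)
are profile parameters with defaults in the range of an eight-channel
1000 uL instrument; needle washing is folded into the per-method overhead.
Channels reset between commands — per-channel tip occupancy across
methods is not modeled. Every busy/idle transition is published with its
timestamp; overlapping executions are refused (a breach would be a
scheduler bug, and the mutual-exclusion property is tested).

## The synthetic plant

The plant generates the sensor streams a real system would provide, with
the simplest kinetics that reproduce the qualitative signature driving the
scheduler's interesting behavior: Monod glucose uptake
($q_{glc,max} = 1.2$ g/(g h), $K_S = 0.05$ g/L) with a fixed overflow
fraction (0.2) diverted to acetate, which acidifies the broth linearly
(0.3 pH units per g/L net acetate); after glucose depletion acetate is
re-consumed ($q_{ace,max} = 0.35$ g/(g h)) and the pH rises again. The
"metabolic switch" is thus implemented as acetate re-consumption — the pH
phenomenology, not a pathway model. DO follows a first-order balance
between transfer and uptake. Base raises pH by $k_{pH,base} \cdot v /
V_{fill}$ (0.05 pH per uL per mL); feeds add glucose mass at 300 g/L and
dilute; samples remove volume at unchanged concentrations. Initial state:
10 mL fill, 2 g/L biomass, 1 g/L glucose, pH 7.0, DO 90% — a fed-batch
start just after batch glucose is nearly spent. Sensor noise (pH 0.005,
DO 0.3 SD) is applied on read only; stirrer malfunctions are a seeded
per-reactor Poisson process (default rate 0 — malfunction scenarios turn
it on explicitly).

What the generator does *not* emulate: temperature and gassing dynamics,
inter-reactor coupling, evaporation, structured metabolism, sensor drift.
A green end-to-end test therefore establishes that the *scheduling* stack
behaves correctly against plausible dynamics — not that the kinetic
parameters describe any particular organism.

## The reference scenario

`fedBatchConfig()` is the package's stated world: 48 reactors, 8 h
horizon; exponential feed ($v_0 = 60$ uL, $\mu_{set} = 0.2$/h) on a
[1500 s, 2100 s] interval window with dynamic-time priority (10/100);
proportional pH control ($g = 60$ uL/pH, setpoint 7.0, deadband 0.1) with
dynamic-volume priority (10/80) on a [5, 60] uL span; hourly five-stage
sampling (withdraw 500 uL) with dynamic-time stage 1 (10/60) and
step-priority follow-up stages (20/60), chosen so a pending chain finishes
promptly but yields to a feed approaching its window ceiling. A 15 mL
working-volume cap guards every dispensing task. These choices were made
once, for plausibility at this scale, and are not tuned per test: under
this world the feed's elapsed-time gaps return to the 1500 s floor when
uncontended and keep their mean within 5% of it against the hourly
sampling bursts, which is the package's operationalization of "dynamic
scheduling retains a stable average execution interval".

Tasks evaluate the *acquired* sensor values (sample-and-hold from the
last sweep, with noise), not plant internals; sensor-driven demand is
suppressed once readings are older than 300 s. A visible consequence of
this fidelity choice: near the titration threshold the fleet
desynchronizes by a few millipH, so pH control issues more and smaller
dispatches than a noise-free world would — the titration law doses only
to the deadband edge, and the minimum-pipettable-volume hard constraint
is the only hysteresis. With the full task mix this chattering adds
enough LHS load to push the mean feed gap slightly past 5% of the floor
(about 5.5% at seed 1) while still respecting both window bounds.

## Data and verification

Every priority report, sensor sweep, execution, exclusion and state
transition is persisted as a tagged time-series point — measurement name,
timestamp, tags (experiment, reactor, task), numeric fields; a point is
unique by (measurement, timestamp, tags) and rewriting overwrites. The
store is an append log with an in-memory index (data.table underneath),
flushed to JSON-lines on close; queries filter by measurement, tag
equality and half-open time range; CSV/JSON-lines exports round-trip
exactly (numbers are written with 17 significant digits).

Runs are verified by an independent greedy-replay oracle: from the
persisted priority log alone (each point carries the value, the tie-break
fields and the declaration index), re-derive which task must have been
dispatched at every timestamp the LHS was available, and require the
re-derived sequence to equal the dispatch log exactly. Pure greedy
dispatch on current priorities is intentional — no look-ahead to imminent
priority crossings, no preemption, one LHS.

```{r example, eval = FALSE}
cfg <- fedBatchConfig(seed = 1)
run <- runExperiment(cfg)
replayDispatches(run)$match
dispatchLog(run) |> head()
```

## Known limitations

Single LHS resource; no runtime network API (task add/remove is an
in-process queue); no retention policies or dashboards on the datastore;
the plant model is phenomenological; execution-time parameters are
plausible defaults, not fitted to vendor telemetry. Test and acceptance
runs scale some scenarios down (2–4 h horizons for determinism and
malfunction checks) purely for runtime; the scenario parameters themselves
are unchanged.
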