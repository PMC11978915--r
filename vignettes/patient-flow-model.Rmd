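---
title: "Modelling patient flow as a dynamic nonlinear network flow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling patient flow as a dynamic nonlinear network flow}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hospitalflow)
```

## The problem and the model

Patient flow in a hospital is dynamic and nonlinear: arrival rates vary by
hour and season, and service times vary by patient, ward and staffing.
Classical flow algorithms built for transport or telecom networks focus on
edge capacities and congestion-driven routing; a hospital is the opposite
case. The wards (vertices) do the work — beds, staff and service-time
variability drive bottlenecks — while an edge's capacity is merely a
waiting queue, and routing follows the patient's health issue, not the
shortest path.

`hospitalflow` therefore treats the hospital as a single-commodity directed
network with one entry and one exit vertex and runs a modified augmenting
path flow computation per arrival-rate step. Three modelling commitments
shape everything:

1. **Capacities are load-adjusted each step.** With sampled service time
   $s$ and $S_v$ servers, the ward's service rate is $\mu_v = S_v/s$, its
   traffic intensity $\rho_v = r_t/\mu_v$, and its adjusted capacity
   $$C'_v = \begin{cases} C_v & \rho_v = 0\\ 0 & |\rho_v - 1| < \varepsilon\\
   \min\!\big(C_v,\; C_v \tfrac{1-\rho_v}{\rho_v}\big) & \text{otherwise}
   \end{cases}$$
   The quantity $\rho_v/(1-\rho_v)$ — current over remaining intensity —
   is the overflow ratio; dividing $C_v$ by it yields the formula above.
   Edges become $Q_e - r_t\,DP_e$. An edge's static residual is its own
   adjusted capacity plus the receiving ward's $C'_v$ (sink edges carry
   only the edge term). Residuals are **real-valued and signed**: a
   positive residual measures headroom, a negative one the *intensity* of
   an overflow, not a count of free beds. They are never rounded.

2. **Depth-first path search.** Augmenting paths are simple paths over
   strictly positive residuals only; negative or zero residuals block
   flow. Depth-first search is used deliberately instead of breadth-first:
   it explores deep into long paths, so bottlenecks in low-priority wards
   are not overshadowed by short, high-priority routes.

3. **Forward-only augmentation.** The bottleneck (minimum residual along
   the path) is subtracted from every on-path edge and no backward
   residual edges are created. Patients do not take alternative care
   pathways, so flow, once pushed, is never rerouted. A consequence tested
   explicitly: per-step pushed flow is bounded above by the classical
   max-flow of the same adjusted graph, with equality on single-path
   networks.

Continuity across steps lives in two dynamic records rather than in the
static residuals (which are rebuilt from the formulas each step): **DynRG**
holds each edge's running minimum and maximum residual (initialised to
$+\infty/-\infty$ before any observation), and **DynV** holds each ward's
per-step residual.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| `beds` ($C_v$) | beds | fixture-specific | physical ward capacity; caps $C'_v$ |
| `servers` ($S_v$) | staff | = beds | divides service time into a rate; the beds = servers fallback mirrors how real datasets lacking staff counts are handled |
| `capacity` ($Q_e$) | queue slots | 5 | patients allowed to wait for a bed in the next ward |
| `probability` ($DP_e$) | — | importance-weighted | fraction of patients leaving a ward along the edge; sums to 1 per ward (tolerance 1e-6, since real tables carry rounding) |
| `family` | — | `lognormal` | hospital lengths of stay are right-skewed; configurable per run because source datasets rarely name the family |
| `samples_per_step` | draws | 1 | one service time per ward per arrival-rate change; > 1 averages draws |
| `vertex_arrival` | — | `"raw"` | each ward sees the raw hospital arrival rate; routing probabilities act only at the edge adjustment. `"weighted"` instead thins the ward arrival by the sum of incoming `DP`, for deep wards |
| `max_augmentations_per_step` | paths | uncapped | push until blocked; a cap of $\lceil r_t \rceil$ mimics a literal patient count |
| `epsilon_full` | — | 1e-9 | half-width of the "exactly full" band at $\rho = 1$ |
| `eps_positive` | — | 1e-12 | threshold for "strictly positive" residual, so subtraction chains cannot admit phantom paths |
| `outlier_bound` | residual units | 1000 | symmetric filter on ward time series before plotting/summarising |

## Numerical and design choices

* **"Effect of" operators.** The source description of capacity adjustment
  names the inputs and the sign semantics but not the operators. We use
  subtraction for edges ($Q - \text{inflow}$) and the capped ratio
  $\min(C, C/\text{overflow ratio})$ for wards. The ward formula is the
  package's own choice; it satisfies the stated contract exactly —
  positive iff $\rho < 1$, zero at $\rho = 1$, negative iff $\rho > 1$,
  non-increasing in $\rho$ — and never exceeds the physical bed count.
  The acceptance suite pins the contract, not the formula.
* **Overwrite vs carry-over.** Static residuals are recomputed from the
  adjustment formulas each step and then depleted by that step's
  augmentations; they do not carry over. The alternative reading (letting
  depleted residuals persist across steps) conflates the load model with
  the flow ledger; DynRG/DynV already provide continuity.
* **DFS determinism.** Neighbours are explored in descending distribution
  probability, ties broken by input edge order; a visited set restricts
  the search to simple paths, which also guarantees termination on cyclic
  networks (cycles are accepted with a validation warning — patients do
  occasionally return to earlier wards).
* **DynV aggregation.** "Capacity per vertex per time unit" needs a
  per-ward scalar from per-edge residuals; we use the mean over the ward's
  incoming edges after the step's augmentations (the source uses its
  outgoing edges). Means, not sums, keep wards with different in-degrees
  comparable on one plot.
* **Rejection cap.** Bounded sampling redraws until the value lies within
  the observed length-of-stay range, but a literal "retry until valid"
  loop does not terminate when the distribution's mass misses the bounds
  (a constant 1000-hour mean against a [1, 2]-hour range). After 1000
  rounds the draw is clamped to the nearest bound, preserving the bounds
  guarantee unconditionally.
* **Full-capacity sentinel.** $\rho = 1$ makes the overflow ratio blow up;
  within `epsilon_full` of 1 the ratio reports `Inf` and the adjusted
  capacity is exactly 0, so the boundary case is handled without
  catastrophic cancellation.
* **Source/sink.** Entry and exit points are ordinary ward records whose
  beds and servers are forced to a 1e9 sentinel and which carry no
  length-of-stay values; they mark where flow originates and terminates
  and never constrain it (sink edges skip the vertex term entirely).

## What the synthetic generator emulates — and what it does not

`make_toy_hospital()` is a fixed, versioned 20-ward / 62-pathway network
with the structural features the algorithm assumes: one entrance, one
discharge vertex, a named set of core wards (Emergency Department,
Infectious diseases Unit, Medical Ward, Cardiac, Respiratory, ...), every
queue capacity 5, staff equal to beds, and routing probabilities derived
from per-ward importance weights (the Emergency Department takes the
largest share of arrivals). The exact wiring is this package's own
artifact: no published topology exists to copy, only the constraints
above. `make_spike_arrivals()` is the fixed 24-hour profile
1,1,1,1,1,1,1,10,20,30,40,30,20,10,1,...,1 — a quiet night, a sharp
mid-day surge peaking at 40 patients/hour. `make_random_hospital()`
generalises the fixture for property tests: layered, seeded,
source-to-sink-connected networks that always validate.

What the generator does **not** emulate: real length-of-stay distributions
(ours are small plausible value sets, not fitted hospital records),
correlated arrivals, ward-specific arrival streams, staff rosters, or the
scale and routing-probability skew of a real 45-ward hospital (where
routing probabilities as small as 3e-5 and service times near 1300 hours
drive much of the observed blockage). A green test therefore establishes
that the algorithm's mechanics are correct and its qualitative behaviours
(spike response, servers-vs-beds monotonicity, blockage evolution) hold on
a structurally faithful network — not that any specific real hospital's
blockage counts are reproduced.

## What the diagnostics mean

Per edge over the run: persistency `max − min` (divergence: flow
stability), severity `0 − max` (non-negative when the edge is at or over
capacity even in its best state), overflow `0 − min` (positive when it
overflowed at least once). The identity `persistency = overflow − severity`
holds exactly and is asserted exactly. Matrix cells exist only where edges
exist — an absent cell is "no pathway", never zero.

A ward is *blocked* when no augmenting path visited it over the whole run —
the definition behind the flow-evolution colouring — rather than when its
final residual is negative; a ward can carry flow early and be overflowed
later, and the colouring asks "did flow ever pass", so longer horizons can
only shrink the blocked set (tested at 1-day vs 1-week). Root-cause traces
walk `k` hops from a focal ward: predecessors are ranked by the flow they
pushed into it (high-outflow ancestors feed the bottleneck), successors by
their mean outgoing residual, lowest first (a dammed-up descendant blocks
flow back). The two metrics differ because the path log observes pushed
flow directly, while a successor's damming shows up as depressed residuals.

## Known limitations

Single commodity only (one entry, one exit); fixed server counts over time;
no disease-specific routing — each is a deliberate exclusion, matching the
method's stated scope, and the natural next extensions. The per-step flow
is not bounded by the literal arriving patient count unless
`max_augmentations_per_step` is set. No queueing-theoretic waiting times
(this is a flow model, not an Erlang-C calculator), and no statistical
testing on residual differences: the diagnostics are descriptive.
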