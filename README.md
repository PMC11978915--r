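# hospitalflow

Dynamic nonlinear flow modelling of patient flow through a hospital
network, for health-systems analysts and hospital capacity planners who
need a quick, holistic view of where bottlenecks sit, how severe and how
persistent they are, and which wards cause them.

## The model

A hospital is a directed graph `DG(V, E)` with a single entry vertex
(source) and a single exit vertex (sink). Each ward `v` has a bed capacity
`C_v`, a staff (server) count `S_v`, and a service-time distribution fitted
to its observed lengths of stay, bounded to `[min L_v, max L_v]` by
rejection sampling. Each care pathway `e = (u, v)` has a waiting-queue
capacity `Q_e` and a distribution probability `DP_e` (outgoing `DP` sums to
1 per ward).

The engine iterates over an hourly arrival-rate profile `r_t`. At each
step, for every ward:

    mu_v  = S_v / sTime_v                (service rate, patients/hour)
    rho_v = r_t / mu_v                   (traffic intensity)
    C'_v  = C_v                 if rho_v = 0
          = 0                   if rho_v = 1
          = min(C_v, C_v (1 - rho_v) / rho_v)  otherwise

so the adjusted ward capacity is positive while the ward can take more
flow, zero at full capacity, and negative when overflowed (the magnitude
grading the overflow). Each edge is adjusted to `Q_e - r_t * DP_e`, and the
static residual of `(u, v)` is the edge term plus `C'_v` (edges into the
sink carry only the edge term). Augmenting paths are then found by
**depth-first search** over strictly positive residuals — depth-first so
that deep, low-priority wards are not overshadowed by short paths — and the
path's bottleneck flow is pushed **forward only**: no backward residual
edges, because patients do not take alternative care pathways.

Two dynamic records accumulate across steps: **DynRG**, each edge's
minimum/maximum residual over the run, and **DynV**, each ward's residual
per time step. From DynRG come the three bottleneck diagnostics, per edge:

| diagnostic  | definition        | reading                                  |
|-------------|-------------------|------------------------------------------|
| persistency | `max - min`       | small = stable flow, large = fluctuation |
| severity    | `0 - max`         | `>= 0` = at/over capacity even at best   |
| overflow    | `0 - min`         | `> 0` = overflowed at least once         |

A ward never visited by any augmenting path is **blocked**; k-hop
root-cause traces rank predecessors by the flow they pushed into a focal
ward and successors by their (low) mean outgoing residual.

## Worked example

A fixed synthetic 20-ward hospital (62 care pathways, every queue capacity
5, staff = beds) under a 24-hour arrival profile that spikes from 1 to 40
patients/hour, with a constant 5.01-hour service time in every ward:

```r
library(hospitalflow)
net <- make_toy_hospital()
sim <- run_simulation(net, make_spike_arrivals(),
                      make_constant_service(net, 5.01), seed = 1)
print(sim)
#> <flow_simulation> 24 steps over 20 wards / 62 pathways (seed 1)
#>   total flow pushed: 1028.075 (per-step mean 42.836)
#>   residual range observed: [-39.557, 44.750]

blockage_classification(sim)
#> <blockage_coloring> 14 reached / 4 blocked interior wards
#>   blocked: Surgery, Orthopedics, Neurology, Urology

trace_root_cause(sim, "Emergency Department", depth = 2)
#> <root_cause_trace> Emergency Department (k = 2)
#>   predecessors by pushed flow:
#>       ward hops   metric
#> 1 Entrance    1 586.9048
#>   successors by mean outgoing residual (low = blocker):
#>             ward hops    metric
#> 1     Laboratory    2 -5.208333
#> 2      Radiology    2 -5.208333
#> 3 Rehabilitation    2 -5.208333
#> 4        Urology    1 -2.375000
#> 5       Oncology    2  1.657487
```

Reading this: 1028 patient-equivalents of flow crossed the network in 24
hours; four wards were never reached by any augmenting path (their routes
exhaust upstream residual first — raise their routing probability or the
upstream capacity to unblock them); the Emergency Department's inflow
pressure comes from the entrance (587 units pushed through it), and its
most suspect downstream blockers are the small diagnostic units whose mean
outgoing residual is negative (overflowed queues).

The worst overflow cells (`overflow_matrix(sim)`) are the entrance edge
into the Emergency Department (39.6) and the Infectious diseases Unit to
Medical Ward pathway (37.0) — exactly the arrival-surge signature the spike
profile is designed to produce.

## Command line

```sh
Rscript inst/cli/hospitalflow.R generate --out-dir inputs --toy
Rscript inst/cli/hospitalflow.R validate --wards inputs/wards.csv \
    --edges inputs/edges.csv --source Entrance --sink Discharge
Rscript inst/cli/hospitalflow.R run --config run.json --seed 7
Rscript inst/cli/hospitalflow.R report --result-dir run \
    --ward "Emergency Department" --depth 3 --outlier-bound 1000
```

`run` writes a self-describing directory (dynrg.csv, dynv.csv, paths.jsonl,
manifest.json, copied inputs); `report` derives persistency/severity/
overflow CSVs, an annotated blockage GraphML, the outlier-filtered ward
time series, and the root-cause JSON. The run config is JSON; any key can
be overridden by a flag (e.g. `--equal-dp` replaces routing probabilities
with `1/outdegree`, `--repeats 7` runs a week of a daily profile).

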