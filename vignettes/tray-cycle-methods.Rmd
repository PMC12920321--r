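---
title: "Modelling the hospital tray cycle: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the hospital tray cycle: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(traycycle)
```

## The problem

Reusable surgical instrument trays circulate in a closed loop: sterile
storage → operating room → Central Sterilisation Services (CSS) →
storage. A hospital must decide how many trays of each type ($Q_s$) to
keep in that loop. Too few and surgeries are delayed or rescheduled when
no sterile tray is available; too many and capital is tied up in
inventory that spends its life on a shelf. Because many tray types are
shared across surgery types and several trays equip a single surgery,
per-type demand is *dependent* — sizing each type in isolation against a
marginal demand distribution misses that structure. `traycycle` takes
the route of simulating the whole loop and sizing stocks from the
simulated demand.

## The simulation model

The CSS is modelled as a tandem of FIFO queues with infinite capacity:

1. **Use.** Each scheduled surgery requests its *preferred configuration*
   (a multiset of tray types). If any tray is missing, the feasible
   alternatives of its surgery type are tried in descending configuration
   probability (counted as an *alternative tray* outcome); failing that,
   the surgery retries on every restock and is *rescheduled* once 120
   minutes have elapsed. Used trays arrive at the CSS at surgery start +
   realized duration, with no transport delay; outpatient trays
   accumulate in a batch buffer released into the CSS at fixed insertion
   times (defaults 11:00 and 16:00 — the reference hospital's values are
   not published, so these are deliberate placeholders, configurable per
   instance).
2. **Manual stages.** Pre-cleaning, assembly and wrapping each need one
   free workstation slot *and* one free staff member of the mapped team
   (pre-cleaning team: pre-clean and disinfector loading by default;
   post-cleaning team: disinfector unloading, assembly, wrapping,
   autoclave loading — the split is configurable because only the team
   names, not the task assignment, are documented for the reference
   hospital). Task durations are lognormal; tasks in progress finish even
   if the shift ends, but nothing new starts outside staffed hours.
3. **Machines.** Disinfectors (capacity 48 size units on a 4 × 12-unit
   layer rack) and autoclaves (30 trays) run deterministic 60-minute
   cycles flanked by lognormal load/unload tasks. A free machine is only
   started once it can be filled to its threshold ($\alpha_{dis} = 20\%$,
   $\alpha_{ster} = 50\%$). Disinfector charges are built by a FIFO scan
   with layer bookkeeping: trays of another compatibility class (e.g.
   eye or anaesthetic trays, which must be washed separately) or that fit
   no layer remainder are skipped. The charge's class is fixed by its
   first selected tray; candidate classes are tried in order of first
   appearance in the queue, so a single tray of a low-volume class at the
   queue head cannot stall the stage below its threshold — without this
   rule the simulated loop deadlocks for hours at a time, which is
   incompatible with the continuous flow the thresholds are meant to
   maintain. Machines below threshold simply wait (also overnight); they
   are never force-started.

The loop is *closed*: at every simulated instant the trays of type $s$
summed over all locations equal $Q_s$. This conservation law, the
capacity and threshold rules, and FIFO order among served trays are all
asserted by the test suite on recorded event logs.

### Time and units

The clock is in minutes; days are calendar days with day 0 a Monday.
Tray sizes map to machine size units as S = 1, M = 2, L = 3, XL = 4 —
the reference parameters give the size classes and unit capacities but
never the mapping itself, so this default is our choice and is
configurable per instance (`size_map`). Lognormal parameters are stored
on the log scale; `lognormal_params()` converts the natural-scale
mean/sd figures that hospital time studies usually report.

## The surgery schedule generator

Demand is driven by a generated surgery schedule. For each day $t$ and
surgery type $o$, the number of surgeries is Poisson with the weekday
rate $\lambda_{v,o}$; durations are lognormal $(\mu_o, \sigma_o)$; the
preferred configuration is sampled by configuration probability.
Surgeries are packed into operating rooms worst-fit — each goes to the
room with the least accumulated *expected* duration
$\exp(\mu_o + \sigma_o^2/2)$, ties to the lowest room index — then the
order within each room-day is uniformly shuffled and start times are
spread evenly: the $i$-th of $n$ surgeries starts at
$\text{open} + (i-1)(\text{close}-\text{open})/n$. "Evenly" admits
several readings; this one pins the first surgery to the window opening
and is frozen in the tests. If a day draws more work than the rooms
hold, surgeries are still scheduled (the day logically overruns);
emergencies are not modelled separately but absorbed in the rates.
Outpatient demand is a homogeneous Poisson process per outpatient tray
type within a daily window, at a constant rate across weekdays (whether
it should vary by weekday is unknown; a constant is the neutral
choice). Outpatient demand that finds no sterile tray is counted as
unmet and lost — unlike surgeries, outpatient procedures get no
two-hour retry window.

Counts, durations/configurations, and shuffling use three independent
seeded streams, so experiments can hold demand fixed while
re-randomising service.

## The three sizing heuristics

**Empirical weekday quantile (`base_stock`).**
$Q_s = \max_v F^{-1}_{d_{s,v}}(\alpha)$ over weekdays $v$, where
$F_{d_{s,v}}$ is the empirical distribution of daily demand on weekday
$v$ and the inverse CDF uses the convention "smallest observed value
with $F(x) \ge \alpha$" (the convention matters for small samples and is
fixed by tests).

**Cycle-time rule (`fk_levels`).**
$Q_s = \lceil \text{stat}_t(d_{s,t}) \cdot \bar\tau \rceil$ with
stat ∈ {mean, median, max} over all days and $\bar\tau$ the mean tray
cycle time in days, estimated by the sample mean of simulated makespans
(`mean_cycle_days()`); since used trays reach the CSS with zero
transport delay, the makespan *is* the cycle time.

**Markov-chain service level (`di_levels`).** Time is discretised into
equal periods (default 4 h, including nights — the period sweep this
method is usually subjected to implies contiguous periods; a staffed-
hours-only variant can be mimicked by passing a filtered event table).
Inventory of a type is either sterile on hand ($u_k$ at the start of
period $k$) or dirty ($v_k$ at its end); trays used in $k$ are processed
in $k+1$ and usable in $k+2$, so $Q_s = u_k + v_{k-1}$ and

$$u_{k} = (u_{k-1} - d_{k-1})^+ + (Q_s - u_{k-1}) =
\begin{cases} Q_s - u_{k-1} & d_{k-1} \ge u_{k-1} \\
              Q_s - d_{k-1} & d_{k-1} < u_{k-1}.\end{cases}$$

(The printed source of this model states the dirty inventory with a
stray $u$ on the left-hand side; we read it as
$v_k = \min(u_k, d_k)$, which is the only reading consistent with the
transition law above, and verify the resulting chain against a
brute-force construction.) With i.i.d. per-period demand, $u_k$ is a
Markov chain on $\{0, \dots, Q_s\}$; its boundary stationary
probabilities have closed forms and the interior follows by a recursion
filling $\pi_i$ and $\pi_{Q-i}$ jointly from both ends. The
implementation renormalises only to absorb float drift below $10^{-6}$
and raises a hard error beyond that (drift of that size would signal a
transcription bug, not rounding); degenerate denominators (e.g. demand
that is never zero while $Q$ lies inside its support) raise an explicit
error rather than producing NaN. The service level is
$\beta = 1 - \sum_i \pi_i P(d > i)$, and `di_levels()` returns the
smallest $Q \ge 1$ reaching a target $\beta$, searching up to twice the
demand support ($Q = 0$ for demand-free types).

Every steady state is checked in the test suite against
`stationary_distribution(di_transition_matrix(...))` — the explicitly
built transition matrix solved as a linear system — to an ∞-norm of
$10^{-8}$ over 500 random demand PMFs.

## Output analysis

Weekly KPI series (aggregating days already smooths the weekday
pattern) feed MSER-$m$ warm-up truncation with $m = 2$: batch the series
into pairs, and choose the truncation $d$ minimising
$\sum_{j>d}(z_j - \bar z_d)^2 / (k-d)^2$, restricted to the first half
of the batched series — the standard guard against spurious minima at
the series end; the exact variant is not nailed down by its original
sources, so the guard is our documented choice. Replication analysis
uses Student-$t$ intervals, and validation against operational
reference means uses a $t$-interval on the mean difference, flagged
consistent when it covers zero. `compare_policies()` evaluates a set of
inventory policies under common random numbers: every policy sees the
same replication schedules and the same service-randomness seeds, so
policy differences are not drowned in between-replication noise.

## The synthetic instance generator

No hospital dataset ships with the package (none is published), so
`make_synthetic_instance()` builds instances with the *statistical
shape* of a real mid-size hospital's tray catalogue after clustering:
32 high-use surgical tray types (mean stock ≈ 10, expected weekly
demand ≈ 14 per type), 77 low-use surgical types (stock ≈ 2.2, weekly
demand ≈ 0.8) and 10 outpatient types (weekly demand ≈ 11.9) returned
in batches. Demand dependence is induced structurally — alternative
configurations share a configurable fraction of the preferred
configuration's trays, and configurations hold multiple trays — rather
than through any copula machinery. Weekday rates (Mon–Fri full, Sat
30%, Sun 20%) are scaled so the expected weekly demand per cluster hits
its target exactly in expectation; a 10,000-day check in the test suite
keeps the realised means within 5%. Resources default to the reference
parameters (two workstations per manual stage, four 48-unit
disinfectors, three 30-tray autoclaves, three weekday shifts and one
weekend shift per team).

What the generator does *not* emulate: the real catalogue's 1213 tray
types, surgeon/block scheduling constraints, instrument-level tray
composition, damage and maintenance, or sterilisation failures. Passing
tests therefore demonstrate correctness of the mechanics and the
heuristics' comparative behaviour on realistic demand structure — not
calibration to any particular hospital.

## Problem sizes used in tests

Desk-scale defaults keep the full suite fast while preserving the
comparisons' structure: the policy-comparison experiment uses a
~120-type synthetic instance with 5 replications of 20 weeks (2 weeks
warm-up) under common random numbers; generator statistics use 10,000
simulated days; the chain-vs-oracle property uses 500 random PMFs with
support ≤ 6 and $Q \le 8$. The full-scale experiment shape (30
replications, 104 weeks plus 6 weeks warm-up — the defaults of
`simulate_cycle()`) remains available through the same functions.

## Known limitations

* The simulator is pure R; a 140-day run of the default synthetic
  instance takes on the order of ten seconds. Large parameter sweeps
  should scale replications before horizon.
* Head-of-queue blocking across compatibility classes is resolved by
  the first-feasible-class rule described above; other operator
  policies (e.g. strict head-class waiting) are not modelled.
* Staff are interchangeable within a team and tasks are
  single-operator; space-transition minimisation between the two CSS
  areas is out of scope.
* Outpatient stockouts are lost demand, not backorders.
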