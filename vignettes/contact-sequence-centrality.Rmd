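---
title: "Event mapping and contact sequence centrality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Event mapping and contact sequence centrality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(contactseq)
library(ggplot2)
```

## The problem

Spreading processes — pathogens, rumours, delays — travel over contacts, and
contacts happen in a precise temporal order. A static "who ever met whom"
graph discards that order: person B can only pass something from A to C if
the A–B contact happened *before* the B–C contact. `contactseq` analyses
timestamped pairwise contact data (as produced by proximity sensors at,
say, a fair, a school, or a supermarket) while respecting contact sequences,
and quantifies each individual's impact on them.

## The representation: snapshots, events, event graph

Raw contact records `(agent_a, agent_b, timestamp)` are binned into
**snapshots** of a configurable resolution (`read_contact_log()`, half-open
bins, 0-based indices). Within each snapshot, the connected components of the
contact graph are **events**: groups of people in direct or indirect contact
during that time bin. Isolated agents form singleton events, so the events of
a snapshot always partition the agent universe.

Two conventions, both standard for this representation, matter downstream:

* **Within an event the contact structure is treated as complete.** If 1–2
  and 2–3 are recorded but 1–3 is not, the event `{1,2,3}` still links 1 and
  3. This is appropriate when the transmission time scale is short relative
  to the event duration; it is the convention used by all tracing and by
  `aggregate_contacts()`.
* **The agent universe is fixed.** Agents observed at any time (or declared
  via the `agents` argument) stay in the universe even when isolated, and the
  denominator `N` of every fraction below counts all of them.

Events of consecutive snapshots are linked whenever they share an agent,
giving a **time-directed event graph** (`build_event_graph()`), a DAG layered
by snapshot index. Singleton events are materialised and included by default
(an idle agent remains traceable to itself); event-betweenness analyses drop
them by default because chains of singletons carry no other agent's paths.

## Traceability and contact sequence centrality

For a source agent $j$, start snapshot $t$ and window of $\Delta t$ snapshots
$[t, t+\Delta t)$,

$$P(j,t,\Delta t) = \frac{\#\{\text{agents traceable to } j\}}{N}$$

where tracing seeds from $j$'s event at snapshot $t$ and propagates along
event-graph links; every member of a reached event is traced
(`trace_fraction()`). Averaging over all $N$ sources gives
$\bar P(t,\Delta t)$ (`mean_trace()`), the system's mingling speed.

**Window convention.** $\Delta t$ counts whole snapshots, so $\Delta t = 1$
sees only snapshot $t$ — on the toy network (`toy_network()`),
$P(5,0,1) = 2/8$ because agent 5's snapshot-0 event $\{3,5\}$ already counts,
and $P(5,0,2) = 6/8$ after one propagation step.

The impact of agent $i$ is measured by deleting every contact of $i$ (while
keeping $i$ in the universe, so $N$ is unchanged) and recomputing the mean:

$$C(i,t,\Delta t) = \bar P(t,\Delta t) - \bar P_{-i}(t,\Delta t) \ge 0,$$

the **contact sequence centrality** (`contact_sequence_centrality()`). A
window-isolated agent has exactly $C = 0$; a low-degree agent that bridges
two otherwise separate groups can dominate $C$ at long windows. Rankings use
the $t$-averaged $C$ at a chosen $\Delta t$ (`rank_agents()`), with ties
broken by agent id so output is deterministic.

**Removed source convention.** On the perturbed network the removed agent
still contributes its isolated self-trace $1/N$ to $\bar P_{-i}$; this keeps
both means over the same $N$ sources and makes isolated-agent centrality
exactly zero. The alternative — excluding $i$ and averaging over $N-1$ — is
available as `removed_source = "exclude"` for sensitivity checks; note that
under it a window-isolated agent gets slightly *negative* centrality
(removing a low-$P$ source raises the mean), which is why it is not the
default.

## A note on the direction of time

`reverse_time()` re-indexes snapshots so that forward tracing on the reversed
network answers "who could have reached $j$" instead of "whom can $j$ reach"
— the natural direction for upstream-exposure questions. Static aggregated
metrics are exactly invariant under reversal. For traceability the picture is
more subtle than it may first appear: because reachable (source, target)
pairs simply transpose under reversal, $\bar P$ on the reversed network at
start $t$ equals $\bar P$ on the original at the mirrored window, and
averaging over *all* valid starts at a fixed $\Delta t$ is therefore
reversal-invariant as well. Genuine sensitivity to the arrow of time shows up
in per-window quantities: at a fixed $(t, \Delta t)$ both the $P(j)$ values
and the $C$ rankings generally change, which the test suite witnesses on a
three-contact chain fixture.

## Comparison metrics

Six per-agent metrics serve as static and temporal baselines
(`metric_table()`): aggregated degree; contact betweenness (unordered-pair
normalisation $\binom{n-1}{2}^{-1}$); the number of non-individual events
attended; the mean size of all attended events (singletons included); event
betweenness (directed event graph, normalised by $(n-1)(n-2)$, averaged over
the agent's events); and temporal betweenness (betweenness on the
time-expanded graph whose vertices are agent–snapshot copies, averaged over
an agent's copies). In the time-expanded graph, contact edges are mutual and
persistence edges point forward by default (`directed = TRUE`), matching the
time-respecting semantics used everywhere else; an undirected mode exists
because the convention is not universal. On a single-snapshot window temporal
betweenness reduces exactly to contact betweenness.

Because the betweenness variants are expensive on long recordings, they are
computed on consecutive sub-windows and averaged (`windowed_metrics()`), by
default ten 4-minute windows — the conventional operating point for
hour-scale sensor deployments; `metric_table()` falls back to a single
all-covering window for shorter observations.

`degree_centrality_correlation()` computes, per $\Delta t$, the Spearman rank
correlation between contact degree (per-window or overall) and $t$-averaged
$C$. $\Delta t$ is capped at half the observation so enough start snapshots
remain to average over; with fewer than 3 varying agents the value is
reported missing rather than fabricated.

## Synthetic study conditions

`generate_network()` draws networks under four regimes chosen to emulate the
qualitative contrast between mingling crowds and segregated bubbles:
`"uniform"` (random events among all active agents), `"bubbles"` (events
confined to fixed blocks; traceability can never exceed the block fraction),
`"bubbles-bridge"` and `"idle"`. Defaults, fixed once as field-realistic
conditions: per-snapshot activity 0.35, event sizes drawn from 2–4 (one
trailing leftover may be absorbed, so sizes up to 5 occur), two bubbles. The
bridge agent emulates an occasional courier between clusters: it switches its
home bubble every 10 snapshots and is active with probability 0.1, keeping
its aggregated degree low while making it the only conduit between bubbles —
the canonical low-degree, high-impact profile. Events are materialised as a
random path among members, which is equivalent to any connected wiring under
the complete-event convention.

What the generator does *not* emulate: contact durations spanning bins,
sensor dropouts and clock desynchronisation, spatial structure (stands,
walking routes), or attribute-driven mixing. Passing tests on generated data
therefore validate the algorithms and their qualitative regime contrasts,
not any quantitative property of a particular empirical deployment.

```{r spectra, fig.width = 6, fig.height = 3.5}
net <- generate_network(30, 80, regime = "bubbles-bridge", seed = 3)
autoplot(centrality_spectrum(net, dt_grid = c(2, 5, 10, 20, 40)))
```

## Numerical and design choices

* **Exact arithmetic.** Traced sets are counted as integers; every reported
  fraction is an integer divided by $N$ (or $N^2$), so worked-example values
  are reproduced exactly, not to a tolerance.
* **Kernel.** The leave-one-out sweep runs in compiled code: per-snapshot
  components via union-find, then a backward pass over the window that keeps,
  per event, the bitset of agents traceable forward from it. The full sweep
  over all agents costs $O(T N^2)$ word operations, which is the practical
  complexity budget of the method; the test suite checks this scaling
  empirically on uniform networks with $N \in \{16, 32, 64\}$ at $T = 512$
  and $T \in \{128, 256, 512\}$ at $N = 48$ — sizes where the compiled kernel
  dominates interpreter overhead and the membership matrix stays
  cache-resident.
* **Dual implementations.** `trace_fraction()` uses an independent R-level
  frontier propagation; the kernel and the frontier are cross-checked against
  each other and against a time-expanded-graph BFS oracle in the tests.
* **Determinism.** Event labels are ordered by smallest member index;
  rankings break ties by agent id; the generator seeds a local RNG and
  restores the caller's state.
* **Degenerate inputs.** Empty logs give an `N = 0, T = 0` network; empty
  windows give edgeless graphs; agents with no events in a betweenness window
  get 0 with a warning; malformed or self-contact rows fail with the
  offending line number.
* **Gap handling.** Sensor-specific gap filtering is out of scope;
  `longest_active_run()` reports the longest contiguous stretch of non-empty
  snapshots so a caller can pre-trim.

## Limitations

* Reachability is purely topological: no transmission probability, latency
  or recovery. A traced agent is a *potential* recipient, not an infection.
* The complete-event convention can connect agents who never met directly;
  with slow transmission relative to event duration this overstates reach.
* Leave-one-out removal is a conceptual probe; an actual removal would change
  others' behaviour.
* All-pairs betweenness on the time-expanded graph scales poorly with
  $N \times T$; use windowing for long recordings.
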