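# contactseq

Temporal contact networks analysed the way spreading actually works: in
sequence. `contactseq` is for researchers working with timestamped
person-to-person contact data — proximity-sensor deployments at events,
schools, workplaces — who want to know how fast a population mingles and
*which individuals matter most* for the chains of contact that any spreading
process (a pathogen, a rumour) would have to travel.

## The method

Contacts `(agent_a, agent_b, timestamp)` are binned into snapshots. Within
each snapshot, connected components of the contact graph are **events**
(groups in direct or indirect contact, treated as completely connected);
events of consecutive snapshots are linked when they share an agent, giving a
time-directed **event graph** that preserves contact order.

On this representation, for a window of Δt snapshots starting at t:

- **Traceability** P(j, t, Δt) = (number of unique agents traceable to agent
  j through time-respecting event chains) / N,
- **Mean traceability** P̄(t, Δt) = (1/N) Σⱼ P(j, t, Δt) — the population's
  mingling speed,
- **Contact sequence centrality**
  C(i, t, Δt) = P̄(t, Δt) − P̄₋ᵢ(t, Δt) ≥ 0,
  where P̄₋ᵢ is recomputed after deleting all of agent i's contacts (N
  unchanged): the drop in average reach caused by one individual. Ranking
  agents by C identifies *behavioural super-spreaders* — who are, at longer
  time scales, often **not** the highest-degree agents.

Six classical baselines (aggregated degree, contact/event/temporal
betweenness, event counts and sizes), the Spearman correlation of degree with
C across time scales, synthetic generators (uniform mixing, closed bubbles,
bubbles with a low-degree bridge, idle), and contact-log I/O round out the
toolkit. The leave-one-out sweep runs in compiled code at O(T·N²).

## Worked example

The bundled eight-agent toy network has the pair contact {3,5} in snapshot 0
and events {5,8} and {1,2,3,7} in snapshot 1:

```r
library(contactseq)
net <- toy_network()
trace_fraction(net, agents = "5", t = 0, dt = c(1, 2))
#> # A tibble: 2 × 6
#>   agent     t    dt n_traced     p traced
#>   <chr> <int> <int>    <int> <dbl> <list>
#> 1 5         0     1        2  0.25 <chr [2]>
#> 2 5         0     2        6  0.75 <chr [6]>
```

With only snapshot 0 in view, agent 5's event {3,5} traces 2 of 8 agents
(25%); one propagation step later its sequence has reached {1,2,3,5,7,8}
(75%). Removing agent 3's contacts and re-tracing quantifies 3's impact:

```r
contact_sequence_centrality(net, agents = "3", t = 0, dt = 2)
#> # A tibble: 1 × 6
#>   agent     t    dt p_bar p_bar_removed centrality
#>   <chr> <int> <int> <dbl>         <dbl>      <dbl>
#> 1 3         0     2 0.438         0.188       0.25
```

Mean reach drops from 43.8% to 18.8% — agent 3 alone carries a quarter of
the population's average contact sequence, and `rank_agents(net, dt = 2)`
puts it first.

On a larger simulated population the signature result appears: a sparse
bridge between two bubbles (agent `a001`, the *minimum*-degree agent) is
invisible to degree but dominates centrality at long time scales, and the
degree–centrality correlation decays with Δt:

```r
sim <- generate_network(60, 120, regime = "bubbles-bridge", seed = 1)
degree_centrality_correlation(sim, dt_grid = c(5, 20, 60))
#> # A tibble: 3 × 4
#>      dt   rho n_agents degree_mode
#>   <int> <dbl>    <int> <chr>
#> 1     5 0.856       60 window
#> 2    20 0.204       60 window
#> 3    60 0.223       60 window

rank_agents(sim, dt = 60)
#> # A tibble: 60 × 4
#>   agent    dt mean_centrality  rank
#>   <chr> <int>           <dbl> <int>
#> 1 a001     60          0.263      1
#> 2 a024     60          0.170      2
#> 3 a025     60          0.0411    3
#> # ℹ 57 more rows
```

Results are tibbles throughout, so they pipe into dplyr/ggplot2 directly;
`autoplot()` methods cover activity, growth curves and centrality spectra,
and `tidy()`/`glance()` summarise networks and event graphs.

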