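#' Remove all temporal links of one agent
#'
#' Deletes every contact involving agent `i` from every snapshot while keeping
#' `i` in the agent universe, so `N` (the denominator of all traceability
#' fractions) is unchanged and the removed agent becomes an isolated node.
#' Events are recomputed on the perturbed contact lists: components of a
#' snapshot may split when `i` was the only connector between sub-groups.
#' The removal is a conceptual probe of the agent's impact, not a model of an
#' actual intervention.
#'
#' @param net A `temporal_network`.
#' @param agent The agent whose links are removed.
#' @return A `temporal_network` over the same universe and snapshots.
#' @examples
#' remove_agent_links(toy_network(), "3")
#' @export
remove_agent_links <- function(net, agent) {
  stopifnot(inherits(net, "temporal_network"))
  agent <- check_agent(net, agent)
  stopifnot(length(agent) == 1)
  contacts <- filter(net$contacts, .data$from != agent, .data$to != agent)
  temporal_network(contacts, agents = net$agents,
                   n_snapshots = net$n_snapshots,
                   resolution = net$resolution)
}

#' Traceability after removing one agent's links
#'
#' `P_{-i}(j, t, dt)`: [trace_fraction()] evaluated on the network with all
#' temporal links of agent `removed` deleted (see [remove_agent_links()]).
#' The denominator stays `N`, so `P_{-i}(j) <= P(j)` always, with equality
#' when `removed` never sits on any tracing path of `j` in the window.
#'
#' @param net A `temporal_network`.
#' @param removed The agent whose links are removed (may equal a traced agent;
#'   the removed agent's own trace is its isolated self, `1/N`).
#' @inheritParams trace_fraction
#' @return As [trace_fraction()], plus a `removed` column.
#' @examples
#' perturbed_trace(toy_network(), removed = "3", agents = "5", t = 0, dt = 2)
#' @export
perturbed_trace <- function(net, removed, agents = NULL, t, dt,
                            direction = c("forward", "backward")) {
  pert <- remove_agent_links(net, removed)
  out <- trace_fraction(pert, agents = agents, t = t, dt = dt,
                        direction = direction)
  mutate(out, removed = as.character(removed), .before = 1)
}

## Mean-trace sums (per start t) for the full network and for each removal.
## Returns list(base = numeric per t, pert = matrix agents x t). The removed
## agent stays a source on the perturbed network (its count is 1).
impact_sums <- function(net, agents, t_starts, dt) {
  sums <- cpp_impact_sums(
    as.integer(net$contacts$snapshot),
    match(net$contacts$from, net$agents) - 1L,
    match(net$contacts$to, net$agents) - 1L,
    n_agents(net), net$n_snapshots,
    as.integer(t_starts), as.integer(dt),
    match(agents, net$agents) - 1L
  )
  list(base = sums[1, ], pert = sums[-1, , drop = FALSE])
}

#' Contact sequence centrality
#'
#' `C(i, t, dt) = p_bar(t, dt) - p_bar_{-i}(t, dt)`: the drop in mean
#' traceability when all temporal links of agent `i` are removed. It is
#' non-negative, zero for agents isolated within the window, and measures the
#' agent's impact on contact sequences -- the behavioural spreading potential.
#' A high value can reflect many contacts, but also a low-degree agent that
#' bridges otherwise separate groups, which is exactly what static metrics
#' miss at longer time scales.
#'
#' Both means run over the same `N` sources; on the perturbed network the
#' removed agent still contributes its isolated self-trace `1/N`. Set
#' `removed_source = "exclude"` to instead average the perturbed trace over
#' the `N - 1` remaining sources (a sensitivity variant; the default keeps
#' isolated-agent centrality exactly zero).
#'
#' @param net A `temporal_network`.
#' @param agents Agents to probe; default the whole universe.
#' @param t Start snapshot(s), 0-based. Default all valid starts for each
#'   `dt`.
#' @param dt Window length(s) in snapshots.
#' @param direction `"forward"` or `"backward"`.
#' @param removed_source Whether the removed agent's own (isolated) trace
#'   enters the perturbed mean: `"include"` (default) or `"exclude"`.
#' @return A tibble with columns `agent`, `t`, `dt`, `p_bar`, `p_bar_removed`
#'   and `centrality`.
#' @examples
#' contact_sequence_centrality(toy_network(), agents = "3", t = 0, dt = 2)
#' @seealso [rank_agents()], [centrality_spectrum()]
#' @export
contact_sequence_centrality <- function(net, agents = NULL, t = NULL, dt,
                                        direction = c("forward", "backward"),
                                        removed_source = c("include",
                                                           "exclude")) {
  stopifnot(inherits(net, "temporal_network"))
  net <- resolve_direction(net, direction)
  removed_source <- match.arg(removed_source)
  agents <- check_agent(net, agents %||% net$agents)
  N <- n_agents(net)
  dt <- sort(unique(as.integer(dt)))
  rows <- lapply(dt, function(d) {
    ts <- as.integer(t %||% seq.int(0L, net$n_snapshots - d))
    check_trace_args(net, ts, d)
    sums <- impact_sums(net, agents, ts, d)
    if (removed_source == "exclude") {
      ## drop the removed agent's self count (always 1) and average over N-1
      p_pert <- (sums$pert - 1) / (N * (N - 1))
    } else {
      p_pert <- sums$pert / N^2
    }
    p_bar <- rep(sums$base / N^2, times = length(agents))
    p_bar_removed <- as.vector(t(p_pert))
    n_rows <- length(agents) * length(ts)
    tibble::new_tibble(list(
      agent = rep(agents, each = length(ts)),
      t = rep(ts, times = length(agents)),
      dt = rep(d, n_rows),
      p_bar = p_bar,
      p_bar_removed = p_bar_removed,
      centrality = p_bar - p_bar_removed
    ), nrow = n_rows)
  })
  bind_rows(rows)
}

#' Rank agents by time-averaged contact sequence centrality
#'
#' Averages `C(i, t, dt)` over all valid start snapshots `t` at a fixed window
#' length `dt` and ranks agents by the mean, descending. This is the standard
#' policy for naming a 'most impactful agent' at a chosen time scale; note the
#' identity of the top agent can change with `dt`. Ties are broken by agent id
#' ascending, so the ranking is deterministic.
#'
#' @param net A `temporal_network`.
#' @param dt Window length in snapshots (single value).
#' @param t Start snapshots to average over; default all valid starts.
#' @inheritParams contact_sequence_centrality
#' @return A tibble `agent`, `dt`, `mean_centrality`, `rank` sorted by rank.
#' @examples
#' rank_agents(toy_network(), dt = 2)
#' @export
rank_agents <- function(net, dt, t = NULL,
                        direction = c("forward", "backward"),
                        removed_source = c("include", "exclude")) {
  stopifnot(length(dt) == 1)
  net2 <- resolve_direction(net, direction)
  if (net2$n_snapshots < dt) abort_range("No valid start snapshot for `dt`.")
  percell <- contact_sequence_centrality(
    net2, t = t, dt = dt, removed_source = removed_source)
  out <- percell |>
    group_by(.data$agent) |>
    summarise(mean_centrality = mean(.data$centrality), .groups = "drop") |>
    mutate(dt = as.integer(dt), .after = "agent") |>
    arrange(dplyr::desc(.data$mean_centrality),
            match(.data$agent, net2$agents)) |>
    mutate(rank = row_number())
  out
}

#' Centrality spectra across window lengths
#'
#' Time-averaged contact sequence centrality of each agent as a function of
#' the window length `dt` -- the per-agent impact spectrum. Comparing spectra
#' reveals agents whose importance only emerges at long time scales (e.g.
#' bridges between bubbles) versus agents whose impact is immediate and local.
#'
#' @param net A `temporal_network`.
#' @param dt_grid Window lengths in snapshots.
#' @param agents Agents to include; default all.
#' @inheritParams contact_sequence_centrality
#' @return A tibble of class `centrality_spectrum`: `agent`, `dt`,
#'   `mean_centrality`. Plot with [ggplot2::autoplot()].
#' @examples
#' centrality_spectrum(toy_network(), dt_grid = 1:4)
#' @export
centrality_spectrum <- function(net, dt_grid, agents = NULL,
                                direction = c("forward", "backward"),
                                removed_source = c("include", "exclude")) {
  net2 <- resolve_direction(net, direction)
  dt_grid <- sort(unique(as.integer(dt_grid)))
  percell <- contact_sequence_centrality(
    net2, agents = agents, t = NULL, dt = dt_grid,
    removed_source = removed_source)
  out <- percell |>
    group_by(.data$agent, .data$dt) |>
    summarise(mean_centrality = mean(.data$centrality), .groups = "drop") |>
    arrange(match(.data$agent, net2$agents), .data$dt)
  class(out) <- c("centrality_spectrum", class(out))
  out
}
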