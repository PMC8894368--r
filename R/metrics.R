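#' Aggregated contact degree
#'
#' Number of unique agents each agent has been in an event with during the
#' window, i.e. the degree in the clique-aggregated static contact graph
#' (see [aggregate_contacts()]). A purely static metric: contact frequency
#' and ordering play no role.
#'
#' @param net A `temporal_network`.
#' @param window Half-open snapshot interval `c(start, end)`; default all.
#' @return A tibble `agent`, `degree`.
#' @examples
#' contact_degree(toy_network(), window = c(0, 2))
#' @export
contact_degree <- function(net, window = NULL) {
  g <- aggregate_contacts(net, window)
  tibble(agent = net$agents,
         degree = as.integer(igraph::degree(g)[net$agents]))
}

#' Betweenness in the aggregated contact graph
#'
#' Fraction of shortest paths between unordered agent pairs that pass through
#' each agent, computed on the unweighted aggregated contact graph and
#' normalised by `(n-1)(n-2)/2`. Pairs with no connecting path contribute
#' nothing (standard convention for disconnected graphs).
#'
#' @inheritParams contact_degree
#' @return A tibble `agent`, `contact_betweenness`.
#' @export
contact_betweenness <- function(net, window = NULL) {
  g <- aggregate_contacts(net, window)
  n <- igraph::vcount(g)
  b <- igraph::betweenness(g, directed = FALSE, normalized = FALSE)
  norm <- if (n > 2) (n - 1) * (n - 2) / 2 else 1
  tibble(agent = net$agents,
         contact_betweenness = unname(b[net$agents]) / norm)
}

#' Event participation: count and mean size of attended events
#'
#' `n_events` counts the non-individual events (size at least 2) an agent
#' attends in the window; `avg_event_size` averages the sizes of *all* its
#' attended events, singletons included, so an agent that is mostly isolated
#' is pulled towards 1.
#'
#' @inheritParams contact_degree
#' @return A tibble `agent`, `n_events`, `avg_event_size`. In an empty window
#'   `n_events = 0` and `avg_event_size = NaN` (no attended events).
#' @examples
#' event_participation(toy_network(), window = c(0, 2))
#' @export
event_participation <- function(net, window = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  window <- check_window(net, window)
  N <- n_agents(net)
  n_ev <- integer(N)
  size_sum <- numeric(N)
  n_att <- integer(N)
  if (window[2] > window[1]) {
    mem <- tn_membership(net)
    for (s in seq.int(window[1], window[2] - 1L)) {
      ev <- mem[, s + 1L]
      sizes <- tabulate(ev + 1L)
      per_agent <- sizes[ev + 1L]
      n_ev <- n_ev + (per_agent >= 2L)
      size_sum <- size_sum + per_agent
      n_att <- n_att + 1L
    }
  }
  tibble(agent = net$agents, n_events = n_ev,
         avg_event_size = size_sum / n_att)
}

#' Event betweenness of agents
#'
#' Betweenness centrality is computed on the time-directed event graph of the
#' window (shortest paths between ordered event pairs, normalised by
#' `(n-1)(n-2)`), then averaged over all events the agent attends in the
#' window. Captures how often an agent's events relay contact sequences
#' between other events; finer structure within events is invisible here.
#'
#' @inheritParams contact_degree
#' @param include_singletons Include singleton events as event-graph nodes?
#'   Default `FALSE` (an idle agent's chain of singleton events carries no
#'   other agent's paths but would dilute the normalisation).
#' @return A tibble `agent`, `event_betweenness`. Agents attending no event in
#'   the window get 0 with a warning.
#' @export
event_betweenness <- function(net, window = NULL, include_singletons = FALSE) {
  stopifnot(inherits(net, "temporal_network"))
  window <- check_window(net, window)
  sub <- window_network(net, window)
  eg <- build_event_graph(sub, include_singletons = include_singletons)
  n <- igraph::vcount(eg$graph)
  b <- if (n) igraph::betweenness(eg$graph, directed = TRUE,
                                  normalized = FALSE) else numeric()
  norm <- if (n > 2) (n - 1) * (n - 2) else 1
  val <- numeric(n_agents(net))
  cnt <- integer(n_agents(net))
  if (nrow(eg$events)) {
    for (k in seq_len(nrow(eg$events))) {
      idx <- match(eg$events$members[[k]], net$agents)
      val[idx] <- val[idx] + b[[k]] / norm
      cnt[idx] <- cnt[idx] + 1L
    }
  }
  if (any(cnt == 0)) {
    warn(sprintf("%d agent(s) attend no event in the window; betweenness 0.",
                 sum(cnt == 0)))
  }
  tibble(agent = net$agents,
         event_betweenness = ifelse(cnt > 0, val / pmax(cnt, 1L), 0))
}

## Restrict a network to a half-open snapshot window, re-indexed to 0.
window_network <- function(net, window) {
  contacts <- filter(net$contacts,
                     .data$snapshot >= window[1], .data$snapshot < window[2])
  contacts$snapshot <- contacts$snapshot - window[1]
  temporal_network(contacts, agents = net$agents,
                   n_snapshots = max(window[2] - window[1], 0L),
                   resolution = net$resolution)
}

## Time-expanded graph of a window: one vertex per (agent, snapshot),
## within-snapshot clique edges (mutual arcs when directed), and per-agent
## persistence arcs between consecutive snapshots.
time_expanded_graph <- function(net, window, directed = TRUE) {
  W <- window[2] - window[1]
  N <- n_agents(net)
  vid <- function(a_idx, s) (s - window[1]) * N + a_idx # 1-based vertex ids
  names <- as.vector(outer(net$agents,
                           seq.int(window[1], length.out = W),
                           function(a, s) paste0(a, "@", s)))
  edges <- integer(0)
  pairs <- clique_pairs(net, window)
  if (nrow(pairs)) {
    f <- vid(pairs$from_idx, pairs$snapshot)
    t <- vid(pairs$to_idx, pairs$snapshot)
    edges <- c(edges, rbind(f, t), if (directed) rbind(t, f))
  }
  if (W > 1) {
    for (s in seq.int(window[1], window[2] - 2L)) {
      edges <- c(edges, rbind(vid(seq_len(N), s), vid(seq_len(N), s + 1L)))
    }
  }
  g <- igraph::make_empty_graph(n = 0, directed = directed)
  g <- igraph::add_vertices(g, N * W, name = names)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

#' Temporal betweenness of agents
#'
#' Betweenness on the time-expanded graph of the window: vertices are
#' (agent, snapshot) copies, contacts within a snapshot connect copies of the
#' same time layer, and persistence edges connect an agent's consecutive
#' copies. With `directed = TRUE` (default) persistence edges point forward in
#' time and contact edges are mutual, so shortest paths are time-respecting.
#' The betweenness of an agent is the mean over its time copies, normalised by
#' `(n-1)(n-2)` (directed) or `(n-1)(n-2)/2` (undirected) with `n` the number
#' of time-expanded vertices. On a single-snapshot window this reduces exactly
#' to [contact_betweenness()].
#'
#' @inheritParams contact_degree
#' @param directed Treat persistence edges as forward-directed? Default
#'   `TRUE`.
#' @return A tibble `agent`, `temporal_betweenness`.
#' @export
temporal_betweenness <- function(net, window = NULL, directed = TRUE) {
  stopifnot(inherits(net, "temporal_network"))
  window <- check_window(net, window)
  N <- n_agents(net)
  W <- window[2] - window[1]
  if (W == 0 || N == 0) {
    return(tibble(agent = net$agents, temporal_betweenness = numeric(N)))
  }
  g <- time_expanded_graph(net, window, directed = directed)
  n <- igraph::vcount(g)
  b <- igraph::betweenness(g, directed = directed, normalized = FALSE)
  norm <- if (n > 2) {
    if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2) / 2
  } else 1
  per_copy <- matrix(b / norm, nrow = N) # rows: agents, cols: snapshots
  tibble(agent = net$agents, temporal_betweenness = rowMeans(per_copy))
}

#' Windowed event and temporal betweenness
#'
#' The two temporal betweenness variants are expensive on long observations,
#' so they are conventionally computed on consecutive sub-windows (by default
#' ten 4-minute intervals) and averaged per agent.
#'
#' @param net A `temporal_network`.
#' @param n_windows Number of consecutive sub-windows (default 10).
#' @param window_length Sub-window length in seconds (default 240).
#' @param directed Passed to [temporal_betweenness()].
#' @param include_singletons Passed to [event_betweenness()].
#' @return A tibble `agent`, `event_betweenness`, `temporal_betweenness`
#'   (means across sub-windows), with attributes `n_windows` and
#'   `window_length`.
#' @export
windowed_metrics <- function(net, n_windows = 10, window_length = 240,
                             directed = TRUE, include_singletons = FALSE) {
  stopifnot(inherits(net, "temporal_network"))
  L <- window_length / net$resolution
  if (L != floor(L) || L < 1) {
    abort_config("`window_length` must be a positive multiple of the resolution.")
  }
  L <- as.integer(L)
  if (n_windows * L > net$n_snapshots) {
    abort_range(sprintf(
      "%d windows of %d snapshots exceed the observation (T = %d).",
      n_windows, L, net$n_snapshots))
  }
  per_window <- lapply(seq_len(n_windows) - 1L, function(k) {
    w <- c(k * L, (k + 1L) * L)
    eb <- suppressWarnings(
      event_betweenness(net, w, include_singletons = include_singletons))
    tb <- temporal_betweenness(net, w, directed = directed)
    left_join(eb, tb, by = "agent")
  })
  out <- bind_rows(per_window) |>
    group_by(.data$agent) |>
    summarise(event_betweenness = mean(.data$event_betweenness),
              temporal_betweenness = mean(.data$temporal_betweenness),
              .groups = "drop") |>
    arrange(match(.data$agent, net$agents))
  attr(out, "n_windows") <- n_windows
  attr(out, "window_length") <- window_length
  out
}

#' All six comparison metrics in one table
#'
#' Convenience wrapper returning, per agent: aggregated `degree`,
#' `contact_betweenness`, `n_events`, `avg_event_size` (all over the full
#' observation) and the windowed `event_betweenness` and
#' `temporal_betweenness`. When the observation is shorter than
#' `n_windows * window_length`, a single window covering everything is used.
#'
#' @inheritParams windowed_metrics
#' @return A tibble of class `metric_table` with one row per agent.
#' @examples
#' metric_table(toy_network())
#' @export
metric_table <- function(net, n_windows = 10, window_length = 240,
                         directed = TRUE, include_singletons = FALSE) {
  stopifnot(inherits(net, "temporal_network"))
  span <- net$n_snapshots * net$resolution
  if (n_windows * window_length > span) {
    n_windows <- 1
    window_length <- span
  }
  wm <- windowed_metrics(net, n_windows, window_length,
                         directed = directed,
                         include_singletons = include_singletons)
  out <- contact_degree(net) |>
    left_join(contact_betweenness(net), by = "agent") |>
    left_join(event_participation(net), by = "agent") |>
    left_join(wm, by = "agent")
  class(out) <- c("metric_table", class(out))
  out
}

#' Correlation between contact degree and centrality across time scales
#'
#' For each window length `dt`, computes the Spearman rank correlation between
#' the agents' contact degree and their time-averaged contact sequence
#' centrality at that `dt`. At short time scales degree predicts impact well;
#' at longer time scales sequence effects take over and the correlation
#' typically decays. Window lengths are capped at half the observation so
#' enough start snapshots remain to average over.
#'
#' @param net A `temporal_network`.
#' @param dt_grid Window lengths in snapshots; values above `T/2` are dropped
#'   with a warning. Default: up to 10 lengths spread over `[1, T/2]`.
#' @param degree_mode `"window"` (default) uses, per `dt`, the mean over start
#'   snapshots of the agent's degree within `[t, t + dt)`; `"overall"` uses the
#'   whole-observation degree for every `dt`.
#' @param direction Passed to the centrality computation.
#' @return A tibble `dt`, `rho`, `n_agents`, `degree_mode`. `rho` is `NA` when
#'   fewer than 3 agents vary.
#' @export
degree_centrality_correlation <- function(net, dt_grid = NULL,
                                          degree_mode = c("window",
                                                          "overall"),
                                          direction = c("forward",
                                                        "backward")) {
  stopifnot(inherits(net, "temporal_network"))
  degree_mode <- match.arg(degree_mode)
  net2 <- resolve_direction(net, direction)
  T_ <- net2$n_snapshots
  cap <- floor(T_ / 2)
  if (cap < 1) abort_range("The observation is too short to correlate.")
  if (is.null(dt_grid)) {
    dt_grid <- unique(pmax(1L, as.integer(round(
      seq(1, cap, length.out = min(10, cap))))))
  }
  dt_grid <- sort(unique(as.integer(dt_grid)))
  if (any(dt_grid > cap)) {
    warn(sprintf("Dropping dt values above half the observation (%d).", cap))
    dt_grid <- dt_grid[dt_grid <= cap]
  }
  if (!length(dt_grid)) abort_range("No usable dt values.")

  overall_deg <- contact_degree(net2)$degree
  rows <- lapply(dt_grid, function(d) {
    rk <- rank_agents(net2, dt = d) |> arrange(match(.data$agent, net2$agents))
    deg <- if (degree_mode == "overall") {
      overall_deg
    } else {
      windowed_degree(net2, d)
    }
    ok <- sum(!is.na(deg)) >= 3 && stats::sd(deg) > 0 &&
      stats::sd(rk$mean_centrality) > 0
    rho <- if (ok) {
      suppressWarnings(cor(deg, rk$mean_centrality, method = "spearman"))
    } else NA_real_
    tibble(dt = d, rho = rho, n_agents = n_agents(net2),
           degree_mode = degree_mode)
  })
  bind_rows(rows)
}

## Mean over start snapshots of the per-window aggregated degree.
windowed_degree <- function(net, dt) {
  T_ <- net$n_snapshots
  N <- n_agents(net)
  pairs <- clique_pairs(net, c(0L, T_))
  starts <- seq.int(0L, T_ - dt)
  acc <- numeric(N)
  for (t0 in starts) {
    sel <- pairs$snapshot >= t0 & pairs$snapshot < t0 + dt
    if (any(sel)) {
      uq <- unique(pairs[sel, c("from_idx", "to_idx")])
      acc <- acc + tabulate(c(uq$from_idx, uq$to_idx), nbins = N)
    }
  }
  acc / length(starts)
}
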