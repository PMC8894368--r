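#' Build a snapshot-based temporal contact network
#'
#' A temporal network is an ordered sequence of `n_snapshots` snapshots over a
#' fixed universe of `agents`; each snapshot holds the set of unordered agent
#' pairs in contact during that time bin. The universe is fixed for the whole
#' observation: agents that are isolated in every snapshot stay in the universe
#' and in the denominator of every traceability fraction.
#'
#' @param contacts A data frame with columns `snapshot` (0-based integer bin
#'   index), `from` and `to` (agent identifiers). Duplicate pairs within a
#'   snapshot are collapsed; pair orientation is irrelevant. `NULL` or a
#'   zero-row frame gives a contact-free network.
#' @param agents Optional character vector declaring the agent universe. Must
#'   be a superset of the agents appearing in `contacts`. Defaults to the
#'   agents observed in `contacts`, sorted (numerically when ids are numeric).
#' @param n_snapshots Optional total number of snapshots `T`; defaults to
#'   `max(snapshot) + 1`. Snapshots with no contacts are legitimate and count.
#' @param resolution Seconds represented by one snapshot (default 1).
#'
#' @return An object of class `temporal_network`: a list with elements
#'   `contacts` (tibble `snapshot`, `from`, `to`, canonically ordered),
#'   `agents`, `n_snapshots` and `resolution`.
#' @examples
#' net <- temporal_network(
#'   data.frame(snapshot = c(0, 1), from = c("a", "b"), to = c("b", "c"))
#' )
#' net
#' @seealso [read_contact_log()], [toy_network()], [generate_network()]
#' @export
temporal_network <- function(contacts = NULL, agents = NULL,
                             n_snapshots = NULL, resolution = 1) {
  if (!is.numeric(resolution) || length(resolution) != 1 || resolution <= 0) {
    abort_config("`resolution` must be a single positive number.")
  }
  if (is.null(contacts)) {
    contacts <- tibble(snapshot = integer(), from = character(),
                       to = character())
  }
  contacts <- as_tibble(contacts)
  required <- c("snapshot", "from", "to")
  if (!all(required %in% names(contacts))) {
    abort_config("`contacts` needs columns `snapshot`, `from`, `to`.")
  }
  contacts <- contacts[required]
  contacts$from <- as.character(contacts$from)
  contacts$to <- as.character(contacts$to)
  if (any(contacts$from == contacts$to)) {
    bad <- which(contacts$from == contacts$to)[1]
    abort_parse(sprintf("Self-contact in row %d: agent '%s'.",
                        bad, contacts$from[bad]))
  }
  if (any(!is.finite(contacts$snapshot)) || any(contacts$snapshot < 0) ||
      any(contacts$snapshot != floor(contacts$snapshot))) {
    abort_range("`snapshot` indices must be non-negative integers.")
  }
  contacts$snapshot <- as.integer(contacts$snapshot)

  observed <- sort_agent_ids(c(contacts$from, contacts$to))
  if (is.null(agents)) {
    agents <- observed
  } else {
    agents <- sort_agent_ids(agents)
    missing <- setdiff(observed, agents)
    if (length(missing)) {
      abort_lookup(sprintf(
        "Contacts reference agents outside the declared universe: %s",
        paste(missing, collapse = ", ")))
    }
  }

  if (is.null(n_snapshots)) {
    n_snapshots <- if (nrow(contacts)) max(contacts$snapshot) + 1L else 0L
  }
  n_snapshots <- as.integer(n_snapshots)
  if (nrow(contacts) && n_snapshots <= max(contacts$snapshot)) {
    abort_range("`n_snapshots` must exceed the largest snapshot index.")
  }

  ## canonical pair orientation: by agent position in the universe
  idx_from <- match(contacts$from, agents)
  idx_to <- match(contacts$to, agents)
  swap <- idx_from > idx_to
  tmp <- contacts$from[swap]
  contacts$from[swap] <- contacts$to[swap]
  contacts$to[swap] <- tmp
  contacts <- distinct(contacts) |>
    arrange(.data$snapshot, match(.data$from, agents), match(.data$to, agents))

  structure(
    list(contacts = contacts, agents = agents,
         n_snapshots = n_snapshots, resolution = as.numeric(resolution)),
    class = "temporal_network"
  )
}

#' @export
print.temporal_network <- function(x, ...) {
  cat(sprintf(
    "<temporal_network> %d agents, %d snapshots (%g s each), %d contacts\n",
    n_agents(x), x$n_snapshots, x$resolution, nrow(x$contacts)))
  invisible(x)
}

#' Number of agents in the universe of a temporal network
#'
#' @param net A `temporal_network`.
#' @return Integer `N`, counting every agent in the universe including those
#'   isolated in all snapshots.
#' @export
n_agents <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  length(net$agents)
}

## 0-based event-membership matrix (agents x snapshots); shared by the tracing
## kernel, event mapping and the aggregation helpers.
tn_membership <- function(net, contacts = NULL) {
  contacts <- contacts %||% net$contacts
  N <- n_agents(net)
  T_ <- net$n_snapshots
  cpp_event_membership(
    as.integer(contacts$snapshot),
    match(contacts$from, net$agents) - 1L,
    match(contacts$to, net$agents) - 1L,
    N, T_
  )
}

check_agent <- function(net, agent) {
  agent <- as.character(agent)
  unknown <- setdiff(agent, net$agents)
  if (length(unknown)) {
    abort_lookup(sprintf("Unknown agent(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  agent
}

check_window <- function(net, window) {
  T_ <- net$n_snapshots
  if (is.null(window)) return(c(0L, T_))
  if (length(window) != 2 || any(window != floor(window))) {
    abort_range("`window` must be two integers c(start, end) (half-open).")
  }
  window <- as.integer(window)
  if (window[1] < 0 || window[2] > T_ || window[1] > window[2]) {
    abort_range(sprintf("`window` must satisfy 0 <= start <= end <= %d.", T_))
  }
  window
}

#' Aggregate a temporal network into a static contact graph
#'
#' Collapses the snapshots of a window into one unweighted, undirected graph on
#' the full agent universe. Two agents are linked if they ever co-occur in the
#' same event (connected component of a snapshot), i.e. each event contributes
#' a complete clique among its members -- the within-event complete-graph
#' convention used throughout the package. All sequence information is
#' discarded.
#'
#' @param net A `temporal_network`.
#' @param window Half-open snapshot interval `c(start, end)`; default the whole
#'   observation `c(0, T)`. An empty window gives an edgeless graph.
#' @return An [igraph::graph] with one vertex per agent (named) and the
#'   aggregated clique edges.
#' @examples
#' g <- aggregate_contacts(toy_network(), window = c(0, 2))
#' igraph::degree(g)["3"] # agent 3 met 5, 1, 2 and 7
#' @export
aggregate_contacts <- function(net, window = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  window <- check_window(net, window)
  pairs <- clique_pairs(net, window)
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, n_agents(net), name = net$agents)
  if (nrow(pairs)) {
    g <- igraph::add_edges(g, rbind(pairs$from_idx, pairs$to_idx))
  }
  g
}

## Unique clique-expanded pairs (1-based agent indices) over a window.
clique_pairs <- function(net, window) {
  if (window[1] >= window[2] || n_agents(net) == 0) {
    return(tibble(snapshot = integer(), from_idx = integer(),
                  to_idx = integer()))
  }
  mem <- tn_membership(net)
  out <- lapply(seq.int(window[1], window[2] - 1L), function(s) {
    ev <- mem[, s + 1L]
    sizes <- tabulate(ev + 1L)
    multi <- which(sizes >= 2) - 1L
    if (!length(multi)) return(NULL)
    ps <- lapply(multi, function(e) {
      members <- which(ev == e)
      cp <- combn(members, 2)
      tibble(snapshot = s, from_idx = cp[1, ], to_idx = cp[2, ])
    })
    bind_rows(ps)
  })
  out <- bind_rows(out)
  if (!nrow(out)) {
    return(tibble(snapshot = integer(), from_idx = integer(),
                  to_idx = integer()))
  }
  out
}

#' Longest contiguous run of non-empty snapshots
#'
#' Contact loggers can drop out for stretches of an experiment; a common
#' pre-processing step is to restrict analysis to the longest uninterrupted
#' stretch of activity. This helper reports that stretch so the caller can trim
#' the input; no filtering is applied by the package itself.
#'
#' @param net A `temporal_network`.
#' @return A one-row tibble with `start` (first snapshot of the run, 0-based),
#'   `end` (exclusive) and `length`. All-empty networks give a zero-length run.
#' @export
longest_active_run <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  T_ <- net$n_snapshots
  if (T_ == 0) return(tibble(start = 0L, end = 0L, length = 0L))
  active <- tabulate(net$contacts$snapshot + 1L, nbins = T_) > 0
  r <- rle(active)
  if (!any(r$values)) return(tibble(start = 0L, end = 0L, length = 0L))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  best <- which(r$values)[which.max(r$lengths[r$values])]
  tibble(start = as.integer(starts[best]), end = as.integer(ends[best]),
         length = as.integer(r$lengths[best]))
}

#' Reverse the direction of time of a temporal network
#'
#' Re-indexes snapshot `t` to `T - 1 - t`. Static aggregated quantities are
#' unaffected, but time-respecting traceability and contact sequence centrality
#' at a fixed start snapshot generally change: tracing forward on the reversed
#' network corresponds to tracing backward on the original, which is the
#' natural direction when asking where an agent's contacts came *from* (e.g.
#' upstream exposure) rather than where they may lead.
#'
#' @param net A `temporal_network`.
#' @return A `temporal_network` with reversed snapshot order. Applying the
#'   function twice returns the original network.
#' @export
reverse_time <- function(net) {
  stopifnot(inherits(net, "temporal_network"))
  contacts <- net$contacts
  contacts$snapshot <- net$n_snapshots - 1L - contacts$snapshot
  temporal_network(contacts, agents = net$agents,
                   n_snapshots = net$n_snapshots,
                   resolution = net$resolution)
}
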