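#' The eight-agent, four-snapshot toy network
#'
#' A small deterministic temporal network used throughout the documentation
#' and tests. Snapshot 0 holds the single contact \{3,5\}; snapshot 1 holds
#' contacts realising the events \{5,8\} and \{1,2,3,7\}; every other agent is
#' isolated in those snapshots. On this fixture the worked traceability values
#' are exact rationals: `P(5,0,1) = 2/8`, `P(5,0,2) = 6/8`, and after removing
#' agent 3's links `P_{-3}(5,0,2) = 2/8`.
#'
#' Snapshots 2 and 3 are a fixed completion: snapshot 2 holds \{1,2\},
#' \{7,8\} and \{4,6\}; snapshot 3 holds \{2,3\} and \{4,6\}. The completion
#' keeps agents 4 and 6 in a bubble of their own, so they never enter agent
#' 5's contact sequence while still counting in the denominator `N = 8`.
#'
#' @return A `temporal_network` with `N = 8`, `T = 4`, resolution 1 s.
#' @examples
#' trace_fraction(toy_network(), agents = "5", t = 0, dt = 2)
#' @export
toy_network <- function() {
  contacts <- tibble(
    snapshot = c(0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 3L, 3L),
    from = c("3", "5", "1", "2", "3", "1", "7", "4", "2", "4"),
    to   = c("5", "8", "2", "3", "7", "2", "8", "6", "3", "6")
  )
  temporal_network(contacts, agents = as.character(1:8),
                   n_snapshots = 4L, resolution = 1)
}

#' Generate a synthetic temporal contact network
#'
#' Draws a temporal network under one of four mixing regimes, emulating the
#' qualitative contrast between freely mingling crowds and populations
#' segregated into bubbles:
#'
#' * `"uniform"`: in each snapshot, each agent is active with probability
#'   `activity`; active agents are randomly partitioned into events of sizes
#'   drawn uniformly from `2:max_event_size` (a trailing leftover agent joins
#'   the last event).
#' * `"bubbles"`: same grouping, but agents are split into `n_bubbles`
#'   near-equal fixed blocks and events form within blocks only, so contact
#'   sequences can never cross bubbles.
#' * `"bubbles-bridge"`: as `"bubbles"`, except the first agent is a bridge:
#'   it floats between bubbles, switching its home bubble every
#'   `bridge_interval` snapshots, and is active with the (typically smaller)
#'   probability `bridge_activity`. The bridge is the canonical low-degree,
#'   high-impact agent: almost invisible to static degree, decisive for
#'   long-window traceability.
#' * `"idle"`: no contacts at all; every trace is an agent's own self.
#'
#' Events are materialised as a path of contacts among the (already shuffled)
#' members, which under the within-event clique convention is equivalent to
#' any other connected wiring. Given the same `seed` the generator is fully
#' reproducible and leaves the caller's RNG state untouched.
#'
#' @param n_agents,n_snapshots Universe size `N` and snapshot count `T`.
#' @param regime One of `"uniform"`, `"bubbles"`, `"bubbles-bridge"`,
#'   `"idle"`.
#' @param activity Per-snapshot probability that an agent participates in any
#'   event (default 0.35).
#' @param max_event_size Largest event size drawn (default 4).
#' @param n_bubbles Number of fixed blocks in the bubble regimes (default 2).
#' @param bridge_interval Snapshots between the bridge agent's bubble switches
#'   (default 10).
#' @param bridge_activity Per-snapshot activity of the bridge agent (default
#'   0.1; sparse on purpose).
#' @param resolution Seconds per snapshot (default 1).
#' @param seed Optional integer seed; identical seeds give identical networks.
#' @return A `temporal_network` with agents `"a001"`, `"a002"`, ...
#' @examples
#' net <- generate_network(20, 50, regime = "bubbles", seed = 1)
#' trace_growth_curve(net, dt_grid = c(5, 10, 25))
#' @export
generate_network <- function(n_agents, n_snapshots,
                             regime = c("uniform", "bubbles",
                                        "bubbles-bridge", "idle"),
                             activity = 0.35, max_event_size = 4,
                             n_bubbles = 2, bridge_interval = 10,
                             bridge_activity = 0.1,
                             resolution = 1, seed = NULL) {
  regime <- match.arg(regime)
  if (n_agents < 1 || n_snapshots < 1) {
    abort_config("`n_agents` and `n_snapshots` must be positive.")
  }
  if (max_event_size < 2) abort_config("`max_event_size` must be >= 2.")
  if (regime %in% c("bubbles", "bubbles-bridge") && n_bubbles < 2) {
    abort_config("Bubble regimes need at least 2 bubbles.")
  }
  if (regime %in% c("bubbles", "bubbles-bridge") &&
      n_agents < 2 * n_bubbles) {
    abort_config("Each bubble needs at least 2 agents.")
  }
  agents <- sprintf("a%03d", seq_len(n_agents))
  draw <- function() {
    if (regime == "idle") {
      return(tibble(snapshot = integer(), from = character(),
                    to = character()))
    }
    bubble_of <- sort(rep(seq_len(n_bubbles), length.out = n_agents))
    bridge <- if (regime == "bubbles-bridge") 1L else 0L
    rows <- vector("list", n_snapshots)
    for (s in seq_len(n_snapshots) - 1L) {
      act <- stats::runif(n_agents) < activity
      if (bridge) act[bridge] <- stats::runif(1) < bridge_activity
      groups <- list()
      if (regime == "uniform") {
        groups <- chop_groups(which(act), max_event_size)
      } else {
        home <- bubble_of
        if (bridge) {
          home[bridge] <-
            (floor(s / bridge_interval) %% n_bubbles) + 1L
        }
        for (bb in seq_len(n_bubbles)) {
          members <- which(act & home == bb)
          groups <- c(groups, chop_groups(members, max_event_size))
        }
      }
      if (length(groups)) {
        rows[[s + 1L]] <- bind_rows(lapply(groups, function(g) {
          tibble(snapshot = s, from = agents[g[-length(g)]],
                 to = agents[g[-1]])
        }))
      }
    }
    bind_rows(rows)
  }
  contacts <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (!nrow(contacts)) {
    contacts <- tibble(snapshot = integer(), from = character(),
                       to = character())
  }
  temporal_network(contacts, agents = agents, n_snapshots = n_snapshots,
                   resolution = resolution)
}

## Randomly partition `members` (already a random subset) into groups of sizes
## drawn from 2:max_size; a single leftover joins the last group. Groups of
## size 1 (when only one agent is active) are dropped: an isolated agent is
## simply not in contact.
chop_groups <- function(members, max_size) {
  if (length(members) < 2) return(list())
  members <- sample(members)
  groups <- list()
  while (length(members) >= 2) {
    k <- sample(2:max_size, 1)
    if (length(members) - k == 1) k <- k + 1 # absorb the leftover
    k <- min(k, length(members))
    groups[[length(groups) + 1L]] <- members[seq_len(k)]
    members <- members[-seq_len(k)]
  }
  groups
}
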