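# Fixture builders used across the suite. All randomness is seeded locally.

# Shorthand: network from a matrix-like spec list(c(snapshot, from, to), ...)
make_net <- function(triples, agents = NULL, n_snapshots = NULL,
                     resolution = 1) {
  df <- do.call(rbind, lapply(triples, function(x) {
    data.frame(snapshot = as.integer(x[[1]]), from = as.character(x[[2]]),
               to = as.character(x[[3]]))
  }))
  if (is.null(df)) df <- data.frame(snapshot = integer(), from = character(),
                                    to = character())
  temporal_network(df, agents = agents, n_snapshots = n_snapshots,
                   resolution = resolution)
}

# Erdos-Renyi-per-snapshot contact noise: every unordered pair flips a coin in
# every snapshot. Deliberately NOT built from the package generator, so the
# regimes and the raw sampler exercise different code paths.
random_pairs_network <- function(n, t, p = 0.15, seed = 1) {
  withr::with_seed(seed, {
    agents <- as.character(seq_len(n))
    pairs <- utils::combn(agents, 2)
    rows <- lapply(seq_len(t) - 1L, function(s) {
      on <- stats::runif(ncol(pairs)) < p
      if (!any(on)) return(NULL)
      data.frame(snapshot = s, from = pairs[1, on], to = pairs[2, on])
    })
    df <- do.call(rbind, rows)
    temporal_network(
      df %||% data.frame(snapshot = integer(), from = character(),
                         to = character()),
      agents = agents, n_snapshots = t)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A small network drawn from a randomly chosen regime (or the raw pair
# sampler); used for the oracle-equivalence sweeps.
random_mixed_network <- function(seed, n_max = 15, t_max = 8) {
  withr::with_seed(seed, {
    n <- sample(3:n_max, 1)
    t <- sample(2:t_max, 1)
    kind <- sample(c("pairs", "uniform", "bubbles", "bubbles-bridge",
                     "idle"), 1)
    NULL
  })
  # draw sizes under the seed above, then build (generators seed themselves)
  if (kind == "pairs") {
    random_pairs_network(n, t, p = 0.2, seed = seed + 1L)
  } else {
    n <- max(n, 4)
    generate_network(n, t, regime = kind, seed = seed + 1L,
                     activity = 0.5, bridge_interval = 2,
                     bridge_activity = 0.5)
  }
}

# Two 3-agent bubbles plus agent "7" bridging them through lone pair
# contacts: 3-7 at snapshot 1 and 4-7 at snapshot 2 (while 3 and 4 sit out of
# their bubble cliques in those snapshots, so the bridge never joins a large
# event). The bridge has aggregated degree 2 yet is the only conduit between
# the bubbles.
bridge_fixture <- function() {
  cl <- function(s, members) {
    cp <- utils::combn(members, 2)
    lapply(seq_len(ncol(cp)), function(k) c(s, cp[1, k], cp[2, k]))
  }
  tri <- c(
    cl(0, 1:3), cl(0, 4:6),
    cl(1, 1:2), list(c(1, 3, 7)), cl(1, 4:6),
    cl(2, 1:3), list(c(2, 4, 7)), cl(2, 5:6),
    cl(3, 1:3), cl(3, 4:6)
  )
  make_net(tri, agents = as.character(1:7), n_snapshots = 4)
}

# Directed chain of pair contacts 1-2, 2-3, 3-4 in consecutive snapshots:
# the canonical fixture where forward and reversed tracing disagree.
chain_fixture <- function() {
  make_net(list(c(0, 1, 2), c(1, 2, 3), c(2, 3, 4)),
           agents = as.character(1:4), n_snapshots = 3)
}
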