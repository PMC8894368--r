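# Independent oracles. These re-derive traceability and betweenness from
# first principles -- a time-expanded igraph BFS and a plain-R shortest-path
# enumerator -- and never call the package's propagation code.

# Time-expanded graph of window [t0, t0 + dt): one vertex per
# (agent, snapshot), mutual arcs for raw within-snapshot contacts (transitive
# closure through undirected contact edges reproduces the within-event clique
# convention), forward persistence arcs between an agent's consecutive copies.
oracle_expanded_graph <- function(net, t0, dt) {
  N <- n_agents(net)
  vid <- function(a_idx, s) (s - t0) * N + a_idx
  g <- igraph::make_empty_graph(n = N * dt, directed = TRUE)
  edges <- integer(0)
  cc <- net$contacts[net$contacts$snapshot >= t0 &
                       net$contacts$snapshot < t0 + dt, ]
  if (nrow(cc)) {
    fa <- vid(match(cc$from, net$agents), cc$snapshot)
    ta <- vid(match(cc$to, net$agents), cc$snapshot)
    edges <- c(edges, rbind(fa, ta), rbind(ta, fa))
  }
  if (dt > 1) {
    for (s in seq.int(t0, t0 + dt - 2L)) {
      edges <- c(edges, rbind(vid(seq_len(N), s), vid(seq_len(N), s + 1L)))
    }
  }
  if (length(edges)) g <- igraph::add_edges(g, edges)
  g
}

# Unique agents reachable from agent j's copy at t0 (BFS over the expanded
# graph), as a sorted character vector of agent ids.
oracle_traced <- function(net, j, t0, dt, g = NULL) {
  N <- n_agents(net)
  g <- g %||% oracle_expanded_graph(net, t0, dt)
  start <- match(j, net$agents)
  reached <- as.integer(igraph::subcomponent(g, start, mode = "out"))
  agent_idx <- unique((reached - 1L) %% N + 1L)
  sort(net$agents[agent_idx])
}

oracle_counts <- function(net, t0, dt) {
  g <- oracle_expanded_graph(net, t0, dt)
  vapply(net$agents, function(j) length(oracle_traced(net, j, t0, dt, g)),
         integer(1))
}

oracle_mean_trace <- function(net, t0, dt) {
  sum(oracle_counts(net, t0, dt)) / n_agents(net)^2
}

oracle_remove <- function(net, i) {
  keep <- net$contacts$from != i & net$contacts$to != i
  temporal_network(net$contacts[keep, ], agents = net$agents,
                   n_snapshots = net$n_snapshots,
                   resolution = net$resolution)
}

oracle_centrality <- function(net, i, t0, dt) {
  oracle_mean_trace(net, t0, dt) - oracle_mean_trace(oracle_remove(net, i),
                                                     t0, dt)
}

# Unnormalised betweenness by explicit shortest-path counting (BFS distances
# and path multiplicities from every source; no Brandes accumulation).
# `edges`: 2-column matrix of 1-based vertex indices.
oracle_betweenness_raw <- function(n, edges, directed) {
  adj <- vector("list", n)
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      a <- edges[k, 1]; b <- edges[k, 2]
      adj[[a]] <- c(adj[[a]], b)
      if (!directed) adj[[b]] <- c(adj[[b]], a)
    }
  }
  bfs <- function(s) {
    dist <- rep(Inf, n); sigma <- numeric(n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(dist[w])) {
            dist[w] <- dist[v] + 1
            nxt <- c(nxt, w)
          }
          if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
        }
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  sp <- lapply(seq_len(n), bfs)
  b <- numeric(n)
  for (s in seq_len(n)) {
    for (t in seq_len(n)) {
      if (s == t) next
      if (!directed && s > t) next
      dst <- sp[[s]]$dist[t]
      if (is.infinite(dst)) next
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (sp[[s]]$dist[v] + sp[[v]]$dist[t] == dst) {
          b[v] <- b[v] +
            sp[[s]]$sigma[v] * sp[[v]]$sigma[t] / sp[[s]]$sigma[t]
        }
      }
    }
  }
  b
}

oracle_betweenness_graph <- function(g) {
  oracle_betweenness_raw(igraph::vcount(g),
                         igraph::as_edgelist(g, names = FALSE),
                         directed = igraph::is_directed(g))
}
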