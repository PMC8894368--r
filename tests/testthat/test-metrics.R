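test_that("aggregated degree counts unique event partners", {
  toy <- toy_network()
  deg <- contact_degree(toy, window = c(0, 2))
  expect_equal(deg$degree[deg$agent == "3"], 4)
  expect_equal(deg$degree[deg$agent == "4"], 0)
  # star contacts in one snapshot form one event: clique degrees k - 1
  star <- make_net(list(c(0, 1, 2), c(0, 1, 3), c(0, 1, 4), c(0, 1, 5)))
  expect_equal(contact_degree(star)$degree, rep(4, 5))
})

test_that("contact betweenness follows unordered-pair normalisation", {
  # contacts in *different* snapshots keep the aggregated graph a path
  path3 <- make_net(list(c(0, 1, 2), c(1, 2, 3)))
  cb <- contact_betweenness(path3)
  expect_equal(cb$contact_betweenness[cb$agent == "2"], 1.0)
  expect_equal(cb$contact_betweenness[cb$agent == "1"], 0)
  # complete components carry no shortest paths through interior vertices
  tri <- make_net(list(c(0, 1, 2), c(0, 2, 3)))
  expect_equal(contact_betweenness(tri)$contact_betweenness, rep(0, 3))
})

test_that("event participation counts non-individual events, sizes include singletons", {
  toy <- toy_network()
  ep <- event_participation(toy, window = c(0, 2))
  expect_equal(ep$n_events[ep$agent == "5"], 2) # events {3,5} and {5,8}
  expect_equal(ep$n_events[ep$agent == "4"], 0)
  expect_equal(ep$avg_event_size[ep$agent == "4"], 1.0)
  # agent 7: singleton at snapshot 0, size-4 event at snapshot 1
  expect_equal(ep$avg_event_size[ep$agent == "7"], (1 + 4) / 2)
  expect_equal(ep$n_events[ep$agent == "7"], 1)
})

test_that("event betweenness is the mean over an agent's events", {
  # pair 1-2 in contact every snapshot, singletons excluded: the event graph
  # is a directed path; endpoints carry no paths, interior events do
  net <- make_net(lapply(0:3, function(s) c(s, 1, 2)), n_snapshots = 4)
  eg <- build_event_graph(net, include_singletons = FALSE)
  b <- igraph::betweenness(eg$graph, directed = TRUE)
  snaps <- igraph::V(eg$graph)$snapshot
  expect_true(all(b[snaps %in% c(1, 2)] > 0))
  expect_true(all(b[snaps %in% c(0, 3)] == 0))
  eb <- event_betweenness(net)
  expect_equal(eb$event_betweenness[1], eb$event_betweenness[2])
  expect_true(eb$event_betweenness[1] > 0)
})

test_that("an agent with no events in the window gets 0 with a warning", {
  net <- make_net(list(c(0, 1, 2)), agents = as.character(1:3),
                  n_snapshots = 1)
  expect_warning(eb <- event_betweenness(net), "no event")
  expect_equal(eb$event_betweenness[eb$agent == "3"], 0)
})

test_that("event betweenness matches exhaustive path counting on the toy network", {
  toy <- toy_network()
  for (inc in c(TRUE, FALSE)) {
    eg <- build_event_graph(toy, include_singletons = inc)
    ours <- igraph::betweenness(eg$graph, directed = TRUE)
    ref <- oracle_betweenness_graph(eg$graph)
    expect_equal(unname(ours), ref)
  }
})

test_that("temporal betweenness on one snapshot equals contact betweenness", {
  net <- make_net(list(c(0, 1, 2), c(1, 2, 3), c(2, 3, 4), c(1, 4, 5)))
  for (s in 0:2) {
    w <- c(s, s + 1L)
    tb <- temporal_betweenness(net, window = w)
    cb <- contact_betweenness(net, window = w)
    expect_equal(tb$temporal_betweenness, cb$contact_betweenness)
  }
})

test_that("temporal betweenness is symmetric on a fully idle network", {
  idle <- make_net(list(), agents = letters[1:4], n_snapshots = 4)
  tb <- temporal_betweenness(idle)
  expect_equal(length(unique(round(tb$temporal_betweenness, 12))), 1)
})

test_that("betweenness engines agree with the oracle on small graphs", {
  net <- random_pairs_network(6, 3, p = 0.3, seed = 17)
  # aggregated (undirected)
  g <- aggregate_contacts(net)
  expect_equal(unname(igraph::betweenness(g, directed = FALSE)),
               oracle_betweenness_graph(g))
  # time-expanded, directed and undirected modes
  for (directed in c(TRUE, FALSE)) {
    te <- contactseq:::time_expanded_graph(net, c(0L, net$n_snapshots),
                                           directed = directed)
    expect_equal(unname(igraph::betweenness(te, directed = directed)),
                 oracle_betweenness_graph(te))
  }
})

test_that("a single window reproduces unwindowed betweenness", {
  net <- random_pairs_network(7, 4, p = 0.25, seed = 5)
  wm <- windowed_metrics(net, n_windows = 1,
                         window_length = net$n_snapshots * net$resolution)
  eb <- suppressWarnings(event_betweenness(net))
  tb <- temporal_betweenness(net)
  expect_equal(wm$event_betweenness, eb$event_betweenness)
  expect_equal(wm$temporal_betweenness, tb$temporal_betweenness)
})

test_that("shifting contacts by a whole window permutes but preserves means", {
  tri <- list(c(0, 1, 2), c(1, 2, 3), c(2, 1, 3), c(3, 3, 4))
  a <- make_net(tri, agents = as.character(1:4), n_snapshots = 8)
  b <- make_net(lapply(tri, function(x) c(x[1] + 4, x[2], x[3])),
                agents = as.character(1:4), n_snapshots = 8)
  wa <- suppressWarnings(windowed_metrics(a, n_windows = 2, window_length = 4))
  wb <- suppressWarnings(windowed_metrics(b, n_windows = 2, window_length = 4))
  expect_equal(wa$event_betweenness, wb$event_betweenness)
  expect_equal(wa$temporal_betweenness, wb$temporal_betweenness)
})

test_that("infeasible windowing is rejected", {
  net <- make_net(list(c(0, 1, 2)), n_snapshots = 5)
  expect_error(windowed_metrics(net, n_windows = 3, window_length = 2),
               class = "contactseq_error_range")
})

test_that("degree-centrality correlation is 1 when impact mirrors degree", {
  # one snapshot of full cliques with distinct sizes (plus an empty snapshot
  # so at least one window length is admissible): removing an agent from a
  # clique of size m costs 2(m-1) traced pairs, so C orders exactly as degree
  cl <- function(members) {
    cp <- utils::combn(members, 2)
    lapply(seq_len(ncol(cp)), function(k) c(0, cp[1, k], cp[2, k]))
  }
  tri <- c(cl(1:2), cl(3:5), cl(6:9), cl(10:14))
  net <- make_net(tri, agents = as.character(1:14), n_snapshots = 2)
  res <- degree_centrality_correlation(net, dt_grid = 1,
                                       degree_mode = "overall")
  expect_equal(res$rho, 1)
})

test_that("correlation is invariant under agent relabelling", {
  net <- generate_network(16, 20, regime = "uniform", seed = 4)
  relabel <- setNames(rev(net$agents), net$agents)
  contacts <- net$contacts
  contacts$from <- unname(relabel[contacts$from])
  contacts$to <- unname(relabel[contacts$to])
  net2 <- temporal_network(contacts, agents = net$agents,
                           n_snapshots = net$n_snapshots)
  r1 <- degree_centrality_correlation(net, dt_grid = c(2, 5))
  r2 <- degree_centrality_correlation(net2, dt_grid = c(2, 5))
  expect_equal(r1$rho, r2$rho)
})

test_that("window lengths above half the observation are dropped", {
  net <- generate_network(10, 12, regime = "uniform", seed = 2)
  expect_warning(res <- degree_centrality_correlation(net, dt_grid = c(3, 10)),
                 "half")
  expect_equal(res$dt, 3L)
})

test_that("metric_table assembles all six metrics per agent", {
  toy <- toy_network()
  mt <- metric_table(toy)
  expect_equal(nrow(mt), 8)
  expect_named(mt, c("agent", "degree", "contact_betweenness", "n_events",
                     "avg_event_size", "event_betweenness",
                     "temporal_betweenness"))
  expect_true(all(mt$degree >= 0 & mt$degree <= 7))
  expect_true(all(mt$avg_event_size >= 1))
})
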