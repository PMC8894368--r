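test_that("link removal isolates the agent but preserves the universe", {
  toy <- toy_network()
  pert <- remove_agent_links(toy, "3")
  expect_equal(n_agents(pert), 8)
  expect_false(any(pert$contacts$from == "3" | pert$contacts$to == "3"))
  # snapshot 1 loses 3 from the big event; 1,2,7 stay connected via 1-2, 2-..?
  ev <- map_events(pert, snapshot = 1)
  sizes <- sort(ev$size, decreasing = TRUE)
  members <- lapply(ev$members, sort)
  expect_true(any(vapply(members, identical, TRUE, y = c("5", "8"))))
  # raw snapshot-1 contacts were 1-2, 2-3, 3-7: without 3, agent 7 splits off
  expect_true(any(vapply(members, identical, TRUE, y = c("1", "2"))))
  expect_true(any(vapply(members, identical, TRUE, y = "7")))
})

test_that("removing an always-isolated agent changes nothing", {
  net <- make_net(list(c(0, 1, 2)), agents = as.character(1:4),
                  n_snapshots = 2)
  pert <- remove_agent_links(net, "4")
  expect_identical(pert$contacts, net$contacts)
})

test_that("the worked perturbed trace holds and P_{-i} <= P elementwise", {
  toy <- toy_network()
  pt <- perturbed_trace(toy, removed = "3", agents = "5", t = 0, dt = 2)
  expect_identical(pt$n_traced, 2L)
  expect_identical(pt$p, 2 / 8)
  expect_setequal(pt$traced[[1]], c("5", "8"))

  for (seed in 1:4) {
    net <- random_mixed_network(seed + 20)
    d <- net$n_snapshots
    base <- trace_fraction(net, t = 0, dt = d)
    for (i in net$agents[1:2]) {
      pert <- perturbed_trace(net, removed = i, t = 0, dt = d)
      expect_true(all(pert$p <= base$p + 1e-12))
    }
  }
})

test_that("removing an agent isolated in the window leaves traces unchanged", {
  net <- make_net(list(c(0, 1, 2), c(1, 2, 3)), agents = as.character(1:5),
                  n_snapshots = 2)
  base <- trace_fraction(net, t = 0, dt = 2)
  pert <- perturbed_trace(net, removed = "5", t = 0, dt = 2)
  expect_identical(base$p, pert$p)
  cc <- contact_sequence_centrality(net, agents = "5", t = 0, dt = 2)
  expect_identical(cc$centrality, 0)
})

test_that("a single pair contact gives both agents centrality 2/N^2", {
  net <- make_net(list(c(0, "a", "b")), agents = letters[1:5],
                  n_snapshots = 1)
  cc <- contact_sequence_centrality(net, t = 0, dt = 1)
  expect_equal(cc$centrality[cc$agent == "a"], 2 / 25)
  expect_equal(cc$centrality[cc$agent == "b"], 2 / 25)
  expect_true(all(cc$centrality[!cc$agent %in% c("a", "b")] == 0))
  rk <- rank_agents(net, dt = 1)
  expect_setequal(rk$agent[rk$rank <= 2], c("a", "b"))
  expect_equal(rk$mean_centrality[1], rk$mean_centrality[2])
})

test_that("centrality is non-negative and matches the oracle on random networks", {
  for (seed in 1:8) {
    net <- random_mixed_network(seed + 300, n_max = 12, t_max = 6)
    T_ <- net$n_snapshots
    t0 <- withr::with_seed(seed, sample(0:(T_ - 1), 1))
    d <- withr::with_seed(seed + 1, sample(seq_len(T_ - t0), 1))
    cc <- contact_sequence_centrality(net, t = t0, dt = d)
    expect_true(all(cc$centrality >= -1e-12))
    for (i in head(net$agents, 3)) {
      expect_equal(cc$centrality[cc$agent == i & cc$t == t0],
                   oracle_centrality(net, i, t0, d))
    }
  }
})

test_that("mirror-symmetric bubbles tie and are broken by agent id", {
  tri <- list()
  for (s in 0:2) tri <- c(tri, list(c(s, 1, 2), c(s, 3, 4)))
  net <- make_net(tri, agents = as.character(1:4), n_snapshots = 3)
  rk <- rank_agents(net, dt = 3)
  expect_equal(length(unique(rk$mean_centrality)), 1)
  expect_equal(rk$agent, as.character(1:4)) # id order on full tie
  expect_equal(rk$rank, 1:4)
})

test_that("a low-degree bridge dominates at long windows but not short ones", {
  net <- bridge_fixture()
  deg <- contact_degree(net)
  expect_equal(deg$degree[deg$agent == "7"], 2)
  expect_equal(min(deg$degree), 2) # nobody has fewer partners than the bridge

  rk_long <- rank_agents(net, dt = 4)
  expect_equal(rk_long$agent[1], "7")

  spec <- centrality_spectrum(net, dt_grid = c(1, 4))
  top_at <- function(d) {
    s <- spec[spec$dt == d, ]
    s$agent[which.max(s$mean_centrality)]
  }
  expect_false(top_at(1) == "7") # short windows favour clique members
  expect_equal(top_at(4), "7")
  # every spectrum value is bounded by the unperturbed mean
  curve <- trace_growth_curve(net, dt_grid = c(1, 4))
  for (d in c(1, 4)) {
    expect_true(all(spec$mean_centrality[spec$dt == d] <=
                      curve$p_mean[curve$dt == d] + 1e-12))
  }
})

test_that("excluding the removed source is a documented variant", {
  net <- bridge_fixture()
  inc <- contact_sequence_centrality(net, agents = "7", t = 0, dt = 4)
  exc <- contact_sequence_centrality(net, agents = "7", t = 0, dt = 4,
                                     removed_source = "exclude")
  expect_false(identical(inc$centrality, exc$centrality))
  # default convention: a window-isolated agent has exactly zero impact
  semi <- make_net(list(c(0, 1, 2)), agents = as.character(1:4),
                   n_snapshots = 1)
  cc <- contact_sequence_centrality(semi, agents = "4", t = 0, dt = 1)
  expect_identical(cc$centrality, 0)
  # excluding the removed source shifts the perturbed mean upward instead
  cc_ex <- contact_sequence_centrality(semi, agents = "4", t = 0, dt = 1,
                                       removed_source = "exclude")
  expect_lt(cc_ex$centrality, 0)
  # on a fully idle network both conventions agree on zero
  idle <- make_net(list(), agents = as.character(1:4), n_snapshots = 2)
  for (mode in c("include", "exclude")) {
    cc0 <- contact_sequence_centrality(idle, agents = "1", t = 0, dt = 2,
                                       removed_source = mode)
    expect_equal(cc0$centrality, 0)
  }
})

test_that("rankings at a fixed start differ under time reversal", {
  net <- chain_fixture()
  fwd <- contact_sequence_centrality(net, t = 0, dt = 2)
  bwd <- contact_sequence_centrality(reverse_time(net), t = 0, dt = 2)
  top_fwd <- fwd$agent[which.max(fwd$centrality)]
  top_bwd <- bwd$agent[which.max(bwd$centrality)]
  expect_equal(top_fwd, "2")
  expect_equal(top_bwd, "3")
  # while static degree is reversal-invariant
  expect_equal(contact_degree(net), contact_degree(reverse_time(net)))
})
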