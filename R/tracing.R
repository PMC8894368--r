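## Shared validation for tracing windows. `t` and `dt` are snapshot counts:
## the window [t, t + dt) covers dt whole snapshots, so dt = 1 sees only
## snapshot t. t is 0-based.
check_trace_args <- function(net, t, dt) {
  T_ <- net$n_snapshots
  if (any(t != floor(t)) || any(dt != floor(dt))) {
    abort_range("`t` and `dt` must be integers (snapshot counts).")
  }
  if (any(dt < 1)) abort_range("`dt` must be at least 1 snapshot.")
  if (any(t < 0) || any(t >= T_)) {
    abort_range(sprintf("`t` must lie in [0, %d).", T_))
  }
  if (any(outer(t, dt, "+") > T_)) {
    abort_range(sprintf("Windows must fit the observation: t + dt <= %d.", T_))
  }
  invisible(TRUE)
}

resolve_direction <- function(net, direction) {
  direction <- match.arg(direction, c("forward", "backward"))
  if (direction == "backward") reverse_time(net) else net
}

## Frontier propagation for one source over a window, in plain R. Returns the
## logical reach vector after each of the first `dt` snapshots. Kept separate
## from the C++ kernel: the two are cross-checked in the test suite.
trace_reach_profile <- function(mem, j_idx, t, dt) {
  N <- nrow(mem)
  r <- logical(N)
  r[j_idx] <- TRUE
  out <- vector("list", dt)
  for (k in seq_len(dt)) {
    ev <- mem[, t + k] # column t + k is snapshot t + k - 1 (0-based)
    r <- r | (ev %in% ev[r])
    out[[k]] <- r
  }
  out
}

#' Time-respecting traceability of single agents
#'
#' `P(j, t, dt)` is the fraction of the `N`-agent universe that can be linked
#' to agent `j` at snapshot `t` through a time-respecting chain of events
#' within the window of `dt` snapshots `[t, t + dt)`. Tracing seeds from the
#' whole event containing `j` at snapshot `t` (so `dt = 1` already counts
#' `j`'s contacts at `t`), then propagates event-to-event through shared
#' agents; every member of a reached event is traced. An agent isolated
#' throughout the window traces only itself: `P = 1/N`.
#'
#' @param net A `temporal_network`.
#' @param agents Agents to trace from; default the whole universe.
#' @param t Start snapshot (0-based, single value).
#' @param dt Window length(s) in snapshots; may be a vector, in which case one
#'   row per (agent, dt) combination is returned from a single propagation.
#' @param direction `"forward"` (default) traces who can be reached from `j`;
#'   `"backward"` traces on the time-reversed network, i.e. who could have
#'   reached `j`.
#' @return A tibble with columns `agent`, `t`, `dt`, `n_traced`, `p` and a
#'   list column `traced` of traced agent ids.
#' @examples
#' trace_fraction(toy_network(), agents = "5", t = 0, dt = c(1, 2))
#' @seealso [mean_trace()], [perturbed_trace()]
#' @export
trace_fraction <- function(net, agents = NULL, t, dt,
                           direction = c("forward", "backward")) {
  stopifnot(inherits(net, "temporal_network"))
  net <- resolve_direction(net, direction)
  agents <- check_agent(net, agents %||% net$agents)
  stopifnot(length(t) == 1)
  check_trace_args(net, t, dt)
  dt <- sort(unique(as.integer(dt)))
  N <- n_agents(net)
  mem <- tn_membership(net)
  rows <- lapply(agents, function(j) {
    profile <- trace_reach_profile(mem, match(j, net$agents), t, max(dt))
    traced <- lapply(dt, function(d) net$agents[profile[[d]]])
    tibble(
      agent = j, t = as.integer(t), dt = dt,
      n_traced = lengths(traced),
      p = lengths(traced) / N,
      traced = traced
    )
  })
  bind_rows(rows)
}

#' Mean traceability of a temporal network
#'
#' The population mean of [trace_fraction()] over all `N` agents (isolated
#' agents included). High values mean the system mingles quickly within the
#' window -- an entity introduced at snapshot `t` could reach a large share of
#' the population by `t + dt`.
#'
#' @param net A `temporal_network`.
#' @param t Start snapshot(s), 0-based; default all starts valid for each
#'   `dt`.
#' @param dt Window length(s) in snapshots.
#' @param direction `"forward"` or `"backward"` (time-reversed tracing).
#' @return A tibble with one row per (t, dt) pair: columns `t`, `dt`, `p_bar`.
#' @examples
#' mean_trace(toy_network(), t = 0, dt = 2)
#' @export
mean_trace <- function(net, t = NULL, dt,
                       direction = c("forward", "backward")) {
  stopifnot(inherits(net, "temporal_network"))
  net <- resolve_direction(net, direction)
  N <- n_agents(net)
  if (N == 0) abort_range("The network has no agents.")
  dt <- sort(unique(as.integer(dt)))
  mem <- tn_membership(net)
  rows <- lapply(dt, function(d) {
    ts <- t %||% seq.int(0L, net$n_snapshots - d)
    check_trace_args(net, ts, d)
    sums <- cpp_trace_count_sums(mem, as.integer(ts), d)
    tibble(t = as.integer(ts), dt = d, p_bar = sums / N^2)
  })
  bind_rows(rows)
}

#' Growth of mean traceability with window length
#'
#' For each window length `dt`, computes the mean traceability
#' `p_bar(t, dt)` at every valid start snapshot `t` and summarises its
#' mean, minimum and maximum over `t`. The mean curve is non-decreasing in
#' `dt` for every fixed `t`; a flat, low curve signals a segregated
#' population, a steep one fast mingling.
#'
#' @param net A `temporal_network`.
#' @param dt_grid Window lengths in snapshots; default `1:T`.
#' @param direction `"forward"` or `"backward"`.
#' @return A tibble of class `trace_curve`: `dt`, `p_mean`, `p_min`, `p_max`,
#'   `n_starts`. Plot with [ggplot2::autoplot()].
#' @examples
#' trace_growth_curve(toy_network())
#' @export
trace_growth_curve <- function(net, dt_grid = NULL,
                               direction = c("forward", "backward")) {
  stopifnot(inherits(net, "temporal_network"))
  net <- resolve_direction(net, direction)
  T_ <- net$n_snapshots
  dt_grid <- dt_grid %||% seq_len(T_)
  if (!length(dt_grid)) {
    out <- tibble(dt = integer(), p_mean = double(), p_min = double(),
                  p_max = double(), n_starts = integer())
    class(out) <- c("trace_curve", class(out))
    return(out)
  }
  dt_grid <- sort(unique(as.integer(dt_grid)))
  check_trace_args(net, 0L, dt_grid)
  per_t <- mean_trace(net, t = NULL, dt = dt_grid)
  out <- per_t |>
    group_by(.data$dt) |>
    summarise(
      p_mean = mean(.data$p_bar),
      p_min = min(.data$p_bar),
      p_max = max(.data$p_bar),
      n_starts = dplyr::n(),
      .groups = "drop"
    )
  class(out) <- c("trace_curve", class(out))
  out
}
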