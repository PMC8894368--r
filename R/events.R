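#' Events of a temporal network
#'
#' An *event* is a connected component of one snapshot's contact graph: a group
#' of agents in (possibly indirect) contact during that time bin. Isolated
#' agents form singleton events, so the events of a snapshot always partition
#' the agent universe. Within an event the contact structure is treated as a
#' complete graph for all downstream tracing and aggregation.
#'
#' `event_table()` lists the events of all (or selected) snapshots;
#' `map_events()` is the single-snapshot convenience wrapper.
#'
#' @param net A `temporal_network`.
#' @param snapshots Integer vector of 0-based snapshot indices; default all.
#' @param snapshot A single 0-based snapshot index.
#' @return A tibble with one row per event: `id` (stable identifier combining
#'   snapshot and sorted members), `snapshot`, `event` (0-based index within
#'   the snapshot), `size`, and `members` (list column of agent ids).
#' @examples
#' map_events(toy_network(), snapshot = 1)
#' @export
event_table <- function(net, snapshots = NULL) {
  stopifnot(inherits(net, "temporal_network"))
  T_ <- net$n_snapshots
  snapshots <- snapshots %||% (seq_len(T_) - 1L)
  if (length(snapshots) && (any(snapshots < 0) || any(snapshots >= T_))) {
    abort_range(sprintf("Snapshot indices must lie in [0, %d).", T_))
  }
  mem <- tn_membership(net)
  rows <- lapply(as.integer(snapshots), function(s) {
    ev <- mem[, s + 1L]
    members <- split(net$agents, ev)
    tibble(
      snapshot = s,
      event = as.integer(names(members)),
      size = lengths(members),
      members = unname(members)
    )
  })
  out <- bind_rows(rows)
  if (!nrow(out)) {
    return(tibble(id = character(), snapshot = integer(), event = integer(),
                  size = integer(), members = list()))
  }
  out$id <- paste0(out$snapshot, ":",
                   vapply(out$members, paste, "", collapse = "|"))
  out[, c("id", "snapshot", "event", "size", "members")]
}

#' @rdname event_table
#' @export
map_events <- function(net, snapshot) {
  event_table(net, snapshots = snapshot)
}

#' Build the time-directed event graph
#'
#' Nodes are events; a directed edge runs from an event at snapshot `t` to an
#' event at snapshot `t + 1` whenever the two share at least one agent (the
#' 're-usage' of agents across snapshots). The result is a DAG layered by
#' snapshot index, and is the substrate on which contact sequences propagate.
#' Edges are unweighted.
#'
#' @param net A `temporal_network` with at least one snapshot (an empty
#'   network gives an empty graph).
#' @param include_singletons Keep singleton events (isolated agents) as nodes?
#'   Default `TRUE`, so an idle agent remains traceable to itself through its
#'   chain of singleton events. Event-betweenness analyses conventionally drop
#'   them (see [event_betweenness()]).
#' @return An object of class `event_graph`: list with `events` (tibble as in
#'   [event_table()]), `graph` (directed [igraph::graph] whose vertex names are
#'   event ids, with `snapshot` and `size` attributes), and
#'   `include_singletons`.
#' @examples
#' eg <- build_event_graph(toy_network())
#' igraph::neighbors(eg$graph, "0:3|5", mode = "out")
#' @export
build_event_graph <- function(net, include_singletons = TRUE) {
  stopifnot(inherits(net, "temporal_network"))
  events <- event_table(net)
  if (!include_singletons) events <- filter(events, .data$size >= 2)

  edges <- event_graph_edges(net, events)
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, nrow(events), name = events$id,
                            snapshot = events$snapshot, size = events$size)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges$from, events$id),
                                    match(edges$to, events$id)))
  }
  structure(
    list(events = events, graph = g, include_singletons = include_singletons),
    class = "event_graph"
  )
}

## Distinct (event at s) -> (event at s+1) links induced by agent persistence,
## restricted to the events retained in `events`.
event_graph_edges <- function(net, events) {
  T_ <- net$n_snapshots
  if (T_ < 2 || !nrow(events)) {
    return(tibble(from = character(), to = character()))
  }
  mem <- tn_membership(net)
  ids <- matrix(NA_character_, nrow = n_agents(net), ncol = T_)
  for (k in seq_len(nrow(events))) {
    e <- events[k, ]
    ids[match(e$members[[1]], net$agents), e$snapshot + 1L] <- e$id
  }
  out <- lapply(seq_len(T_ - 1L), function(s) {
    from <- ids[, s]
    to <- ids[, s + 1L]
    keep <- !is.na(from) & !is.na(to)
    if (!any(keep)) return(NULL)
    distinct(tibble(from = from[keep], to = to[keep]))
  })
  out <- bind_rows(out)
  if (!nrow(out)) tibble(from = character(), to = character()) else out
}

#' @export
print.event_graph <- function(x, ...) {
  cat(sprintf(
    "<event_graph> %d events over %d snapshots, %d links (singletons %s)\n",
    nrow(x$events),
    if (nrow(x$events)) max(x$events$snapshot) + 1L else 0L,
    igraph::ecount(x$graph),
    if (x$include_singletons) "included" else "excluded"))
  invisible(x)
}

#' Export an event graph as node and edge tables
#'
#' `write_event_graph()` writes two CSV files (nodes: `id`, `snapshot`, `size`,
#' pipe-joined `members`; edges: `source`, `target`);
#' `write_event_graph_json()` writes the same content as a single JSON
#' document.
#'
#' @param eg An `event_graph`.
#' @param nodes_path,edges_path CSV output paths.
#' @param path JSON output path.
#' @return The first output path, invisibly.
#' @export
write_event_graph <- function(eg, nodes_path, edges_path) {
  stopifnot(inherits(eg, "event_graph"))
  nodes <- tibble(
    id = eg$events$id,
    snapshot = eg$events$snapshot,
    size = eg$events$size,
    members = vapply(eg$events$members, paste, "", collapse = "|")
  )
  el <- igraph::as_edgelist(eg$graph)
  edges <- tibble(source = el[, 1], target = el[, 2])
  readr::write_csv(nodes, nodes_path)
  readr::write_csv(edges, edges_path)
  invisible(nodes_path)
}

#' @rdname write_event_graph
#' @export
write_event_graph_json <- function(eg, path) {
  stopifnot(inherits(eg, "event_graph"))
  el <- igraph::as_edgelist(eg$graph)
  doc <- list(
    nodes = lapply(seq_len(nrow(eg$events)), function(k) {
      list(id = eg$events$id[k], snapshot = eg$events$snapshot[k],
           size = eg$events$size[k], members = eg$events$members[[k]])
    }),
    edges = lapply(seq_len(nrow(el)), function(k) {
      list(source = el[k, 1], target = el[k, 2])
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}
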