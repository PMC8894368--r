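#' Tidy a temporal network into its contact table
#'
#' @param x A `temporal_network`.
#' @param ... Unused.
#' @return A tibble `snapshot`, `from`, `to` (one row per contact).
#' @export
tidy.temporal_network <- function(x, ...) {
  x$contacts
}

#' One-row summary of a temporal network
#'
#' @param x A `temporal_network`.
#' @param ... Unused.
#' @return A tibble with `n_agents`, `n_snapshots`, `resolution`,
#'   `n_contacts`, `n_active_snapshots` and `duration` (seconds).
#' @export
glance.temporal_network <- function(x, ...) {
  tibble(
    n_agents = n_agents(x),
    n_snapshots = x$n_snapshots,
    resolution = x$resolution,
    n_contacts = nrow(x$contacts),
    n_active_snapshots = length(unique(x$contacts$snapshot)),
    duration = x$n_snapshots * x$resolution
  )
}

#' Tidy an event graph into its event table
#'
#' @param x An `event_graph`.
#' @param ... Unused.
#' @return The event tibble (`id`, `snapshot`, `event`, `size`, `members`).
#' @export
tidy.event_graph <- function(x, ...) {
  x$events
}

#' One-row summary of an event graph
#'
#' @param x An `event_graph`.
#' @param ... Unused.
#' @return A tibble with `n_events`, `n_links`, `n_snapshots`,
#'   `max_event_size` and `include_singletons`.
#' @export
glance.event_graph <- function(x, ...) {
  tibble(
    n_events = nrow(x$events),
    n_links = igraph::ecount(x$graph),
    n_snapshots = if (nrow(x$events)) max(x$events$snapshot) + 1L else 0L,
    max_event_size = if (nrow(x$events)) max(x$events$size) else NA_integer_,
    include_singletons = x$include_singletons
  )
}

#' Plot contact activity of a temporal network
#'
#' Bars of the number of contacts per snapshot: a quick look at gaps, bursts
#' and overall activity.
#'
#' @param object A `temporal_network`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.temporal_network <- function(object, ...) {
  counts <- tibble(snapshot = seq_len(object$n_snapshots) - 1L) |>
    left_join(
      object$contacts |> dplyr::count(.data$snapshot, name = "contacts"),
      by = "snapshot") |>
    mutate(contacts = dplyr::coalesce(.data$contacts, 0L))
  ggplot2::ggplot(counts,
                  ggplot2::aes(x = .data$snapshot, y = .data$contacts)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(x = "snapshot", y = "contacts",
                  title = "Contact activity") +
    ggplot2::theme_minimal()
}

#' Plot a mean-traceability growth curve
#'
#' Mean of `p_bar(t, dt)` over start snapshots against window length, with a
#' ribbon spanning the min--max across starts.
#'
#' @param object A `trace_curve` from [trace_growth_curve()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trace_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dt, y = .data$p_mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$p_min, ymax = .data$p_max),
      fill = "grey80") +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = expression(Delta * t ~ "(snapshots)"),
                  y = expression(bar(P)),
                  title = "Growth of mean traceability") +
    ggplot2::theme_minimal()
}

#' Plot centrality spectra across window lengths
#'
#' One line per agent of time-averaged contact sequence centrality against
#' window length; the agents leading at the largest window are highlighted.
#'
#' @param object A `centrality_spectrum` from [centrality_spectrum()].
#' @param highlight Number of top agents (at the largest `dt`) to colour
#'   (default 3).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.centrality_spectrum <- function(object, highlight = 3, ...) {
  last_dt <- max(object$dt)
  top <- object |>
    filter(.data$dt == last_dt) |>
    arrange(dplyr::desc(.data$mean_centrality)) |>
    head(highlight)
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$dt, y = .data$mean_centrality,
                                    group = .data$agent)) +
    ggplot2::geom_line(colour = "grey70", linewidth = 0.3) +
    ggplot2::labs(x = expression(Delta * t ~ "(snapshots)"),
                  y = expression(bar(C)(i, Delta * t)),
                  title = "Contact sequence centrality spectra") +
    ggplot2::theme_minimal()
  if (nrow(top)) {
    p <- p + ggplot2::geom_line(
      data = filter(object, .data$agent %in% top$agent),
      ggplot2::aes(colour = .data$agent), linewidth = 0.7) +
      ggplot2::labs(colour = "agent")
  }
  p
}
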