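#' Read a delimited contact log into a temporal network
#'
#' Parses a three-column delimited text file of timestamped pairwise contacts
#' (`agent_a`, `agent_b`, `timestamp` in seconds) and bins the records into
#' snapshots of `resolution` seconds. The delimiter (comma or tab) and the
#' presence of a header row are auto-detected. Timestamps are normalised to
#' the earliest record, then binned into half-open intervals
#' `[k * resolution, (k + 1) * resolution)`; duplicate pairs within a bin
#' collapse to a single contact.
#'
#' @param path Path to the contact log.
#' @param resolution Seconds per snapshot (default 1, i.e. the raw logging
#'   resolution of typical proximity sensors).
#' @param agents Optional agent universe (superset of the agents in the file);
#'   when supplied, `N` is its size, so agents that never appear still count in
#'   traceability denominators.
#' @param n_snapshots Optional total number of snapshots (to pad trailing empty
#'   bins).
#' @param origin Timestamp mapped to snapshot 0. Default `NULL` uses the
#'   earliest timestamp in the file; pass `0` to keep absolute bins.
#' @return A [temporal_network()]. An empty file yields an empty network
#'   (`N = 0`, `T = 0`).
#' @examples
#' tmp <- tempfile(fileext = ".csv")
#' write_contact_log(toy_network(), tmp)
#' read_contact_log(tmp, resolution = 1)
#' @export
read_contact_log <- function(path, resolution = 1, agents = NULL,
                             n_snapshots = NULL, origin = NULL) {
  if (!is.numeric(resolution) || resolution <= 0) {
    abort_config("`resolution` must be positive.")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(temporal_network(NULL, agents = agents,
                            n_snapshots = n_snapshots %||% 0L,
                            resolution = resolution))
  }
  delim <- if (grepl("\t", lines[1], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  first <- trimws(fields[[1]])
  has_header <- length(first) >= 3 &&
    is.na(suppressWarnings(as.numeric(first[3])))
  start_row <- if (has_header) 2L else 1L
  if (start_row > length(fields)) {
    return(temporal_network(NULL, agents = agents,
                            n_snapshots = n_snapshots %||% 0L,
                            resolution = resolution))
  }

  rows <- fields[seq.int(start_row, length(fields))]
  bad <- which(vapply(rows, length, integer(1)) != 3L)
  if (length(bad)) {
    abort_parse(sprintf(
      "Line %d of '%s' does not have 3 fields.",
      bad[1] + start_row - 1L, path))
  }
  m <- matrix(trimws(unlist(rows)), ncol = 3, byrow = TRUE)
  ts <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(ts) || any(!is.finite(ts))) {
    bad <- which(is.na(ts) | !is.finite(ts))[1]
    abort_parse(sprintf(
      "Line %d of '%s': timestamp '%s' is not a finite number.",
      bad + start_row - 1L, path, m[bad, 3]))
  }
  if (any(m[, 1] == m[, 2])) {
    bad <- which(m[, 1] == m[, 2])[1]
    abort_parse(sprintf(
      "Line %d of '%s': self-contact of agent '%s'.",
      bad + start_row - 1L, path, m[bad, 1]))
  }
  origin <- origin %||% min(ts)
  if (any(ts < origin)) {
    abort_range("Timestamps precede the requested `origin`.")
  }
  snapshot <- floor((ts - origin) / resolution)
  temporal_network(
    tibble(snapshot = snapshot, from = m[, 1], to = m[, 2]),
    agents = agents, n_snapshots = n_snapshots, resolution = resolution
  )
}

#' Write a temporal network back to a delimited contact log
#'
#' Each contact is written as one CSV row `agent_a, agent_b, timestamp` with
#' `timestamp = snapshot * resolution`. Together with a JSON metadata sidecar
#' (see [write_fixture()]) the round trip through [read_contact_log()]
#' reproduces the network exactly, including trailing empty snapshots and
#' never-observed agents.
#'
#' @param net A `temporal_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_contact_log <- function(net, path) {
  stopifnot(inherits(net, "temporal_network"))
  out <- tibble(
    agent_a = net$contacts$from,
    agent_b = net$contacts$to,
    timestamp = net$contacts$snapshot * net$resolution
  )
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a contact-log fixture with its JSON metadata sidecar
#'
#' Writes the CSV contact log plus `<path>.json` holding the agent universe,
#' snapshot count and resolution, so that [read_fixture()] restores the
#' network field-for-field (the CSV alone cannot represent isolated agents or
#' leading/trailing empty snapshots).
#'
#' @param net A `temporal_network`.
#' @param path Path for the CSV log; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_fixture <- function(net, path) {
  write_contact_log(net, path)
  meta <- list(
    n_agents = n_agents(net),
    agents = net$agents,
    n_snapshots = net$n_snapshots,
    resolution = net$resolution,
    origin = 0
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a contact-log fixture written by [write_fixture()]
#'
#' @param path Path to the CSV log; the metadata sidecar is expected at
#'   `<path>.json`.
#' @return A [temporal_network()].
#' @export
read_fixture <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  read_contact_log(
    path,
    resolution = meta$resolution,
    agents = as.character(meta$agents),
    n_snapshots = meta$n_snapshots,
    origin = meta$origin %||% 0
  )
}
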