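# Hospital network construction, validation, transformation and export.
#
# A hospital is a directed graph: wards (vertices) carry bed capacity C_v,
# server (staff) count S_v and an optional list of observed lengths of stay;
# care pathways (edges) carry a waiting-queue capacity Q_e and a distribution
# probability DP_e (the fraction of patients leaving the source ward along
# that edge; outgoing DP must sum to 1 per ward).

# Source/sink are pure entry/exit points: sentinel capacity so they never
# constrain flow, and no length-of-stay values.
.SENTINEL_CAPACITY <- 1e9

#' Construct a hospital network
#'
#' Builds the directed ward/care-pathway network used by the flow engine.
#' The source and sink are ordinary ward records, but their beds and servers
#' are forced to a large sentinel (`1e9`) so that they never constrain flow;
#' they represent where patients enter and leave the hospital, not care
#' delivery units.
#'
#' @param wards data.frame with columns `name`, `beds`, `servers`. Rows for
#'   the source/sink are optional; missing ones are added automatically.
#' @param pathways data.frame with columns `source`, `target`, `capacity`
#'   (queue slots, >= 0) and `probability` (in `[0, 1]`).
#' @param source_name,sink_name names of the entry and exit vertices.
#' @param los named list mapping ward name to a numeric vector of observed
#'   lengths of stay in hours (all > 0). May be empty.
#' @param check if `TRUE` (default) run [validate_network()] and raise an
#'   error on any issue of severity `"error"`.
#' @return an object of class `hospital_network`: a list with elements
#'   `wards`, `pathways`, `los`, `source`, `sink`, `n` (ward count) and `m`
#'   (pathway count).
#' @examples
#' net <- hospital_network(
#'   wards = data.frame(name = "A", beds = 10, servers = 10),
#'   pathways = data.frame(source = c("in", "A"), target = c("A", "out"),
#'                         capacity = 5, probability = 1),
#'   source_name = "in", sink_name = "out")
#' net$n  # 3 wards: in, A, out
#' @export
hospital_network <- function(wards, pathways, source_name, sink_name,
                             los = list(), check = TRUE) {
  stopifnot(is.data.frame(wards), is.data.frame(pathways))
  need_w <- c("name", "beds", "servers")
  need_p <- c("source", "target", "capacity", "probability")
  if (!all(need_w %in% names(wards)))
    stop("wards must have columns: ", paste(need_w, collapse = ", "))
  if (!all(need_p %in% names(pathways)))
    stop("pathways must have columns: ", paste(need_p, collapse = ", "))

  wards <- data.frame(name = trimws(as.character(wards$name)),
                      beds = as.numeric(wards$beds),
                      servers = as.numeric(wards$servers),
                      stringsAsFactors = FALSE)
  pathways <- data.frame(source = trimws(as.character(pathways$source)),
                         target = trimws(as.character(pathways$target)),
                         capacity = as.numeric(pathways$capacity),
                         probability = as.numeric(pathways$probability),
                         stringsAsFactors = FALSE)
  source_name <- trimws(source_name)
  sink_name <- trimws(sink_name)
  if (identical(source_name, sink_name))
    stop("source and sink must be distinct wards")

  for (endpoint in c(source_name, sink_name)) {
    if (!endpoint %in% wards$name) {
      wards <- rbind(wards, data.frame(name = endpoint,
                                       beds = .SENTINEL_CAPACITY,
                                       servers = .SENTINEL_CAPACITY))
    }
  }
  # entry/exit points never constrain flow, whatever the input table said
  endpoints <- wards$name %in% c(source_name, sink_name)
  wards$beds[endpoints] <- .SENTINEL_CAPACITY
  wards$servers[endpoints] <- .SENTINEL_CAPACITY

  los <- lapply(los, as.numeric)
  names(los) <- trimws(names(los))
  los <- los[!names(los) %in% c(source_name, sink_name)]

  net <- structure(
    list(wards = wards, pathways = pathways, los = los,
         source = source_name, sink = sink_name,
         n = nrow(wards), m = nrow(pathways)),
    class = "hospital_network")

  if (check) {
    rep <- validate_network(net)
    if (!rep$ok) {
      errs <- rep$issues[rep$issues$severity == "error", ]
      stop("invalid hospital network:\n  ",
           paste(sprintf("[%s] %s", errs$id, errs$message), collapse = "\n  "))
    }
  }
  net
}

#' @export
print.hospital_network <- function(x, ...) {
  cat(sprintf("<hospital_network> %d wards, %d care pathways\n", x$n, x$m))
  cat(sprintf("  source: %s   sink: %s\n", x$source, x$sink))
  interior <- setdiff(x$wards$name, c(x$source, x$sink))
  cat(sprintf("  interior wards: %d (beds %s, servers %s)\n",
              length(interior),
              paste(range(x$wards$beds[x$wards$name %in% interior]),
                    collapse = "-"),
              paste(range(x$wards$servers[x$wards$name %in% interior]),
                    collapse = "-")))
  invisible(x)
}

#' Names of the interior (care-delivering) wards
#'
#' All wards except the source and sink entry/exit points.
#' @param net a `hospital_network`
#' @return character vector of ward names, in network order
#' @export
interior_wards <- function(net) {
  setdiff(net$wards$name, c(net$source, net$sink))
}

#' Validate a hospital network
#'
#' Checks every structural invariant and returns a report instead of
#' throwing. Errors: duplicate or dangling ward names, non-positive beds or
#' servers, self-loops, parallel edges, probabilities outside `[0, 1]`,
#' outgoing distribution probabilities not summing to 1 (tolerance
#' `1e-6`), source with incoming edges, sink with outgoing edges, sink
#' unreachable from the source, non-positive length-of-stay values.
#' Warnings (do not flip `ok`): cycles, interior wards with no incoming
#' pathway.
#'
#' @param net a `hospital_network` (built with `check = FALSE` if you expect
#'   violations)
#' @param tol tolerance on per-ward outgoing probability sums
#' @return an object of class `validation_report`: list with `ok` (logical)
#'   and `issues` (data.frame `severity`, `id`, `message`).
#' @export
validate_network <- function(net, tol = 1e-6) {
  issues <- list()
  add <- function(severity, id, message) {
    issues[[length(issues) + 1L]] <<-
      data.frame(severity = severity, id = id, message = message,
                 stringsAsFactors = FALSE)
  }
  w <- net$wards
  p <- net$pathways

  dup <- unique(w$name[duplicated(w$name)])
  for (d in dup) add("error", d, "duplicate ward name")

  bad_cap <- w$name[!is.finite(w$beds) | w$beds < 1 | w$beds != round(w$beds) |
                    !is.finite(w$servers) | w$servers < 1 |
                    w$servers != round(w$servers)]
  for (b in bad_cap) add("error", b, "beds and servers must be positive integers")

  known <- w$name
  dangling <- unique(c(p$source[!p$source %in% known],
                       p$target[!p$target %in% known]))
  for (d in dangling) add("error", d, "pathway endpoint is not a known ward")

  self <- p$source == p$target
  for (s in unique(p$source[self])) add("error", s, "self-loop pathway")

  key <- paste(p$source, p$target, sep = " -> ")
  for (k in unique(key[duplicated(key)]))
    add("error", k, "parallel pathways between the same ward pair")

  badp <- !is.finite(p$probability) | p$probability < 0 | p$probability > 1
  for (k in key[badp]) add("error", k, "probability must lie in [0, 1]")

  if (length(dangling) == 0 && !any(badp)) {
    for (u in unique(p$source)) {
      if (u == net$sink) next
      s <- sum(p$probability[p$source == u])
      if (abs(s - 1) > tol)
        add("error", u, sprintf(
          "outgoing distribution probabilities sum to %.7g, not 1", s))
    }
  }

  if (any(p$target == net$source))
    add("error", net$source, "source in-degree must be 0")
  if (any(p$source == net$sink))
    add("error", net$sink, "sink out-degree must be 0")
  if (any(!is.finite(p$capacity) | p$capacity < 0))
    add("error", "edges", "queue capacities must be >= 0")

  # reachability ignoring capacities
  if (length(dangling) == 0 && nrow(p) > 0) {
    reach <- net$source
    repeat {
      nxt <- unique(p$target[p$source %in% reach])
      new <- setdiff(nxt, reach)
      if (length(new) == 0) break
      reach <- c(reach, new)
    }
    if (!net$sink %in% reach)
      add("error", net$sink, "sink is not reachable from the source")
  } else if (nrow(p) == 0) {
    add("error", net$sink, "sink is not reachable from the source")
  }

  for (nm in names(net$los)) {
    v <- net$los[[nm]]
    if (!nm %in% known) add("error", nm, "length-of-stay entry for unknown ward")
    if (length(v) > 0 && any(!is.finite(v) | v <= 0))
      add("error", nm, "length-of-stay values must all be > 0")
  }

  # cycles: patients occasionally repeat procedures; accepted, but flagged
  if (length(dangling) == 0 && nrow(p) > 0 && !any(self)) {
    g <- igraph::graph_from_data_frame(p[, c("source", "target")],
                                       vertices = unique(known))
    if (!igraph::is_dag(g))
      add("warning", "network", "network contains cycles (back-transfers)")
  }
  orphan <- setdiff(known[!known %in% p$target], net$source)
  for (o in orphan) add("warning", o, "interior ward has no incoming pathway")

  issues <- if (length(issues)) do.call(rbind, issues) else
    data.frame(severity = character(), id = character(),
               message = character(), stringsAsFactors = FALSE)
  structure(list(ok = !any(issues$severity == "error"), issues = issues),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> ok: %s, %d issue(s)\n",
              x$ok, nrow(x$issues)))
  if (nrow(x$issues)) {
    for (i in seq_len(nrow(x$issues)))
      cat(sprintf("  %-7s %s: %s\n", x$issues$severity[i],
                  x$issues$id[i], x$issues$message[i]))
  }
  invisible(x)
}

.read_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                    strip.white = TRUE, check.names = FALSE)
}

#' Load a hospital network from tabular adjacency lists
#'
#' @param wards_file CSV/TSV with header `ward,beds,staff`. Staff counts that
#'   are missing (`NA`) fall back to the ward's bed count (beds = servers),
#'   the standard assumption when staffing data are unavailable.
#' @param edges_file CSV/TSV with header `source,target,capacity,probability`.
#' @param source_name,sink_name entry and exit vertex names.
#' @param los_file optional CSV/TSV with header `ward,los_hours`, one row per
#'   observed stay.
#' @return a validated [hospital_network()]
#' @export
load_network <- function(wards_file, edges_file, source_name, sink_name,
                         los_file = NULL) {
  wt <- .read_table(wards_file)
  if (!all(c("ward", "beds", "staff") %in% names(wt)))
    stop("wards table needs columns ward,beds,staff: ", wards_file)
  beds <- suppressWarnings(as.numeric(wt$beds))
  staff <- suppressWarnings(as.numeric(wt$staff))
  if (any(is.na(beds) & !is.na(wt$beds)))
    stop("non-numeric beds value in ", wards_file)
  staff[is.na(staff)] <- beds[is.na(staff)]  # beds = servers fallback
  wards <- data.frame(name = wt$ward, beds = beds, servers = staff,
                      stringsAsFactors = FALSE)

  et <- .read_table(edges_file)
  if (!all(c("source", "target", "capacity", "probability") %in% names(et)))
    stop("edges table needs columns source,target,capacity,probability: ",
         edges_file)
  for (col in c("capacity", "probability")) {
    v <- suppressWarnings(as.numeric(et[[col]]))
    if (any(is.na(v) & !is.na(et[[col]])))
      stop("non-numeric ", col, " value in ", edges_file)
    et[[col]] <- v
  }

  los <- list()
  if (!is.null(los_file)) {
    lt <- .read_table(los_file)
    if (!all(c("ward", "los_hours") %in% names(lt)))
      stop("LOS table needs columns ward,los_hours: ", los_file)
    los <- split(as.numeric(lt$los_hours), trimws(lt$ward))
  }

  hospital_network(wards, et, source_name, sink_name, los = los)
}

#' Replace routing probabilities with equal distribution
#'
#' Substitutes every ward's outgoing distribution probabilities with
#' `1 / outdegree`, the comparison scenario used to tell blockages caused by
#' very small routing probabilities apart from blockages caused by ward
#' capacity or service time.
#'
#' @param net a `hospital_network`
#' @return a new `hospital_network`, identical except for the probabilities
#' @export
set_equal_distribution <- function(net) {
  p <- net$pathways
  outdeg <- table(p$source)
  p$probability <- 1 / as.numeric(outdeg[p$source])
  hospital_network(net$wards, p, net$source, net$sink, los = net$los,
                   check = FALSE)
}

#' Convert a hospital network to an igraph object
#'
#' Vertices carry `beds` and `servers`; edges carry `capacity` and
#' `probability`.
#' @param net a `hospital_network`
#' @return an `igraph` directed graph
#' @export
as_igraph <- function(net) {
  igraph::graph_from_data_frame(net$pathways, directed = TRUE,
                                vertices = net$wards)
}

#' Export the network as GraphML or DOT
#'
#' Writes the graph with beds/servers/capacity/probability and any extra
#' annotation (for example a blockage `status`) as attributes. The format is
#' chosen by file extension: `.graphml` (default) or `.dot`/`.gv`.
#'
#' @param net a `hospital_network`
#' @param path output file path
#' @param vertex_attrs optional data.frame with a `ward` column plus one
#'   column per annotation to attach to vertices
#' @param edge_attrs optional data.frame with `source` and `target` columns
#'   plus one column per annotation to attach to edges
#' @return the path, invisibly
#' @export
export_graph <- function(net, path, vertex_attrs = NULL, edge_attrs = NULL) {
  g <- as_igraph(net)
  if (!is.null(vertex_attrs)) {
    if (!"ward" %in% names(vertex_attrs))
      stop("vertex_attrs needs a 'ward' column")
    unknown <- setdiff(vertex_attrs$ward, net$wards$name)
    if (length(unknown))
      stop("unknown ward in vertex_attrs: ", paste(unknown, collapse = ", "))
    idx <- match(igraph::V(g)$name, vertex_attrs$ward)
    for (col in setdiff(names(vertex_attrs), "ward"))
      g <- igraph::set_vertex_attr(g, col, value = vertex_attrs[[col]][idx])
  }
  if (!is.null(edge_attrs)) {
    if (!all(c("source", "target") %in% names(edge_attrs)))
      stop("edge_attrs needs 'source' and 'target' columns")
    ekey <- paste(net$pathways$source, net$pathways$target)
    akey <- paste(edge_attrs$source, edge_attrs$target)
    if (any(!akey %in% ekey))
      stop("unknown edge in edge_attrs: ",
           paste(akey[!akey %in% ekey], collapse = ", "))
    idx <- match(ekey, akey)
    for (col in setdiff(names(edge_attrs), c("source", "target")))
      g <- igraph::set_edge_attr(g, col, value = edge_attrs[[col]][idx])
  }
  fmt <- switch(tolower(tools::file_ext(path)),
                graphml = "graphml", dot = "dot", gv = "dot",
                stop("unsupported export extension: ", path))
  igraph::write_graph(g, path, format = fmt)
  invisible(path)
}
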