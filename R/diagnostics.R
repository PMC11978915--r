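# Bottleneck diagnostics derived from a completed run.
#
# Three per-edge matrices summarise the dynamic residual graph:
#   persistency = max_cap - min_cap   (divergence: fluctuation/instability)
#   severity    = 0 - max_cap         (>= 0: at/over capacity even at best)
#   overflow    = 0 - min_cap         (> 0: overflowed at least once)
# Blockage colouring marks wards/edges never visited by any augmenting
# path, and root-cause traces walk k hops up (predecessors, ranked by flow
# pushed through them into the focal ward) or down (successors, ranked by
# low mean outgoing residual).

.edge_matrix <- function(dynrg, values, label) {
  wards <- unique(c(dynrg$source, dynrg$target))
  m <- matrix(NA_real_, length(wards), length(wards),
              dimnames = list(wards, wards))
  m[cbind(dynrg$source, dynrg$target)] <- values
  structure(m, label = label, class = c("edge_matrix", class(m)))
}

.check_observed <- function(dynrg) {
  bad <- !is.finite(dynrg$min_cap) | !is.finite(dynrg$max_cap)
  if (any(bad))
    stop("unobserved edge(s) in DynRG: ",
         paste(dynrg$source[bad], dynrg$target[bad], sep = "->",
               collapse = ", "))
}

.get_dynrg <- function(x) {
  if (inherits(x, "flow_simulation")) x$dynrg else as.data.frame(x)
}

#' Bottleneck persistency matrix
#'
#' Per edge, the divergence between the highest and lowest residual observed
#' over the run (`max_cap - min_cap`). Small values mean persistent, stable
#' flow; large values mean fluctuation and instability.
#' @param x a `flow_simulation` or its `dynrg` data.frame
#' @return ward-by-ward matrix, `NA` where no edge exists (absent cells are
#'   not zeros: there is no pathway there)
#' @export
persistency_matrix <- function(x) {
  d <- .get_dynrg(x); .check_observed(d)
  .edge_matrix(d, d$max_cap - d$min_cap, "persistency")
}

#' Bottleneck severity matrix
#'
#' Per edge, `0 - max_cap`: non-negative values mean the edge was at or over
#' capacity even in its best observed state.
#' @inheritParams persistency_matrix
#' @return ward-by-ward matrix, `NA` where no edge exists
#' @export
severity_matrix <- function(x) {
  d <- .get_dynrg(x); .check_observed(d)
  .edge_matrix(d, 0 - d$max_cap, "severity")
}

#' Overflow matrix
#'
#' Per edge, `0 - min_cap`: positive values mean the edge overflowed at
#' least once during the run.
#' @inheritParams persistency_matrix
#' @return ward-by-ward matrix, `NA` where no edge exists
#' @export
overflow_matrix <- function(x) {
  d <- .get_dynrg(x); .check_observed(d)
  .edge_matrix(d, 0 - d$min_cap, "overflow")
}

#' Long-format view of an edge matrix
#'
#' One row per defined cell (i.e. per network edge); absent cells are absent
#' rows, never zeros.
#' @param m an `edge_matrix`
#' @return data.frame `source,target,value`
#' @export
edge_matrix_long <- function(m) {
  idx <- which(!is.na(m), arr.ind = TRUE)
  data.frame(source = rownames(m)[idx[, 1]], target = colnames(m)[idx[, 2]],
             value = m[idx], stringsAsFactors = FALSE)
}

#' Classify wards and edges by whether flow ever reached them
#'
#' A ward/edge is `"reached"` iff it lies on at least one augmenting path
#' over the whole run, otherwise `"blocked"` — i.e. the colouring of the
#' flow-evolution pictures, where blocked elements show where flow cannot
#' pass (because of tiny routing probabilities, long service times or low
#' capacities). Source and sink carry their own statuses.
#'
#' @param result a `flow_simulation` run with `path_log = TRUE`
#' @param net the network (defaults to the one stored in the result)
#' @return list of class `blockage_coloring`: `vertex_status` (named
#'   character), `edge_status` (data.frame `source,target,status`), and
#'   `counts` (`reached`/`blocked` over interior wards)
#' @export
blockage_classification <- function(result, net = result$network) {
  if (is.null(result$paths))
    stop("path log absent: rerun with config path_log = TRUE")
  on_path_w <- character(0)
  on_path_e <- character(0)
  for (step in result$paths) {
    for (p in step) {
      w <- p$wards
      on_path_w <- c(on_path_w, w)
      if (length(w) > 1)
        on_path_e <- c(on_path_e, paste(w[-length(w)], w[-1], sep = " -> "))
    }
  }
  on_path_w <- unique(on_path_w)
  on_path_e <- unique(on_path_e)

  vs <- ifelse(net$wards$name %in% on_path_w, "reached", "blocked")
  vs[net$wards$name == net$source] <- "source"
  vs[net$wards$name == net$sink] <- "sink"
  names(vs) <- net$wards$name

  ekey <- paste(net$pathways$source, net$pathways$target, sep = " -> ")
  es <- data.frame(source = net$pathways$source, target = net$pathways$target,
                   status = ifelse(ekey %in% on_path_e, "reached", "blocked"),
                   stringsAsFactors = FALSE)
  interior <- vs[!names(vs) %in% c(net$source, net$sink)]
  structure(list(vertex_status = vs, edge_status = es,
                 counts = c(reached = sum(interior == "reached"),
                            blocked = sum(interior == "blocked"))),
            class = "blockage_coloring")
}

#' @export
print.blockage_coloring <- function(x, ...) {
  cat(sprintf("<blockage_coloring> %d reached / %d blocked interior wards\n",
              x$counts["reached"], x$counts["blocked"]))
  blocked <- names(x$vertex_status)[x$vertex_status == "blocked"]
  if (length(blocked))
    cat("  blocked:", paste(blocked, collapse = ", "), "\n")
  invisible(x)
}

#' Per-ward residual time series with outlier filtering
#'
#' Extracts DynV series for the requested wards and drops values outside
#' `[-outlier_bound, +outlier_bound]` (default 1000), the filter used to
#' observe proper ward behaviour without numerically extreme excursions.
#'
#' @param result a `flow_simulation` (or a steps-by-wards DynV matrix)
#' @param wards ward names (default: all interior wards)
#' @param outlier_bound symmetric bound; `Inf` disables filtering
#' @return list of class `ward_timeseries`: `series` (data.frame
#'   `ward,step,residual`, filtered) and `dropped` (named integer count of
#'   removed values per ward)
#' @export
ward_timeseries <- function(result, wards = NULL, outlier_bound = 1000) {
  dynv <- if (inherits(result, "flow_simulation")) result$dynv else result
  if (is.null(wards))
    wards <- if (inherits(result, "flow_simulation"))
      interior_wards(result$network) else colnames(dynv)
  unknown <- setdiff(wards, colnames(dynv))
  if (length(unknown))
    stop("unknown ward(s): ", paste(unknown, collapse = ", "))
  out <- list(); dropped <- integer(length(wards)); names(dropped) <- wards
  for (w in wards) {
    v <- dynv[, w]
    step <- seq_along(v)
    keep <- !is.na(v) & abs(v) <= outlier_bound
    dropped[w] <- sum(!is.na(v) & !keep)
    out[[w]] <- data.frame(ward = w, step = step[keep], residual = v[keep],
                           stringsAsFactors = FALSE)
  }
  structure(list(series = do.call(rbind, c(out, make.row.names = FALSE)),
                 dropped = dropped, outlier_bound = outlier_bound),
            class = "ward_timeseries")
}

.khop <- function(pathways, start, depth, direction) {
  frontier <- start
  seen <- stats::setNames(integer(0), character(0))
  for (d in seq_len(depth)) {
    nxt <- if (direction == "predecessors")
      pathways$source[pathways$target %in% frontier]
    else
      pathways$target[pathways$source %in% frontier]
    nxt <- setdiff(unique(nxt), c(start, names(seen)))
    if (length(nxt) == 0) break
    seen[nxt] <- d
    frontier <- nxt
  }
  seen
}

#' Trace the root causes of a ward's bottleneck
#'
#' Walks up to `depth` hops away from the focal ward in both directions.
#' Predecessors are ranked by the total flow pushed through them into the
#' focal ward over the run (a high-outflow ancestor feeds the bottleneck);
#' successors are ranked by their mean outgoing residual, lowest first (a
#' low-outflow descendant dams the flow back). Ties break by ward name.
#'
#' @param result a `flow_simulation` run with `path_log = TRUE`
#' @param ward focal ward name
#' @param depth maximum hop count k, >= 1
#' @param net network (defaults to the one in the result)
#' @return list of class `root_cause_trace` with elements `ward`, `depth`,
#'   `predecessors` and `successors`: data.frames
#'   (`ward`, `hops`, `metric`) sorted by suspicion
#' @export
trace_root_cause <- function(result, ward, depth = 2L, net = result$network) {
  if (depth < 1) stop("depth must be >= 1")
  if (!ward %in% net$wards$name) stop("unknown ward: ", ward)
  preds <- .khop(net$pathways, ward, depth, "predecessors")
  succs <- .khop(net$pathways, ward, depth, "successors")

  # predecessor metric: flow pushed along logged paths that pass through the
  # ancestor strictly before the focal ward
  pushed <- stats::setNames(numeric(length(preds)), names(preds))
  if (length(preds)) {
    if (is.null(result$paths))
      stop("path log absent: rerun with config path_log = TRUE")
    for (step in result$paths) for (p in step) {
      i <- match(ward, p$wards)
      if (is.na(i) || i == 1L) next
      before <- intersect(p$wards[seq_len(i - 1L)], names(preds))
      pushed[before] <- pushed[before] + p$bottleneck
    }
  }
  pred_df <- data.frame(ward = names(preds), hops = as.integer(preds),
                        metric = as.numeric(pushed[names(preds)]),
                        stringsAsFactors = FALSE)
  pred_df <- pred_df[order(-pred_df$metric, pred_df$ward), , drop = FALSE]

  # successor metric: mean outgoing residual (low = suspected blocker)
  mean_out <- vapply(names(succs), function(s) {
    e <- result$dynrg$source == s
    if (!any(e)) Inf else mean(result$dynrg$mean_cap[e])
  }, numeric(1))
  succ_df <- data.frame(ward = names(succs), hops = as.integer(succs),
                        metric = as.numeric(mean_out),
                        stringsAsFactors = FALSE)
  succ_df <- succ_df[order(succ_df$metric, succ_df$ward), , drop = FALSE]
  rownames(pred_df) <- rownames(succ_df) <- NULL

  structure(list(ward = ward, depth = as.integer(depth),
                 predecessors = pred_df, successors = succ_df),
            class = "root_cause_trace")
}

#' @export
print.root_cause_trace <- function(x, ...) {
  cat(sprintf("<root_cause_trace> %s (k = %d)\n", x$ward, x$depth))
  cat("  predecessors by pushed flow:\n")
  print(utils::head(x$predecessors, 5))
  cat("  successors by mean outgoing residual (low = blocker):\n")
  print(utils::head(x$successors, 5))
  invisible(x)
}
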