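# Shared fixtures and independent oracles.

# minimal source -> A -> sink chain
make_chain <- function(beds = 10, servers = 10, q = 5, los = c(4, 8, 16)) {
  hospital_network(
    wards = data.frame(name = "A", beds = beds, servers = servers),
    pathways = data.frame(source = c("S", "A"), target = c("A", "T"),
                          capacity = q, probability = 1),
    source_name = "S", sink_name = "T",
    los = list(A = los))
}

# linear chain S -> W1 -> ... -> Wk -> T
make_path_network <- function(k = 3, beds = 10, q = 5) {
  wn <- paste0("W", seq_len(k))
  nodes <- c("S", wn, "T")
  hospital_network(
    wards = data.frame(name = wn, beds = beds, servers = beds),
    pathways = data.frame(source = nodes[-length(nodes)], target = nodes[-1],
                          capacity = q, probability = 1),
    source_name = "S", sink_name = "T",
    los = stats::setNames(rep(list(c(2, 6)), k), wn))
}

# wrap a bare edge table as a static residual graph
as_residual <- function(df, step = 0L) {
  if (is.null(df$probability)) df$probability <- 1
  structure(df[, c("source", "target", "probability", "residual")],
            class = c("static_residual", "data.frame"), step = step)
}

# random residual graph with signed residuals between "S" and "T"
random_residual_graph <- function(n_mid = 5, p_edge = 0.35,
                                  res_range = c(-5, 5)) {
  nodes <- c("S", paste0("V", seq_len(n_mid)), "T")
  src <- character(0); tgt <- character(0)
  for (a in nodes) for (b in nodes) {
    if (a == b || b == "S" || a == "T") next
    if (stats::runif(1) < p_edge) { src <- c(src, a); tgt <- c(tgt, b) }
  }
  # anchor S and T so both always exist in the graph (edges may be blocked)
  if (!"S" %in% src) { src <- c(src, "S"); tgt <- c(tgt, sample(nodes[-1], 1)) }
  if (!"T" %in% tgt) {
    src <- c(src, sample(nodes[-length(nodes)], 1)); tgt <- c(tgt, "T")
  }
  as_residual(data.frame(
    source = src, target = tgt,
    probability = stats::runif(length(src)),
    residual = stats::runif(length(src), res_range[1], res_range[2]),
    stringsAsFactors = FALSE))
}

# brute-force oracle: is the sink reachable over residuals strictly > eps?
# (breadth-first frontier expansion, independent of dfs_find_path)
oracle_reachable <- function(residuals, source, sink, eps = 1e-12) {
  open <- residuals$residual > eps
  reach <- source
  repeat {
    nxt <- unique(residuals$target[open & residuals$source %in% reach])
    new <- setdiff(nxt, reach)
    if (length(new) == 0) return(sink %in% reach)
    reach <- c(reach, new)
  }
}

# classical max-flow (with backward edges) on the positive-residual subgraph
oracle_maxflow <- function(residuals, source, sink, eps = 1e-12) {
  keep <- residuals$residual > eps
  if (!any(keep)) return(0)
  vs <- unique(c(residuals$source, residuals$target, source, sink))
  g <- igraph::graph_from_data_frame(
    data.frame(from = residuals$source[keep], to = residuals$target[keep]),
    vertices = vs)
  igraph::max_flow(g, source, sink,
                   capacity = residuals$residual[keep])$value
}

# run one step against a prebuilt residual graph without a full network
run_step_on <- function(residuals, source = "S", sink = "T", ...) {
  fake_net <- list(source = source, sink = sink)
  run_time_step(fake_net, residuals, r_t = 0, ...)
}
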