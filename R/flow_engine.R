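# Dynamic flow loop.
#
# Per arrival-rate step: sample service times, rebuild the static residual
# graph, then repeatedly find a source-to-sink augmenting path by
# depth-first search over strictly positive residuals and push its
# bottleneck forward along the path. Forward-only: no backward residual
# edges are ever created, because patients do not take alternative care
# pathways. Continuity across steps lives in the dynamic records: DynRG
# (per-edge min/max residual over the run) and DynV (per-ward residual per
# step).

.default_config <- function() {
  list(family = "lognormal",
       samples_per_step = 1L,
       vertex_arrival = "raw",
       max_augmentations_per_step = Inf,
       path_log = TRUE,
       epsilon_full = 1e-9,
       eps_positive = 1e-12,  # strictly-positive threshold for residuals
       repeats = 1L)
}

.merge_config <- function(config) {
  cfg <- .default_config()
  unknown <- setdiff(names(config), names(cfg))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(config)] <- config
  cfg
}

#' Find an augmenting path by depth-first search
#'
#' Searches for a simple source-to-sink path using only edges with residual
#' strictly above `eps`. Negative or zero residuals block flow (overflow).
#' Depth-first search deliberately explores deep, low-priority wards that a
#' shortest-path search would overshadow. Neighbour order: descending
#' distribution probability, ties broken by edge input order, which makes
#' the search deterministic.
#'
#' @param residuals a `static_residual` from [build_static_residual()]
#' @param source,sink ward names
#' @param eps strictly-positive threshold (default 1e-12)
#' @return `NULL` when the sink is unreachable through positive residuals,
#'   otherwise a list of class `augmenting_path` with `wards` (ordered
#'   names), `edges` (row indices into `residuals`) and `bottleneck`.
#' @export
dfs_find_path <- function(residuals, source, sink, eps = 1e-12) {
  vs <- unique(c(residuals$source, residuals$target))
  if (!source %in% vs || !sink %in% vs)
    stop("source or sink absent from the residual graph")
  open <- which(residuals$residual > eps)
  if (length(open) == 0) return(NULL)
  # adjacency over positive edges, neighbours by descending DP (stable ties)
  ord <- open[order(-residuals$probability[open])]
  adj <- split(ord, residuals$source[ord])

  visited <- character(0)
  # stack frames: list(ward, edge_path, ward_path)
  path_edges <- integer(0)
  found <- NULL
  dfs <- function(u, edges_so_far, wards_so_far) {
    if (u == sink) {
      found <<- list(edges = edges_so_far, wards = wards_so_far)
      return(TRUE)
    }
    for (e in adj[[u]]) {
      v <- residuals$target[e]
      if (v %in% wards_so_far) next  # simple paths only
      if (dfs(v, c(edges_so_far, e), c(wards_so_far, v))) return(TRUE)
    }
    FALSE
  }
  if (!dfs(source, integer(0), source)) return(NULL)
  structure(list(wards = found$wards, edges = found$edges,
                 bottleneck = min(residuals$residual[found$edges])),
            class = "augmenting_path")
}

#' Bottleneck of an augmenting path
#'
#' @param residuals a `static_residual`
#' @param path an `augmenting_path` (or list with an `edges` element)
#' @return the minimum residual along the path's edges
#' @export
path_bottleneck <- function(residuals, path) {
  if (length(path$edges) == 0) stop("empty path")
  min(residuals$residual[path$edges])
}

#' Push flow along a path (forward only)
#'
#' Subtracts `amount` from every on-path residual. No backward residual
#' edges are created or incremented; pushed flow is never undone.
#'
#' @param residuals a `static_residual`
#' @param path an `augmenting_path`
#' @param amount flow to push, `0 < amount <= path_bottleneck`
#' @return the updated `static_residual`
#' @export
augment <- function(residuals, path, amount) {
  b <- path_bottleneck(residuals, path)
  if (!is.finite(amount) || amount <= 0) stop("amount must be > 0")
  if (amount > b + 1e-9) stop("amount exceeds the path bottleneck")
  residuals$residual[path$edges] <- residuals$residual[path$edges] - amount
  residuals
}

#' Run one arrival-rate step
#'
#' Starting from a freshly built static residual graph, repeatedly finds an
#' augmenting path, pushes its bottleneck, and records it, until no
#' positive-residual path remains (or the configured per-step cap is hit).
#'
#' @param net a `hospital_network`
#' @param residuals `static_residual` built for this step's arrival rate
#' @param r_t the step's arrival rate (echoed into the result)
#' @param config list of config overrides (see [run_simulation()])
#' @return list of class `step_result`: `step`, `arrival_rate`, `paths`
#'   (list of `list(wards, bottleneck)`), `total_flow`, `residuals`
#'   (post-augmentation `static_residual`)
#' @export
run_time_step <- function(net, residuals, r_t, config = list()) {
  cfg <- .merge_config(config)
  paths <- list()
  total <- 0
  while (length(paths) < cfg$max_augmentations_per_step) {
    p <- dfs_find_path(residuals, net$source, net$sink,
                       eps = cfg$eps_positive)
    if (is.null(p)) break
    b <- p$bottleneck
    residuals <- augment(residuals, p, b)
    paths[[length(paths) + 1L]] <- list(wards = p$wards, bottleneck = b)
    total <- total + b
  }
  structure(list(step = attr(residuals, "step"), arrival_rate = r_t,
                 paths = paths, total_flow = total, residuals = residuals),
            class = "step_result")
}

#' Run the full dynamic flow simulation
#'
#' Iterates over the arrival-rate profile. Per step: one service time is
#' sampled per interior ward (the mean of `samples_per_step` draws), vertex
#' and edge capacities are adjusted into a static residual graph, and flow
#' is pushed along depth-first augmenting paths until blocked. The static
#' residuals are rebuilt each step; the dynamic records carry continuity:
#' DynRG keeps each edge's min/max (and mean) post-augmentation residual
#' over the run, DynV each ward's per-step residual (mean over incoming
#' post-augmentation residuals; for the source, mean over outgoing).
#'
#' @param net a valid `hospital_network`
#' @param arrivals numeric vector of arrival rates (patients/hour, one per
#'   step), or an object with a `rates` element
#' @param service_dists named list of [service_distribution()] objects, one
#'   per interior ward. Defaults to distributions fitted from `net$los` with
#'   the configured `family`.
#' @param config list of overrides: `family`, `samples_per_step`,
#'   `vertex_arrival` (`"raw"`/`"weighted"`), `max_augmentations_per_step`,
#'   `path_log` (logical), `epsilon_full`, `eps_positive`, `repeats`
#'   (repeat the profile this many times, e.g. 7 for a week of a daily
#'   profile)
#' @param seed integer master seed; every random draw in the run flows from
#'   it, so identical inputs and seed reproduce the result bit for bit
#' @return object of class `flow_simulation`: list with `dynrg` (data.frame
#'   `source,target,min_cap,max_cap,mean_cap`), `dynv` (steps x wards
#'   matrix), `paths` (per-step list of augmenting paths, if logged),
#'   `flow` (per-step pushed flow), `arrival_rates`, `config`, `seed`,
#'   `network`
#' @export
run_simulation <- function(net, arrivals, service_dists = NULL,
                           config = list(), seed = 1L) {
  if (!inherits(net, "hospital_network")) stop("net must be a hospital_network")
  cfg <- .merge_config(config)
  rates <- if (is.list(arrivals) && !is.null(arrivals$rates))
    as.numeric(arrivals$rates) else as.numeric(arrivals)
  if (length(rates) == 0) stop("arrival profile must be non-empty")
  if (any(rates < 0)) stop("arrival rates must be >= 0")
  if (cfg$repeats > 1) rates <- rep(rates, cfg$repeats)

  wards <- interior_wards(net)
  if (is.null(service_dists)) {
    missing <- setdiff(wards, names(net$los))
    if (length(missing))
      stop("no service distribution or LOS data for ward(s): ",
           paste(missing, collapse = ", "))
    service_dists <- lapply(net$los[wards], fit_distribution,
                            family = cfg$family)
  }
  missing <- setdiff(wards, names(service_dists))
  if (length(missing))
    stop("missing service distribution for ward(s): ",
         paste(missing, collapse = ", "))

  set.seed(as.integer(seed))
  t_max <- length(rates)
  all_wards <- net$wards$name
  m <- net$m
  # DynRG extrema start at +/- infinity, before any observation
  min_cap <- rep(Inf, m)
  max_cap <- rep(-Inf, m)
  sum_cap <- rep(0, m)
  dynv <- matrix(NA_real_, nrow = t_max, ncol = length(all_wards),
                 dimnames = list(NULL, all_wards))
  flow <- numeric(t_max)
  path_log <- if (cfg$path_log) vector("list", t_max) else NULL

  inc_edges <- lapply(all_wards, function(w) which(net$pathways$target == w))
  names(inc_edges) <- all_wards
  out_src <- which(net$pathways$source == net$source)

  for (t in seq_len(t_max)) {
    draws <- vapply(wards, function(w)
      mean(sample_service_time(service_dists[[w]], n = cfg$samples_per_step)),
      numeric(1))
    loads <- compute_vertex_loads(net, rates[t], draws,
                                  vertex_arrival = cfg$vertex_arrival,
                                  epsilon = cfg$epsilon_full)
    residuals <- build_static_residual(net, rates[t], loads, step = t)
    step <- run_time_step(net, residuals, rates[t], config = cfg)

    res <- step$residuals$residual
    min_cap <- pmin(min_cap, res)
    max_cap <- pmax(max_cap, res)
    sum_cap <- sum_cap + res
    for (w in all_wards) {
      e <- if (w == net$source) out_src else inc_edges[[w]]
      dynv[t, w] <- if (length(e)) mean(res[e]) else NA_real_
    }
    flow[t] <- step$total_flow
    if (cfg$path_log) path_log[[t]] <- step$paths
  }

  structure(list(
    dynrg = data.frame(source = net$pathways$source,
                       target = net$pathways$target,
                       min_cap = min_cap, max_cap = max_cap,
                       mean_cap = sum_cap / t_max,
                       stringsAsFactors = FALSE),
    dynv = dynv, paths = path_log, flow = flow,
    arrival_rates = rates, config = cfg, seed = as.integer(seed),
    network = net), class = "flow_simulation")
}

#' @export
print.flow_simulation <- function(x, ...) {
  cat(sprintf("<flow_simulation> %d steps over %d wards / %d pathways (seed %d)\n",
              length(x$flow), x$network$n, x$network$m, x$seed))
  cat(sprintf("  total flow pushed: %.3f (per-step mean %.3f)\n",
              sum(x$flow), mean(x$flow)))
  cat(sprintf("  residual range observed: [%.3f, %.3f]\n",
              min(x$dynrg$min_cap), max(x$dynrg$max_cap)))
  invisible(x)
}
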