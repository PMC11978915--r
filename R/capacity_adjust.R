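# Per-step capacity adjustment.
#
# At each arrival-rate step the physical capacities are converted into
# load-adjusted residual capacities. Ward side: service rate mu = S / sTime,
# traffic intensity rho = r / mu, overflow ratio rho / (1 - rho), and an
# adjusted bed capacity that is positive while rho < 1, zero at rho = 1 and
# negative beyond (the magnitude grading the overflow, not a bed count).
# Edge side: inflow r * DP is subtracted from the queue capacity. The static
# residual of an edge (u, v) is the adjusted edge capacity plus the adjusted
# capacity of the receiving ward v (edges into the sink carry only the edge
# term: the exit point never constrains flow).

#' Ward service rate
#'
#' Patients a ward can process per hour: servers divided by the sampled
#' per-patient service time.
#' @param servers staff count, >= 1
#' @param s_time sampled service time in hours, > 0
#' @return patients/hour
#' @export
service_rate <- function(servers, s_time) {
  if (any(s_time <= 0)) stop("s_time must be > 0")
  if (any(servers < 1)) stop("servers must be >= 1")
  servers / s_time
}

#' Traffic (flow) intensity
#'
#' Arrival rate over service rate. 0 means no inflow; values in (0, 1) an
#' occupied but not overloaded ward; 1 full capacity; above 1 an overflowed
#' ward.
#' @param arrival_rate patients/hour, >= 0
#' @param service_rate patients/hour, > 0
#' @return dimensionless intensity rho
#' @export
flow_intensity <- function(arrival_rate, service_rate) {
  if (any(service_rate <= 0)) stop("service_rate must be > 0")
  if (any(arrival_rate < 0)) stop("arrival_rate must be >= 0")
  arrival_rate / service_rate
}

#' Overflow ratio
#'
#' Current intensity over remaining intensity, `rho / (1 - rho)`; unbounded
#' intensities are mapped onto a signed ratio whose sign tracks
#' `sign(1 - rho)`. Within `epsilon` of `rho = 1` the ward is exactly full
#' and the ratio is the `Inf` sentinel, which [adjust_vertex_capacity()]
#' turns into an adjusted capacity of 0.
#' @param intensity rho, >= 0
#' @param epsilon half-width of the "exactly full" band (default 1e-9)
#' @return dimensionless ratio (`Inf` at full capacity)
#' @export
overflow_ratio <- function(intensity, epsilon = 1e-9) {
  if (any(intensity < 0)) stop("intensity must be >= 0")
  ifelse(abs(1 - intensity) < epsilon, Inf, intensity / (1 - intensity))
}

#' Adjusted ward capacity
#'
#' Scales the physical bed count by the load: `C` when idle (`rho = 0`),
#' `min(C, C * (1 - rho) / rho)` otherwise, and exactly 0 at `rho = 1`.
#' Positive iff `rho < 1` (capacity left for flow), negative iff `rho > 1`
#' (the magnitude grades the overflow), non-increasing in `rho`, and never
#' above the physical bed count.
#' @param beds physical capacity C, >= 1
#' @param intensity rho, >= 0
#' @param epsilon "exactly full" band, as in [overflow_ratio()]
#' @return adjusted capacity in bed-equivalents (real, may be negative)
#' @export
adjust_vertex_capacity <- function(beds, intensity, epsilon = 1e-9) {
  if (any(beds < 1)) stop("beds must be >= 1")
  if (any(intensity < 0)) stop("intensity must be >= 0")
  ifelse(intensity == 0, beds,
         ifelse(abs(1 - intensity) < epsilon, 0,
                pmin(beds, beds * (1 - intensity) / intensity)))
}

#' Edge inflow rate
#'
#' The hospital arrival rate thinned by the edge's distribution probability.
#' @param arrival_rate patients/hour, >= 0
#' @param probability routing probability DP in `[0, 1]`
#' @return patients/hour entering the edge
#' @export
edge_inflow <- function(arrival_rate, probability) {
  if (any(arrival_rate < 0)) stop("arrival_rate must be >= 0")
  if (any(probability < 0 | probability > 1))
    stop("probability must lie in [0, 1]")
  arrival_rate * probability
}

#' Adjusted edge capacity
#'
#' Queue slots left after the step's inflow: `Q - inflow`. Negative values
#' mean the queue alone cannot absorb the inflow.
#' @param queue_capacity Q, >= 0
#' @param inflow patients/hour, >= 0
#' @return queue-slot equivalents (real, may be negative)
#' @export
adjust_edge_capacity <- function(queue_capacity, inflow) {
  if (any(queue_capacity < 0)) stop("queue_capacity must be >= 0")
  if (any(inflow < 0)) stop("inflow must be >= 0")
  queue_capacity - inflow
}

#' Per-ward loads for one arrival-rate step
#'
#' Computes sampled-service-time derived quantities for every interior ward:
#' service rate, intensity, overflow ratio and adjusted capacity.
#'
#' @param net a `hospital_network`
#' @param arrival_rate the step's hospital arrival rate r_t
#' @param s_times named numeric vector: sampled service time (hours) per
#'   interior ward
#' @param vertex_arrival `"raw"` (default: every ward sees r_t, routing
#'   probabilities act only on the edges) or `"weighted"` (a ward sees r_t
#'   scaled by the sum of its incoming routing probabilities)
#' @param epsilon "exactly full" band for the intensity
#' @return data.frame (`ward`, `s_time`, `service_rate`, `intensity`,
#'   `overflow_ratio`, `adjusted_capacity`), one row per interior ward
#' @export
compute_vertex_loads <- function(net, arrival_rate, s_times,
                                 vertex_arrival = c("raw", "weighted"),
                                 epsilon = 1e-9) {
  vertex_arrival <- match.arg(vertex_arrival)
  wards <- interior_wards(net)
  missing <- setdiff(wards, names(s_times))
  if (length(missing))
    stop("missing service time for ward(s): ", paste(missing, collapse = ", "))
  st <- as.numeric(s_times[wards])
  idx <- match(wards, net$wards$name)
  mu <- service_rate(net$wards$servers[idx], st)
  arr <- rep(arrival_rate, length(wards))
  if (vertex_arrival == "weighted") {
    dpin <- vapply(wards, function(w)
      sum(net$pathways$probability[net$pathways$target == w]), numeric(1))
    arr <- arrival_rate * dpin
  }
  rho <- flow_intensity(arr, mu)
  data.frame(ward = wards, s_time = st, service_rate = mu, intensity = rho,
             overflow_ratio = overflow_ratio(rho, epsilon),
             adjusted_capacity = adjust_vertex_capacity(net$wards$beds[idx],
                                                        rho, epsilon),
             stringsAsFactors = FALSE)
}

#' Build the static residual graph for one step
#'
#' For every edge (u, v): adjusted edge capacity plus the receiving ward's
#' adjusted capacity; edges into the sink carry only the edge term. The
#' result is real-valued and may be negative — negative residuals block flow
#' and their magnitude grades the overflow.
#'
#' @param net a `hospital_network`
#' @param arrival_rate the step's arrival rate r_t
#' @param vertex_loads data.frame from [compute_vertex_loads()] covering
#'   every interior ward
#' @param step step index stored on the result (default 0)
#' @return object of class `static_residual`: data.frame (`source`,
#'   `target`, `probability`, `residual`) with one row per network edge, in
#'   network edge order; attribute `step`.
#' @export
build_static_residual <- function(net, arrival_rate, vertex_loads, step = 0L) {
  p <- net$pathways
  adj <- stats::setNames(vertex_loads$adjusted_capacity, vertex_loads$ward)
  vterm <- numeric(nrow(p))
  into_ward <- p$target != net$sink
  missing <- setdiff(unique(p$target[into_ward]), names(adj))
  if (length(missing))
    stop("missing vertex load for ward(s): ", paste(missing, collapse = ", "))
  vterm[into_ward] <- adj[p$target[into_ward]]
  res <- adjust_edge_capacity(p$capacity,
                              edge_inflow(arrival_rate, p$probability)) + vterm
  out <- data.frame(source = p$source, target = p$target,
                    probability = p$probability, residual = res,
                    stringsAsFactors = FALSE)
  structure(out, class = c("static_residual", "data.frame"), step = step)
}
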