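# Synthetic hospitals.
#
# Real single-hospital datasets are rarely shareable, so every analysis here
# is testable against generated networks that copy the structure such data
# has: one entry and one exit vertex, wards with beds and staff, care
# pathways with a 5-slot waiting queue, per-ward outgoing routing
# probabilities summing to 1, and an hourly arrival profile.

# Fixed 20-ward / 62-edge reference fixture. The wiring below is a
# versioned artifact of this package: routing weights encode ward
# importance (the Emergency Department takes most arrivals) and are
# normalised to probabilities per source ward.
.toy_wards <- function() {
  data.frame(
    name = c("Emergency Department", "Infectious diseases Unit",
             "Medical Ward", "Cardiac", "Respiratory", "Surgery",
             "Orthopedics", "ICU", "Pediatrics", "Maternity", "Oncology",
             "Neurology", "Geriatrics", "Radiology", "Laboratory",
             "Rehabilitation", "Psychiatry", "Urology"),
    beds = c(30, 15, 40, 20, 18, 25, 22, 12, 20, 16, 24, 18, 28, 8, 6,
             30, 20, 12),
    stringsAsFactors = FALSE)
}

.toy_edges <- function() {
  # source, target, importance weight
  e <- rbind(
    c("Entrance", "Emergency Department", 10),
    c("Entrance", "Infectious diseases Unit", 2),
    c("Entrance", "Medical Ward", 3),
    c("Entrance", "Cardiac", 2),
    c("Entrance", "Maternity", 2),
    c("Entrance", "Psychiatry", 1),
    c("Entrance", "Pediatrics", 1),
    c("Emergency Department", "Medical Ward", 4),
    c("Emergency Department", "Cardiac", 3),
    c("Emergency Department", "Respiratory", 2),
    c("Emergency Department", "Surgery", 3),
    c("Emergency Department", "Orthopedics", 2),
    c("Emergency Department", "ICU", 2),
    c("Emergency Department", "Neurology", 2),
    c("Emergency Department", "Urology", 1),
    c("Emergency Department", "Discharge", 5),
    c("Infectious diseases Unit", "Medical Ward", 2),
    c("Infectious diseases Unit", "Respiratory", 1),
    c("Infectious diseases Unit", "ICU", 1),
    c("Infectious diseases Unit", "Discharge", 4),
    c("Medical Ward", "Cardiac", 1),
    c("Medical Ward", "Respiratory", 1),
    c("Medical Ward", "Oncology", 1),
    c("Medical Ward", "Geriatrics", 2),
    c("Medical Ward", "Radiology", 1),
    c("Medical Ward", "Laboratory", 1),
    c("Medical Ward", "Discharge", 5),
    c("Cardiac", "ICU", 2),
    c("Cardiac", "Radiology", 1),
    c("Cardiac", "Rehabilitation", 1),
    c("Cardiac", "Discharge", 4),
    c("Respiratory", "ICU", 1),
    c("Respiratory", "Laboratory", 1),
    c("Respiratory", "Discharge", 3),
    c("Surgery", "ICU", 2),
    c("Surgery", "Orthopedics", 1),
    c("Surgery", "Rehabilitation", 2),
    c("Surgery", "Discharge", 3),
    c("Orthopedics", "Radiology", 1),
    c("Orthopedics", "Rehabilitation", 2),
    c("Orthopedics", "Discharge", 3),
    c("ICU", "Rehabilitation", 1),
    c("ICU", "Geriatrics", 1),
    c("ICU", "Discharge", 2),
    c("Pediatrics", "Respiratory", 1),
    c("Pediatrics", "Laboratory", 1),
    c("Pediatrics", "Discharge", 3),
    c("Maternity", "Pediatrics", 1),
    c("Maternity", "Discharge", 4),
    c("Oncology", "Radiology", 1),
    c("Oncology", "Laboratory", 1),
    c("Oncology", "Discharge", 3),
    c("Neurology", "Radiology", 1),
    c("Neurology", "Rehabilitation", 1),
    c("Neurology", "Discharge", 3),
    c("Geriatrics", "Rehabilitation", 1),
    c("Geriatrics", "Discharge", 4),
    c("Radiology", "Discharge", 1),
    c("Laboratory", "Discharge", 1),
    c("Rehabilitation", "Discharge", 1),
    c("Psychiatry", "Discharge", 1),
    c("Urology", "Discharge", 1))
  data.frame(source = e[, 1], target = e[, 2], weight = as.numeric(e[, 3]),
             stringsAsFactors = FALSE)
}

.toy_los <- function() {
  list(
    `Emergency Department` = c(1, 2, 3, 4, 6, 8, 12),
    `Infectious diseases Unit` = c(48, 72, 120, 168, 240),
    `Medical Ward` = c(24, 48, 72, 96, 144),
    Cardiac = c(24, 48, 96, 120),
    Respiratory = c(24, 48, 72, 120),
    Surgery = c(12, 24, 48, 96),
    Orthopedics = c(24, 48, 72, 120),
    ICU = c(24, 48, 96, 168, 240),
    Pediatrics = c(12, 24, 48, 72),
    Maternity = c(24, 48, 72),
    Oncology = c(48, 96, 168, 240),
    Neurology = c(24, 72, 120, 168),
    Geriatrics = c(72, 120, 240, 360),
    Radiology = c(0.5, 1, 1.5, 2),
    Laboratory = c(0.25, 0.5, 1),
    Rehabilitation = c(120, 240, 360, 504),
    Psychiatry = c(72, 168, 336),
    Urology = c(12, 24, 48, 72))
}

#' The 20-ward / 62-edge reference hospital
#'
#' A fixed, versioned synthetic fixture: 20 wards (including the Entrance
#' source and Discharge sink) connected by 62 care pathways, every edge with
#' a 5-slot waiting queue, staff equal to beds, routing probabilities
#' derived from per-ward importance weights (summing to 1 per ward), and a
#' plausible set of observed lengths of stay per ward. Deterministic: the
#' same network on every call.
#'
#' @param queue_capacity waiting-queue slots on every pathway (default 5)
#' @return a valid `hospital_network` with `n = 20`, `m = 62`
#' @export
make_toy_hospital <- function(queue_capacity = 5) {
  w <- .toy_wards()
  wards <- data.frame(name = w$name, beds = w$beds, servers = w$beds,
                      stringsAsFactors = FALSE)
  e <- .toy_edges()
  wsum <- tapply(e$weight, e$source, sum)
  pathways <- data.frame(source = e$source, target = e$target,
                         capacity = queue_capacity,
                         probability = e$weight / as.numeric(wsum[e$source]),
                         stringsAsFactors = FALSE)
  hospital_network(wards, pathways, "Entrance", "Discharge",
                   los = .toy_los())
}

#' The reference 24-hour spike arrival profile
#'
#' One arrival rate per hour: a quiet baseline of 1 patient/hour with a
#' mid-day surge rising to 40 patients/hour at hour index 10 (0-based),
#' used to study ward overflow under a sharp arrival fluctuation.
#'
#' @return numeric vector of length 24 (patients/hour)
#' @export
make_spike_arrivals <- function() {
  c(1, 1, 1, 1, 1, 1, 1, 10, 20, 30, 40, 30, 20, 10,
    1, 1, 1, 1, 1, 1, 1, 1, 1, 1)
}

#' Generate a random valid hospital network
#'
#' Builds a layered, source-to-sink-connected directed network for property
#' testing: each interior ward gets at least one incoming and one outgoing
#' pathway (toward later wards or the sink, so the base wiring is acyclic),
#' plus extra forward edges at the requested density. Routing probabilities
#' come from normalised random weights; lengths of stay are drawn uniformly
#' within `los_range`.
#'
#' @param n_wards total ward count including source and sink, >= 3
#' @param edge_density probability of each optional forward edge
#' @param beds_range integer range to draw bed counts from
#' @param servers_rule `"equal-to-beds"`, `"half-beds"` (ceiling),
#'   `"double-beds"`, or a numeric vector of explicit server counts
#' @param queue_capacity waiting-queue slots per pathway
#' @param los_range range (hours) for the generated length-of-stay values
#' @param n_los observed stays generated per ward
#' @param seed integer seed; same seed, same network
#' @return a valid `hospital_network`
#' @export
make_random_hospital <- function(n_wards = 10, edge_density = 0.3,
                                 beds_range = c(5, 40),
                                 servers_rule = "equal-to-beds",
                                 queue_capacity = 5,
                                 los_range = c(2, 240), n_los = 8,
                                 seed = 1L) {
  if (n_wards < 3) stop("n_wards must be >= 3 (source, sink, >= 1 ward)")
  set.seed(as.integer(seed))
  k <- n_wards - 2L
  wn <- sprintf("Ward %02d", seq_len(k))
  beds <- sample(seq(beds_range[1], beds_range[2]), k, replace = TRUE)
  servers <- if (is.numeric(servers_rule)) {
    if (length(servers_rule) != k) stop("explicit servers need one value per ward")
    servers_rule
  } else switch(servers_rule,
    `equal-to-beds` = beds,
    `half-beds` = ceiling(beds / 2),
    `double-beds` = beds * 2,
    stop("unknown servers_rule: ", servers_rule))

  nodes <- c("Source", wn, "Sink")  # positions 1..k+2, forward edges only
  src <- character(0); tgt <- character(0)
  add_edge <- function(a, b) { src <<- c(src, a); tgt <<- c(tgt, b) }
  # backbone: every interior ward reachable and draining
  add_edge("Source", wn[1])
  for (i in seq_len(k)) {
    later <- if (i < k) c(wn[(i + 1):k], "Sink") else "Sink"
    add_edge(wn[i], sample(later, 1))
    if (i > 1) {
      earlier <- c("Source", wn[seq_len(i - 1)])
      from <- sample(earlier, 1)
      if (!any(src == from & tgt == wn[i])) add_edge(from, wn[i])
    }
  }
  # optional forward edges at the requested density
  for (i in seq_len(k + 1)) for (j in (i + 1):(k + 2)) {
    a <- nodes[i]; b <- nodes[j]
    if (a == "Source" && b == "Sink") next
    if (any(src == a & tgt == b)) next
    if (stats::runif(1) < edge_density) add_edge(a, b)
  }
  w <- stats::runif(length(src), 0.2, 1)
  wsum <- tapply(w, src, sum)
  pathways <- data.frame(source = src, target = tgt,
                         capacity = queue_capacity,
                         probability = w / as.numeric(wsum[src]),
                         stringsAsFactors = FALSE)
  los <- lapply(stats::setNames(seq_len(k), wn), function(i)
    stats::runif(n_los, los_range[1], los_range[2]))
  hospital_network(
    data.frame(name = wn, beds = beds, servers = servers,
               stringsAsFactors = FALSE),
    pathways, "Source", "Sink", los = los)
}

#' Constant service-time distributions for every ward
#'
#' Assigns the same constant service time to every interior ward, the
#' controlled-variability scenario (e.g. 5.01 hours everywhere) used to
#' isolate the effect of the arrival-rate profile.
#'
#' @param net a `hospital_network`
#' @param value service time in hours, > 0
#' @return named list of constant [service_distribution()]s, one per
#'   interior ward
#' @export
make_constant_service <- function(net, value = 5.01) {
  if (!is.finite(value) || value <= 0) stop("value must be > 0")
  wards <- interior_wards(net)
  stats::setNames(lapply(wards, function(w)
    service_distribution("constant", list(value = value), value, value)),
    wards)
}

#' Write a generated hospital to tabular files
#'
#' Emits the wards, edges, arrival-profile and length-of-stay tables in the
#' formats [load_network()] reads.
#'
#' @param net a `hospital_network`
#' @param dir output directory (created if needed)
#' @param arrivals optional numeric arrival profile to write
#' @return named character vector of written paths, invisibly
#' @export
write_network_tables <- function(net, dir, arrivals = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(wards = file.path(dir, "wards.csv"),
             edges = file.path(dir, "edges.csv"))
  utils::write.csv(data.frame(ward = net$wards$name, beds = net$wards$beds,
                              staff = net$wards$servers),
                   paths["wards"], row.names = FALSE, quote = TRUE)
  utils::write.csv(data.frame(source = net$pathways$source,
                              target = net$pathways$target,
                              capacity = net$pathways$capacity,
                              probability = net$pathways$probability),
                   paths["edges"], row.names = FALSE, quote = TRUE)
  if (length(net$los)) {
    paths["los"] <- file.path(dir, "los.csv")
    utils::write.csv(data.frame(
      ward = rep(names(net$los), lengths(net$los)),
      los_hours = unlist(net$los, use.names = FALSE)),
      paths["los"], row.names = FALSE, quote = TRUE)
  }
  if (!is.null(arrivals)) {
    paths["arrivals"] <- file.path(dir, "arrivals.csv")
    utils::write.csv(data.frame(hour = seq_along(arrivals) - 1L,
                                rate = arrivals),
                     paths["arrivals"], row.names = FALSE, quote = FALSE)
  }
  invisible(paths)
}
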