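# Run-directory serialization.
#
# A completed run is written as plain-text artifacts: dynrg.csv (per-edge
# min/max/mean residual), dynv.csv (long per-ward residual series),
# paths.jsonl (one augmenting path per line), manifest.json (config echo,
# seed, versions) and a copy of the input tables, so that the directory is
# self-describing and the run reproducible.

#' Read an arrival-rate profile from a file
#'
#' Accepts a `hour,rate` CSV/TSV (any column named `rate` is used) or a
#' plain one-value-per-line list without header.
#' @param path file path
#' @return numeric vector of rates
#' @export
load_arrivals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  has_header <- is.na(suppressWarnings(
    as.numeric(strsplit(first, "[,\t]")[[1]][1])))
  if (has_header) {
    tab <- .read_table(path)
    col <- if ("rate" %in% names(tab)) "rate" else names(tab)[ncol(tab)]
    rates <- as.numeric(tab[[col]])
  } else {
    rates <- as.numeric(readLines(path))
  }
  if (any(is.na(rates))) stop("non-numeric arrival rate in ", path)
  if (any(rates < 0)) stop("arrival rates must be >= 0")
  rates
}

#' Write a simulation result to a run directory
#'
#' @param result a `flow_simulation`
#' @param dir output directory (created if needed)
#' @param inputs optional named character vector of input files to copy into
#'   `dir/inputs/` (making the run self-describing)
#' @return the directory, invisibly
#' @export
write_simulation <- function(result, dir, inputs = NULL) {
  stopifnot(inherits(result, "flow_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(result$dynrg, file.path(dir, "dynrg.csv"),
                   row.names = FALSE)
  dynv_long <- data.frame(
    ward = rep(colnames(result$dynv), each = nrow(result$dynv)),
    step = rep(seq_len(nrow(result$dynv)), ncol(result$dynv)),
    residual = as.vector(result$dynv), stringsAsFactors = FALSE)
  utils::write.csv(dynv_long, file.path(dir, "dynv.csv"), row.names = FALSE)

  if (!is.null(result$paths)) {
    con <- file(file.path(dir, "paths.jsonl"), "w")
    on.exit(close(con))
    for (t in seq_along(result$paths)) for (p in result$paths[[t]]) {
      writeLines(jsonlite::toJSON(
        list(step = t, wards = p$wards, bottleneck = p$bottleneck),
        auto_unbox = TRUE, digits = NA), con)
    }
  }
  manifest <- list(
    seed = result$seed,
    config = result$config[!vapply(result$config, is.function, logical(1))],
    source = result$network$source, sink = result$network$sink,
    n_wards = result$network$n, n_pathways = result$network$m,
    steps = length(result$flow), total_flow = sum(result$flow),
    arrival_rates = result$arrival_rates,
    package_version = as.character(utils::packageVersion("hospitalflow")),
    r_version = as.character(getRversion()))
  if (!is.null(inputs)) {
    idir <- file.path(dir, "inputs")
    dir.create(idir, showWarnings = FALSE)
    copied <- vapply(names(inputs), function(k) {
      dest <- file.path(idir, basename(inputs[[k]]))
      file.copy(inputs[[k]], dest, overwrite = TRUE)
      file.path("inputs", basename(inputs[[k]]))
    }, character(1))
    manifest$inputs <- as.list(copied)
  }
  # Inf is not valid JSON; the cap is encoded as null when uncapped
  if (is.infinite(manifest$config$max_augmentations_per_step))
    manifest$config$max_augmentations_per_step <- NULL
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(dir)
}

#' Read a run directory back into a result object
#'
#' Reconstructs a `flow_simulation`-compatible object (DynRG, DynV, path
#' log, config, and the network re-loaded from the copied inputs) from the
#' files written by [write_simulation()].
#' @param dir run directory
#' @return a `flow_simulation`
#' @export
read_simulation <- function(dir) {
  need <- file.path(dir, c("dynrg.csv", "dynv.csv", "manifest.json"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    stop("missing result file(s): ", paste(missing, collapse = ", "))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  dynrg <- utils::read.csv(file.path(dir, "dynrg.csv"),
                           stringsAsFactors = FALSE, check.names = FALSE)
  dynv_long <- utils::read.csv(file.path(dir, "dynv.csv"),
                               stringsAsFactors = FALSE)
  wards <- unique(dynv_long$ward)
  steps <- max(dynv_long$step)
  dynv <- matrix(NA_real_, steps, length(wards),
                 dimnames = list(NULL, wards))
  dynv[cbind(dynv_long$step, match(dynv_long$ward, wards))] <-
    dynv_long$residual

  paths <- NULL
  pfile <- file.path(dir, "paths.jsonl")
  if (file.exists(pfile)) {
    paths <- vector("list", steps)
    for (t in seq_len(steps)) paths[[t]] <- list()
    for (line in readLines(pfile)) {
      rec <- jsonlite::fromJSON(line)
      t <- rec$step
      paths[[t]][[length(paths[[t]]) + 1L]] <-
        list(wards = rec$wards, bottleneck = rec$bottleneck)
    }
  }
  net <- NULL
  if (!is.null(manifest$inputs) && !is.null(manifest$inputs$wards)) {
    wf <- file.path(dir, manifest$inputs$wards)
    ef <- file.path(dir, manifest$inputs$edges)
    lf <- if (!is.null(manifest$inputs$los))
      file.path(dir, manifest$inputs$los) else NULL
    if (file.exists(wf) && file.exists(ef))
      net <- load_network(wf, ef, manifest$source, manifest$sink,
                          los_file = lf)
  }
  flow <- vapply(seq_len(steps), function(t) {
    if (is.null(paths) || length(paths[[t]]) == 0) return(0)
    sum(vapply(paths[[t]], function(p) p$bottleneck, numeric(1)))
  }, numeric(1))
  structure(list(dynrg = dynrg, dynv = dynv, paths = paths, flow = flow,
                 arrival_rates = manifest$arrival_rates,
                 config = manifest$config, seed = manifest$seed,
                 network = net),
            class = "flow_simulation")
}
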