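# network construction, validation, transformation, serialization

test_that("a minimal chain builds with source/sink added as sentinels", {
  net <- make_chain()
  expect_s3_class(net, "hospital_network")
  expect_equal(net$n, 3)
  expect_equal(net$m, 2)
  # entry/exit points never constrain flow
  sentinels <- net$wards[net$wards$name %in% c("S", "T"), ]
  expect_true(all(sentinels$beds == 1e9))
  expect_true(all(sentinels$servers == 1e9))
})

test_that("constructor rejects structural violations", {
  # dangling endpoint
  expect_error(hospital_network(
    data.frame(name = "A", beds = 5, servers = 5),
    data.frame(source = c("S", "A"), target = c("X", "T"),
               capacity = 5, probability = 1),
    "S", "T"), "not a known ward")
  # probability sum 0.9 != 1
  expect_error(hospital_network(
    data.frame(name = c("A", "B", "C"), beds = 5, servers = 5),
    data.frame(source = c("S", "A", "A", "B", "C"),
               target = c("A", "B", "C", "T", "T"),
               capacity = 5, probability = c(1, 0.6, 0.3, 1, 1)),
    "S", "T"), "sum to 0.9")
  # source must equal neither sink nor carry inbound edges
  expect_error(hospital_network(
    data.frame(name = "A", beds = 5, servers = 5),
    data.frame(source = c("S", "A", "A"), target = c("A", "S", "T"),
               capacity = 5, probability = c(1, 0.5, 0.5)),
    "S", "T"), "in-degree")
})

test_that("validate_network reports without throwing and honours tolerance", {
  good <- make_chain()
  rep <- validate_network(good)
  expect_true(rep$ok)
  expect_equal(nrow(rep$issues), 0)

  # DP sum 1.0000001 is inside the 1e-6 tolerance
  p <- data.frame(source = c("S", "A", "A", "B", "C"),
                  target = c("A", "B", "C", "T", "T"),
                  capacity = 5,
                  probability = c(1, 0.6, 0.4000001, 1, 1))
  net <- hospital_network(data.frame(name = c("A", "B", "C"),
                                     beds = 5, servers = 5),
                          p, "S", "T", check = FALSE)
  expect_true(validate_network(net)$ok)
  p$probability[3] <- 0.41  # well outside
  net <- hospital_network(net$wards, p, "S", "T", check = FALSE)
  rep <- validate_network(net)
  expect_false(rep$ok)
  expect_match(rep$issues$message[rep$issues$severity == "error"], "sum to")

  # ok is true iff no error-severity issue: cycles only warn
  cyc <- hospital_network(
    data.frame(name = c("A", "B"), beds = 5, servers = 5),
    data.frame(source = c("S", "A", "B", "B", "A"),
               target = c("A", "B", "A", "T", "T"),
               capacity = 5, probability = c(1, 0.5, 0.5, 0.5, 0.5)),
    "S", "T", check = FALSE)
  rep <- validate_network(cyc)
  expect_true(rep$ok)
  expect_true(any(grepl("cycle", rep$issues$message)))
})

test_that("load_network reads CSV tables, trims names and applies beds=servers fallback", {
  d <- withr::local_tempdir()
  writeLines(c("ward,beds,staff", " A ,10,8", "B,4,"),
             file.path(d, "wards.csv"))
  writeLines(c("source,target,capacity,probability",
               "S,A,5,1", "A,B,5,1", "B,T,5,1"),
             file.path(d, "edges.csv"))
  writeLines(c("ward,los_hours", "A,2", "A,4", "B,8"),
             file.path(d, "los.csv"))
  net <- load_network(file.path(d, "wards.csv"), file.path(d, "edges.csv"),
                      "S", "T", los_file = file.path(d, "los.csv"))
  expect_equal(net$n, 4)
  expect_equal(net$wards$servers[net$wards$name == "B"], 4)  # fallback
  expect_equal(net$wards$servers[net$wards$name == "A"], 8)
  expect_equal(net$los$A, c(2, 4))

  expect_error(load_network(file.path(d, "nope.csv"),
                            file.path(d, "edges.csv"), "S", "T"),
               "file not found")
  writeLines(c("ward,beds,staff", "A,ten,1"), file.path(d, "bad.csv"))
  expect_error(load_network(file.path(d, "bad.csv"),
                            file.path(d, "edges.csv"), "S", "T"),
               "non-numeric")
})

test_that("shipped example tables load into the reference network", {
  wards <- system.file("extdata", "wards.csv", package = "hospitalflow")
  edges <- system.file("extdata", "edges.csv", package = "hospitalflow")
  los <- system.file("extdata", "los.csv", package = "hospitalflow")
  net <- load_network(wards, edges, "Entrance", "Discharge", los_file = los)
  expect_true(validate_network(net)$ok)
  ref <- make_toy_hospital()
  expect_equal(net$wards$beds, ref$wards$beds)
  expect_equal(net$pathways$probability, ref$pathways$probability,
               tolerance = 1e-12)
})

test_that("set_equal_distribution gives 1/outdegree and is idempotent", {
  net <- make_toy_hospital()
  eq <- set_equal_distribution(net)
  outdeg <- table(eq$pathways$source)
  expect_equal(eq$pathways$probability,
               1 / as.numeric(outdeg[eq$pathways$source]))
  # per-ward sums are exactly 1 up to float addition
  sums <- tapply(eq$pathways$probability, eq$pathways$source, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
  # idempotent; everything else unchanged
  eq2 <- set_equal_distribution(eq)
  expect_equal(eq2$pathways, eq$pathways)
  expect_equal(eq$wards, net$wards)
  expect_equal(eq$pathways[, c("source", "target", "capacity")],
               net$pathways[, c("source", "target", "capacity")])
})

test_that("graph export round-trips vertices, edges and numeric attributes", {
  net <- make_toy_hospital()
  f <- withr::local_tempfile(fileext = ".graphml")
  col <- data.frame(ward = net$wards$name,
                    status = rep("reached", net$n))
  export_graph(net, f, vertex_attrs = col)
  g <- igraph::read_graph(f, format = "graphml")
  expect_equal(igraph::vcount(g), net$n)
  expect_equal(igraph::ecount(g), net$m)
  expect_true(all(igraph::V(g)$status == "reached"))
  # numeric attributes preserved to 1e-9
  el <- igraph::as_data_frame(g, what = "edges")
  key_in <- paste(net$pathways$source, net$pathways$target)
  idx <- match(paste(el$from, el$to), key_in)
  expect_true(all(abs(el$probability - net$pathways$probability[idx]) < 1e-9))
  expect_error(export_graph(net, f,
                            vertex_attrs = data.frame(ward = "Nope", x = 1)),
               "unknown ward")
  expect_error(export_graph(net, withr::local_tempfile(fileext = ".xyz")),
               "unsupported")
})

test_that("generated random networks always validate cleanly", {
  for (seed in 1:25) {
    net <- make_random_hospital(n_wards = sample(4:15, 1), seed = seed,
                                edge_density = stats::runif(1, 0.1, 0.6))
    rep <- validate_network(net)
    expect_true(rep$ok, info = paste("seed", seed))
  }
})
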