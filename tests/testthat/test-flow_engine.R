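# dynamic flow loop: path search, augmentation, per-step and full runs

test_that("DFS finds positive-residual paths and respects blockages", {
  r <- as_residual(data.frame(source = c("S", "A"), target = c("A", "T"),
                              residual = c(3, 2)))
  p <- dfs_find_path(r, "S", "T")
  expect_equal(p$wards, c("S", "A", "T"))
  expect_equal(p$bottleneck, 2)

  # a non-positive middle edge blocks the flow
  r$residual[2] <- 0
  expect_null(dfs_find_path(r, "S", "T"))
  r$residual[2] <- -4
  expect_null(dfs_find_path(r, "S", "T"))
  expect_error(dfs_find_path(r, "S", "nope"), "absent")
})

test_that("DFS agrees with a brute-force reachability oracle on random graphs", {
  set.seed(123)
  for (i in 1:200) {
    g <- random_residual_graph(n_mid = sample(2:8, 1),
                               p_edge = stats::runif(1, 0.1, 0.5))
    p <- dfs_find_path(g, "S", "T")
    expect_equal(!is.null(p), oracle_reachable(g, "S", "T"), info = i)
    if (!is.null(p)) {
      # every hop is a real edge with positive residual
      key <- paste(g$source, g$target)
      hops <- paste(p$wards[-length(p$wards)], p$wards[-1])
      expect_true(all(hops %in% key))
      expect_true(all(g$residual[p$edges] > 0))
      expect_equal(p$bottleneck, min(g$residual[p$edges]))
    }
  }
})

test_that("DFS explores by descending routing probability, deterministically", {
  r <- as_residual(data.frame(source = c("S", "S", "A", "B"),
                              target = c("A", "B", "T", "T"),
                              probability = c(0.2, 0.8, 1, 1),
                              residual = c(5, 5, 5, 5)))
  p <- dfs_find_path(r, "S", "T")
  expect_equal(p$wards, c("S", "B", "T"))  # higher-DP branch first
  p2 <- dfs_find_path(r, "S", "T")
  expect_identical(p, p2)
})

test_that("DFS terminates on cyclic residual graphs (simple paths only)", {
  r <- as_residual(data.frame(source = c("S", "A", "B", "B"),
                              target = c("A", "B", "A", "T"),
                              residual = c(2, 2, 2, -1)))
  expect_null(dfs_find_path(r, "S", "T"))  # only exit edge is blocked
  r$residual[4] <- 1
  expect_equal(dfs_find_path(r, "S", "T")$wards, c("S", "A", "B", "T"))
})

test_that("augmentation subtracts exactly the pushed amount, forward only", {
  r <- as_residual(data.frame(source = c("S", "A", "B"),
                              target = c("A", "B", "T"),
                              residual = c(3, 7, 2)))
  p <- dfs_find_path(r, "S", "T")
  expect_equal(path_bottleneck(r, p), 2)
  r2 <- augment(r, p, 2)
  expect_equal(r2$residual, c(1, 5, 0))
  expect_equal(nrow(r2), nrow(r))  # no backward edges appear
  expect_error(augment(r, p, 0), "> 0")
  expect_error(augment(r, p, 3), "exceeds")
  expect_error(path_bottleneck(r, list(edges = integer(0))), "empty")
})

test_that("a step pushes until blocked, conserving flow", {
  net <- make_chain(beds = 10, servers = 10, q = 5)
  loads <- compute_vertex_loads(net, 0, c(A = 1))
  sr <- build_static_residual(net, 0, loads)
  step <- run_time_step(net, sr, 0)
  # unloaded chain: the bottleneck is the sink edge at Q = 5
  expect_equal(step$total_flow, 5)
  expect_equal(length(step$paths), 1)
  expect_equal(step$total_flow,
               sum(vapply(step$paths, function(p) p$bottleneck, numeric(1))))
  expect_null(dfs_find_path(step$residuals, "S", "T"))

  # all source-outgoing residuals blocked: zero paths, zero flow
  blocked <- as_residual(data.frame(source = c("S", "A"), target = c("A", "T"),
                                    residual = c(-2, 5)))
  step0 <- run_step_on(blocked)
  expect_equal(step0$total_flow, 0)
  expect_length(step0$paths, 0)

  # per-step augmentation cap
  fan <- as_residual(data.frame(source = c("S", "S", "A", "B"),
                                target = c("A", "B", "T", "T"),
                                residual = c(4, 4, 4, 4)))
  capped <- run_step_on(fan, config = list(max_augmentations_per_step = 1))
  expect_length(capped$paths, 1)
})

test_that("forward-only pushed flow never exceeds the classical max-flow", {
  set.seed(2024)
  for (i in 1:100) {
    g <- random_residual_graph(n_mid = sample(3:8, 1),
                               p_edge = stats::runif(1, 0.2, 0.5),
                               res_range = c(-3, 8))
    step <- run_step_on(g)
    expect_lte(step$total_flow, oracle_maxflow(g, "S", "T") + 1e-9)
  }
  # equality on single-path networks
  for (i in 1:20) {
    k <- sample(2:5, 1)
    nodes <- c("S", paste0("W", seq_len(k)), "T")
    g <- as_residual(data.frame(source = nodes[-length(nodes)],
                                target = nodes[-1],
                                residual = stats::runif(k + 1, 0.5, 9)))
    step <- run_step_on(g)
    expect_equal(step$total_flow, oracle_maxflow(g, "S", "T"))
  }
})

test_that("full runs are reproducible bit for bit and log what they pushed", {
  net <- make_toy_hospital()
  a <- run_simulation(net, make_spike_arrivals(), seed = 5)
  b <- run_simulation(net, make_spike_arrivals(), seed = 5)
  expect_identical(a$dynv, b$dynv)
  expect_identical(a$dynrg, b$dynrg)
  expect_identical(a$paths, b$paths)
  c <- run_simulation(net, make_spike_arrivals(), seed = 6)
  expect_false(identical(a$dynv, c$dynv))

  # DynRG extrema bracket every recorded DynV-visible residual
  expect_true(all(a$dynrg$min_cap <= a$dynrg$max_cap))
  expect_true(all(a$dynrg$min_cap <= a$dynrg$mean_cap + 1e-12))
  expect_true(all(a$dynrg$mean_cap <= a$dynrg$max_cap + 1e-12))
  # flow equals the per-step sum of logged bottlenecks
  for (t in seq_along(a$flow))
    expect_equal(a$flow[t], sum(vapply(a$paths[[t]], function(p) p$bottleneck,
                                       numeric(1))))
})

test_that("DynRG running extrema match a brute-force min/max over history", {
  # replay a tiny run by hand: chain at two arrival rates
  net <- make_chain(beds = 10, servers = 10, q = 5)
  dists <- make_constant_service(net, 2)
  sim <- run_simulation(net, c(0, 4), dists, seed = 1)
  hist <- lapply(c(0, 4), function(r) {
    loads <- compute_vertex_loads(net, r, c(A = 2))
    sr <- build_static_residual(net, r, loads)
    run_time_step(net, sr, r)$residuals$residual
  })
  h <- do.call(rbind, hist)
  expect_equal(sim$dynrg$min_cap, apply(h, 2, min))
  expect_equal(sim$dynrg$max_cap, apply(h, 2, max))
  expect_equal(sim$dynv[, "A"],
               vapply(hist, function(x) x[1], numeric(1)))  # incoming edge
  expect_equal(sim$dynv[, "S"],
               vapply(hist, function(x) x[1], numeric(1)))  # outgoing edge
})

test_that("a one-step simulation equals a single hand-built step", {
  net <- make_path_network(k = 2)
  dists <- make_constant_service(net, 3)
  sim <- run_simulation(net, 2, dists, seed = 9)
  st <- stats::setNames(rep(3, 2), interior_wards(net))
  sr <- build_static_residual(net, 2, compute_vertex_loads(net, 2, st))
  step <- run_time_step(net, sr, 2)
  expect_equal(sim$flow, step$total_flow)
  expect_equal(sim$dynrg$min_cap, step$residuals$residual)
  expect_equal(sim$dynrg$max_cap, step$residuals$residual)
})

test_that("horizon repeats scale the run and stay tractable with log off", {
  net <- make_toy_hospital()
  dists <- make_constant_service(net, 5.01)
  sim <- run_simulation(net, make_spike_arrivals(), dists,
                        config = list(repeats = 7, path_log = FALSE),
                        seed = 3)
  expect_equal(length(sim$flow), 24 * 7)
  expect_null(sim$paths)
  expect_equal(nrow(sim$dynv), 168)
})

test_that("config is validated and bad inputs are rejected", {
  net <- make_chain()
  expect_error(run_simulation(net, numeric(0), seed = 1), "non-empty")
  expect_error(run_simulation(net, c(1, -2), seed = 1), ">= 0")
  expect_error(run_simulation(net, 1, config = list(bogus = 1), seed = 1),
               "unknown config")
  expect_error(run_simulation(list(), 1, seed = 1), "hospital_network")
})
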