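test_that("dispatch rule: nearest unit, concurrent ALS for FHQ", {
  # one idle BLS, non-FHQ call -> single assignment
  expect_identical(dispatch_rule("non-FHQ", "BLS", 5), 1L)
  # FHQ with nearest BLS and a farther ALS -> both dispatched
  expect_identical(dispatch_rule("FHQ", c("BLS", "ALS"), c(2, 6)), c(1L, 2L))
  # FHQ with nearest ALS -> single assignment
  expect_identical(dispatch_rule("FHQ", c("ALS", "BLS"), c(2, 6)), 1L)
  # returning unit 2 min away beats idle unit 6 min away
  expect_identical(dispatch_rule("non-FHQ", c("BLS", "BLS"), c(6, 2)), 2L)
  expect_identical(dispatch_rule("FHQ", character(0), numeric(0)), integer(0))
})

test_that("single scripted call: response equals pre-trip delay plus travel", {
  reg <- line_region()
  cfg <- deterministic_cfg()
  # at the station node: pre-trip delay only
  r0 <- run_simulation(reg, reg$stations, cfg, seed = 1,
                       calls = script_df(time = 0, node = "n1",
                                         priority = "non-FHQ"))
  expect_equal(r0$calls$response_time, 1)
  # two 3-minute legs away: 1 + 6
  r1 <- run_simulation(reg, reg$stations, cfg, seed = 1,
                       calls = script_df(time = 0, node = "n3",
                                         priority = "non-FHQ"))
  expect_equal(r1$calls$response_time, 7)
})

test_that("degenerate service times give a hand-computable busy time", {
  reg <- line_region()
  cfg <- deterministic_cfg(p_transport_bls = 0, p_transport_als = 0)
  res <- run_simulation(reg, reg$stations, cfg, seed = 2,
                        calls = script_df(time = 0, node = "n2",
                                          priority = "non-FHQ"))
  # pre-trip 1 + travel 3 + scene 15 (non-FHQ BLS mean, cv 0); released at
  # the scene, so committed time is exactly 19 minutes
  expect_equal(res$calls$response_time, 4)
  expect_equal(res$workloads$busy_min, 19)
  expect_false(res$calls$transported)
  expect_true(is.na(res$calls$hospital))
})

test_that("transport extremes: never vs always", {
  reg <- line_region()
  calls <- script_df(time = c(0, 200, 400), node = "n2",
                     priority = "non-FHQ")
  never <- run_simulation(reg, reg$stations,
                          deterministic_cfg(p_transport_bls = 0), seed = 3,
                          calls = calls)
  expect_true(all(!never$calls$transported))
  always <- run_simulation(reg, reg$stations,
                           deterministic_cfg(p_transport_bls = 1), seed = 3,
                           calls = calls)
  expect_true(all(always$calls$transported))
  expect_true(all(always$calls$hospital == "H1"))
  # hospital pathway adds transport (3 min) + drop-off to the busy time
  expect_gt(sum(always$workloads$busy_min), sum(never$workloads$busy_min))
})

test_that("one ambulance, two near-simultaneous calls: second is queued", {
  reg <- line_region()
  res <- run_simulation(reg, reg$stations, deterministic_cfg(
    p_transport_bls = 0), seed = 4,
    calls = script_df(time = c(0, 1 / 60), node = "n2",
                      priority = "non-FHQ"))
  expect_false(res$calls$queued[1])
  expect_true(res$calls$queued[2])
  # second call (same node) is reached the moment the unit frees at t = 19
  expect_equal(res$calls$response_time[2], 19 - 1 / 60)
  expect_equal(res$n_queued_end, 0)
})

test_that("FHQ dual dispatch engages the nearest ALS concurrently", {
  reg <- line_region(station_nodes = c("n1", "n3"),
                     station_types = c("BLS", "ALS"))
  res <- run_simulation(reg, reg$stations, deterministic_cfg(
    p_transport_als = 0), seed = 5,
    calls = script_df(time = 0, node = "n1", priority = "FHQ"))
  expect_equal(res$calls$response_time, 1)  # BLS on the spot
  expect_true(res$calls$crew_als)           # ALS attended
  expect_true(all(res$workloads$busy_min > 0))
})

test_that("a returning unit is redirected from its interpolated position", {
  reg <- line_region()
  cfg <- deterministic_cfg(p_transport_bls = 0)
  # call 1 at n3: depart 1, arrive 7, scene ends 22, returns at standard
  # speed (10/3 min per leg). Call 2 at t = 24, unit between n3 and n2
  # (reaches n2 at 25.333): redirect = 1.333 min to n2 + 3 min to n3.
  res <- run_simulation(reg, reg$stations, cfg, seed = 6,
                        calls = script_df(time = c(0, 24), node = "n3",
                                          priority = "non-FHQ"))
  expect_equal(res$calls$response_time[1], 7)
  expect_equal(res$calls$response_time[2], (22 + 10 / 3 - 24) + 3,
               tolerance = 1e-9)
  expect_false(res$calls$queued[2])
})

test_that("empty call stream leaves all workloads at zero", {
  reg <- line_region()
  res <- run_simulation(reg, reg$stations, deterministic_cfg(), seed = 1,
                        calls = script_df())
  expect_identical(nrow(res$calls), 0L)
  expect_true(all(res$workloads$workload == 0))
})

test_that("NHPP generator recovers rate, spatial weights and determinism", {
  grid <- data.frame(cell_id = c("a", "b"), node_id = c("n1", "n2"),
                     municipality_id = c("M1", "M2"), weight = c(9, 1))
  cfg <- sim_config(daily_volume = 50,
                    hourly_multipliers = rep(1, 24))  # homogeneous
  counts <- vapply(1:200, function(s)
    nrow(generate_calls(cfg, grid, horizon_days = 1, seed = s)), numeric(1))
  # Poisson moments: mean 50, se of the mean over 200 runs = sqrt(50/200)
  expect_lt(abs(mean(counts) - 50), 3 * sqrt(50 / 200))
  # spatial proportionality
  big <- generate_calls(cfg, grid, horizon_days = 60, seed = 77)
  phat <- mean(big$cell_id == "a")
  n <- nrow(big)
  expect_lt(abs(phat - 0.9), 3 * sqrt(0.9 * 0.1 / n))
  # zero rate, determinism, validation
  cfg0 <- sim_config(daily_volume = 0)
  expect_identical(nrow(generate_calls(cfg0, grid, 1, seed = 1)), 0L)
  expect_identical(generate_calls(cfg, grid, 2, seed = 9),
                   generate_calls(cfg, grid, 2, seed = 9))
  bad <- grid; bad$weight <- 0
  expect_error(generate_calls(cfg, bad, 1, 1),
               class = "emsloc_validation_error")
})

test_that("stochastic run conserves calls and keeps workloads in [0,1]", {
  reg <- generate_region(region_spec(n_municipalities = 12,
                                     n_current_stations = 4, seed = 31))
  cfg <- sim_config(horizon_days = 7, daily_volume = 30, replications = 2)
  res <- run_simulation(reg, reg$stations, cfg, seed = 8)
  n <- nrow(res$calls)
  expect_gt(n, 0)
  expect_equal(sum(res$calls$served) + res$n_queued_end, n)
  expect_true(all(res$workloads$workload >= 0 & res$workloads$workload <= 1))
  expect_true(all(res$calls$response_time[res$calls$served] > 0))
  # deterministic replay
  res2 <- run_simulation(reg, reg$stations, cfg, seed = 8)
  expect_identical(res$calls, res2$calls)
  expect_identical(res$workloads, res2$workloads)
})

test_that("indicators match hand arithmetic", {
  log <- data.frame(response_time = c(5, 10, 20, 12),
                    priority = c("FHQ", "non-FHQ", "FHQ", "non-FHQ"),
                    municipality_id = c("A", "A", "B", "B"))
  w <- data.frame(workload = c(0.2, 0.4))
  ind <- compute_indicators(log, w)
  expect_equal(ind$pct_within_15, 75)
  # municipality means: A = 7.5, B = 16 -> one above 15
  expect_equal(ind$munis_over_15, 1L)
  expect_equal(ind$mean_response, 11.75)
  expect_equal(ind$mean_response_fhq, 12.5)
  expect_equal(ind$pct_fhq_within_8, 50)
  expect_equal(ind$mean_workload_pct, 30)
  expect_equal(ind$cv_workload, 0.1 / 0.3)  # population sd over mean
  empty <- compute_indicators(log[0, ], w)
  expect_true(empty$zero_calls)
})

test_that("busy-fraction estimation follows the neighbourhood rule", {
  tt <- matrix(c(0, 10, 25, 40,
                 10, 0, 15, 50,
                 25, 15, 0, 60,
                 40, 50, 60, 0), 4, 4, byrow = TRUE,
               dimnames = list(paste0("n", 1:4), paste0("n", 1:4)))
  results <- list(workloads = data.frame(
    station_node = c("n2", "n3"), workload = c(0.2, 0.4)))
  q <- estimate_busy_fractions(results, paste0("n", 1:4), tt)
  expect_equal(unname(q["n2"]), 0.2)   # own ambulance
  expect_equal(unname(q["n3"]), 0.4)
  expect_equal(unname(q["n1"]), 0.3)   # stations at 10 and 25 min
  expect_equal(unname(q["n4"]), 0.3)   # nothing within 30 -> global mean
  one <- estimate_busy_fractions(list(workloads = data.frame(
    station_node = "n1", workload = 0.32)), "n1", tt)
  expect_equal(unname(one), 0.32)
})

test_that("replication experiment reports Student-t intervals", {
  reg <- line_region()
  cfg <- sim_config(horizon_days = 2, daily_volume = 10, replications = 4,
                    scene_cv = 0.3)
  rep <- run_experiment(reg, reg$stations, cfg, seed = 12)
  # independent recomputation of the t-interval for the mean response
  per_rep <- vapply(attr(rep, "replication_indicators"),
                    function(x) x$mean_response, numeric(1))
  m <- mean(per_rep)
  half <- qt(0.975, 3) * sd(per_rep) / sqrt(4)
  row <- rep[rep$indicator == "mean_response", ]
  expect_equal(row$mean, m)
  expect_equal(row$ci_hi - row$mean, half, tolerance = 1e-9)
  expect_true(all(row$ci_lo <= row$mean & row$mean <= row$ci_hi))
  expect_error(run_experiment(reg, reg$stations,
                              sim_config(replications = 1), seed = 1),
               class = "emsloc_validation_error")
})

test_that("secondary transports occupy idle BLS units", {
  reg <- line_region(station_nodes = c("n1", "n2"),
                     station_types = c("BLS", "BLS"))
  reg$hospitals <- rbind(reg$hospitals,
                         data.frame(id = "H2", node_id = "n1",
                                    specializations = "general",
                                    dropoff_shape = 2L, dropoff_mean = 10))
  cfg <- deterministic_cfg(secondary_rate_per_day = 24)
  res <- run_simulation(reg, reg$stations, cfg, seed = 14, calls = script_df())
  expect_gt(sum(res$workloads$busy_min), 0)
})
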