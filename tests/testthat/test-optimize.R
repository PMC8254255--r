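# Two-site toy instance used in several hand traces:
# sites {1,2}, demand {a,b}; only site 1 covers a, only site 2 covers b
# (travel 3 resp. 1 min within the 7-min standard, the cross pairs 10 min
# outside it); q = 0.5 everywhere; FHQ demand (10, 1); p = 1.
toy_problem <- function(p = 1, q = 0.5) {
  t <- matrix(c(3, 10,
                10, 1), 2, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  location_problem(t, b = c(10, 1), b_fhq = c(10, 1), p = p, r = 1,
                   q = q, T_max = 7)
}

test_that("MEXCLP picks the high-demand site on the toy instance", {
  res <- solve_mexclp(toy_problem())
  # enumeration: open s1 -> 10*(1-0.5) = 5; open s2 -> 1*(1-0.5) = 0.5
  expect_equal(res$f_star, 5)
  expect_identical(res$open_sites, "s1")
  # p = |I|: geometric-series closed form sum b_fhq (1 - q^n_j)
  res2 <- solve_mexclp(toy_problem(p = 2))
  expect_equal(res2$f_star, 10 * 0.5 + 1 * 0.5)
  # q = 0 reduces to maximal covering
  res3 <- solve_mexclp(toy_problem(p = 1, q = 0))
  expect_equal(res3$f_star, 10)
})

test_that("expected coverage matches its closed form and is monotone", {
  t <- matrix(0, 2, 1, dimnames = list(c("s1", "s2"), "a"))
  pr <- location_problem(t, b = 10, b_fhq = 10, p = 2, q = 0.5)
  expect_equal(expected_coverage(c(0L, 0L), pr), 0)
  expect_equal(expected_coverage(c(1L, 1L), pr), 10 * (1 - 0.25))
  expect_gt(expected_coverage(c(1L, 1L), pr), expected_coverage(c(1L, 0L), pr))
})

test_that("weighted p-median with a coverage floor forces the layout", {
  sol <- solve_weighted_pmedian(toy_problem(), coverage_floor = 5.0)
  # floor forces site 1; g = 3*10 + 10*1 = 40
  expect_identical(sol$open_sites, "s1")
  expect_equal(sol$g, 40)
  expect_gte(sol$f, 5.0 * (1 - 1e-6))
  # unattainable floor
  expect_error(solve_weighted_pmedian(toy_problem(), coverage_floor = 11),
               class = "emsloc_infeasible")
  # p = |I| with zero diagonal: every point self-served, g = 0
  t0 <- matrix(c(0, 9, 9, 0), 2, 2,
               dimnames = list(c("s1", "s2"), c("a", "b")))
  pr0 <- location_problem(t0, b = c(5, 5), b_fhq = c(1, 1), p = 2)
  expect_equal(solve_weighted_pmedian(pr0)$g, 0)
})

test_that("total_weighted_time sums the assignment and validates it", {
  pr <- toy_problem()
  expect_equal(total_weighted_time(c(1L, 1L), pr), 40)
  expect_equal(total_weighted_time(c(1L, 2L), pr), 31)
  expect_error(total_weighted_time(c(1L, NA), pr),
               class = "emsloc_validation_error")
})

test_that("hierarchical line instance: ties broken to the lowest index", {
  # three nodes on a line at 0/5/10 minutes, demands (10, 1, 10), p=2, r=1
  t <- matrix(c(0, 5, 10,
                5, 0, 5,
                10, 5, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("s", 1:3), paste0("j", 1:3)))
  pr <- location_problem(t, b = c(10, 1, 10), b_fhq = c(3, 1, 3),
                         p = 2, r = 1, T_max = 7)
  sol <- solve_hierarchical(pr)
  expect_identical(sol$open_sites, c("s1", "s3"))
  expect_equal(sol$g, 5)             # middle node served 5 min away
  expect_equal(sol$g_als, 105)       # ALS at s1 or s3 both give 105
  expect_identical(sol$als_sites, "s1")  # lowest index wins the tie
  # r = p: ALS everywhere, g_als = g
  pr2 <- location_problem(t, b = c(10, 1, 10), b_fhq = c(3, 1, 3),
                          p = 2, r = 2, T_max = 7)
  sol2 <- solve_hierarchical(pr2)
  expect_equal(sol2$g_als, sol2$g)
  expect_error(solve_hierarchical(
    location_problem(t, b = c(10, 1, 10), b_fhq = c(3, 1, 3), p = 2, r = 0)),
    class = "emsloc_validation_error")
})

test_that("fixed-station preprocessing applies both rules", {
  munis <- data.frame(id = c("M1", "M2", "M3"),
                      node_id = c("n1", "n2", "n3"),
                      current_stations = c(2L, 3L, 1L))
  dem <- data.frame(id = c("M1", "M2", "M3"),
                    b = c(5000, 1500, 800), b_fhq = c(1000, 300, 200))
  pre <- preprocess_fixed_stations(munis, dem, capacity_per_ambulance = 2000)
  # fully engaged: both stations fixed, demand reduced to 5000 - 2*2000
  expect_equal(pre$st[1], 2L)
  expect_false(pre$I1[1]); expect_false(pre$open_allowed[1])
  expect_equal(pre$b_reduced[1], 1000)
  # spare capacity: one station fixed into I1, two freed, demand unchanged
  expect_equal(pre$st[2], 1L)
  expect_true(pre$I1[2])
  expect_equal(pre$freed[2], 2L)
  expect_equal(pre$b_reduced[2], 1500)
  # single under-capacity station: fully relocatable
  expect_equal(pre$st[3], 0L)
  expect_true(pre$open_allowed[3])
  expect_equal(attr(pre, "p"), 6L)
  expect_equal(attr(pre, "p") - sum(pre$st), sum(pre$freed))
  expect_error(preprocess_fixed_stations(munis, dem, 0),
               class = "emsloc_validation_error")
})

test_that("exact solvers match brute-force enumeration on 50 instances", {
  for (seed in 1:50) {
    pr <- random_problem(seed)
    mex <- solve_mexclp(pr)
    expect_equal(mex$f_star, bf_mexclp(pr)$f_star, tolerance = 1e-8,
                 label = sprintf("mexclp seed %d", seed))
    pm <- solve_weighted_pmedian(pr)
    expect_equal(pm$g, bf_pmedian(pr)$g, tolerance = 1e-8,
                 label = sprintf("pmp seed %d", seed))
    lex <- lexicographic_solve(pr)
    bl <- bf_lexicographic(pr)
    expect_equal(lex$g, bl$g, tolerance = 1e-8,
                 label = sprintf("lex seed %d", seed))
    expect_gte(lex$f, bl$f_star * (1 - 1e-6))
    hi <- solve_hierarchical(pr)
    bh <- bf_hierarchical(pr)
    expect_equal(hi$g, bh$g, tolerance = 1e-8,
                 label = sprintf("hier lower seed %d", seed))
    expect_equal(hi$g_als, bh$g_als, tolerance = 1e-8,
                 label = sprintf("hier upper seed %d", seed))
  }
})

test_that("structural invariants hold across random instances", {
  for (seed in 51:70) {
    pr <- random_problem(seed)
    lex <- lexicographic_solve(pr)
    pm <- solve_weighted_pmedian(pr)
    hi <- solve_hierarchical(pr)
    # station-count constraint
    expect_equal(sum(lex$x + pr$st), pr$p)
    expect_equal(sum(hi$x + pr$st), pr$p)
    # ALS cardinality and subset relation
    expect_equal(sum(hi$u), pr$r)
    expect_true(all(hi$u <= pr$st + hi$x))
    expect_gte(hi$g_als, hi$g - 1e-9)
    # lexicographic dominance
    expect_lte(pm$g, lex$g + 1e-9)
    expect_gte(lex$f, expected_coverage(pm$x, pr) - 1e-9)
    # MEXCLP objective equals the closed-form recomputation
    mex <- solve_mexclp(pr)
    expect_equal(mex$f_star, expected_coverage(mex$x, pr), tolerance = 1e-9)
    # nearest-assignment optimality of z
    A <- sort(unique(c(which(pm$x == 1L), which(pr$I1))))
    tmin <- apply(pr$t[A, , drop = FALSE], 2, min)
    expect_equal(pr$t[cbind(pm$assignment, seq_along(pr$b))], unname(tmin))
  }
})

test_that("infeasible configurations raise classed errors", {
  t <- matrix(c(0, 5, 5, 0), 2, 2,
              dimnames = list(c("s1", "s2"), c("a", "b")))
  expect_error(location_problem(t, b = c(1, 1), b_fhq = c(1, 1), p = 0,
                                st = c(1L, 0L)),
               class = "emsloc_infeasible")
  expect_error(location_problem(t, b = c(1, 1), b_fhq = c(1, 1), p = 1,
                                q = c(1, 0.2)),
               class = "emsloc_validation_error")
})

test_that("post-hoc ALS allocation follows keep / greedy-match / fill", {
  nodes <- c("n1", "n2", "n3", "n4")
  tt <- matrix(c(0, 4, 9, 6,
                 4, 0, 5, 2,
                 9, 5, 0, 3,
                 6, 2, 3, 0), 4, 4, byrow = TRUE,
               dimnames = list(nodes, nodes))
  current <- data.frame(node_id = c("n1", "n2"), type = c("ALS", "BLS"))
  # no station moved: types identical
  keep <- allocate_als_posthoc(c("n1", "n2"), current, r = 1, tt)
  expect_identical(keep$type, c("ALS", "BLS"))
  # ALS site n1 removed; nearest new site is n2 (4 min) before n3 (9 min)
  moved <- allocate_als_posthoc(c("n2", "n3"), current, r = 1, tt)
  expect_identical(moved$type[moved$node_id == "n2"], "BLS")
  # n2 keeps its BLS identity (unmoved), so the displaced ALS goes to n3
  expect_identical(moved$type[moved$node_id == "n3"], "ALS")
  # pure greedy case: displaced ALS (from n1) with untyped stations at
  # 4 min (n2) and 9 min (n3) -> the 4-min station gets the ALS
  pure <- allocate_als_posthoc(c("n2", "n3"),
                               data.frame(node_id = "n1", type = "ALS"),
                               r = 1, tt)
  expect_identical(pure$type[pure$node_id == "n2"], "ALS")
  expect_identical(pure$type[pure$node_id == "n3"], "BLS")
  # exactly r ALS in all cases
  for (r in 1:3) {
    out <- allocate_als_posthoc(c("n2", "n3", "n4"), current, r, tt)
    expect_equal(sum(out$type == "ALS"), r)
  }
  expect_error(allocate_als_posthoc(c("n1"), current, r = 2, tt),
               class = "emsloc_validation_error")
})
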