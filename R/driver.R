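#' @noRd
multiset_overlap <- function(a, b, p) {
  ta <- table(a); tb <- table(b)
  common <- sum(pmin(ta[names(ta)], ifelse(is.na(tb[names(ta)]), 0,
                                           tb[names(ta)])))
  common / max(1, p)
}

#' @noRd
typed_stations_from_solution <- function(solution, problem, region, tt,
                                         r) {
  nodes <- solution$station_nodes
  if (identical(solution$model, "hierarchical")) {
    als_left <- setNames(as.integer(solution$u), problem$site_ids)
    type <- vapply(seq_along(nodes), function(k) {
      nd <- nodes[k]
      if (!is.na(als_left[nd]) && als_left[nd] > 0) {
        als_left[nd] <<- als_left[nd] - 1L
        "ALS"
      } else "BLS"
    }, character(1))
    data.frame(node_id = nodes, type = type)
  } else {
    allocate_als_posthoc(nodes, region$stations, r, tt)
  }
}

#' Recursive optimize-simulate loop with busy-fraction feedback
#'
#' Implements the five-step planning procedure: (1) fix the stations that
#' cannot move, (2) estimate ambulance busy fractions by simulating the
#' incumbent layout, (3) optimize station locations with those busy
#' fractions, (4) assign ambulance types to the new layout, (5) stop if
#' the station distribution did not change, otherwise re-simulate and
#' repeat. Convergence is measured by the multiset overlap of successive
#' station layouts.
#'
#' @param region an `ems_region`.
#' @param model `"mexclp_pmp"` (lexicographic bi-criteria), `"pmp"`
#'   (weighted p-median) or `"hierarchical"` (pq-median).
#' @param opt list of optimizer settings: `T_max` (default 7),
#'   `capacity_per_ambulance` (3000), `r` (default: current ALS count),
#'   `solver` (`"exact"` or `"kernel"` for the p-median stage; default
#'   exact below `exact_threshold = 250000` of `|I| * |J|`).
#' @param sim an [sim_config()] used for the busy-fraction simulations.
#' @param max_iters iteration cap (default 10).
#' @param seed master seed; all nested seeds are derived from it.
#' @param q_fixed optional fixed busy-fraction vector (or single value)
#'   over demand points; skips all simulation (useful for fixed-point
#'   tests).
#' @param overlap_threshold overlap at which two successive layouts count
#'   as identical (default 1.0).
#' @return List: `solution` (final `ems_solution`), `stations` (typed
#'   layout), `trace` (`data.frame` per iteration), `converged`,
#'   `iterations`, `q` (final busy fractions).
#' @export
iterate_optimize_simulate <- function(region,
                                      model = c("mexclp_pmp", "pmp",
                                                "hierarchical"),
                                      opt = list(), sim = sim_config(),
                                      max_iters = 10, seed = 1,
                                      q_fixed = NULL,
                                      overlap_threshold = 1.0) {
  model <- match.arg(model)
  check_number(max_iters, "max_iters", lower = 1, integer = TRUE)
  T_max <- opt$T_max %||% 7
  cap <- opt$capacity_per_ambulance %||% 3000
  r <- opt$r %||% sum(region$municipalities$current_als)
  exact_threshold <- opt$exact_threshold %||% 250000
  nodes <- region$municipalities$node_id
  tt <- travel_time_matrix(region$network, origins = nodes,
                           destinations = nodes)

  get_q <- function(stations, iter) {
    if (!is.null(q_fixed)) {
      q <- if (length(q_fixed) == 1) rep(q_fixed, length(nodes)) else q_fixed
      return(setNames(q, nodes))
    }
    res <- run_simulation(region, stations, sim,
                          seed = derive_seed(seed, 10L + iter))
    estimate_busy_fractions(res, nodes, tt)
  }

  solve_model <- function(problem) {
    use_kernel <- identical(opt$solver, "kernel") ||
      (is.null(opt$solver) &&
         length(problem$site_ids) * length(problem$demand_ids) >
           exact_threshold)
    if (model == "mexclp_pmp") {
      if (use_kernel) {
        s1 <- solve_mexclp(problem)
        sol <- kernel_search(problem, coverage_floor = s1$f_star)
        sol$model <- "mexclp_pmp"; sol$meta$f_star <- s1$f_star
        sol
      } else lexicographic_solve(problem)
    } else if (model == "pmp") {
      if (use_kernel) kernel_search(problem)
      else solve_weighted_pmedian(problem)
    } else solve_hierarchical(problem)
  }

  stations <- region$stations[, c("node_id", "type")]
  q <- get_q(stations, 0L)
  prev_nodes <- sort(stations$node_id)
  trace <- list()
  converged <- FALSE
  sol <- NULL
  for (it in seq_len(max_iters)) {
    problem <- build_location_problem(region, q = unname(q), T_max = T_max,
                                      capacity_per_ambulance = cap, r = r)
    sol <- solve_model(problem)
    stations <- typed_stations_from_solution(sol, problem, region, tt, r)
    cur_nodes <- sort(sol$station_nodes)
    ov <- multiset_overlap(cur_nodes, prev_nodes, problem$p)
    trace[[it]] <- data.frame(
      iteration = it, q_mean = mean(q), q_min = min(q), q_max = max(q),
      stations = paste(cur_nodes, collapse = ","),
      f = sol$f, g = sol$g, g_als = sol$g_als %||% NA_real_,
      overlap = ov)
    # convergence is judged between successive optimizer outputs; the
    # iteration-1 overlap against the incumbent layout is informative only
    if (it >= 2 && ov >= overlap_threshold) { converged <- TRUE; break }
    prev_nodes <- cur_nodes
    q <- get_q(stations, it)
  }
  trace <- do.call(rbind, trace)
  list(solution = sol, stations = stations, trace = trace,
       converged = converged, iterations = nrow(trace), q = q)
}

#' Compare the current layout with the optimized layouts
#'
#' Runs [iterate_optimize_simulate()] for each requested model and
#' evaluates every resulting layout — plus the incumbent — with
#' [run_experiment()] under the same master seed, i.e. with common random
#' numbers, so indicator differences reflect the layouts only.
#'
#' @param region an `ems_region`.
#' @param models character vector of models to compare.
#' @param opt,sim,max_iters,seed passed to the iteration loop / experiments.
#' @return List: `table` (`data.frame`, one row per layout with the seven
#'   indicators), `reports` (full `ems_report`s), `layouts` (typed station
#'   tables).
#' @export
compare_models <- function(region,
                           models = c("mexclp_pmp", "pmp", "hierarchical"),
                           opt = list(), sim = sim_config(),
                           max_iters = 10, seed = 1) {
  layouts <- list(current = region$stations[, c("node_id", "type")])
  for (m in models) {
    it <- iterate_optimize_simulate(region, model = m, opt = opt, sim = sim,
                                    max_iters = max_iters, seed = seed)
    layouts[[m]] <- it$stations
  }
  reports <- lapply(layouts, function(st)
    run_experiment(region, st, sim, seed = derive_seed(seed, 999L)))
  rows <- lapply(names(layouts), function(nm) {
    rp <- reports[[nm]]
    v <- setNames(rp$mean, rp$indicator)
    cbind(data.frame(layout = nm), as.data.frame(as.list(v)))
  })
  list(table = do.call(rbind, rows), reports = reports, layouts = layouts)
}
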