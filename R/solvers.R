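# Exact solvers for the three location models.
#
# All three models have the property that once the set of opened sites is
# fixed, the remaining variables are determined in closed form: coverage
# variables y_jk follow from the station counts in each neighbourhood
# (their objective coefficients are strictly decreasing in k), and the
# assignment variables z_ij / v_ij go to the nearest assignable site.
# The solvers therefore run a depth-first branch-and-bound over site
# subsets with tight combinatorial bounds; this is exact and needs no
# external MILP engine. Ties are broken toward the lexicographically
# smallest site set (include-branch first, strict improvement only).

#' Expected FHQ coverage of a station layout
#'
#' Closed-form value of the MEXCLP objective given the open-site vector:
#' \deqn{f = \sum_j b^{FHQ}_j (1 - q_j^{m_j})}
#' where `m_j` counts stations (new plus fixed) in the neighbourhood of
#' `j`. Equals the optimum over the coverage variables `y_jk` of the MILP
#' formulation with `x` fixed.
#'
#' @param x 0/1 vector over sites: new stations.
#' @param problem an [location_problem()].
#' @return Expected annual covered FHQ demand.
#' @export
expected_coverage <- function(x, problem) {
  total <- x + problem$st
  m <- vapply(problem$N, function(Nj) sum(total[Nj]), numeric(1))
  sum(problem$b_fhq * (1 - problem$q^m))
}

#' @noRd
assignable_sites <- function(problem, open_idx) {
  sort(unique(c(open_idx, which(problem$I1))))
}

#' Nearest-site assignment and its weighted travel time
#' @noRd
nearest_assignment <- function(problem, open_idx) {
  A <- assignable_sites(problem, open_idx)
  if (!length(A))
    ems_stop("no assignable site (no open station and empty I1)",
             "emsloc_infeasible")
  sub <- problem$t[A, , drop = FALSE]
  pick <- apply(sub, 2, which.min)   # first minimum = lowest site index
  assign_idx <- A[pick]
  tmin <- sub[cbind(pick, seq_len(ncol(sub)))]
  if (any(!is.finite(tmin)))
    ems_stop("some demand point unreachable from all open sites",
             "emsloc_infeasible")
  list(assignment = assign_idx, g = sum(problem$b * tmin))
}

#' Total demand-weighted travel time of an assignment
#'
#' `g = sum_j t[i_j, j] * b_j`. The average response-time proxy is
#' `g / sum(b)`.
#'
#' @param assignment integer vector over demand points: index of the
#'   serving site.
#' @param problem an [location_problem()].
#' @return Weighted travel time (minutes x patients / year).
#' @export
total_weighted_time <- function(assignment, problem) {
  nJ <- length(problem$b)
  if (length(assignment) != nJ || anyNA(assignment))
    ems_stop("assignment must cover every demand point",
             "emsloc_validation_error")
  sum(problem$t[cbind(assignment, seq_len(nJ))] * problem$b)
}

#' Invert neighbourhood lists: for each site, which demand points it covers
#' @noRd
covered_by_site <- function(problem) {
  nI <- length(problem$site_ids)
  M <- vector("list", nI)
  for (j in seq_along(problem$N)) for (i in problem$N[[j]])
    M[[i]] <- c(M[[i]], j)
  M
}

#' Solve the maximum expected covering model (MEXCLP)
#'
#' Chooses where to put the `p - sum(st)` relocatable stations to maximize
#' the expected coverage of high-priority patients, discounting each
#' additional station in a neighbourhood by the busy probability:
#' marginal gain of the k-th station for demand point j is
#' `b_fhq_j (1 - q_j) q_j^(k-1)`. Exact via branch-and-bound with a
#' submodular bound (sum of the largest remaining marginal gains).
#'
#' @param problem an [location_problem()].
#' @return List with `x` (0/1 over sites), `open_sites` (site ids),
#'   `f_star` (optimal expected coverage).
#' @export
solve_mexclp <- function(problem) {
  p_new <- problem$p - sum(problem$st)
  cand <- which(problem$open_allowed)
  if (p_new < 0)
    ems_stop("infeasible: p < number of fixed stations", "emsloc_infeasible")
  if (p_new > length(cand))
    ems_stop("infeasible: fewer open-allowed sites than stations to place",
             "emsloc_infeasible")
  nJ <- length(problem$b)
  Mlist <- covered_by_site(problem)
  base_m <- vapply(problem$N, function(Nj) sum(problem$st[Nj]), numeric(1))
  q <- problem$q; bf <- problem$b_fhq
  env <- new.env()
  env$best_f <- -Inf; env$best_S <- integer(0)
  f0 <- sum(bf * (1 - q^base_m))

  gain_of <- function(i, m) {
    js <- Mlist[[i]]
    if (!length(js)) return(0)
    sum(bf[js] * q[js]^m[js] * (1 - q[js]))
  }
  dfs <- function(k, S, m, f) {
    if (length(S) == p_new) {
      if (f > env$best_f + 1e-9) { env$best_f <- f; env$best_S <- S }
      return(invisible())
    }
    rem <- cand[k:length(cand)]
    need <- p_new - length(S)
    if (length(rem) < need) return(invisible())
    gains <- vapply(rem, gain_of, numeric(1), m = m)
    ub <- f + sum(sort(gains, decreasing = TRUE)[seq_len(need)])
    if (ub <= env$best_f + 1e-9) return(invisible())
    i <- cand[k]
    m2 <- m; m2[Mlist[[i]]] <- m2[Mlist[[i]]] + 1
    dfs(k + 1, c(S, i), m2, f + gains[1])
    dfs(k + 1, S, m, f)
    invisible()
  }
  if (p_new == 0) { env$best_f <- f0; env$best_S <- integer(0) }
  else dfs(1, integer(0), base_m, f0)
  x <- integer(length(problem$site_ids))
  x[env$best_S] <- 1L
  list(x = x, open_sites = problem$site_ids[sort(env$best_S)],
       f_star = env$best_f)
}

#' Internal branch-and-bound for median-type subset selection
#'
#' Minimizes sum_j b_j * min over opened sites of tmat[i, j], opening
#' exactly n_choose sites from `cand`; sites in `always` are assignable
#' regardless. Optional coverage floor (MEXCLP objective >= floor).
#' @noRd
bb_median <- function(tmat, b, cand, n_choose, always = integer(0),
                      floor_value = NULL, cov = NULL,
                      incumbent = NULL) {
  nJ <- length(b)
  ncand <- length(cand)
  if (n_choose > ncand)
    ems_stop("infeasible: not enough candidate sites", "emsloc_infeasible")
  # suffix minima over candidate rows (remaining candidates are a suffix)
  suffmin <- matrix(Inf, ncand + 1, nJ)
  for (k in rev(seq_len(ncand)))
    suffmin[k, ] <- pmin(suffmin[k + 1, ], tmat[cand[k], ])
  if (!is.null(cov)) {
    suffcov <- matrix(0, ncand + 1, nJ)
    for (k in rev(seq_len(ncand))) {
      inc <- numeric(nJ); inc[cov$Mlist_byj[[cand[k]]]] <- 1
      suffcov[k, ] <- suffcov[k + 1, ] + inc
    }
  }
  dmin0 <- if (length(always)) {
    do.call(pmin, c(lapply(always, function(i) tmat[i, ]), list(Inf)))
  } else rep(Inf, nJ)
  env <- new.env()
  env$best_g <- if (is.null(incumbent)) Inf else incumbent$g
  env$best_S <- if (is.null(incumbent)) NULL else incumbent$S
  cov_f <- function(m) sum(cov$b_fhq * (1 - cov$q^m))
  dfs <- function(k, S, m, dmin) {
    need <- n_choose - length(S)
    if (need == 0) {
      if (!is.null(floor_value) && cov_f(m) < floor_value) return(invisible())
      if (any(!is.finite(dmin))) return(invisible())
      g <- sum(b * dmin)
      if (g < env$best_g - 1e-9) { env$best_g <- g; env$best_S <- S }
      return(invisible())
    }
    if (ncand - k + 1 < need) return(invisible())
    if (!is.null(floor_value) && cov_f(m + suffcov[k, ]) < floor_value - 1e-9)
      return(invisible())
    glb <- sum(b * pmin(dmin, suffmin[k, ]))
    if (glb >= env$best_g - 1e-9) return(invisible())
    i <- cand[k]
    m2 <- m
    if (!is.null(cov)) {
      js <- cov$Mlist_byj[[i]]
      m2[js] <- m2[js] + 1
    }
    dfs(k + 1, c(S, i), m2, pmin(dmin, tmat[i, ]))
    dfs(k + 1, S, m, dmin)
    invisible()
  }
  m0 <- if (is.null(cov)) numeric(nJ) else cov$base_m
  dfs(1, integer(0), m0, dmin0)
  if (is.null(env$best_S) && env$best_g == Inf)
    ems_stop(if (is.null(floor_value))
      "weighted p-median infeasible (unreachable demand?)"
      else "coverage floor unattainable with any feasible layout",
      "emsloc_infeasible")
  list(S = sort(env$best_S %||% integer(0)), g = env$best_g)
}

#' @noRd
coverage_context <- function(problem) {
  list(b_fhq = problem$b_fhq, q = problem$q,
       base_m = vapply(problem$N, function(Nj) sum(problem$st[Nj]),
                       numeric(1)),
       Mlist_byj = covered_by_site(problem))
}

#' @noRd
make_solution <- function(problem, open_idx, model, floor_value = NULL,
                          meta = list()) {
  x <- integer(length(problem$site_ids)); x[open_idx] <- 1L
  asg <- nearest_assignment(problem, open_idx)
  structure(list(
    model = model,
    x = x,
    open_sites = problem$site_ids[sort(open_idx)],
    station_nodes = rep(problem$site_ids,
                        times = x + problem$st),
    assignment = asg$assignment,
    f = expected_coverage(x, problem),
    g = asg$g,
    coverage_floor = floor_value,
    u = NULL, v_assignment = NULL, g_als = NULL,
    meta = meta),
    class = "ems_solution")
}

#' Solve the weighted p-median model
#'
#' Minimizes total demand-weighted travel time `g = sum t_ij b_j z_ij`,
#' assigning every demand point to its nearest open or spare-capacity
#' (`I1`) station, with exactly `p` stations overall. An optional coverage
#' floor enforces that the expected FHQ coverage does not fall below a
#' MEXCLP optimum (lexicographic second stage); the floor is applied with
#' a `1 - 1e-6` relative tolerance to absorb floating-point slack.
#'
#' @param problem an [location_problem()].
#' @param coverage_floor expected-coverage lower bound, or `NULL`.
#' @return An `ems_solution` with fields `x`, `open_sites`, `assignment`,
#'   `f`, `g`.
#' @export
solve_weighted_pmedian <- function(problem, coverage_floor = NULL) {
  p_new <- problem$p - sum(problem$st)
  cand <- which(problem$open_allowed)
  if (p_new < 0)
    ems_stop("infeasible: p < number of fixed stations", "emsloc_infeasible")
  floor_eff <- if (is.null(coverage_floor)) NULL else
    coverage_floor * (1 - 1e-6)
  cov <- if (is.null(coverage_floor)) NULL else coverage_context(problem)
  res <- bb_median(problem$t, problem$b, cand, p_new,
                   always = which(problem$I1),
                   floor_value = floor_eff, cov = cov)
  make_solution(problem, res$S, model = "pmp", floor_value = coverage_floor,
                meta = list(method = "exact"))
}

#' Lexicographic bi-criteria solve (MEXCLP then p-median)
#'
#' First maximizes expected FHQ coverage (MEXCLP); then minimizes total
#' weighted travel time subject to the coverage staying at the optimum
#' `f*` (within a `1e-6` relative tolerance).
#'
#' @param problem an [location_problem()].
#' @return An `ems_solution`; `meta$f_star` holds the first-stage optimum.
#' @export
lexicographic_solve <- function(problem) {
  stage1 <- solve_mexclp(problem)
  sol <- solve_weighted_pmedian(problem, coverage_floor = stage1$f_star)
  sol$model <- "mexclp_pmp"
  sol$meta$f_star <- stage1$f_star
  sol
}

#' Solve the hierarchical pq-median model
#'
#' Lower level: the plain weighted p-median (no coverage floor) locates
#' `p` stations. Upper level: chooses `r` of the opened or fixed sites to
#' house ALS units, minimizing the demand-weighted travel time of ALS
#' ambulances `g_ALS = sum t_ij b_j v_ij` with every demand point assigned
#' to its nearest ALS site. ALS sites are restricted to sites with a
#' station (`u_i <= st_i + x_i`), so `g_ALS >= g`.
#'
#' @param problem an [location_problem()] with `r >= 1`.
#' @return An `ems_solution` with additional fields `u` (0/1 ALS
#'   indicator), `als_sites`, `v_assignment` and `g_als`.
#' @export
solve_hierarchical <- function(problem) {
  if (problem$r < 1)
    ems_stop("hierarchical model needs r >= 1", "emsloc_validation_error")
  lower <- solve_weighted_pmedian(problem, coverage_floor = NULL)
  open_idx <- which(lower$x == 1L)
  eligible <- sort(unique(c(open_idx, which(problem$st >= 1))))
  if (problem$r > length(eligible))
    ems_stop("r exceeds the number of opened + fixed sites",
             "emsloc_infeasible")
  up <- bb_median(problem$t, problem$b, eligible, problem$r)
  u <- integer(length(problem$site_ids)); u[up$S] <- 1L
  subA <- problem$t[up$S, , drop = FALSE]
  pick <- apply(subA, 2, which.min)
  lower$model <- "hierarchical"
  lower$u <- u
  lower$als_sites <- problem$site_ids[up$S]
  lower$v_assignment <- up$S[pick]
  lower$g_als <- up$g
  lower
}

#' A-posteriori ALS allocation to an untyped station layout
#'
#' Types the stations of a solved layout: (1) fixed stations and stations
#' at sites that already host one keep the current type of that site's
#' station(s); (2) ALS units whose current site lost its station are
#' matched greedily, in increasing travel time, to the nearest still
#' untyped relocated stations; (3) every other station becomes BLS.
#' Finally the ALS count is adjusted to exactly `r` (demoting the worst
#' matches or promoting BLS stations nearest to a former ALS site).
#'
#' @param station_nodes character vector of node ids hosting the new
#'   layout's stations (repeats allowed for multi-station towns).
#' @param current_stations `data.frame` with `node_id`, `type` for the
#'   incumbent layout.
#' @param r required ALS count.
#' @param tt symmetric travel-time matrix over nodes (dimnames = node ids).
#' @return `data.frame` with `node_id`, `type`, exactly `r` rows `"ALS"`.
#' @export
allocate_als_posthoc <- function(station_nodes, current_stations, r, tt) {
  n <- length(station_nodes)
  if (r > n)
    ems_stop("r exceeds the number of stations", "emsloc_validation_error")
  type <- rep(NA_character_, n)
  cur <- current_stations
  cur$used <- FALSE
  # rule 1: stations at a node that currently hosts one keep that type
  for (s in seq_len(n)) {
    hit <- which(!cur$used & cur$node_id == station_nodes[s])
    if (length(hit)) {
      hit <- hit[order(cur$type[hit] != "ALS")][1]  # prefer matching ALS slot
      type[s] <- cur$type[hit]
      cur$used[hit] <- TRUE
    }
  }
  # rule 2: displaced ALS units go to the nearest untyped station
  lost_als <- which(!cur$used & cur$type == "ALS")
  repeat {
    open <- which(is.na(type))
    if (!length(lost_als) || !length(open)) break
    d <- outer(lost_als, open, function(a, bb)
      tt[cbind(cur$node_id[a], station_nodes[bb])])
    ij <- arrayInd(which.min(d), dim(d))
    type[open[ij[2]]] <- "ALS"
    lost_als <- lost_als[-ij[1]]
  }
  type[is.na(type)] <- "BLS"
  # enforce exactly r ALS
  als_idx <- which(type == "ALS")
  if (length(als_idx) > r) {
    # demote ALS farthest from any current ALS node
    cur_als_nodes <- current_stations$node_id[current_stations$type == "ALS"]
    dist_to_als <- vapply(als_idx, function(s)
      min(tt[cur_als_nodes, station_nodes[s]]), numeric(1))
    demote <- als_idx[order(-dist_to_als, -als_idx)][
      seq_len(length(als_idx) - r)]
    type[demote] <- "BLS"
  } else if (length(als_idx) < r) {
    cur_als_nodes <- current_stations$node_id[current_stations$type == "ALS"]
    bls_idx <- which(type == "BLS")
    score <- if (length(cur_als_nodes)) vapply(bls_idx, function(s)
      min(tt[cur_als_nodes, station_nodes[s]]), numeric(1)) else bls_idx
    promote <- bls_idx[order(score, bls_idx)][seq_len(r - length(als_idx))]
    type[promote] <- "ALS"
  }
  data.frame(node_id = station_nodes, type = type)
}
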