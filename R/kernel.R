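# Kernel search for the weighted p-median (with optional coverage floor).
#
# Classic kernel search builds the kernel from the LP relaxation and
# sorts the remaining variables by reduced cost. No LP engine ships with
# this package, so the kernel is seeded combinatorially instead: a greedy
# p-median construction provides the incumbent and promising sites, and
# the remaining sites are ranked by a demand-weighted attractiveness
# score (the single-site improvement each would bring over the greedy
# layout). Restricted subproblems are solved exactly by the same
# branch-and-bound as the exact path, so on instances where one bucket
# absorbs all variables the method coincides with the exact solver.

#' @noRd
greedy_pmedian_sites <- function(problem) {
  p_new <- problem$p - sum(problem$st)
  cand <- which(problem$open_allowed)
  always <- which(problem$I1)
  dmin <- if (length(always))
    do.call(pmin, c(lapply(always, function(i) problem$t[i, ]), list(Inf)))
  else rep(Inf, length(problem$b))
  S <- integer(0)
  for (step in seq_len(p_new)) {
    rem <- setdiff(cand, S)
    red <- vapply(rem, function(i) {
      d2 <- pmin(dmin, problem$t[i, ])
      sum(problem$b * ifelse(is.finite(d2), dmin - d2,
                             0))  # Inf-dmin handled below
    }, numeric(1))
    # when dmin is Inf anywhere, prefer sites that make points reachable
    unreach <- !is.finite(dmin)
    if (any(unreach)) {
      red <- red + vapply(rem, function(i)
        sum(problem$b[unreach] * is.finite(problem$t[i, unreach]) * 1e6),
        numeric(1))
    }
    best <- rem[which.max(red)]
    S <- c(S, best)
    dmin <- pmin(dmin, problem$t[best, ])
  }
  sort(S)
}

#' Kernel-search matheuristic for the weighted p-median
#'
#' Heuristic for instances too large for full enumeration. Solves a
#' sequence of exact restricted subproblems: first over the kernel of
#' promising sites, then over the kernel plus one bucket of the remaining
#' sites at a time; sites entering an improved incumbent join the kernel.
#' Stops after a full pass without improvement or `max_passes` passes.
#' The returned objective never exceeds the initial kernel-only solve,
#' and with `kernel_size = Inf` the method is the exact solver.
#'
#' @param problem an [location_problem()].
#' @param coverage_floor optional expected-coverage floor (lexicographic
#'   second stage); applied with the same `1 - 1e-6` tolerance as
#'   [solve_weighted_pmedian()].
#' @param params list: `kernel_size` (default `max(p_new + 2, 2 p_new)`),
#'   `bucket_size` (default `2 * kernel_size`), `max_passes` (default 3).
#' @return An `ems_solution`; `meta` records passes and improvements.
#' @export
kernel_search <- function(problem, coverage_floor = NULL, params = list()) {
  p_new <- problem$p - sum(problem$st)
  cand <- which(problem$open_allowed)
  if (p_new > length(cand))
    ems_stop("infeasible: fewer open-allowed sites than stations to place",
             "emsloc_infeasible")
  floor_eff <- if (is.null(coverage_floor)) NULL else
    coverage_floor * (1 - 1e-6)
  cov <- if (is.null(coverage_floor)) NULL else coverage_context(problem)
  always <- which(problem$I1)

  greedy <- if (p_new > 0) greedy_pmedian_sites(problem) else integer(0)
  dmin_g <- if (length(c(greedy, always)))
    do.call(pmin, c(lapply(c(greedy, always), function(i) problem$t[i, ]),
                    list(Inf)))
  else rep(Inf, length(problem$b))
  score <- vapply(cand, function(i)
    sum(problem$b * pmax(0, dmin_g - pmin(dmin_g, problem$t[i, ]))),
    numeric(1))
  ksize <- params$kernel_size %||% max(p_new + 2, 2 * p_new)
  ksize <- min(length(cand), max(ksize, p_new))
  ranked <- cand[order(-score, cand)]
  kernel <- sort(unique(c(greedy, head(setdiff(ranked, greedy),
                                       max(0, ksize - length(greedy))))))
  outside <- setdiff(ranked, kernel)
  bsize <- params$bucket_size %||% (2 * length(kernel))
  bsize <- max(1, bsize)
  buckets <- if (length(outside))
    split(outside, ceiling(seq_along(outside) / bsize)) else list()
  max_passes <- params$max_passes %||% 3

  solve_restricted <- function(sites, incumbent) {
    tryCatch(
      bb_median(problem$t, problem$b, sort(sites), p_new, always = always,
                floor_value = floor_eff, cov = cov, incumbent = incumbent),
      emsloc_infeasible = function(e) NULL)
  }

  inc <- solve_restricted(kernel, NULL)
  bi <- 1L
  while (is.null(inc) && bi <= length(buckets)) {
    # kernel alone cannot meet the floor: grow it bucket by bucket
    kernel <- sort(c(kernel, buckets[[bi]]))
    buckets[[bi]] <- integer(0)
    bi <- bi + 1L
    inc <- solve_restricted(kernel, NULL)
  }
  if (is.null(inc))
    ems_stop("kernel search found no feasible subproblem",
             "emsloc_infeasible")
  g_initial <- inc$g
  improvements <- 0L; passes <- 0L
  repeat {
    passes <- passes + 1L
    improved_this_pass <- FALSE
    for (kbi in seq_along(buckets)) {
      bucket <- buckets[[kbi]]
      if (!length(bucket)) next
      res <- solve_restricted(c(kernel, bucket), inc)
      if (!is.null(res) && res$g < inc$g - 1e-9) {
        newly <- intersect(res$S, bucket)
        kernel <- sort(unique(c(kernel, newly)))
        buckets[[kbi]] <- setdiff(bucket, newly)
        inc <- res
        improvements <- improvements + 1L
        improved_this_pass <- TRUE
      }
    }
    if (!improved_this_pass || passes >= max_passes) break
  }
  sol <- make_solution(problem, inc$S, model = "pmp",
                       floor_value = coverage_floor,
                       meta = list(method = "kernel_search",
                                   passes = passes,
                                   improvements = improvements,
                                   g_initial_kernel = g_initial))
  sol
}
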