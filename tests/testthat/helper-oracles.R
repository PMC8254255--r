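# Independent oracles: brute-force enumeration and plain graph searches,
# deliberately sharing no code with the package's solvers.

# breadth-first search reachability (no igraph)
bfs_reaches_all <- function(edge_from, edge_to, n) {
  adj <- vector("list", n)
  for (k in seq_along(edge_from)) {
    adj[[edge_from[k]]] <- c(adj[[edge_from[k]]], edge_to[k])
    adj[[edge_to[k]]] <- c(adj[[edge_to[k]]], edge_from[k])
  }
  seen <- rep(FALSE, n)
  frontier <- 1L
  seen[1] <- TRUE
  while (length(frontier)) {
    nxt <- unique(unlist(adj[frontier]))
    nxt <- nxt[!seen[nxt]]
    seen[nxt] <- TRUE
    frontier <- nxt
  }
  all(seen)
}

# exhaustive simple-path shortest times on a small weighted graph
all_pairs_by_path_enumeration <- function(edge_from, edge_to, minutes, n) {
  adj <- vector("list", n)
  for (k in seq_along(edge_from)) {
    adj[[edge_from[k]]] <- rbind(adj[[edge_from[k]]], c(edge_to[k], minutes[k]))
    adj[[edge_to[k]]] <- rbind(adj[[edge_to[k]]], c(edge_from[k], minutes[k]))
  }
  best <- matrix(Inf, n, n)
  diag(best) <- 0
  dfs <- function(v, target, visited, acc) {
    if (v == target) {
      if (acc < best[start, target]) best[start, target] <<- acc
      return(invisible())
    }
    nb <- adj[[v]]
    if (is.null(nb)) return(invisible())
    for (k in seq_len(nrow(nb))) {
      w <- nb[k, 1]
      if (!visited[w]) dfs(w, target, `[<-`(visited, w, TRUE), acc + nb[k, 2])
    }
  }
  for (start in seq_len(n)) for (target in seq_len(n)) {
    if (start != target) dfs(start, target, `[<-`(rep(FALSE, n), start, TRUE), 0)
  }
  best
}

# closed-form expected coverage for an explicit station-count vector
oracle_coverage <- function(problem, open_idx) {
  total <- problem$st
  total[open_idx] <- total[open_idx] + 1
  m <- vapply(problem$N, function(Nj) sum(total[Nj]), numeric(1))
  sum(problem$b_fhq * (1 - problem$q^m))
}

oracle_g <- function(problem, open_idx) {
  A <- sort(unique(c(open_idx, which(problem$I1))))
  if (!length(A)) return(Inf)
  tmin <- apply(problem$t[A, , drop = FALSE], 2, min)
  if (any(!is.finite(tmin))) return(Inf)
  sum(problem$b * tmin)
}

enumerate_subsets <- function(cand, k) {
  if (k == 0) return(list(integer(0)))
  if (length(cand) < k) return(list())
  cols <- utils::combn(cand, k)
  lapply(seq_len(ncol(cols)), function(j) cols[, j])
}

bf_mexclp <- function(problem) {
  p_new <- problem$p - sum(problem$st)
  subs <- enumerate_subsets(which(problem$open_allowed), p_new)
  f <- vapply(subs, function(S) oracle_coverage(problem, S), numeric(1))
  list(f_star = max(f), S = subs[[which.max(f)]])
}

bf_pmedian <- function(problem, coverage_floor = NULL) {
  p_new <- problem$p - sum(problem$st)
  subs <- enumerate_subsets(which(problem$open_allowed), p_new)
  floor_eff <- if (is.null(coverage_floor)) -Inf else
    coverage_floor * (1 - 1e-6)
  best <- Inf; best_S <- NULL
  for (S in subs) {
    if (oracle_coverage(problem, S) < floor_eff) next
    g <- oracle_g(problem, S)
    if (g < best - 1e-9) { best <- g; best_S <- S }
  }
  list(g = best, S = best_S)
}

bf_lexicographic <- function(problem) {
  f_star <- bf_mexclp(problem)$f_star
  res <- bf_pmedian(problem, coverage_floor = f_star)
  list(f_star = f_star, g = res$g, S = res$S)
}

bf_hierarchical <- function(problem) {
  lower <- bf_pmedian(problem)
  # lexicographically smallest among optimal lower-level subsets
  p_new <- problem$p - sum(problem$st)
  subs <- enumerate_subsets(which(problem$open_allowed), p_new)
  opt <- Filter(function(S) abs(oracle_g(problem, S) - lower$g) <= 1e-6, subs)
  keys <- vapply(opt, function(S)
    paste(sprintf("%04d", sort(S)), collapse = ","), character(1))
  S <- opt[[order(keys)[1]]]
  eligible <- sort(unique(c(S, which(problem$st >= 1))))
  best <- Inf
  for (U in enumerate_subsets(eligible, problem$r)) {
    gA <- sum(problem$b * apply(problem$t[U, , drop = FALSE], 2, min))
    if (gA < best - 1e-9) best <- gA
  }
  list(g = lower$g, g_als = best)
}

# random small instances for oracle-equivalence suites
random_problem <- function(seed, nI = NULL, p = NULL, with_fixed = TRUE) {
  set.seed(seed)
  nI <- nI %||% sample(4:10, 1)
  nJ <- nI
  p <- p %||% sample(2:min(4, nI - 1), 1)
  t <- matrix(round(runif(nI * nJ, 1, 20), 2), nI, nJ)
  t[cbind(seq_len(nI), seq_len(nJ))] <- 0
  b <- round(runif(nJ, 1, 500))
  b_fhq <- round(b * runif(nJ, 0.1, 0.4), 1)
  q <- runif(nJ, 0.05, 0.6)
  st <- rep(0L, nI); I1 <- rep(FALSE, nI)
  if (with_fixed && runif(1) < 0.4) {
    i_fix <- sample.int(nI, 1)
    if (runif(1) < 0.5) st[i_fix] <- 1L
    else { st[i_fix] <- 1L; I1[i_fix] <- TRUE }
  }
  p <- max(p, sum(st) + 1L)
  # r capped by the relocatable count so the ALS level is always feasible
  r <- sample(seq_len(max(1L, p - sum(st))), 1)
  location_problem(t, b, b_fhq, p = p, r = r, st = st, I1 = I1, q = q,
                   T_max = 7)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
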