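#' Performance indicators of one replication
#'
#' The standard indicator block: mean response time, percentage of calls
#' answered within 15 minutes, number of municipalities whose average
#' response exceeds 15 minutes, mean FHQ response time, percentage of FHQ
#' calls within 8 minutes, mean ambulance workload (%) and its coefficient
#' of variation (population standard deviation over mean).
#'
#' @param call_log per-call log from [run_simulation()].
#' @param workloads per-ambulance workloads from [run_simulation()].
#' @return Named list of the seven indicators; all `NA` (with
#'   `zero_calls = TRUE`) when the log holds no served call.
#' @export
compute_indicators <- function(call_log, workloads) {
  served <- call_log[!is.na(call_log$response_time), , drop = FALSE]
  w <- workloads$workload
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  if (nrow(served) == 0) {
    return(list(mean_response = NA_real_, pct_within_15 = NA_real_,
                munis_over_15 = NA_integer_, mean_response_fhq = NA_real_,
                pct_fhq_within_8 = NA_real_,
                mean_workload_pct = if (length(w)) 100 * mean(w) else NA_real_,
                cv_workload = NA_real_, zero_calls = TRUE))
  }
  fhq <- served[served$priority == "FHQ", , drop = FALSE]
  muni_avg <- tapply(served$response_time, served$municipality_id, mean)
  mw <- mean(w)
  list(
    mean_response = mean(served$response_time),
    pct_within_15 = 100 * mean(served$response_time <= 15),
    munis_over_15 = sum(muni_avg > 15),
    mean_response_fhq = if (nrow(fhq)) mean(fhq$response_time) else NA_real_,
    pct_fhq_within_8 = if (nrow(fhq))
      100 * mean(fhq$response_time <= 8) else NA_real_,
    mean_workload_pct = 100 * mw,
    cv_workload = if (mw > 0) pop_sd(w) / mw else NA_real_,
    zero_calls = FALSE)
}

#' Replicated simulation experiment
#'
#' Runs `config$replications` independent replications (seeds derived from
#' the master seed) and reports the mean of each indicator across
#' replication means together with a Student-t 95% confidence interval.
#'
#' @param region an `ems_region`.
#' @param stations station layout (`node_id`, `type`).
#' @param config an [sim_config()] with `replications >= 2`.
#' @param seed master seed.
#' @param speed a [speed_model()].
#' @return Object of class `ems_report`: `data.frame` with columns
#'   `indicator`, `mean`, `ci_lo`, `ci_hi`; plus attributes
#'   `replication_indicators` and `replication_results`.
#' @export
run_experiment <- function(region, stations, config = sim_config(),
                           seed = 1, speed = speed_model()) {
  R <- config$replications
  if (R < 2)
    ems_stop("need at least 2 replications for confidence intervals",
             "emsloc_validation_error")
  reps <- lapply(seq_len(R), function(k)
    run_simulation(region, stations, config,
                   seed = derive_seed(seed, 100L + k), speed = speed))
  ind <- lapply(reps, function(r) compute_indicators(r$calls, r$workloads))
  keys <- c("mean_response", "pct_within_15", "munis_over_15",
            "mean_response_fhq", "pct_fhq_within_8", "mean_workload_pct",
            "cv_workload")
  rows <- lapply(keys, function(k) {
    v <- vapply(ind, function(x) as.numeric(x[[k]] %||% NA_real_), numeric(1))
    v <- v[!is.na(v)]
    if (!length(v))
      return(data.frame(indicator = k, mean = NA_real_,
                        ci_lo = NA_real_, ci_hi = NA_real_))
    m <- mean(v)
    half <- if (length(v) > 1 && sd(v) > 0)
      qt(0.975, length(v) - 1) * sd(v) / sqrt(length(v)) else 0
    data.frame(indicator = k, mean = m, ci_lo = m - half, ci_hi = m + half)
  })
  out <- do.call(rbind, rows)
  attr(out, "replication_indicators") <- ind
  attr(out, "replication_results") <- reps
  class(out) <- c("ems_report", class(out))
  out
}

#' Busy-fraction estimates for candidate locations
#'
#' For every candidate location: if it hosts at least one simulated
#' ambulance, its busy probability is the average workload of those
#' ambulances; otherwise it is the average workload of the stations within
#' 30 minutes of travel; with no station within 30 minutes it falls back
#' to the global mean workload. Values are clamped to `[0, 1 - 1e-6]`.
#'
#' @param results one replication result or a list of them (from
#'   [run_simulation()]); workloads are pooled across replications.
#' @param candidate_nodes node ids of the candidate locations.
#' @param tt travel-time matrix over nodes (minutes, dimnames = node ids),
#'   typically lights-and-sirens off-peak.
#' @param radius_min neighbourhood radius in minutes (default 30).
#' @return Named numeric vector of busy fractions over `candidate_nodes`.
#' @export
estimate_busy_fractions <- function(results, candidate_nodes, tt,
                                    radius_min = 30) {
  if (!is.null(results$workloads)) results <- list(results)
  w <- do.call(rbind, lapply(results, `[[`, "workloads"))
  if (nrow(w) == 0)
    ems_stop("no simulated station", "emsloc_validation_error")
  station_mean <- tapply(w$workload, w$station_node, mean)
  station_nodes <- names(station_mean)
  global <- mean(w$workload)
  q <- vapply(candidate_nodes, function(cn) {
    if (cn %in% station_nodes) return(station_mean[[cn]])
    d <- tt[cn, station_nodes]
    near <- station_nodes[d <= radius_min]
    if (length(near)) mean(station_mean[near]) else global
  }, numeric(1))
  pmin(pmax(q, 0), 1 - 1e-6)
}
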