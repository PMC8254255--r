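# Discrete-event, agent-based EMS simulator. One ambulance per station.
# Service pathway per call: pre-trip delay, lights-and-sirens travel to
# the scene, on-scene treatment, Bernoulli transport decision (p depends
# on crew qualification), lights-and-sirens transport to the nearest
# compatible hospital, Erlang drop-off, return home at standard speeds.
# Returning units stay dispatchable and are redirected from their
# interpolated position on the road network.

#' Simulation configuration
#'
#' @param horizon_days length of one replication (default 91 days).
#' @param replications number of replications for experiments (default 10).
#' @param daily_volume mean calls per day; `NULL` derives it from the
#'   region's annual demand (`sum(b) / 365`).
#' @param hourly_multipliers 24 non-negative arrival-rate multipliers, one
#'   per hour of day; the default has peaks of 1.5 between 09:00-11:00 and
#'   1.4 between 17:00-21:00 and is rescaled to `daily_volume`.
#' @param pre_trip_delay_min activation delay before a dispatched idle
#'   unit departs (default 1 minute).
#' @param p_transport_bls probability a patient treated by a paramedic
#'   crew is transported to hospital (default 0.77).
#' @param p_transport_als transport probability with a physician present
#'   (default 0.51).
#' @param fhq_probability probability a call is high-priority (First Hour
#'   Quintet; default 0.2651).
#' @param scene_mean_min named mean on-scene minutes for
#'   `FHQ_ALS`, `FHQ_BLS`, `nonFHQ_ALS`, `nonFHQ_BLS` (lognormal).
#' @param scene_cv coefficient of variation of on-scene times; 0 gives
#'   degenerate (deterministic) times.
#' @param diagnosis_probs named probabilities for diagnosis classes
#'   `general`, `cardio`, `pediatric`.
#' @param secondary_rate_per_day rate of scheduled inter-hospital
#'   transports (default 0).
#' @return Object of class `ems_sim_config`.
#' @export
sim_config <- function(horizon_days = 91,
                       replications = 10,
                       daily_volume = NULL,
                       hourly_multipliers = NULL,
                       pre_trip_delay_min = 1,
                       p_transport_bls = 0.77,
                       p_transport_als = 0.51,
                       fhq_probability = 0.2651,
                       scene_mean_min = c(FHQ_ALS = 20, FHQ_BLS = 18,
                                          nonFHQ_ALS = 16, nonFHQ_BLS = 15),
                       scene_cv = 0.4,
                       diagnosis_probs = c(general = 0.80, cardio = 0.15,
                                           pediatric = 0.05),
                       secondary_rate_per_day = 0) {
  check_number(horizon_days, "horizon_days", lower = 1e-9)
  check_number(replications, "replications", lower = 1, integer = TRUE)
  check_proportion(p_transport_bls, "p_transport_bls")
  check_proportion(p_transport_als, "p_transport_als")
  check_proportion(fhq_probability, "fhq_probability")
  if (is.null(hourly_multipliers)) {
    hourly_multipliers <- rep(1, 24)
    hourly_multipliers[10:11] <- 1.5   # 09:00-11:00
    hourly_multipliers[18:21] <- 1.4   # 17:00-21:00
  }
  if (length(hourly_multipliers) != 24 || any(hourly_multipliers < 0))
    ems_stop("'hourly_multipliers' must be 24 non-negative values",
             "emsloc_validation_error")
  structure(list(horizon_days = horizon_days, replications = replications,
                 daily_volume = daily_volume,
                 hourly_multipliers = hourly_multipliers,
                 pre_trip_delay_min = pre_trip_delay_min,
                 p_transport_bls = p_transport_bls,
                 p_transport_als = p_transport_als,
                 fhq_probability = fhq_probability,
                 scene_mean_min = scene_mean_min, scene_cv = scene_cv,
                 diagnosis_probs = diagnosis_probs,
                 secondary_rate_per_day = secondary_rate_per_day),
            class = "ems_sim_config")
}

#' @noRd
resolve_daily_volume <- function(config, region) {
  config$daily_volume %||% (sum(region_demand(region)$b) / 365)
}

#' Generate a stochastic call stream
#'
#' Arrival times follow a non-homogeneous Poisson process (thinning
#' against the profile maximum) whose piecewise-constant daily rate is the
#' hourly multiplier profile rescaled to `daily_volume`. Each call lands
#' in an ambient-population grid cell with probability proportional to the
#' cell's population weight, at the cell's network node; priority is FHQ
#' with `fhq_probability` and a diagnosis class is drawn independently.
#'
#' @param config an [sim_config()] with non-`NULL` `daily_volume`.
#' @param grid population grid (`cell_id`, `node_id`, `municipality_id`,
#'   `weight`).
#' @param horizon_days days to generate.
#' @param seed integer seed.
#' @return `data.frame`: `time` (minutes), `cell_id`, `node`,
#'   `municipality_id`, `priority`, `diagnosis`.
#' @export
generate_calls <- function(config, grid, horizon_days = config$horizon_days,
                           seed = 1) {
  if (sum(grid$weight) <= 0)
    ems_stop("grid has no population", "emsloc_validation_error")
  if (any(grid$weight < 0))
    ems_stop("grid weights must be non-negative", "emsloc_validation_error")
  vol <- config$daily_volume
  if (is.null(vol))
    ems_stop("daily_volume must be set (or derived via the region)",
             "emsloc_validation_error")
  with_seed(seed, {
    mult <- config$hourly_multipliers
    lam_hour <- if (sum(mult) > 0) mult / sum(mult) * vol else rep(0, 24)
    lam_min <- lam_hour / 60
    lmax <- max(lam_min)
    H <- horizon_days * 1440
    times <- numeric(0)
    if (lmax > 0) {
      t <- 0
      # generate candidate times in blocks for speed
      expected <- lmax * H
      repeat {
        block <- rexp(max(100, ceiling(expected * 0.2)), rate = lmax)
        cand <- t + cumsum(block)
        t <- cand[length(cand)]
        times <- c(times, cand)
        if (t > H) break
      }
      times <- times[times <= H]
      hr <- floor((times %% 1440) / 60) + 1
      keep <- runif(length(times)) < lam_min[hr] / lmax
      times <- times[keep]
    }
    n <- length(times)
    if (n == 0)
      return(data.frame(time = numeric(0), cell_id = character(0),
                        node = character(0), municipality_id = character(0),
                        priority = character(0), diagnosis = character(0)))
    cell <- sample.int(nrow(grid), n, replace = TRUE, prob = grid$weight)
    priority <- ifelse(runif(n) < config$fhq_probability, "FHQ", "non-FHQ")
    dg <- names(config$diagnosis_probs)
    diagnosis <- dg[sample.int(length(dg), n, replace = TRUE,
                               prob = config$diagnosis_probs)]
    data.frame(time = times, cell_id = grid$cell_id[cell],
               node = grid$node_id[cell],
               municipality_id = grid$municipality_id[cell],
               priority = priority, diagnosis = diagnosis)
  })
}

#' Nearest-available dispatch rule
#'
#' The closest available ambulance is always dispatched regardless of
#' type; if the call is high priority (FHQ) and that unit is BLS, the
#' closest available ALS unit is dispatched concurrently.
#'
#' @param priority `"FHQ"` or `"non-FHQ"`.
#' @param types character vector of available unit types (`"ALS"`/`"BLS"`).
#' @param est_minutes estimated travel minutes of each available unit from
#'   its current position to the scene.
#' @return Integer indices (into the availability vectors) of the units to
#'   dispatch; length 0 if none available.
#' @export
dispatch_rule <- function(priority, types, est_minutes) {
  if (!length(types)) return(integer(0))
  first <- which.min(est_minutes)       # first minimum: lowest index tie-break
  chosen <- first
  if (priority == "FHQ" && types[first] == "BLS") {
    als <- which(types == "ALS")
    if (length(als)) {
      best_als <- als[which.min(est_minutes[als])]
      chosen <- c(chosen, best_als)
    }
  }
  chosen
}

#' @noRd
lognormal_pars <- function(mean, cv) {
  if (cv <= 0) return(NULL)
  sdlog <- sqrt(log(1 + cv^2))
  list(meanlog = log(mean) - sdlog^2 / 2, sdlog = sdlog)
}

#' @noRd
draw_scene_time <- function(config, priority, crew) {
  key <- paste0(if (priority == "FHQ") "FHQ" else "nonFHQ", "_", crew)
  m <- config$scene_mean_min[[key]]
  if (is.null(m) || is.na(m)) m <- 15
  if (config$scene_cv <= 0) return(m)
  p <- lognormal_pars(m, config$scene_cv)
  rlnorm(1, p$meanlog, p$sdlog)
}

#' Run one simulation replication
#'
#' Event-driven execution of the full service pathway over the horizon.
#' Deterministic given `seed` (and the call stream). Calls still waiting
#' when the fleet never frees up remain queued and are flagged in the log.
#'
#' @param region an `ems_region`.
#' @param stations `data.frame` with `node_id`, `type` (one ambulance per
#'   row).
#' @param config an [sim_config()].
#' @param seed integer seed for every stochastic element of the run.
#' @param calls optional deterministic call stream ([generate_call_script()]
#'   or a `data.frame` with `time`, `node`, `priority`, optional
#'   `diagnosis`); replaces the stochastic generator.
#' @param speed a [speed_model()].
#' @return List with `calls` (per-call log), `workloads` (per-ambulance
#'   busy fraction), `horizon_min`, `n_queued_end`.
#' @export
run_simulation <- function(region, stations, config = sim_config(),
                           seed = 1, calls = NULL, speed = speed_model()) {
  if (nrow(stations) == 0)
    ems_stop("at least one station required", "emsloc_validation_error")
  g <- region$network
  node_ids <- igraph::V(g)$name
  nidx <- setNames(seq_along(node_ids), node_ids)
  H <- config$horizon_days * 1440

  # travel-time matrices per mode x regime, path tables per mode
  emin <- list(); ttm <- list()
  for (mode in c("lights_sirens", "standard")) {
    emin[[mode]] <- lapply(setNames(SPEED_REGIMES, SPEED_REGIMES),
                           function(rg) network_edge_minutes(g, speed, mode, rg))
    ttm[[mode]] <- lapply(emin[[mode]], function(w)
      igraph::distances(g, weights = w))
  }
  paths <- list()
  for (mode in c("lights_sirens", "standard")) {
    w <- emin[[mode]][["offpeak"]]
    paths[[mode]] <- lapply(seq_along(node_ids), function(v) {
      sp <- igraph::shortest_paths(g, from = v, weights = w, output = "both")
      list(nodes = lapply(sp$vpath, as.integer),
           edges = lapply(sp$epath, as.integer))
    })
  }

  # call stream
  if (is.null(calls)) {
    cfg2 <- config
    cfg2$daily_volume <- resolve_daily_volume(config, region)
    calls <- generate_calls(cfg2, region$grid, config$horizon_days,
                            seed = derive_seed(seed, 1L))
  } else {
    calls <- as.data.frame(calls)
    if (is.null(calls$diagnosis)) calls$diagnosis <- "general"
    if (is.null(calls$municipality_id)) {
      mmap <- setNames(region$municipalities$id, region$municipalities$node_id)
      calls$municipality_id <- unname(mmap[as.character(calls$node)])
    }
    if (is.null(calls$cell_id))
      calls$cell_id <- rep(NA_character_, nrow(calls))
  }
  ncall <- nrow(calls)

  hosp <- region$hospitals
  hosp_nodes <- as.integer(nidx[hosp$node_id])
  hosp_specs <- strsplit(hosp$specializations %||% character(0), ";")

  na <- nrow(stations)
  S <- new.env(parent = emptyenv())
  S$now <- 0
  S$state <- rep("idle_at_base", na)
  S$type <- stations$type
  S$home <- as.integer(nidx[stations$node_id])
  S$node <- S$home
  S$avail <- rep(TRUE, na)
  S$busy_since <- rep(NA_real_, na)
  S$busy <- rep(0, na)
  S$epoch <- rep(0L, na)
  S$path_nodes <- vector("list", na)
  S$path_times <- vector("list", na)
  S$queue <- integer(0)

  calls <- calls[order(calls$time), , drop = FALSE]
  rownames(calls) <- NULL
  ca_node <- as.integer(nidx[as.character(calls$node)])
  if (anyNA(ca_node))
    ems_stop("call stream references unknown nodes", "emsloc_validation_error")
  ca_fhq <- calls$priority == "FHQ"
  ca_first <- rep(NA_real_, ncall)
  ca_scene_end <- rep(NA_real_, ncall)
  ca_done <- rep(FALSE, ncall)
  ca_crew_als <- rep(FALSE, ncall)
  ca_transported <- rep(NA, ncall)
  ca_hospital <- rep(NA_character_, ncall)
  ca_queued <- rep(FALSE, ncall)
  ca_units <- vector("list", ncall)

  # call arrivals are fed lazily from the (sorted) stream so the event
  # heap only ever holds the handful of in-flight unit events
  h <- new_heap(1024L)
  next_call <- 1L

  if (config$secondary_rate_per_day > 0 && nrow(hosp) >= 2) {
    with_seed(derive_seed(seed, 3L), {
      tsec <- 0
      repeat {
        tsec <- tsec + stats::rexp(1, config$secondary_rate_per_day / 1440)
        if (tsec > H) break
        heap_push(h, tsec, "sec")
      }
    })
  }

  regime_now <- function() regime_at(S$now)

  position_next <- function(u) {
    pn <- S$path_nodes[[u]]; pt <- S$path_times[[u]]
    if (is.null(pn)) return(list(node = S$node[u], t_next = 0))
    if (S$now >= pt[length(pt)])
      return(list(node = pn[length(pn)], t_next = 0))
    li <- findInterval(S$now, pt)
    # exactly at an intermediate node: redirect from that node directly
    if (li >= 1L && S$now - pt[li] < 1e-9)
      return(list(node = pn[li], t_next = 0))
    nxt <- max(li + 1L, 1L)
    list(node = pn[nxt], t_next = pt[nxt] - S$now)
  }

  start_trip <- function(u, from, to, depart, mode) {
    if (from == to) {
      S$path_nodes[[u]] <- c(from)
      S$path_times[[u]] <- c(depart)
      return(depart)
    }
    rg <- regime_at(depart)
    vp <- paths[[mode]][[from]]$nodes[[to]]
    ep <- paths[[mode]][[from]]$edges[[to]]
    tms <- depart + c(0, cumsum(emin[[mode]][[rg]][ep]))
    S$path_nodes[[u]] <- vp
    S$path_times[[u]] <- tms
    tms[length(tms)]
  }

  assign_unit <- function(u, ci) {
    S$epoch[u] <- S$epoch[u] + 1L
    if (S$state[u] == "returning") {
      pn <- position_next(u)
      arr <- start_trip(u, pn$node, ca_node[ci], S$now + pn$t_next,
                        "lights_sirens")
    } else {
      arr <- start_trip(u, S$node[u], ca_node[ci],
                        S$now + config$pre_trip_delay_min, "lights_sirens")
    }
    S$state[u] <- "en_route"
    S$avail[u] <- FALSE
    S$busy_since[u] <- S$now
    ca_units[[ci]] <<- c(ca_units[[ci]], u)
    if (S$type[u] == "ALS") ca_crew_als[ci] <<- TRUE
    heap_push(h, arr, "scene", a1 = u, a2 = ci, epoch = S$epoch[u])
  }

  dispatch_call <- function(ci) {
    avail <- which(S$avail)
    if (!length(avail)) {
      S$queue <- c(S$queue, ci)
      ca_queued[ci] <<- TRUE
      return(invisible())
    }
    tt <- ttm[["lights_sirens"]][[regime_now()]]
    est <- vapply(avail, function(u) {
      pn <- position_next(u)
      pn$t_next + tt[pn$node, ca_node[ci]]
    }, numeric(1))
    pick <- dispatch_rule(if (ca_fhq[ci]) "FHQ" else "non-FHQ",
                          S$type[avail], est)
    for (u in avail[pick]) assign_unit(u, ci)
    invisible()
  }

  choose_hospital <- function(scene, diag) {
    if (nrow(hosp) == 0) return(NA_integer_)
    tt <- ttm[["lights_sirens"]][[regime_now()]]
    compat <- vapply(hosp_specs, function(s) diag %in% s, logical(1))
    if (!any(compat))
      compat <- vapply(hosp_specs, function(s) "general" %in% s, logical(1))
    if (!any(compat)) compat <- rep(TRUE, nrow(hosp))
    cand <- which(compat)
    cand[which.min(tt[scene, hosp_nodes[cand]])]
  }

  release_unit <- function(u) {
    add <- max(0, min(S$now, H) - min(S$busy_since[u], H))
    S$busy[u] <- S$busy[u] + add
    S$busy_since[u] <- NA_real_
    S$avail[u] <- TRUE
    if (S$node[u] == S$home[u]) {
      S$state[u] <- "idle_at_base"
      S$path_nodes[u] <- list(NULL)
      S$path_times[u] <- list(NULL)
    } else {
      S$epoch[u] <- S$epoch[u] + 1L
      arr <- start_trip(u, S$node[u], S$home[u], S$now, "standard")
      S$state[u] <- "returning"
      heap_push(h, arr, "home", a1 = u, epoch = S$epoch[u])
    }
    process_queue()
  }

  process_queue <- function() {
    while (length(S$queue) && any(S$avail)) {
      fhq_pos <- which(ca_fhq[S$queue])
      pos <- if (length(fhq_pos)) fhq_pos[1] else 1L
      ci <- S$queue[pos]
      S$queue <- S$queue[-pos]
      dispatch_call(ci)
    }
  }

  with_seed(derive_seed(seed, 2L), {
    repeat {
      tcall <- if (next_call <= ncall) calls$time[next_call] else Inf
      theap <- heap_peek_time(h)
      if (!is.finite(tcall) && !is.finite(theap)) break
      if (tcall <= theap) {
        if (tcall < S$now - 1e-9)
          ems_stop("event clock moved backwards (internal error)",
                   "emsloc_internal_error")
        S$now <- tcall
        ci <- next_call
        next_call <- next_call + 1L
        dispatch_call(ci)
        next
      }
      ev <- heap_pop(h)
      if (ev$time < S$now - 1e-9)
        ems_stop("event clock moved backwards (internal error)",
                 "emsloc_internal_error")
      S$now <- ev$time
      switch(ev$type,
        scene = {
          u <- ev$a1; ci <- ev$a2
          if (ev$epoch == S$epoch[u]) {
            pn <- S$path_nodes[[u]]
            S$node[u] <- pn[length(pn)]
            if (ca_done[ci] ||
                (!is.na(ca_scene_end[ci]) && S$now >= ca_scene_end[ci])) {
              release_unit(u)   # arrived after the scene wrapped up
            } else {
              S$state[u] <- "on_scene"
              if (is.na(ca_first[ci])) {
                ca_first[ci] <- S$now
                crew <- if (ca_crew_als[ci]) "ALS" else "BLS"
                dur <- draw_scene_time(config,
                                       if (ca_fhq[ci]) "FHQ" else "non-FHQ",
                                       crew)
                ca_scene_end[ci] <- S$now + dur
                heap_push(h, ca_scene_end[ci], "scene_end", a1 = ci)
              }
            }
          }
        },
        scene_end = {
          ci <- ev$a1
          ca_done[ci] <- TRUE
          here <- ca_units[[ci]][S$state[ca_units[[ci]]] == "on_scene" &
                                   S$node[ca_units[[ci]]] == ca_node[ci]]
          p_tr <- if (ca_crew_als[ci]) config$p_transport_als
                  else config$p_transport_bls
          transported <- runif(1) < p_tr
          hi <- if (transported) choose_hospital(ca_node[ci],
                                                 calls$diagnosis[ci])
                else NA_integer_
          if (transported && is.na(hi)) transported <- FALSE
          ca_transported[ci] <- transported
          if (transported) {
            ca_hospital[ci] <- hosp$id[hi]
            als_here <- here[S$type[here] == "ALS"]
            carrier <- if (length(als_here)) als_here[1] else here[1]
            S$epoch[carrier] <- S$epoch[carrier] + 1L
            arr <- start_trip(carrier, ca_node[ci], hosp_nodes[hi], S$now,
                              "lights_sirens")
            S$state[carrier] <- "transporting"
            heap_push(h, arr, "hosp", a1 = carrier, a2 = hi,
                      epoch = S$epoch[carrier])
            for (u in setdiff(here, carrier)) release_unit(u)
          } else {
            for (u in here) release_unit(u)
          }
        },
        hosp = {
          u <- ev$a1
          if (ev$epoch == S$epoch[u]) {
            hi <- ev$a2
            S$node[u] <- hosp_nodes[hi]
            S$state[u] <- "at_hospital"
            shape <- hosp$dropoff_shape[hi]
            dur <- rgamma(1, shape = shape, rate = shape / hosp$dropoff_mean[hi])
            heap_push(h, S$now + dur, "drop", a1 = u, epoch = S$epoch[u])
          }
        },
        drop = {
          u <- ev$a1
          if (ev$epoch == S$epoch[u]) release_unit(u)
        },
        home = {
          u <- ev$a1
          if (ev$epoch == S$epoch[u] && S$state[u] == "returning") {
            S$node[u] <- S$home[u]
            S$state[u] <- "idle_at_base"
            S$path_nodes[u] <- list(NULL)
            S$path_times[u] <- list(NULL)
          }
        },
        sec = {
          idle_bls <- which(S$avail & S$state == "idle_at_base" &
                              S$type == "BLS")
          oi <- sample.int(nrow(hosp), 1)
          di <- sample.int(nrow(hosp) - 1, 1)
          if (di >= oi) di <- di + 1L
          if (length(idle_bls)) {
            tt <- ttm[["standard"]][[regime_now()]]
            u <- idle_bls[which.min(tt[S$node[idle_bls], hosp_nodes[oi]])]
            S$epoch[u] <- S$epoch[u] + 1L
            shape <- hosp$dropoff_shape[di]
            dur <- tt[S$node[u], hosp_nodes[oi]] +
              tt[hosp_nodes[oi], hosp_nodes[di]] +
              rgamma(1, shape = shape, rate = shape / hosp$dropoff_mean[di])
            S$avail[u] <- FALSE
            S$busy_since[u] <- S$now
            S$state[u] <- "transporting"
            S$path_nodes[u] <- list(NULL)
            S$path_times[u] <- list(NULL)
            heap_push(h, S$now + dur, "sec_done", a1 = u, a2 = di,
                      epoch = S$epoch[u])
          }
        },
        sec_done = {
          u <- ev$a1
          if (ev$epoch == S$epoch[u]) {
            S$node[u] <- hosp_nodes[ev$a2]
            release_unit(u)
          }
        })
    }
  })

  log <- data.frame(
    id = seq_len(ncall),
    time = calls$time,
    node = node_ids[ca_node],
    municipality_id = calls$municipality_id %||% NA_character_,
    priority = calls$priority,
    diagnosis = calls$diagnosis,
    response_time = ca_first - calls$time,
    served = ca_done,
    crew_als = ca_crew_als,
    transported = ca_transported,
    hospital = ca_hospital,
    queued = ca_queued)
  workloads <- data.frame(
    ambulance = seq_len(na),
    station_node = stations$node_id,
    type = stations$type,
    busy_min = S$busy,
    workload = if (ncall == 0) rep(0, na) else S$busy / H)
  list(calls = log, workloads = workloads, horizon_min = H,
       n_queued_end = length(S$queue))
}
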