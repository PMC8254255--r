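#' Build a station-location problem instance
#'
#' Container for all sets and parameters the location models share:
#' candidate sites `I` (with fixed-station counts `st_i` and the subset
#' `I1` of fixed sites with spare capacity), demand points `J` with annual
#' demands `b_j` / `b_fhq_j` and busy probabilities `q_j`, the travel-time
#' matrix `t_ij` and the coverage neighbourhoods `N_j` within `T_max`.
#'
#' @param t travel-time matrix (minutes), sites in rows, demand points in
#'   columns; dimnames used as ids when present.
#' @param b,b_fhq annual all-patient / high-priority (FHQ) demand per
#'   demand point.
#' @param p total number of stations to site (including fixed ones).
#' @param r number of ALS stations (hierarchical model); default 0.
#' @param st fixed stations per site (vector over sites).
#' @param I1 logical over sites: fixed station with spare capacity, i.e.
#'   other demand points may be assigned to it (constraint analogous to a
#'   free server); such sites cannot take an additional new station.
#' @param q busy probability per demand point, each in `[0, 1)`.
#' @param T_max coverage standard in minutes (default 7).
#' @param open_allowed logical over sites: may a new station open here?
#'   Defaults to `TRUE` except at `I1` sites.
#' @return Object of class `ems_problem`.
#' @export
location_problem <- function(t, b, b_fhq, p, r = 0,
                             st = rep(0L, nrow(t)),
                             I1 = rep(FALSE, nrow(t)),
                             q = rep(0, ncol(t)),
                             T_max = 7,
                             open_allowed = NULL) {
  t <- as.matrix(t)
  nI <- nrow(t); nJ <- ncol(t)
  if (length(q) == 1L) q <- rep(q, nJ)
  stopifnot(length(b) == nJ, length(b_fhq) == nJ, length(q) == nJ,
            length(st) == nI, length(I1) == nI)
  if (any(q < 0 | q >= 1))
    ems_stop("busy probabilities q must lie in [0, 1)",
             "emsloc_validation_error")
  if (any(b < 0) || any(b_fhq < 0))
    ems_stop("demands must be non-negative", "emsloc_validation_error")
  check_number(p, "p", lower = 0, integer = TRUE)
  check_number(r, "r", lower = 0, integer = TRUE)
  if (p < sum(st))
    ems_stop("p is smaller than the number of fixed stations",
             "emsloc_infeasible")
  if (r > p)
    ems_stop("r cannot exceed p", "emsloc_validation_error")
  if (any(!is.finite(apply(t, 2, min))))
    ems_stop("every demand point needs a finite travel time to some site",
             "emsloc_validation_error")
  open_allowed <- open_allowed %||% !I1
  open_allowed <- open_allowed & !I1
  site_ids <- rownames(t) %||% paste0("i", seq_len(nI))
  demand_ids <- colnames(t) %||% paste0("j", seq_len(nJ))
  N <- lapply(seq_len(nJ), function(j) which(t[, j] <= T_max))
  structure(list(site_ids = site_ids, demand_ids = demand_ids,
                 t = t, b = as.numeric(b), b_fhq = as.numeric(b_fhq),
                 p = as.integer(p), r = as.integer(r),
                 st = as.integer(st), I1 = as.logical(I1),
                 open_allowed = as.logical(open_allowed),
                 q = as.numeric(q), T_max = T_max,
                 N = N, n = lengths(N)),
            class = "ems_problem")
}

#' Fixed-station preprocessing
#'
#' Decides which current stations stay where they are before optimization:
#' \itemize{
#' \item Fully engaged towns, where annual demand exceeds the capacity of
#'   all locally stationed ambulances (`b_j > capacity * current`), keep
#'   all their stations (`st_i = current`); their demand is reduced by the
#'   patients those stations absorb (`capacity * st_i`, floored at 0) and
#'   no station may be added or removed there.
#' \item Towns with several stations but demand below one ambulance's
#'   capacity keep one station with spare capacity (`st_i = 1`, member of
#'   `I1`, so other municipalities may be assigned to it); the remaining
#'   stations are freed for relocation.
#' \item All other stations are fully relocatable.
#' }
#' The total station count `p` is preserved.
#'
#' @param municipalities municipality table with columns `id`, `node_id`,
#'   `current_stations`.
#' @param demand demand table from [region_demand()] (columns `id`, `b`,
#'   `b_fhq`).
#' @param capacity_per_ambulance annual calls one ambulance can absorb;
#'   default 3000.
#' @return `data.frame` over municipalities with columns `id`, `node_id`,
#'   `st`, `I1`, `open_allowed`, `b_reduced`, `freed` plus attribute `p`
#'   (total stations).
#' @export
preprocess_fixed_stations <- function(municipalities, demand,
                                      capacity_per_ambulance = 3000) {
  if (capacity_per_ambulance <= 0)
    ems_stop("'capacity_per_ambulance' must be positive",
             "emsloc_validation_error")
  d <- merge(municipalities[, c("id", "node_id", "current_stations")],
             demand[, c("id", "b", "b_fhq")], by = "id", sort = FALSE)
  d <- d[match(municipalities$id, d$id), ]
  cnt <- d$current_stations
  cap <- capacity_per_ambulance
  st <- integer(nrow(d)); I1 <- logical(nrow(d))
  open_allowed <- rep(TRUE, nrow(d)); b_red <- d$b
  full <- cnt >= 1 & d$b > cap * cnt
  st[full] <- cnt[full]
  open_allowed[full] <- FALSE
  b_red[full] <- pmax(0, d$b[full] - cap * cnt[full])
  spare <- !full & cnt >= 2 & d$b < cap
  st[spare] <- 1L
  I1[spare] <- TRUE
  open_allowed[spare] <- FALSE
  out <- data.frame(id = d$id, node_id = d$node_id, st = st, I1 = I1,
                    open_allowed = open_allowed, b_reduced = b_red,
                    b_fhq = d$b_fhq, freed = cnt - st)
  attr(out, "p") <- sum(cnt)
  out
}

#' Assemble a location problem from a region
#'
#' Convenience wrapper: demand estimation, fixed-station preprocessing,
#' travel-time matrix (lights-and-sirens, off-peak) and neighbourhoods.
#'
#' @param region an `ems_region`.
#' @param q busy probability: single value or vector over demand points.
#' @param rates an [age_group_rates()].
#' @param T_max coverage standard in minutes.
#' @param capacity_per_ambulance see [preprocess_fixed_stations()].
#' @param speed a [speed_model()].
#' @param r number of ALS stations; default: current ALS count.
#' @return An `ems_problem` whose sites and demand points are the
#'   municipality nodes.
#' @export
build_location_problem <- function(region, q = 0.3,
                                   rates = age_group_rates(),
                                   T_max = 7,
                                   capacity_per_ambulance = 3000,
                                   speed = speed_model(),
                                   r = NULL) {
  dem <- region_demand(region, rates)
  pre <- preprocess_fixed_stations(region$municipalities, dem,
                                   capacity_per_ambulance)
  nodes <- region$municipalities$node_id
  tt <- travel_time_matrix(region$network, speed,
                           origins = nodes, destinations = nodes,
                           mode = "lights_sirens", regime = "offpeak")
  r <- r %||% sum(region$municipalities$current_als)
  location_problem(tt, b = pre$b_reduced, b_fhq = pre$b_fhq,
                   p = attr(pre, "p"), r = r,
                   st = pre$st, I1 = pre$I1, q = q, T_max = T_max,
                   open_allowed = pre$open_allowed)
}
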