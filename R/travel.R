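#' Per-edge travel time in minutes
#'
#' `minutes = 60 * length_km / speed`, with the speed looked up in the
#' model for the edge's road category and urban flag.
#'
#' @param length_km edge length in km.
#' @param category road category.
#' @param urban logical urban flag.
#' @param model an [speed_model()].
#' @param mode driving mode.
#' @param regime time-of-day regime.
#' @return Travel time in minutes.
#' @export
edge_travel_time <- function(length_km, category, urban,
                             model = speed_model(),
                             mode = "lights_sirens", regime = "offpeak") {
  if (any(length_km <= 0))
    ems_stop("edge lengths must be positive", "emsloc_validation_error")
  speeds <- model$lookup[paste(category, urban, mode, regime)]
  if (anyNA(speeds))
    ems_stop("unknown (category, urban) combination in edge list",
             "emsloc_config_error")
  60 * length_km / unname(speeds)
}

#' Edge weights (minutes) for a whole network
#' @noRd
network_edge_minutes <- function(network, model, mode, regime) {
  if (igraph::ecount(network) == 0) return(numeric(0))
  edge_travel_time(igraph::E(network)$length_km,
                   igraph::E(network)$category,
                   igraph::E(network)$urban,
                   model, mode, regime)
}

#' Shortest-path travel-time matrix
#'
#' Pairwise shortest travel times in minutes between network nodes, with
#' per-edge times from the speed model. Disconnected pairs get `Inf`.
#'
#' @param network an undirected `igraph` road network with edge attributes
#'   `length_km`, `category`, `urban` (see [generate_region()]).
#' @param model an [speed_model()].
#' @param origins,destinations node ids (igraph vertex names); default all.
#' @param mode driving mode; response trips use `"lights_sirens"`.
#' @param regime time-of-day regime.
#' @return Object of class `ems_ttmatrix`: a numeric matrix (minutes) with
#'   origin/destination node names, plus `mode` and `regime` attributes.
#' @export
travel_time_matrix <- function(network, model = speed_model(),
                               origins = NULL, destinations = NULL,
                               mode = "lights_sirens", regime = "offpeak") {
  all_ids <- igraph::V(network)$name
  origins <- origins %||% all_ids
  destinations <- destinations %||% all_ids
  if (!all(as.character(origins) %in% all_ids) ||
      !all(as.character(destinations) %in% all_ids))
    ems_stop("origins/destinations must be network nodes",
             "emsloc_validation_error")
  w <- network_edge_minutes(network, model, mode, regime)
  m <- igraph::distances(network, v = as.character(origins),
                         to = as.character(destinations), weights = w)
  structure(m, class = c("ems_ttmatrix", class(m)),
            mode = mode, regime = regime)
}

#' Coverage neighbourhoods
#'
#' For every demand point `j`, the set `N_j` of candidate locations whose
#' travel time to `j` is at most `T_max` minutes (closed inequality).
#'
#' @param tt an [travel_time_matrix()] with candidate sites as rows and
#'   demand points as columns.
#' @param T_max travel-time standard in minutes; default 7 (an 8-minute
#'   response standard for critical patients minus 1 minute of pre-trip
#'   delay).
#' @return Object of class `ems_neighbourhoods`: list with `T_max`, `N`
#'   (list per demand point of candidate row indices) and `n` (sizes).
#' @export
neighbourhoods <- function(tt, T_max = 7) {
  check_number(T_max, "T_max")
  if (T_max <= 0)
    ems_stop("'T_max' must be positive", "emsloc_validation_error")
  N <- lapply(seq_len(ncol(tt)), function(j) which(tt[, j] <= T_max))
  names(N) <- colnames(tt)
  structure(list(T_max = T_max, N = N, n = lengths(N)),
            class = "ems_neighbourhoods")
}
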