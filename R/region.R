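# Synthetic-region generator. Stands in for the census / road-network /
# ambient-population inputs of a real deployment so that the demand,
# travel, optimization and simulation layers are testable offline.

#' Specification of a synthetic region
#'
#' @param n_municipalities number of municipalities (each becomes one road
#'   node, one candidate site and one demand point).
#' @param urban_fraction fraction of municipalities flagged urban.
#' @param age_structure_params list with elements `share_0_14` and
#'   `share_65plus`, each a length-2 range of population shares; the
#'   15-64 share is the remainder.
#' @param n_hospitals number of hospitals (placed in the largest towns).
#' @param n_current_stations number of currently operated stations.
#' @param als_fraction fraction of current stations that are ALS
#'   (physician-staffed); the rest are BLS.
#' @param grid_resolution ambient-population grid cells per municipality.
#' @param network_style `"grid"` (perturbed lattice, guaranteed connected)
#'   or `"random-geometric"` (k-nearest-neighbour graph made connected).
#' @param max_stations_per_town upper bound of stations a town can host.
#' @param seed integer seed; fully determines the generated region.
#' @return Object of class `ems_region_spec`.
#' @export
region_spec <- function(n_municipalities = 20,
                        urban_fraction = 0.3,
                        age_structure_params = list(
                          share_0_14 = c(0.10, 0.20),
                          share_65plus = c(0.08, 0.25)),
                        n_hospitals = 2,
                        n_current_stations = 6,
                        als_fraction = 1 / 3,
                        grid_resolution = 2,
                        network_style = c("grid", "random-geometric"),
                        max_stations_per_town = 3,
                        seed = 1) {
  network_style <- match.arg(network_style)
  check_number(n_municipalities, "n_municipalities", lower = 1, integer = TRUE)
  check_proportion(urban_fraction, "urban_fraction")
  check_proportion(als_fraction, "als_fraction")
  check_number(n_hospitals, "n_hospitals", lower = 0, integer = TRUE)
  check_number(n_current_stations, "n_current_stations", lower = 1,
               integer = TRUE)
  check_number(grid_resolution, "grid_resolution", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  for (nm in c("share_0_14", "share_65plus")) {
    rng <- age_structure_params[[nm]]
    if (is.null(rng) || length(rng) != 2 || any(rng < 0) || any(rng > 1))
      ems_stop(sprintf("age_structure_params$%s must be a range in [0,1]", nm),
               "emsloc_validation_error")
  }
  if (n_current_stations > n_municipalities * max_stations_per_town)
    ems_stop("n_current_stations exceeds n_municipalities * max_stations_per_town",
             "emsloc_validation_error")
  structure(list(n_municipalities = as.integer(n_municipalities),
                 urban_fraction = urban_fraction,
                 age_structure_params = age_structure_params,
                 n_hospitals = as.integer(n_hospitals),
                 n_current_stations = as.integer(n_current_stations),
                 als_fraction = als_fraction,
                 grid_resolution = as.integer(grid_resolution),
                 network_style = network_style,
                 max_stations_per_town = as.integer(max_stations_per_town),
                 seed = as.integer(seed)),
            class = "ems_region_spec")
}

#' Run code with a private RNG state
#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' @noRd
sample_edge_category <- function(n, urban) {
  cats_u <- c("local", "national", "residential", "important_national", "minor")
  w_u <- c(0.35, 0.25, 0.2, 0.1, 0.1)
  cats_r <- c("national", "important_national", "local", "minor", "expressway",
              "motorway")
  w_r <- c(0.3, 0.2, 0.25, 0.1, 0.08, 0.07)
  out <- character(n)
  if (any(urban)) out[urban] <- sample(cats_u, sum(urban), TRUE, w_u)
  if (any(!urban)) out[!urban] <- sample(cats_r, sum(!urban), TRUE, w_r)
  out
}

#' @noRd
build_network <- function(spec, urban) {
  n <- spec$n_municipalities
  if (spec$network_style == "grid") {
    nc <- ceiling(sqrt(n))
    nr <- ceiling(n / nc)
    row <- (seq_len(n) - 1) %/% nc
    col <- (seq_len(n) - 1) %% nc
    x <- col * 5 + runif(n, -1, 1)
    y <- row * 5 + runif(n, -1, 1)
    from <- integer(0); to <- integer(0)
    for (v in seq_len(n)) {
      if (col[v] < nc - 1 && v + 1 <= n) { from <- c(from, v); to <- c(to, v + 1) }
      if (v + nc <= n) { from <- c(from, v); to <- c(to, v + nc) }
    }
  } else {
    x <- runif(n, 0, 5 * sqrt(n))
    y <- runif(n, 0, 5 * sqrt(n))
    k <- min(3L, n - 1L)
    from <- integer(0); to <- integer(0)
    if (n > 1) {
      for (v in seq_len(n)) {
        d <- sqrt((x - x[v])^2 + (y - y[v])^2)
        d[v] <- Inf
        nb <- order(d)[seq_len(k)]
        from <- c(from, rep(v, k)); to <- c(to, nb)
      }
      keep <- from < to
      pairs <- unique(cbind(from[keep], to[keep]))
      # also deduplicate mirrored pairs
      a <- pmin(from, to); b <- pmax(from, to)
      pairs <- unique(cbind(a, b))
      from <- pairs[, 1]; to <- pairs[, 2]
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  igraph::V(g)$name <- paste0("n", seq_len(n))
  igraph::V(g)$x <- round(x, 3)
  igraph::V(g)$y <- round(y, 3)
  if (length(from)) g <- igraph::add_edges(g, rbind(from, to))
  # stitch components together (random-geometric graphs may fragment)
  comp <- igraph::components(g)
  while (comp$no > 1) {
    c1 <- which(comp$membership == 1)
    c2 <- which(comp$membership == 2)
    d <- outer(c1, c2, function(a, b)
      sqrt((igraph::V(g)$x[a] - igraph::V(g)$x[b])^2 +
             (igraph::V(g)$y[a] - igraph::V(g)$y[b])^2))
    ij <- arrayInd(which.min(d), dim(d))
    g <- igraph::add_edges(g, c(c1[ij[1]], c2[ij[2]]))
    comp <- igraph::components(g)
  }
  el <- igraph::as_edgelist(g, names = FALSE)
  eu <- urban[el[, 1]] & urban[el[, 2]]
  dx <- igraph::V(g)$x[el[, 1]] - igraph::V(g)$x[el[, 2]]
  dy <- igraph::V(g)$y[el[, 1]] - igraph::V(g)$y[el[, 2]]
  eucl <- sqrt(dx^2 + dy^2)
  igraph::E(g)$length_km <- round(pmax(0.2, eucl * runif(length(eucl), 1.05, 1.4)), 3)
  igraph::E(g)$category <- sample_edge_category(length(eucl), eu)
  igraph::E(g)$urban <- eu
  g
}

#' Generate a synthetic region
#'
#' Builds a connected road network, age-structured municipal populations,
#' an ambient-population grid (Dirichlet split per municipality), current
#' stations concentrated in the largest towns (ALS preferentially at
#' hospital towns) and hospitals with Erlang drop-off parameters. The
#' output is fully determined by `spec$seed`.
#'
#' @param spec an [region_spec()].
#' @return Object of class `ems_region`: list with `municipalities`,
#'   `network` (igraph), `hospitals`, `stations`, `grid`, `spec`.
#' @export
generate_region <- function(spec = region_spec()) {
  if (!inherits(spec, "ems_region_spec"))
    ems_stop("'spec' must be an ems_region_spec", "emsloc_validation_error")
  with_seed(spec$seed, {
    n <- spec$n_municipalities
    urban <- rep(FALSE, n)
    n_urb <- round(spec$urban_fraction * n)
    if (n_urb > 0) urban[sample.int(n, n_urb)] <- TRUE
    network <- build_network(spec, urban)

    pop_total <- integer(n)
    pop_total[urban] <- round(exp(runif(sum(urban), log(5000), log(60000))))
    pop_total[!urban] <- round(exp(runif(sum(!urban), log(400), log(4000))))
    asp <- spec$age_structure_params
    s014 <- runif(n, asp$share_0_14[1], asp$share_0_14[2])
    s65 <- runif(n, asp$share_65plus[1], asp$share_65plus[2])
    pop_0_14 <- round(pop_total * s014)
    pop_65 <- round(pop_total * s65)
    pop_15_64 <- pop_total - pop_0_14 - pop_65

    ord <- order(pop_total, decreasing = TRUE)
    stations_per <- integer(n)
    left <- spec$n_current_stations
    lvl <- 1L
    while (left > 0) {
      for (i in ord) {
        if (left == 0) break
        if (stations_per[i] < lvl &&
            stations_per[i] < spec$max_stations_per_town) {
          stations_per[i] <- stations_per[i] + 1L
          left <- left - 1L
        }
      }
      lvl <- lvl + 1L
      if (lvl > spec$max_stations_per_town) break
    }

    hosp_idx <- head(ord, spec$n_hospitals)
    hospitals <- if (spec$n_hospitals > 0) {
      specs <- vapply(seq_along(hosp_idx), function(k) {
        if (k == 1) "general;cardio;pediatric"
        else paste(c("general",
                     c("cardio", "pediatric")[runif(2) < 0.5]),
                   collapse = ";")
      }, character(1))
      data.frame(id = paste0("H", seq_along(hosp_idx)),
                 node_id = paste0("n", hosp_idx),
                 specializations = specs,
                 dropoff_shape = sample(2:4, length(hosp_idx), TRUE),
                 dropoff_mean = round(runif(length(hosp_idx), 7.1, 36.2), 1))
    } else {
      data.frame(id = character(0), node_id = character(0),
                 specializations = character(0),
                 dropoff_shape = integer(0), dropoff_mean = numeric(0))
    }

    # ALS units sit preferentially where hospitals are
    n_als <- round(spec$als_fraction * spec$n_current_stations)
    st_nodes <- rep(seq_len(n), stations_per)
    pref <- order(!(st_nodes %in% hosp_idx), -pop_total[st_nodes])
    types <- rep("BLS", length(st_nodes))
    if (n_als > 0) types[pref[seq_len(min(n_als, length(types)))]] <- "ALS"
    stations <- data.frame(id = paste0("S", seq_along(st_nodes)),
                           node_id = paste0("n", st_nodes),
                           type = types)

    gr <- spec$grid_resolution
    cells <- lapply(seq_len(n), function(i) {
      w <- rgamma(gr, shape = 1)   # Dirichlet(1,...,1) split
      w <- w / sum(w)
      data.frame(cell_id = paste0("c", i, "_", seq_len(gr)),
                 node_id = paste0("n", i),
                 municipality_id = paste0("M", i),
                 weight = round(pop_total[i] * w, 3))
    })
    grid <- do.call(rbind, cells)

    municipalities <- data.frame(
      id = paste0("M", seq_len(n)),
      name = paste0("Town", seq_len(n)),
      node_id = paste0("n", seq_len(n)),
      urban = urban,
      pop_0_14 = pop_0_14, pop_15_64 = pop_15_64, pop_65plus = pop_65,
      current_stations = stations_per,
      current_als = vapply(seq_len(n), function(i)
        sum(types[st_nodes == i] == "ALS"), integer(1)))

    structure(list(municipalities = municipalities, network = network,
                   hospitals = hospitals, stations = stations, grid = grid,
                   spec = spec),
              class = "ems_region")
  })
}

#' Deterministic call script
#'
#' A pre-specified call stream the simulator can consume in place of its
#' stochastic generator, for hand-traceable tests.
#'
#' @param events `data.frame` with columns `time` (minutes, nondecreasing),
#'   `node` (network node id) and `priority` (`"FHQ"` or `"non-FHQ"`);
#'   optional `diagnosis` (default `"general"`).
#' @param region an `ems_region`; used to validate node ids.
#' @return Object of class `ems_call_script`.
#' @export
generate_call_script <- function(events, region = NULL) {
  if (nrow(events) == 0)
    return(structure(data.frame(time = numeric(0), node = character(0),
                                priority = character(0),
                                diagnosis = character(0)),
                     class = c("ems_call_script", "data.frame")))
  need <- c("time", "node", "priority")
  if (!all(need %in% names(events)))
    ems_stop("events must have columns time, node, priority",
             "emsloc_validation_error")
  if (is.unsorted(events$time))
    ems_stop("event times must be nondecreasing", "emsloc_validation_error")
  if (!all(events$priority %in% c("FHQ", "non-FHQ")))
    ems_stop("priority must be 'FHQ' or 'non-FHQ'", "emsloc_validation_error")
  if (!is.null(region)) {
    known <- igraph::V(region$network)$name
    bad <- setdiff(unique(events$node), known)
    if (length(bad))
      ems_stop(paste("unknown node(s):", toString(bad)),
               "emsloc_validation_error")
  }
  if (is.null(events$diagnosis)) events$diagnosis <- "general"
  structure(events[, c("time", "node", "priority", "diagnosis")],
            class = c("ems_call_script", "data.frame"))
}
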