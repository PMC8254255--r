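# Hand-built three-node line region with round-number travel times:
# n1 -- n2 -- n3, each edge 5 km of urban motorway, so lights-and-sirens
# off-peak legs take exactly 3 minutes (100 km/h) and standard-speed legs
# 10/3 minutes (90 km/h). Station at n1, hospital at n3.
line_region <- function(station_nodes = "n1",
                        station_types = "BLS",
                        hospital_node = "n3") {
  g <- igraph::make_graph(rbind(c(1, 2), c(2, 3)), n = 3, directed = FALSE)
  igraph::V(g)$name <- paste0("n", 1:3)
  igraph::V(g)$x <- c(0, 5, 10); igraph::V(g)$y <- c(0, 0, 0)
  igraph::E(g)$length_km <- c(5, 5)
  igraph::E(g)$category <- c("motorway", "motorway")
  igraph::E(g)$urban <- c(TRUE, TRUE)
  munis <- data.frame(id = paste0("M", 1:3), name = paste0("T", 1:3),
                      node_id = paste0("n", 1:3), urban = TRUE,
                      pop_0_14 = 100, pop_15_64 = 700, pop_65plus = 200,
                      current_stations = c(1L, 0L, 0L),
                      current_als = c(0L, 0L, 0L))
  hospitals <- data.frame(id = "H1", node_id = hospital_node,
                          specializations = "general;cardio;pediatric",
                          dropoff_shape = 3L, dropoff_mean = 15)
  stations <- data.frame(id = paste0("S", seq_along(station_nodes)),
                         node_id = station_nodes, type = station_types)
  grid <- data.frame(cell_id = paste0("c", 1:3), node_id = paste0("n", 1:3),
                     municipality_id = paste0("M", 1:3), weight = c(1, 1, 1))
  structure(list(municipalities = munis, network = g, hospitals = hospitals,
                 stations = stations, grid = grid,
                 spec = region_spec(n_municipalities = 3,
                                    n_current_stations = 1, seed = 1)),
            class = "ems_region")
}

script_df <- function(...) {
  generate_call_script(data.frame(...))
}

deterministic_cfg <- function(...) {
  sim_config(horizon_days = 1, daily_volume = 0, replications = 2,
             scene_cv = 0, ...)
}
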