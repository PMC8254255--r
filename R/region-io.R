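# On-disk region format: a directory of plain-text files.
#   municipalities.csv  id,name,node_id,urban,pop_0_14,pop_15_64,pop_65plus,
#                       current_stations,current_als
#   network.graphml     nodes: name,x,y; edges: length_km,category,urban
#   hospitals.csv       id,node_id,specializations,dropoff_shape,dropoff_mean
#   grid.csv            cell_id,node_id,municipality_id,weight
#   stations.csv        id,node_id,type
#   region.json         manifest: format version + the generating spec
# CSV dialect: comma separator, header row, dot decimal, UTF-8.

MUNI_COLS <- c("id", "name", "node_id", "urban", "pop_0_14", "pop_15_64",
               "pop_65plus", "current_stations", "current_als")
HOSP_COLS <- c("id", "node_id", "specializations", "dropoff_shape",
               "dropoff_mean")
GRID_COLS <- c("cell_id", "node_id", "municipality_id", "weight")
STATION_COLS <- c("id", "node_id", "type")

#' Write a region to a directory
#'
#' @param region an `ems_region`.
#' @param directory output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_region <- function(region, directory) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  wcsv <- function(d, f) write.csv(d, file.path(directory, f),
                                   row.names = FALSE, quote = FALSE)
  wcsv(region$municipalities, "municipalities.csv")
  wcsv(region$hospitals, "hospitals.csv")
  wcsv(region$grid, "grid.csv")
  wcsv(region$stations, "stations.csv")
  igraph::write_graph(region$network, file.path(directory, "network.graphml"),
                      format = "graphml")
  spec <- region$spec
  manifest <- list(format = "emsloc-region/1",
                   spec = unclass(spec))
  jsonlite::write_json(manifest, file.path(directory, "region.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(file.path(directory, c("municipalities.csv", "hospitals.csv",
                                   "grid.csv", "stations.csv",
                                   "network.graphml", "region.json")))
}

#' @noRd
read_region_csv <- function(directory, file, cols) {
  path <- file.path(directory, file)
  if (!file.exists(path))
    ems_stop(sprintf("missing file '%s'", path), "emsloc_parse_error")
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(cols, names(d))
  if (length(missing))
    ems_stop(sprintf("file '%s' is missing column(s): %s",
                     file, toString(missing)), "emsloc_parse_error")
  d[, cols]
}

#' Read a region from a directory
#'
#' Inverse of [write_region()]; the round trip is lossless.
#'
#' @param directory directory written by [write_region()].
#' @return An `ems_region`.
#' @export
read_region <- function(directory) {
  municipalities <- read_region_csv(directory, "municipalities.csv", MUNI_COLS)
  hospitals <- read_region_csv(directory, "hospitals.csv", HOSP_COLS)
  grid <- read_region_csv(directory, "grid.csv", GRID_COLS)
  stations <- read_region_csv(directory, "stations.csv", STATION_COLS)
  gpath <- file.path(directory, "network.graphml")
  if (!file.exists(gpath))
    ems_stop(sprintf("missing file '%s'", gpath), "emsloc_parse_error")
  network <- igraph::read_graph(gpath, format = "graphml")
  # drop the synthetic XML node-id attribute igraph adds on read
  if ("id" %in% igraph::vertex_attr_names(network))
    network <- igraph::delete_vertex_attr(network, "id")
  igraph::E(network)$urban <- as.logical(igraph::E(network)$urban)
  jpath <- file.path(directory, "region.json")
  if (!file.exists(jpath))
    ems_stop(sprintf("missing file '%s'", jpath), "emsloc_parse_error")
  manifest <- jsonlite::read_json(jpath, simplifyVector = TRUE)
  spec <- manifest$spec
  spec$age_structure_params <- lapply(spec$age_structure_params, as.numeric)
  spec <- do.call(region_spec, spec)
  bad <- setdiff(municipalities$node_id, igraph::V(network)$name)
  if (length(bad))
    ems_stop(paste("municipalities reference unknown nodes:", toString(bad)),
             "emsloc_parse_error")
  structure(list(municipalities = municipalities, network = network,
                 hospitals = hospitals, stations = stations, grid = grid,
                 spec = spec),
            class = "ems_region")
}
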