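# Average ambulance speeds (km/h) by road category, urban/rural setting,
# driving mode (lights & sirens vs standard) and time-of-day regime
# (off-peak, morning rush 6:30-9:00, evening rush 15:00-18:00), derived
# from GPS records of ambulance trips.
#
# The urban residential- and minor-road rows of the source table are
# typographically garbled; their defaults below are conservative values
# below the local-road row and are configurable via `speed_model()`.

ROAD_CATEGORIES <- c("motorway", "expressway", "important_national",
                     "national", "local", "residential", "minor")
SPEED_MODES <- c("lights_sirens", "standard")
SPEED_REGIMES <- c("offpeak", "morning_rush", "evening_rush")

default_speed_rows <- function() {
  # category, urban, mode: offpeak, morning_rush, evening_rush
  rows <- list(
    # urban, lights & sirens
    list("motorway",           TRUE,  "lights_sirens", c(100, 92, 90)),
    list("expressway",         TRUE,  "lights_sirens", c(100, 92, 89)),
    list("important_national", TRUE,  "lights_sirens", c(65, 60, 56)),
    list("national",           TRUE,  "lights_sirens", c(60, 51, 55)),
    list("local",              TRUE,  "lights_sirens", c(59, 50, 50)),
    list("residential",        TRUE,  "lights_sirens", c(40, 36, 36)),
    list("minor",              TRUE,  "lights_sirens", c(35, 31, 31)),
    # urban, standard
    list("motorway",           TRUE,  "standard", c(90, 86, 86)),
    list("expressway",         TRUE,  "standard", c(90, 84, 82)),
    list("important_national", TRUE,  "standard", c(46, 42, 40)),
    list("national",           TRUE,  "standard", c(40, 39, 38)),
    list("local",              TRUE,  "standard", c(36, 35, 35)),
    list("residential",        TRUE,  "standard", c(30, 27, 27)),
    list("minor",              TRUE,  "standard", c(26, 23, 23)),
    # rural, lights & sirens
    list("motorway",           FALSE, "lights_sirens", c(110, 100, 102)),
    list("expressway",         FALSE, "lights_sirens", c(110, 98, 98)),
    list("important_national", FALSE, "lights_sirens", c(101, 88, 89)),
    list("national",           FALSE, "lights_sirens", c(91, 78, 80)),
    list("local",              FALSE, "lights_sirens", c(68, 59, 60)),
    list("residential",        FALSE, "lights_sirens", c(60, 55, 55)),
    list("minor",              FALSE, "lights_sirens", c(55, 55, 55)),
    # rural, standard
    list("motorway",           FALSE, "standard", c(100, 100, 100)),
    list("expressway",         FALSE, "standard", c(100, 90, 90)),
    list("important_national", FALSE, "standard", c(86, 67, 65)),
    list("national",           FALSE, "standard", c(67, 58, 57)),
    list("local",              FALSE, "standard", c(58, 53, 55)),
    list("residential",        FALSE, "standard", c(55, 50, 50)),
    list("minor",              FALSE, "standard", c(50, 50, 50))
  )
  do.call(rbind, lapply(rows, function(r) {
    data.frame(category = r[[1]], urban = r[[2]], mode = r[[3]],
               regime = SPEED_REGIMES, speed_kmh = r[[4]])
  }))
}

#' Ambulance speed model
#'
#' Table of average speeds in km/h indexed by road category, urban flag,
#' driving mode (`lights_sirens` for response trips, `standard` for the
#' journey home) and time-of-day regime (`offpeak`, `morning_rush`
#' 06:30-09:00, `evening_rush` 15:00-18:00).
#'
#' @param table optional replacement/override `data.frame` with columns
#'   `category`, `urban`, `mode`, `regime`, `speed_kmh`; rows override the
#'   defaults for matching keys.
#' @return Object of class `ems_speed_model`.
#' @export
speed_model <- function(table = NULL) {
  tab <- default_speed_rows()
  if (!is.null(table)) {
    need <- c("category", "urban", "mode", "regime", "speed_kmh")
    if (!all(need %in% names(table)))
      ems_stop("override table must have columns category, urban, mode, regime, speed_kmh",
               "emsloc_config_error")
    key <- function(d) paste(d$category, d$urban, d$mode, d$regime)
    idx <- match(key(table), key(tab))
    if (anyNA(idx))
      ems_stop("override table contains unknown (category, urban, mode, regime) keys",
               "emsloc_config_error")
    tab$speed_kmh[idx] <- table$speed_kmh
  }
  if (any(tab$speed_kmh <= 0))
    ems_stop("all speeds must be positive", "emsloc_config_error")
  lookup <- setNames(tab$speed_kmh,
                     paste(tab$category, tab$urban, tab$mode, tab$regime))
  structure(list(table = tab, lookup = lookup), class = "ems_speed_model")
}

#' Look up an average speed
#'
#' @param model an [speed_model()].
#' @param category road category, one of `r toString(ROAD_CATEGORIES)`.
#' @param urban logical, inside built-up area?
#' @param mode `"lights_sirens"` or `"standard"`.
#' @param regime `"offpeak"`, `"morning_rush"` or `"evening_rush"`.
#' @return Speed in km/h.
#' @export
speed_lookup <- function(model, category, urban, mode, regime = "offpeak") {
  key <- paste(category, urban, mode, regime)
  v <- model$lookup[key]
  if (anyNA(v))
    ems_stop(sprintf("no speed for (%s, urban=%s, %s, %s)",
                     category, urban, mode, regime), "emsloc_config_error")
  unname(v)
}

#' Time-of-day regime at a simulated clock time
#'
#' @param time_min simulation clock in minutes since midnight of day 0.
#' @return `"morning_rush"` within 06:30-09:00, `"evening_rush"` within
#'   15:00-18:00, `"offpeak"` otherwise.
#' @export
regime_at <- function(time_min) {
  tod <- time_min %% 1440
  ifelse(tod >= 390 & tod < 540, "morning_rush",
         ifelse(tod >= 900 & tod < 1080, "evening_rush", "offpeak"))
}
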