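Package: emsloc
Title: Ambulance Station Location Optimization and Simulation
Version: 0.1.0
Authors@R:
    person("EMS", "Modelling Group", email = "emsloc@example.org",
           role = c("aut", "cre"))
Description: Tools for planning emergency medical service (EMS) station
    networks in mixed urban-rural regions. Estimates age-structured annual
    call demand per municipality, computes road-network travel times under
    a mode- and time-of-day-dependent speed model, and sites ambulance
    stations with three mixed-integer location models: a bi-criteria model
    combining maximal expected coverage of high-priority patients (MEXCLP)
    with a weighted p-median response-time objective solved
    lexicographically, a plain weighted p-median, and a hierarchical
    pq-median for two-tier ALS/BLS fleets. A kernel-search matheuristic
    handles instances beyond exact enumeration. A discrete-event simulator
    of the full service pathway (dispatch, scene care, hospital transport,
    drop-off, return, redirection of returning units) evaluates candidate
    layouts, estimates ambulance busy fractions that feed back into the
    location models through a recursive optimize-simulate loop, and a
    logistic survival model translates response-time gains into expected
    additional survivors. A seeded synthetic-region generator makes the
    whole pipeline reproducible without external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
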