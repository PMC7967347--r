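#' Simulation configuration
#'
#' Collects every regulatory and modelling constant the simulator needs: the
#' maximum allowed response time (MART), the compliance target (MARTCR), the
#' response-time variant, the high-priority set, dispatch cut-offs, the
#' follow-up-incident mode, service-time distributions and speed profiles.
#'
#' @param mart Maximum allowed response time in minutes. The Swiss default is
#'   15 min.
#' @param martcr_target Required compliance rate in percent (Swiss default 90).
#' @param rt_variant Which leg of the incident timeline counts as response
#'   time: `"TRANSIT_ONLY"` (from departure at base, used e.g. in Bavaria),
#'   `"PREP_PLUS_TRANSIT"` (from the call to the EMS unit, Swiss standard) or
#'   `"FROM_DISPATCH_CALL"` (from the call to the dispatch centre, used in
#'   Baden-Wuerttemberg).
#' @param high_priority_set Priority codes dispatched with the closest-idle
#'   strategy. Defaults to `c("P1", "P2")`.
#' @param cutoff_km,cutoff_min Optional dispatch cut-offs: candidate units
#'   farther than `cutoff_km` (great-circle) or with an ETA above
#'   `cutoff_min` are never considered. `NULL` disables a cut-off.
#' @param enforce_regions When `TRUE`, a unit may only serve incidents whose
#'   `organization` equals its base's `region` (models the federal border
#'   constraint). Default `FALSE`.
#' @param follow_up_mode `"START_AT_BASE"`: every mission departs from the
#'   unit's base (the paper's simplification for follow-up incidents);
#'   `"CHAINED"`: a freed unit can be dispatched from the location where it
#'   became free while still on its return leg.
#' @param seed Integer seed governing all stochastic service-time draws.
#' @param epsilon_pp Minimum worthwhile RTCR improvement in percentage points
#'   for the reserve-capacity iteration (default 1.0).
#' @param epoch ISO-8601 instant that second 0 of the scenario refers to.
#'   Defaults to a Monday so weekday masks are anchored.
#' @param horizon Optional numeric `c(start, end)` in seconds since `epoch`.
#' @param service_times List of distance-independent duration parameters
#'   (lognormal medians in minutes and log-scale sigmas) for turnout,
#'   on-scene, handover and the modelled transport leg, plus `replay = TRUE`
#'   to reuse each incident's historical durations (the simulated-historical
#'   setting).
#' @param profiles Named list of [speed_profile()] objects keyed by
#'   `profile_id`.
#' @param mco List with `speed_kmh` and `range_km` for the multicopter
#'   dispatch rule.
#' @param count_unserved When `TRUE` (default) incidents whose required unit
#'   type never becomes available count as non-compliant in the RTCR; when
#'   `FALSE` they are dropped from the denominator.
#' @return An object of class `ems_config`.
#' @export
ems_config <- function(mart = 15, martcr_target = 90,
                       rt_variant = c("PREP_PLUS_TRANSIT", "TRANSIT_ONLY",
                                      "FROM_DISPATCH_CALL"),
                       high_priority_set = c("P1", "P2"),
                       cutoff_km = NULL, cutoff_min = NULL,
                       enforce_regions = FALSE,
                       follow_up_mode = c("START_AT_BASE", "CHAINED"),
                       seed = 1L, epsilon_pp = 1.0,
                       epoch = DEFAULT_EPOCH, horizon = NULL,
                       service_times = default_service_times(),
                       profiles = default_profiles(),
                       mco = list(speed_kmh = 80, range_km = 50),
                       count_unserved = TRUE) {
  rt_variant <- match.arg(rt_variant)
  follow_up_mode <- match.arg(follow_up_mode)
  stopifnot(mart > 0, martcr_target > 0, martcr_target <= 100,
            epsilon_pp > 0)
  if (!all(high_priority_set %in% PRIORITY_CODES)) {
    stop("unknown priority code in high_priority_set")
  }
  st <- default_service_times()
  st[names(service_times)] <- service_times
  structure(list(
    mart = mart, martcr_target = martcr_target, rt_variant = rt_variant,
    high_priority_set = high_priority_set,
    cutoff_km = cutoff_km, cutoff_min = cutoff_min,
    enforce_regions = isTRUE(enforce_regions),
    follow_up_mode = follow_up_mode,
    seed = as.integer(seed), epsilon_pp = epsilon_pp,
    epoch = epoch, horizon = horizon,
    service_times = st, profiles = profiles, mco = mco,
    count_unserved = isTRUE(count_unserved)
  ), class = "ems_config")
}

#' @rdname ems_config
#' @export
default_service_times <- function() {
  list(replay = FALSE,
       turnout_median_min = 2, turnout_sigma = 0.35,
       on_scene_median_min = 15, on_scene_sigma = 0.4,
       handover_median_min = 15, handover_sigma = 0.35,
       transport_median_min = 12, transport_sigma = 0.4)
}

#' Assemble a scenario
#'
#' The scenario is the one merged structure the simulator operates on:
#' incidents, events, EMS units, shifts, bases, optional hospitals and
#' communities, and the configuration.
#'
#' @param incidents Data frame of incident records (see the bundle format in
#'   [read_scenario()]).
#' @param events Data frame with columns `event_id`, `incident_id`; every
#'   incident belongs to exactly one event.
#' @param units Data frame `unit_id`, `type`, `base_id`, `speed_profile_id`.
#' @param shifts Data frame `unit_id`, `start`, `end` (seconds since epoch),
#'   `recurrence` in `once`/`daily`/`weekly`, `weekdays` 7-character 0/1 mask
#'   (Monday first).
#' @param bases Data frame `base_id`, `lon`, `lat`, `name`, `region`.
#' @param hospitals Optional data frame `hospital_id`, `lon`, `lat`,
#'   `capabilities` (codes joined by `;`).
#' @param communities Optional data frame `community_id`, `name`, `lon`,
#'   `lat` (centroids); an attribute `"polygons"` may carry a named list of
#'   lon/lat rings for polygon assignment.
#' @param config An [ems_config()].
#' @return An object of class `ems_scenario`. Incidents are sorted by
#'   `t_call_ems`.
#' @export
ems_scenario <- function(incidents, events, units, shifts, bases,
                         hospitals = NULL, communities = NULL,
                         config = ems_config()) {
  incidents <- normalize_incidents(incidents)
  incidents <- incidents[order(incidents$t_call_ems, incidents$incident_id), ,
                         drop = FALSE]
  rownames(incidents) <- NULL
  structure(list(incidents = incidents, events = events, units = units,
                 shifts = shifts, bases = bases, hospitals = hospitals,
                 communities = communities, config = config),
            class = "ems_scenario")
}

INCIDENT_COLUMNS <- c("incident_id", "event_id", "lon", "lat", "priority",
                      "required_type", CHAIN_FIELDS, "historic_unit_id",
                      "hospital_id", "organization", "diagnosis")

# ensure all canonical columns exist with the right modes
normalize_incidents <- function(inc) {
  inc <- as.data.frame(inc, stringsAsFactors = FALSE)
  for (f in CHAIN_FIELDS) if (is.null(inc[[f]])) inc[[f]] <- NA_real_
  for (f in c("historic_unit_id", "hospital_id", "diagnosis")) {
    if (is.null(inc[[f]])) inc[[f]] <- NA_character_
  }
  if (is.null(inc$organization)) inc$organization <- "own"
  if (is.null(inc$event_id)) inc$event_id <- inc$incident_id
  inc$incident_id <- as.character(inc$incident_id)
  inc$event_id <- as.character(inc$event_id)
  inc[, INCIDENT_COLUMNS, drop = FALSE]
}

#' @export
print.ems_scenario <- function(x, ...) {
  cat("EMS scenario\n")
  cat(sprintf("  incidents : %d (%d events)\n", nrow(x$incidents),
              length(unique(x$events$event_id))))
  cat(sprintf("  units     : %d at %d bases, %d shift rows\n",
              nrow(x$units), nrow(x$bases), nrow(x$shifts)))
  cat(sprintf("  hospitals : %s\n",
              if (is.null(x$hospitals)) "none" else nrow(x$hospitals)))
  cat(sprintf("  MART %g min, target %g%%, RT variant %s\n",
              x$config$mart, x$config$martcr_target, x$config$rt_variant))
  invisible(x)
}

violation <- function(entity, id, field, rule, message) {
  data.frame(entity = entity, id = as.character(id), field = field,
             rule = rule, message = message, stringsAsFactors = FALSE)
}

no_violations <- function() {
  data.frame(entity = character(0), id = character(0), field = character(0),
             rule = character(0), message = character(0),
             stringsAsFactors = FALSE)
}

#' Validate a scenario
#'
#' Checks every structural invariant of the scenario bundle: coordinate
#' ranges, closed priority/unit-type enumerations, the event-sequence
#' ordering of each timestamp chain, identifier uniqueness and referential
#' integrity, the event partition, shift validity and configuration ranges.
#' Violations are returned as data, never raised.
#'
#' @param s An `ems_scenario`.
#' @param roster_resolution Roster grid in seconds (default 900 = 15 min).
#' @return A data frame with columns `entity`, `id`, `field`, `rule`,
#'   `message`; zero rows iff the scenario is valid.
#' @export
validate_scenario <- function(s, roster_resolution = 900) {
  v <- list()
  inc <- s$incidents
  if (nrow(inc) > 0) {
    bad <- which(is.na(inc$lon) | is.na(inc$lat) |
                   inc$lon < -180 | inc$lon > 180 |
                   inc$lat < -90 | inc$lat > 90)
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("incident", inc$incident_id[i], "lon/lat",
                                       "geo_range", "coordinates outside WGS84 range")
    }
    bad <- which(!(inc$priority %in% PRIORITY_CODES))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("incident", inc$incident_id[i], "priority",
                                       "priority_code",
                                       paste0("unknown priority '", inc$priority[i], "'"))
    }
    bad <- which(!(inc$required_type %in% UNIT_TYPES))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("incident", inc$incident_id[i], "required_type",
                                       "unit_type_code",
                                       paste0("unknown unit type '", inc$required_type[i], "'"))
    }
    dup <- inc$incident_id[duplicated(inc$incident_id)]
    for (d in unique(dup)) {
      v[[length(v) + 1L]] <- violation("incident", d, "incident_id",
                                       "unique_id", "duplicated incident_id")
    }
    # chain ordering over present fields
    ord <- chain_order_ok(inc)
    for (i in which(!ord)) {
      v[[length(v) + 1L]] <- violation("incident", inc$incident_id[i], "times",
                                       "chain_order",
                                       "timestamps violate the event-sequence ordering")
    }
    if (is.unsorted(inc$t_call_ems, na.rm = TRUE)) {
      v[[length(v) + 1L]] <- violation("scenario", "", "incidents", "sorted",
                                       "incidents not sorted by t_call_ems")
    }
    # referential: historic units / hospitals / events
    known_units <- s$units$unit_id
    bad <- which(!is.na(inc$historic_unit_id) &
                   !(inc$historic_unit_id %in% known_units))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("incident", inc$incident_id[i],
                                       "historic_unit_id", "ref_integrity",
                                       paste0("unknown unit '", inc$historic_unit_id[i], "'"))
    }
    if (!is.null(s$hospitals)) {
      bad <- which(!is.na(inc$hospital_id) &
                     !(inc$hospital_id %in% s$hospitals$hospital_id))
      for (i in bad) {
        v[[length(v) + 1L]] <- violation("incident", inc$incident_id[i],
                                         "hospital_id", "ref_integrity",
                                         paste0("unknown hospital '", inc$hospital_id[i], "'"))
      }
    }
  }
  ev <- s$events
  if (!is.null(ev) && nrow(ev) > 0) {
    dup <- ev$incident_id[duplicated(ev$incident_id)]
    for (d in unique(dup)) {
      v[[length(v) + 1L]] <- violation("event", d, "incident_id", "partition",
                                       "incident assigned to more than one event group")
    }
    missing <- setdiff(inc$incident_id, ev$incident_id)
    for (d in missing) {
      v[[length(v) + 1L]] <- violation("event", d, "incident_id", "partition",
                                       "incident missing from every event group")
    }
    orphan <- setdiff(ev$incident_id, inc$incident_id)
    for (d in orphan) {
      v[[length(v) + 1L]] <- violation("event", d, "incident_id", "ref_integrity",
                                       "event group references unknown incident")
    }
  } else if (nrow(inc) > 0) {
    v[[length(v) + 1L]] <- violation("scenario", "", "events", "partition",
                                     "no event groups present")
  }
  if (!is.null(s$bases)) {
    dup <- s$bases$base_id[duplicated(s$bases$base_id)]
    for (d in unique(dup)) {
      v[[length(v) + 1L]] <- violation("base", d, "base_id", "unique_id",
                                       "duplicated base_id")
    }
  }
  if (!is.null(s$units) && nrow(s$units) > 0) {
    bad <- which(!(s$units$base_id %in% s$bases$base_id))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("unit", s$units$unit_id[i], "base_id",
                                       "ref_integrity",
                                       paste0("unit '", s$units$unit_id[i],
                                              "' references unknown base '",
                                              s$units$base_id[i], "'"))
    }
    bad <- which(!(s$units$type %in% UNIT_TYPES))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("unit", s$units$unit_id[i], "type",
                                       "unit_type_code",
                                       paste0("unknown unit type '", s$units$type[i], "'"))
    }
  }
  sh <- s$shifts
  if (!is.null(sh) && nrow(sh) > 0) {
    bad <- which(!(sh$unit_id %in% s$units$unit_id))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("shift", sh$unit_id[i], "unit_id",
                                       "ref_integrity",
                                       paste0("shift references unknown unit '",
                                              sh$unit_id[i], "'"))
    }
    bad <- which(!(sh$end > sh$start))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("shift", sh$unit_id[i], "start/end",
                                       "shift_order", "shift end not after start")
    }
    bad <- which(((sh$end - sh$start) %% roster_resolution) != 0)
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("shift", sh$unit_id[i], "start/end",
                                       "roster_grid",
                                       "shift duration not a multiple of the roster resolution")
    }
    bad <- which(!(sh$recurrence %in% c("once", "daily", "weekly")))
    for (i in bad) {
      v[[length(v) + 1L]] <- violation("shift", sh$unit_id[i], "recurrence",
                                       "recurrence_code", "unknown recurrence")
    }
  }
  if (!is.null(s$hospitals) && nrow(s$hospitals) > 0) {
    caps <- strsplit(as.character(s$hospitals$capabilities), ";", fixed = TRUE)
    for (i in seq_along(caps)) {
      ci <- trimws(caps[[i]])
      ci <- ci[nzchar(ci)]
      if (length(ci) == 0) {
        v[[length(v) + 1L]] <- violation("hospital", s$hospitals$hospital_id[i],
                                         "capabilities", "nonempty",
                                         "hospital has an empty capability set")
      } else if (!all(ci %in% TRACER_CODES)) {
        v[[length(v) + 1L]] <- violation("hospital", s$hospitals$hospital_id[i],
                                         "capabilities", "capability_code",
                                         "unknown capability code")
      }
    }
  }
  cfg <- s$config
  if (!inherits(cfg, "ems_config")) {
    v[[length(v) + 1L]] <- violation("config", "", "config", "type",
                                     "config is not an ems_config")
  }
  if (length(v) == 0) no_violations() else do.call(rbind, v)
}

# TRUE per row iff present chain fields are non-decreasing in CHAIN_FIELDS order
chain_order_ok <- function(inc) {
  m <- as.matrix(inc[, CHAIN_FIELDS, drop = FALSE])
  apply(m, 1, function(r) {
    r <- r[!is.na(r)]
    length(r) < 2L || !is.unsorted(r)
  })
}
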