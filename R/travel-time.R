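# Travel-time model: effective unit-type- and priority-specific speeds on
# great-circle distances with a detour factor for ground vehicles, a fixed
# takeoff/landing overhead for air units, and a pluggable external routing
# backend.

#' Speed profile
#'
#' An effective-speed model per (unit type, priority). Ground travel time is
#' great-circle distance times a detour factor divided by the effective
#' speed; air travel is straight-line plus a fixed takeoff/landing overhead.
#' The published speed parameters of operational road networks are
#' confidential, so these profiles are configuration, not constants; every
#' KPI report records the profile used.
#'
#' @param profile_id Identifier referenced by units.
#' @param mode `"GROUND"` or `"AIR"`.
#' @param speeds Numeric matrix of effective speeds in km/h, rows = unit
#'   types, columns = priority codes.
#' @param detour_factor Road-network detour multiplier on the great-circle
#'   distance (ground only, >= 1; default 1.3).
#' @param overhead_min Fixed minutes added to every trip (air: takeoff plus
#'   landing; ground default 0).
#' @param backend_scale Named multiplier per priority applied to durations
#'   returned by an external routing backend (models the speed-up of an EMS
#'   unit with traffic privileges over civilian traffic).
#' @return An object of class `ems_speed_profile`.
#' @export
speed_profile <- function(profile_id = "ground_default",
                          mode = c("GROUND", "AIR"),
                          speeds = default_speed_matrix(),
                          detour_factor = 1.3, overhead_min = 0,
                          backend_scale = default_backend_scale()) {
  mode <- match.arg(mode)
  stopifnot(all(is.na(speeds) | speeds > 0), detour_factor >= 1,
            overhead_min >= 0)
  if (mode == "AIR") detour_factor <- 1
  structure(list(profile_id = profile_id, mode = mode, speeds = speeds,
                 detour_factor = detour_factor, overhead_min = overhead_min,
                 backend_scale = backend_scale),
            class = "ems_speed_profile")
}

# Default ground speeds: P1 62 km/h for ambulances, 70 km/h for PEP cars;
# non-privileged priorities at 0.85 of the P1 speed.
default_speed_matrix <- function() {
  base <- c(AMBULANCE = 62, TRANSPORT = 55, PEP_CAR = 70, HELICOPTER = 200,
            MCO = 80, FIRST_RESPONDER = 55)
  factor <- c(P1 = 1, P2 = 0.85, P3 = 0.85, S1 = 1, S2 = 0.85, S3 = 0.85)
  outer(base, factor)
}

default_backend_scale <- function() {
  c(P1 = 0.8, P2 = 1, P3 = 1, S1 = 0.8, S2 = 1, S3 = 1)
}

#' @rdname speed_profile
#' @export
default_profiles <- function() {
  air_speeds <- default_speed_matrix()
  air_speeds[!(rownames(air_speeds) %in% c("HELICOPTER", "MCO")), ] <- NA
  list(
    ground_default = speed_profile("ground_default", "GROUND"),
    air_default = speed_profile("air_default", "AIR", speeds = air_speeds,
                                overhead_min = 2)
  )
}

#' Great-circle distance
#'
#' Haversine distance on a sphere of mean Earth radius 6371.0 km.
#'
#' @param lon1,lat1,lon2,lat2 Coordinates in degrees WGS84 (vectorized).
#' @return Distance in km.
#' @export
haversine_km <- function(lon1, lat1, lon2, lat2) {
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2),
                           r = 6371000) / 1000
}

#' Travel time between two points
#'
#' With the default (closed-form) backend:
#' `distance_km * detour_factor / effective_speed * 60 + overhead_min`.
#' With an external routing backend, the backend's duration is scaled by the
#' profile's priority-specific factor and the overhead added.
#'
#' @param o_lon,o_lat,d_lon,d_lat Origin and destination (degrees, vectorized).
#' @param unit_type One of the unit-type codes.
#' @param priority One of the priority codes.
#' @param profile An [speed_profile()].
#' @param backend `NULL` for the closed form, or a function
#'   `(o_lon, o_lat, d_lon, d_lat) -> minutes` (e.g. an OSRM table client).
#' @param fallback When `TRUE` a failing backend falls back to the closed
#'   form with a warning instead of an error.
#' @return Travel time in minutes (>= 0; equals `overhead_min` when origin
#'   and destination coincide).
#' @export
travel_minutes <- function(o_lon, o_lat, d_lon, d_lat, unit_type, priority,
                           profile, backend = NULL, fallback = FALSE) {
  stopifnot(inherits(profile, "ems_speed_profile"))
  if (!is.null(backend)) {
    mins <- tryCatch(backend(o_lon, o_lat, d_lon, d_lat), error = function(e) {
      if (!isTRUE(fallback)) stop("routing backend failed: ",
                                  conditionMessage(e))
      warning("routing backend failed (", conditionMessage(e),
              "); falling back to the closed-form model")
      NULL
    })
    if (!is.null(mins)) {
      scale <- profile$backend_scale[[priority]] %||% 1
      return(mins * scale + profile$overhead_min)
    }
  }
  speed <- profile$speeds[unit_type, priority]
  if (is.na(speed)) {
    stop("speed profile '", profile$profile_id, "' has no entry for (",
         unit_type, ", ", priority, ")")
  }
  km <- haversine_km(o_lon, o_lat, d_lon, d_lat)
  km * profile$detour_factor / speed * 60 + profile$overhead_min
}

#' Isochrone band assignment
#'
#' Assigns each point the first travel-time band whose upper bound is at
#' least its travel time from the origin; bands are half-open with an
#' inclusive upper bound, and points beyond the last threshold are
#' `"OUTSIDE"`. The default thresholds reproduce the 0-6, 6-9, 9-12 and
#' 12-15 min reporting bands.
#'
#' @param o_lon,o_lat Origin.
#' @param lon,lat Points to classify.
#' @param thresholds_min Strictly increasing band upper bounds in minutes.
#' @inheritParams travel_minutes
#' @return Factor of band labels (`"0-6"`, `"6-9"`, ..., `"OUTSIDE"`).
#' @export
isochrone_bands <- function(o_lon, o_lat, lon, lat,
                            thresholds_min = c(6, 9, 12, 15),
                            unit_type = "AMBULANCE", priority = "P1",
                            profile = default_profiles()$ground_default,
                            backend = NULL) {
  if (length(thresholds_min) == 0) stop("empty thresholds")
  if (is.unsorted(thresholds_min, strictly = TRUE)) {
    stop("thresholds must be strictly increasing")
  }
  mins <- travel_minutes(o_lon, o_lat, lon, lat, unit_type, priority,
                         profile, backend)
  labels <- c(paste(c(0, utils::head(thresholds_min, -1)), thresholds_min,
                    sep = "-"), "OUTSIDE")
  # round away sub-nanominute float noise so a point exactly on a threshold
  # lands in the lower band (upper bounds are inclusive)
  idx <- findInterval(round(mins, 9), thresholds_min, left.open = TRUE) + 1L
  factor(labels[idx], levels = labels)
}

#' Static coverage
#'
#' Percentage of demand points whose minimum travel time over all bases is
#' within the maximum allowed response time. This is the static counterpart
#' of the unlimited-resources simulation: it ignores rosters and turnout.
#'
#' @param lon,lat Demand points.
#' @param bases Data frame with `lon`, `lat`.
#' @param mart Maximum allowed response time in minutes (default 15).
#' @inheritParams travel_minutes
#' @return Coverage percent in `[0, 100]`.
#' @export
static_coverage <- function(lon, lat, bases, mart = 15,
                            unit_type = "AMBULANCE", priority = "P1",
                            profile = default_profiles()$ground_default,
                            backend = NULL) {
  if (length(lon) == 0) stop("empty point set")
  if (nrow(bases) == 0) stop("at least one base required")
  best <- rep(Inf, length(lon))
  for (b in seq_len(nrow(bases))) {
    m <- travel_minutes(bases$lon[b], bases$lat[b], lon, lat, unit_type,
                        priority, profile, backend)
    best <- pmin(best, m)
  }
  100 * mean(best <= mart)
}
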