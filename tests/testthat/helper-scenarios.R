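# Deterministic fixture builders. Engine-level fixtures use a flat 60 km/h
# profile with detour factor 1 and zero-dispersion service times, so travel
# minutes equal straight-line km and every timeline is closed-form.

KM_PER_DEG_LAT <- 6371 * pi / 180 # consistent with haversine on R = 6371 km

flat60_speeds <- function() {
  types <- c("AMBULANCE", "TRANSPORT", "PEP_CAR", "HELICOPTER", "MCO",
             "FIRST_RESPONDER")
  prios <- c("P1", "P2", "P3", "S1", "S2", "S3")
  matrix(60, nrow = length(types), ncol = length(prios),
         dimnames = list(types, prios))
}

test_profiles <- function() {
  list(
    ground_default = speed_profile("ground_default", "GROUND",
                                   speeds = flat60_speeds(),
                                   detour_factor = 1, overhead_min = 0),
    air_default = speed_profile("air_default", "AIR",
                                speeds = flat60_speeds(), overhead_min = 0)
  )
}

zero_noise_times <- function() {
  list(replay = FALSE,
       turnout_median_min = 1, turnout_sigma = 0,
       on_scene_median_min = 10, on_scene_sigma = 0,
       handover_median_min = 5, handover_sigma = 0,
       transport_median_min = 8, transport_sigma = 0)
}

test_config <- function(..., horizon = c(0, 2 * 86400)) {
  ems_config(service_times = zero_noise_times(), profiles = test_profiles(),
             horizon = horizon, ...)
}

# point `km` kilometres north of (lon0, lat0)
pt_north <- function(lat0, km) lat0 + km / KM_PER_DEG_LAT

# incident row builder; t_call in minutes since epoch, dist_km north of base
h_incident <- function(id, t_call_min, dist_km, priority = "P1",
                       base_lon = 8.5, base_lat = 47.4, event_id = id,
                       required_type = "AMBULANCE",
                       historic_unit_id = NA_character_,
                       transport = FALSE, diagnosis = NA_character_) {
  data.frame(incident_id = id, event_id = event_id,
             lon = base_lon, lat = pt_north(base_lat, dist_km),
             priority = priority, required_type = required_type,
             t_call_ems = t_call_min * 60,
             historic_unit_id = historic_unit_id,
             # sentinel hospital reference marks a transport when no
             # hospital table is attached
             hospital_id = if (transport) "MODEL" else NA_character_,
             diagnosis = diagnosis,
             organization = "own", stringsAsFactors = FALSE)
}

# scenario with one base and n always-on ambulances; incidents from rows
h_scenario <- function(incidents, n_units = 1, config = test_config(),
                       unit_type = "AMBULANCE", hospitals = NULL,
                       base_lon = 8.5, base_lat = 47.4,
                       shift_windows = NULL) {
  bases <- data.frame(base_id = "B1", lon = base_lon, lat = base_lat,
                      name = "Base 1", region = "own",
                      stringsAsFactors = FALSE)
  units <- data.frame(unit_id = sprintf("U%02d", seq_len(n_units)),
                      type = unit_type, base_id = "B1",
                      speed_profile_id = if (unit_type %in% c("MCO", "HELICOPTER"))
                        "air_default" else "ground_default",
                      stringsAsFactors = FALSE)
  if (is.null(shift_windows)) {
    shifts <- data.frame(unit_id = units$unit_id, start = config$horizon[1],
                         end = config$horizon[2], recurrence = "once",
                         weekdays = "1111111", stringsAsFactors = FALSE)
  } else {
    shifts <- do.call(rbind, lapply(seq_len(n_units), function(k) {
      w <- shift_windows[[((k - 1) %% length(shift_windows)) + 1]]
      data.frame(unit_id = units$unit_id[k], start = w[1], end = w[2],
                 recurrence = "daily", weekdays = "1111111",
                 stringsAsFactors = FALSE)
    }))
  }
  events <- data.frame(event_id = incidents$event_id,
                       incident_id = incidents$incident_id,
                       stringsAsFactors = FALSE)
  ems_scenario(incidents, events, units, shifts, bases, hospitals,
               config = config)
}

# random compact scenario for the oracle-equivalence and upper-bound sweeps:
# <= 8 ambulances at <= 3 bases, <= 60 incidents over one day, mixed
# priorities, historic unit references, some transports, a mix of always-on
# and day-only shifts; zero-dispersion service times keep it re-derivable.
rand_mini_scenario <- function(seed) {
  set.seed(seed)
  n_bases <- sample(1:3, 1)
  bases <- data.frame(base_id = paste0("B", seq_len(n_bases)),
                      lon = 8.4 + stats::runif(n_bases, 0, 0.3),
                      lat = 47.3 + stats::runif(n_bases, 0, 0.2),
                      name = paste("Base", seq_len(n_bases)), region = "own",
                      stringsAsFactors = FALSE)
  n_units <- sample(2:8, 1)
  units <- data.frame(unit_id = sprintf("U%02d", seq_len(n_units)),
                      type = "AMBULANCE",
                      base_id = sample(bases$base_id, n_units, replace = TRUE),
                      speed_profile_id = "ground_default",
                      stringsAsFactors = FALSE)
  day_only <- stats::runif(n_units) < 0.3
  shifts <- data.frame(unit_id = units$unit_id,
                       start = ifelse(day_only, 7 * 3600, 0),
                       end = ifelse(day_only, 19 * 3600, 86400),
                       recurrence = "once", weekdays = "1111111",
                       stringsAsFactors = FALSE)
  n <- sample(10:60, 1)
  prio <- sample(c("P1", "P2", "P3", "S1", "S2", "S3"), n, replace = TRUE,
                 prob = c(.25, .35, .1, .05, .1, .15))
  hist_ok <- stats::runif(n) < 0.8
  inc <- data.frame(
    incident_id = sprintf("I%03d", seq_len(n)),
    event_id = sprintf("E%03d", seq_len(n)),
    lon = 8.4 + stats::runif(n, 0, 0.3),
    lat = 47.3 + stats::runif(n, 0, 0.2),
    priority = prio, required_type = "AMBULANCE",
    t_call_ems = sort(round(stats::runif(n, 0, 86000))),
    historic_unit_id = ifelse(hist_ok, sample(units$unit_id, n, replace = TRUE),
                              NA_character_),
    hospital_id = ifelse(stats::runif(n) < 0.4, "MODEL", NA_character_),
    organization = "own", stringsAsFactors = FALSE)
  events <- data.frame(event_id = inc$event_id, incident_id = inc$incident_id,
                       stringsAsFactors = FALSE)
  ems_scenario(inc, events, units, shifts, bases, hospitals = NULL,
               config = test_config(seed = seed, horizon = c(0, 86400 * 2)))
}

# the four-incident event fixture: first call at 0, arrivals at 9/8/14/12
# minutes; staggered unit-call times so the variants differ
fig2_event_chains <- function() {
  data.frame(
    incident_id = paste0("I", 1:4),
    t_call_dispatch = c(-60, -60, -60, -60),
    t_call_ems = c(0, 60, 120, 180),
    t_depart_base = c(120, 150, 300, 360),
    t_arrive_scene = c(9, 8, 14, 12) * 60,
    t_depart_scene = NA_real_, t_arrive_hospital = NA_real_,
    t_free = NA_real_, t_arrive_base = NA_real_,
    stringsAsFactors = FALSE)
}

# Reserve-capacity textbook cases (1-day horizon, one always-on ambulance).
# A: two simultaneous pairs during the day -> one added day unit reaches the
#    target. B: all incidents beyond the MART radius -> no addition helps.
# C: pairs day and night -> two additions (day, then night) reach the target.
capacity_case <- function(which = c("A", "B", "C")) {
  which <- match.arg(which)
  cfg <- test_config(horizon = c(0, 86400))
  pair <- function(hh, km, tag) {
    rbind(h_incident(sprintf("%sa", tag), hh * 60, km),
          h_incident(sprintf("%sb", tag), hh * 60, km))
  }
  inc <- switch(which,
    A = rbind(pair(10, 5, "PA"), pair(14, 5, "PB"),
              do.call(rbind, lapply(c(8, 9, 12, 16, 17, 18), function(h) {
                h_incident(sprintf("S%02d", h), h * 60, 5)
              }))),
    B = do.call(rbind, lapply(c(8, 10, 12, 14), function(h) {
      h_incident(sprintf("R%02d", h), h * 60, 20)
    })),
    C = rbind(pair(2, 5, "PN1"), pair(10, 5, "PD1"),
              pair(14, 5, "PD2"), pair(22, 5, "PN2")))
  h_scenario(inc, n_units = 1, config = cfg)
}
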