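# Synthetic scenarios with the statistical structure the simulator assumes:
# a non-homogeneous Poisson demand with a quarter-hour daily shape, an
# urban-cluster + rural-background spatial mixture, a configurable priority
# mix, lognormal service times and day/night rosters. Stands in for
# confidential dispatch-center data; never calibrated to any real region.

#' Default quarter-hour demand shape
#'
#' 96 relative weights (sum 1): low overnight, rising after 06:00, a broad
#' daytime plateau and an evening decline. A qualitative, generic urban
#' demand shape -- shipped as data, not behaviour, so studies can replace it.
#'
#' @return Numeric vector of length 96 summing to 1.
#' @export
default_demand_curve <- function() {
  hourly <- c(0.40, 0.35, 0.30, 0.30, 0.35, 0.45, # 00-05
              0.70, 1.00, 1.30, 1.50, 1.60, 1.65, # 06-11
              1.60, 1.55, 1.55, 1.60, 1.60, 1.55, # 12-17
              1.45, 1.30, 1.10, 0.90, 0.70, 0.55) # 18-23
  w <- rep(hourly, each = 4)
  w / sum(w)
}

#' Synthetic-scenario configuration
#'
#' @param horizon_days Length of the generated period in days.
#' @param annual_volume Expected incidents per 365 days (default 20,000, a
#'   typical one-organization volume).
#' @param demand_curve 96 relative quarter-hour weights.
#' @param weekend_scale Multiplier on Saturday/Sunday demand (default 1:
#'   weekday/weekend differences are typically not visible).
#' @param spatial_mixture List of urban clusters `list(lon, lat, sd_km,
#'   weight)`; remaining weight is uniform rural background over `bbox`.
#' @param bbox Study area `c(lon_min, lat_min, lon_max, lat_max)`.
#' @param priority_mix Named probabilities over the six priority codes.
#' @param pep_fraction Fraction of P1 incidents that additionally require a
#'   prehospital emergency physician fleet type (kept 0 by default: the
#'   default fleet is ambulances only).
#' @param transport_fraction Probability that a primary (P) incident ends
#'   in a hospital transport; secondary (S) incidents always transport.
#' @param service_times As in [ems_config()].
#' @param n_bases Number of bases (placed at cluster centres first, then on
#'   a grid).
#' @param units_per_base_day,units_per_base_night Ambulances staffed on the
#'   12-h day (07:00-19:00) and night (19:00-07:00) shift per base.
#' @param n_hospitals Hospitals (0 disables the hospital table).
#' @param event_multiplicity Probabilities that one emergency triggers 1, 2
#'   or 3 incidents.
#' @param seed Generator seed.
#' @param config Simulation config used to complete the historical chains.
#' @return An object of class `ems_synth_config`.
#' @export
synth_config <- function(horizon_days = 7, annual_volume = 20000,
                         demand_curve = default_demand_curve(),
                         weekend_scale = 1,
                         spatial_mixture = list(
                           list(lon = 8.55, lat = 47.40, sd_km = 3, weight = 0.45),
                           list(lon = 8.75, lat = 47.50, sd_km = 2, weight = 0.25)),
                         bbox = c(8.45, 47.32, 8.85, 47.58),
                         priority_mix = c(P1 = 0.25, P2 = 0.35, P3 = 0.10,
                                          S1 = 0.05, S2 = 0.10, S3 = 0.15),
                         pep_fraction = 0,
                         transport_fraction = 0.7,
                         service_times = default_service_times(),
                         n_bases = 4,
                         units_per_base_day = 2, units_per_base_night = 2,
                         n_hospitals = 2,
                         event_multiplicity = c(0.93, 0.06, 0.01),
                         seed = 1L, config = NULL) {
  stopifnot(length(demand_curve) == 96, all(demand_curve >= 0),
            abs(sum(priority_mix) - 1) < 1e-6,
            abs(sum(event_multiplicity) - 1) < 1e-6,
            horizon_days >= 1, annual_volume > 0, n_bases >= 1)
  structure(list(horizon_days = horizon_days, annual_volume = annual_volume,
                 demand_curve = demand_curve / sum(demand_curve),
                 weekend_scale = weekend_scale,
                 spatial_mixture = spatial_mixture, bbox = bbox,
                 priority_mix = priority_mix, pep_fraction = pep_fraction,
                 transport_fraction = transport_fraction,
                 service_times = service_times, n_bases = n_bases,
                 units_per_base_day = units_per_base_day,
                 units_per_base_night = units_per_base_night,
                 n_hospitals = n_hospitals,
                 event_multiplicity = event_multiplicity,
                 seed = as.integer(seed), config = config),
            class = "ems_synth_config")
}

#' Generate a synthetic scenario
#'
#' Call times come from a non-homogeneous Poisson process with quarter-hour
#' piecewise-constant intensity proportional to the demand curve, scaled so
#' the expected count is `horizon_days / 365 * annual_volume` (times the
#' weekend scale on weekends). Locations are drawn from the urban-cluster /
#' rural-background mixture, priorities and multiplicities from their
#' mixes. The historical timestamp chains and historic unit assignments are
#' then completed by running the DES once on the generated inputs, so the
#' "historical" data are internally consistent with the travel model.
#' Deterministic per seed.
#'
#' @param cfg An [synth_config()].
#' @return A validated `ems_scenario`.
#' @export
gen_scenario <- function(cfg) {
  stopifnot(inherits(cfg, "ems_synth_config"))
  if (cfg$n_bases < 1) stop("infeasible config: no bases")
  set.seed(cfg$seed)
  day <- 86400
  horizon <- c(0, cfg$horizon_days * day)

  # --- arrival times: NHPP, quarter-hour piecewise-constant intensity
  times <- list()
  for (d in seq_len(cfg$horizon_days) - 1L) {
    wd <- d %% 7
    scale <- if (wd >= 5) cfg$weekend_scale else 1
    lam <- cfg$annual_volume / 365 * scale * cfg$demand_curve
    counts <- stats::rpois(96, lam)
    for (b in which(counts > 0)) {
      times[[length(times) + 1L]] <-
        d * day + (b - 1L) * 900 + stats::runif(counts[b], 0, 900)
    }
  }
  t_call <- sort(unlist(times) %||% numeric(0))
  n_events <- length(t_call)
  if (n_events == 0) stop("generated zero incidents; enlarge the horizon or volume")

  # --- event multiplicity (one emergency may trigger several incidents)
  mult <- sample.int(3, n_events, replace = TRUE, prob = cfg$event_multiplicity)
  event_id <- sprintf("E%06d", seq_len(n_events))

  # --- locations: urban clusters + uniform rural background
  wts <- vapply(cfg$spatial_mixture, function(m) m$weight, numeric(1))
  bg <- max(0, 1 - sum(wts))
  comp <- sample.int(length(wts) + 1L, n_events, replace = TRUE,
                     prob = c(wts, bg))
  lat0 <- mean(cfg$bbox[c(2, 4)])
  km_per_deg_lat <- 111.19
  km_per_deg_lon <- 111.19 * cos(lat0 * pi / 180)
  lon <- lat <- numeric(n_events)
  for (k in seq_along(cfg$spatial_mixture)) {
    idx <- comp == k
    m <- cfg$spatial_mixture[[k]]
    lon[idx] <- stats::rnorm(sum(idx), m$lon, m$sd_km / km_per_deg_lon)
    lat[idx] <- stats::rnorm(sum(idx), m$lat, m$sd_km / km_per_deg_lat)
  }
  idx <- comp == length(wts) + 1L
  lon[idx] <- stats::runif(sum(idx), cfg$bbox[1], cfg$bbox[3])
  lat[idx] <- stats::runif(sum(idx), cfg$bbox[2], cfg$bbox[4])
  lon <- pmin(pmax(lon, cfg$bbox[1]), cfg$bbox[3])
  lat <- pmin(pmax(lat, cfg$bbox[2]), cfg$bbox[4])

  # --- priorities, required types, transport
  prio <- sample(names(cfg$priority_mix), n_events, replace = TRUE,
                 prob = cfg$priority_mix)
  req <- rep("AMBULANCE", n_events)
  if (cfg$pep_fraction > 0) {
    is_pep <- prio == "P1" & stats::runif(n_events) < cfg$pep_fraction
    req[is_pep] <- "PEP_CAR"
  }
  transport <- ifelse(startsWith(prio, "S"), TRUE,
                      stats::runif(n_events) < cfg$transport_fraction)
  dispatch_lag <- stats::rlnorm(n_events, log(1.0), 0.4) * 60 # call-center lag, s

  # expand events into incidents
  rep_idx <- rep.int(seq_len(n_events), mult)
  n <- length(rep_idx)
  inc <- data.frame(
    incident_id = sprintf("I%06d", seq_len(n)),
    event_id = event_id[rep_idx],
    lon = lon[rep_idx], lat = lat[rep_idx],
    priority = prio[rep_idx], required_type = req[rep_idx],
    t_call_dispatch = round(t_call[rep_idx] - dispatch_lag[rep_idx]),
    t_call_ems = round(t_call[rep_idx]) +
      (sequence(mult) - 1L) * 60, # follow-up alerts a minute apart
    organization = "own",
    stringsAsFactors = FALSE)
  is_tr <- transport[rep_idx]

  # --- bases, units, shifts
  centers <- do.call(rbind, lapply(cfg$spatial_mixture,
                                   function(m) c(m$lon, m$lat)))
  need <- cfg$n_bases - nrow(centers)
  if (need > 0) {
    g <- ceiling(sqrt(need))
    gx <- seq(cfg$bbox[1], cfg$bbox[3], length.out = g + 2)[-c(1, g + 2)]
    gy <- seq(cfg$bbox[2], cfg$bbox[4], length.out = g + 2)[-c(1, g + 2)]
    grid <- expand.grid(lon = gx, lat = gy)
    centers <- rbind(centers, as.matrix(grid[seq_len(need), ]))
  }
  centers <- centers[seq_len(cfg$n_bases), , drop = FALSE]
  bases <- data.frame(base_id = sprintf("B%02d", seq_len(cfg$n_bases)),
                      lon = centers[, 1], lat = centers[, 2],
                      name = sprintf("Base %02d", seq_len(cfg$n_bases)),
                      region = "own", stringsAsFactors = FALSE)
  units <- list(); shifts <- list()
  add_unit <- function(base_id, type, shift_name, k) {
    uid <- sprintf("U_%s_%s%d", base_id, shift_name, k)
    units[[length(units) + 1L]] <<- data.frame(
      unit_id = uid, type = type, base_id = base_id,
      speed_profile_id = if (type %in% c("HELICOPTER", "MCO")) "air_default"
      else "ground_default", stringsAsFactors = FALSE)
    win <- if (shift_name == "D") c(7, 19) * 3600 else c(19, 31) * 3600
    shifts[[length(shifts) + 1L]] <<- data.frame(
      unit_id = uid, start = win[1], end = win[2], recurrence = "daily",
      weekdays = "1111111", stringsAsFactors = FALSE)
  }
  for (b in bases$base_id) {
    for (k in seq_len(cfg$units_per_base_day)) add_unit(b, "AMBULANCE", "D", k)
    for (k in seq_len(cfg$units_per_base_night)) add_unit(b, "AMBULANCE", "N", k)
    if (cfg$pep_fraction > 0) add_unit(b, "PEP_CAR", "D", 9)
  }
  units <- do.call(rbind, units)
  shifts <- do.call(rbind, shifts)

  # --- hospitals
  hospitals <- NULL
  if (cfg$n_hospitals > 0) {
    hcenters <- centers[rep_len(seq_len(nrow(centers)), cfg$n_hospitals), ,
                        drop = FALSE]
    caps <- rep_len(c("GENERAL;STROKE;STEMI", "GENERAL;TBI;POLYTRAUMA;SCD;SEPSIS"),
                    cfg$n_hospitals)
    hospitals <- data.frame(
      hospital_id = sprintf("H%02d", seq_len(cfg$n_hospitals)),
      lon = hcenters[, 1] + 0.005, lat = hcenters[, 2] + 0.005,
      capabilities = caps, stringsAsFactors = FALSE)
  }
  # transport incidents get a placeholder hospital reference so the engine
  # treats them as transports; the concrete hospital is (re)selected by rule
  inc$hospital_id <- ifelse(is_tr & !is.null(hospitals),
                            hospitals$hospital_id[1], NA_character_)
  diagnoses <- c(NA, "STROKE", "STEMI", "TBI", "POLYTRAUMA", "SCD", "SEPSIS")
  inc$diagnosis <- sample(diagnoses, n, replace = TRUE,
                          prob = c(0.7, rep(0.3 / 6, 6)))
  inc$diagnosis[!is_tr] <- NA_character_

  events <- data.frame(event_id = inc$event_id, incident_id = inc$incident_id,
                       stringsAsFactors = FALSE)
  base_cfg <- cfg$config %||% ems_config()
  sim_cfg <- base_cfg
  sim_cfg$seed <- cfg$seed
  sim_cfg$horizon <- horizon
  sim_cfg$service_times[names(cfg$service_times)] <- cfg$service_times
  sim_cfg$service_times$replay <- FALSE

  s <- ems_scenario(inc, events, units, shifts, bases, hospitals,
                    communities = NULL, config = sim_cfg)

  # --- complete the historical chains by one engine pass
  # (the transport requirement must be visible to the engine; without a
  # hospital table transports are marked with a sentinel hospital-arrival
  # time, overwritten by the engine's service-time model below)
  if (is.null(hospitals)) {
    s$incidents$t_arrive_hospital[match(inc$incident_id[is_tr],
                                        s$incidents$incident_id)] <- Inf
  }
  sim <- simulate_scenario(s, "STANDARD")
  ord <- match(s$incidents$incident_id, sim$sim_times$incident_id)
  for (f in setdiff(CHAIN_FIELDS, c("t_call_dispatch", "t_call_ems"))) {
    # dispatch systems log at 1-s resolution; rounding keeps the ordering
    s$incidents[[f]] <- round(sim$sim_times[[f]][ord])
  }
  aord <- match(s$incidents$incident_id, sim$assignments$incident_id)
  s$incidents$historic_unit_id <- sim$assignments$unit_id[aord]
  s$incidents$hospital_id <- sim$assignments$hospital_id[aord]
  # drop incidents the generated fleet could never serve (border artefacts)
  keep <- !(s$incidents$incident_id %in% sim$unserved)
  s$incidents <- s$incidents[keep, , drop = FALSE]
  s$events <- s$events[s$events$incident_id %in% s$incidents$incident_id, ,
                       drop = FALSE]
  s$config$seed <- base_cfg$seed
  s
}

#' Inject cleaning defects
#'
#' Mutates exactly the requested number of records per defect class and
#' returns the ground-truth manifest, the oracle for cleaning tests:
#' class `i` swaps two timestamps (an ordering violation), class `ii`
#' blanks the scene-arrival time (missing response time), class `iii`
#' blanks the hospital-arrival time of a transport record (incomplete
#' chain after arrival at scene). Mutated record sets are disjoint.
#'
#' @param records Clean standardized incident records.
#' @param spec Named counts `c(i = , ii = , iii = )`.
#' @param seed RNG seed (same seed, same manifest).
#' @return List `records` (mutated copy) and `manifest` (list of
#'   incident-id vectors per class).
#' @export
inject_defects <- function(records, spec = c(i = 0, ii = 0, iii = 0), seed = 1) {
  spec <- spec[c("i", "ii", "iii")]
  spec[is.na(spec)] <- 0
  set.seed(seed)
  n <- nrow(records)
  if (sum(spec) > n) stop("requested more defects than records")
  elig_iii <- which(!is.na(records$hospital_id) &
                      !is.na(records$t_arrive_hospital))
  elig_i <- which(!is.na(records$t_depart_base) &
                    !is.na(records$t_arrive_scene) &
                    records$t_depart_base < records$t_arrive_scene)
  pick <- function(elig, k, taken) {
    elig <- setdiff(elig, taken)
    if (length(elig) < k) stop("overlapping mutations requested beyond population")
    if (k == 0) integer(0) else sample(elig, k)
  }
  taken <- integer(0)
  ids_iii <- pick(elig_iii, spec[["iii"]], taken); taken <- c(taken, ids_iii)
  ids_i <- pick(elig_i, spec[["i"]], taken); taken <- c(taken, ids_i)
  ids_ii <- pick(seq_len(n), spec[["ii"]], taken)
  out <- records
  if (length(ids_i) > 0) {
    tmp <- out$t_depart_base[ids_i]
    out$t_depart_base[ids_i] <- out$t_arrive_scene[ids_i]
    out$t_arrive_scene[ids_i] <- tmp
  }
  out$t_arrive_scene[ids_ii] <- NA_real_
  out$t_arrive_hospital[ids_iii] <- NA_real_
  list(records = out,
       manifest = list(i = records$incident_id[sort(ids_i)],
                       ii = records$incident_id[sort(ids_ii)],
                       iii = records$incident_id[sort(ids_iii)]))
}
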