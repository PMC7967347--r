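# The rule-based DES core. Incidents are stepped through in call order; at
# each decision epoch the dispatch policy picks a unit, the unit's state
# machine advances along the event sequence, and unserved incidents wait in
# a two-class priority queue that is re-evaluated whenever a unit becomes
# free or comes on shift.

#' Closest-idle selection
#'
#' Returns the candidate with the smallest ETA; ties are broken by the
#' lexicographically smallest `unit_id`. Candidates are assumed to be
#' pre-filtered for type compatibility, roster availability, cut-offs and
#' the region constraint.
#'
#' @param candidates Data frame with columns `unit_id`, `eta_min`.
#' @return The selected `unit_id`, or `NA_character_` if there is none.
#' @export
closest_idle <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NA_character_)
  ord <- order(candidates$eta_min, candidates$unit_id)
  candidates$unit_id[ord[1]]
}

#' Historic-else-closest selection
#'
#' The low-priority strategy: pick the unit that historically served the
#' incident if it is among the available candidates, otherwise fall back to
#' closest-idle.
#'
#' @param historic_unit_id Historic unit identifier (may be `NA`).
#' @param candidates As in [closest_idle()].
#' @return List with `unit_id` (or `NA`) and `policy`
#'   (`"HISTORIC"`/`"HISTORIC_FALLBACK_CLOSEST"`).
#' @export
historic_or_closest <- function(historic_unit_id, candidates) {
  if (!is.na(historic_unit_id) && !is.null(candidates) &&
      historic_unit_id %in% candidates$unit_id) {
    return(list(unit_id = historic_unit_id, policy = "HISTORIC"))
  }
  list(unit_id = closest_idle(candidates), policy = "HISTORIC_FALLBACK_CLOSEST")
}

#' Multicopter-versus-ground decision
#'
#' For an incident requiring a prehospital emergency physician (PEP), the
#' multicopter (MCO) is dispatched iff one is available, the round trip
#' base-scene-base fits its range, and its ETA beats the ground PEP (or no
#' ground PEP is available). The MCO cannot transport patients, so a
#' transport incident served by the MCO additionally needs the closest
#' ambulance.
#'
#' @param ground Candidate data frame (`unit_id`, `eta_min`) of ground PEP
#'   cars, or `NULL`.
#' @param mco Candidate data frame (`unit_id`, `eta_min`, `round_trip_km`)
#'   of multicopters, or `NULL`.
#' @param range_km MCO range in km.
#' @return List with `unit_id` (or `NA`) and `policy` (`"MCO"` or
#'   `"CLOSEST_IDLE"`).
#' @export
mco_or_ground <- function(ground, mco, range_km) {
  if (!is.null(mco) && nrow(mco) > 0) {
    mco <- mco[mco$round_trip_km <= range_km, , drop = FALSE]
  }
  mco_id <- closest_idle(mco)
  ground_id <- closest_idle(ground)
  if (!is.na(mco_id)) {
    mco_eta <- mco$eta_min[mco$unit_id == mco_id]
    if (is.na(ground_id)) return(list(unit_id = mco_id, policy = "MCO"))
    ground_eta <- ground$eta_min[ground$unit_id == ground_id]
    if (mco_eta < ground_eta) return(list(unit_id = mco_id, policy = "MCO"))
  }
  list(unit_id = ground_id, policy = "CLOSEST_IDLE")
}

#' Hospital selection by capability
#'
#' Nearest hospital (by travel time from the scene) whose capability set
#' includes the required tracer diagnosis. The way to the next
#' neurosurgical or pediatric centre may be much further than to the next
#' hospital, so a nearer but incapable hospital is skipped. When no capable
#' hospital exists (within the optional cut-off), the nearest
#' `GENERAL`-capable hospital is returned flagged `downgraded`.
#'
#' @param scene_lon,scene_lat Scene coordinates.
#' @param hospitals Hospital table or `NULL`.
#' @param capability Required tracer-diagnosis code (`NA` means `GENERAL`).
#' @param unit_type,priority,profile Travel model for the transport leg.
#' @param cutoff_min Optional travel-time cut-off for capable hospitals.
#' @return List `hospital_id`, `travel_min`, `downgraded`, or `NULL` when no
#'   hospital table is present (transport duration then comes from the
#'   service-time model).
#' @export
select_hospital <- function(scene_lon, scene_lat, hospitals,
                            capability = NA_character_,
                            unit_type = "AMBULANCE", priority = "P1",
                            profile = default_profiles()$ground_default,
                            cutoff_min = NULL) {
  if (is.null(hospitals) || nrow(hospitals) == 0) return(NULL)
  if (is.na(capability)) capability <- "GENERAL"
  eta <- travel_minutes(scene_lon, scene_lat, hospitals$lon, hospitals$lat,
                        unit_type, priority, profile)
  caps <- strsplit(as.character(hospitals$capabilities), ";", fixed = TRUE)
  capable <- vapply(caps, function(cc) capability %in% trimws(cc), logical(1))
  if (capability == "GENERAL") capable <- rep(TRUE, nrow(hospitals))
  ok <- capable
  if (!is.null(cutoff_min)) ok <- ok & eta <= cutoff_min
  if (any(ok)) {
    k <- which(ok)[order(eta[ok], hospitals$hospital_id[ok])][1]
    return(list(hospital_id = hospitals$hospital_id[k], travel_min = eta[k],
                downgraded = FALSE))
  }
  general <- vapply(caps, function(cc) "GENERAL" %in% trimws(cc), logical(1))
  if (!any(general)) return(NULL)
  k <- which(general)[order(eta[general], hospitals$hospital_id[general])][1]
  list(hospital_id = hospitals$hospital_id[k], travel_min = eta[k],
       downgraded = TRUE)
}

#' Build a simulated timestamp chain
#'
#' Deterministic arithmetic along the event sequence: dispatch, turnout,
#' travel to scene, on-scene care, an optional transport leg with handover,
#' and the return trip. The unit is free again at handover end (or at scene
#' departure for non-transport incidents) -- the crucial instant is when the
#' unit can take the next incident, not its arrival back at base.
#'
#' @param dispatch_s Decision time in seconds since epoch.
#' @param turnout_min,travel_min,on_scene_min Durations in minutes.
#' @param transport `NULL`, or a list with `travel_min` and `handover_min`.
#' @param return_min Return-trip duration in minutes.
#' @return Named numeric vector of the simulated chain fields
#'   (`t_depart_base` ... `t_arrive_base`) plus `t_free`, in seconds.
#' @export
service_timeline <- function(dispatch_s, turnout_min, travel_min,
                             on_scene_min, transport = NULL, return_min = 0) {
  depart <- dispatch_s + turnout_min * 60
  arrive <- depart + travel_min * 60
  depart_scene <- arrive + on_scene_min * 60
  if (!is.null(transport)) {
    arrive_hosp <- depart_scene + transport$travel_min * 60
    free <- arrive_hosp + transport$handover_min * 60
  } else {
    arrive_hosp <- NA_real_
    free <- depart_scene
  }
  c(t_depart_base = depart, t_arrive_scene = arrive,
    t_depart_scene = depart_scene, t_arrive_hospital = arrive_hosp,
    t_free = free, t_arrive_base = free + return_min * 60)
}

default_profile_for <- function(type, cfg) {
  id <- if (type %in% c("HELICOPTER", "MCO")) "air_default" else "ground_default"
  cfg$profiles[[id]] %||% cfg$profiles[[1]]
}

#' Run the rule-based discrete-event simulation
#'
#' Steps through all incidents in call order. In `STANDARD` mode units
#' respect rosters and availability, high-priority incidents are dispatched
#' closest-idle, low-priority incidents historic-else-closest, PEP demands
#' use the multicopter rule when an MCO is in the fleet, and incidents with
#' no available unit wait in a two-class priority queue (high before low,
#' FIFO within class) re-evaluated whenever a unit becomes free or comes on
#' shift. In `UNLIMITED` mode every incident is served immediately by a
#' fresh unit of the required type from its best base, so no queueing
#' occurs; the resulting compliance rate is the upper bound attainable by
#' roster changes at the given bases.
#'
#' The run is deterministic given (scenario, config, seed): all stochastic
#' service durations are pre-drawn indexed by incident, so the same incident
#' receives the same draws in both modes and in fleet variants.
#'
#' @param s A validated `ems_scenario`.
#' @param mode `"STANDARD"` or `"UNLIMITED"`.
#' @return An `ems_sim_result`: `assignments` (one final decision per
#'   incident with policy, ETA, queue delay), `sim_times` (simulated
#'   timestamp chains), `queue_log`, `timelines`, `mode`, `seed`, `config`.
#' @export
simulate_scenario <- function(s, mode = c("STANDARD", "UNLIMITED")) {
  mode <- match.arg(toupper(mode[1]), c("STANDARD", "UNLIMITED"))
  v <- validate_scenario(s)
  if (nrow(v) > 0) {
    stop("scenario is invalid (", nrow(v), " violation(s)); see validate_scenario()")
  }
  cfg <- s$config
  inc <- s$incidents
  n <- nrow(inc)
  horizon <- cfg$horizon %||% default_horizon(inc)
  timelines <- expand_rosters(s$shifts, horizon)

  draws <- draw_service_times(inc, cfg)
  is_transport <- !is.na(inc$hospital_id) | !is.na(inc$t_arrive_hospital)

  if (mode == "UNLIMITED") {
    res <- simulate_unlimited(s, cfg, inc, draws, is_transport)
  } else {
    res <- simulate_standard(s, cfg, inc, draws, is_transport, timelines,
                             horizon)
  }
  structure(c(res, list(timelines = timelines, horizon = horizon,
                        mode = mode, seed = cfg$seed, config = cfg)),
            class = "ems_sim_result")
}

default_horizon <- function(inc) {
  if (nrow(inc) == 0) return(c(0, 86400))
  hi <- max(inc$t_free, inc$t_call_ems, na.rm = TRUE)
  c(min(inc$t_call_ems) - 3600, hi + 86400)
}

# Pre-draw all per-incident service durations (minutes), indexed by incident
# order, from the config seed. replay = TRUE substitutes historical durations
# where the historical chain provides them.
draw_service_times <- function(inc, cfg) {
  n <- nrow(inc)
  st <- cfg$service_times
  set.seed(cfg$seed)
  lognorm <- function(med, sig) {
    if (is.null(sig) || sig <= 0) rep(med, n) else stats::rlnorm(n, log(med), sig)
  }
  d <- data.frame(
    turnout = lognorm(st$turnout_median_min, st$turnout_sigma),
    on_scene = lognorm(st$on_scene_median_min, st$on_scene_sigma),
    handover = lognorm(st$handover_median_min, st$handover_sigma),
    transport = lognorm(st$transport_median_min, st$transport_sigma)
  )
  if (isTRUE(st$replay) && n > 0) {
    sub <- function(model, hist) ifelse(!is.na(hist) & hist >= 0, hist, model)
    d$turnout <- sub(d$turnout, (inc$t_depart_base - inc$t_call_ems) / 60)
    d$on_scene <- sub(d$on_scene, (inc$t_depart_scene - inc$t_arrive_scene) / 60)
    d$handover <- sub(d$handover, (inc$t_free - inc$t_arrive_hospital) / 60)
    d$transport <- sub(d$transport, (inc$t_arrive_hospital - inc$t_depart_scene) / 60)
  }
  d
}

empty_chain_matrix <- function(n) {
  m <- matrix(NA_real_, nrow = n, ncol = length(CHAIN_FIELDS),
              dimnames = list(NULL, CHAIN_FIELDS))
  m
}

sim_times_df <- function(inc, chains) {
  cbind(data.frame(incident_id = inc$incident_id, stringsAsFactors = FALSE),
        as.data.frame(chains))
}

transport_leg <- function(s, cfg, inc, i, unit_type, transport_draw) {
  hosp <- select_hospital(inc$lon[i], inc$lat[i], s$hospitals,
                          inc$diagnosis[i], unit_type, inc$priority[i],
                          default_profile_for(unit_type, cfg),
                          cutoff_min = cfg$cutoff_min)
  if (is.null(hosp)) {
    list(hospital_id = NA_character_, travel_min = transport_draw,
         end_lon = inc$lon[i], end_lat = inc$lat[i])
  } else {
    k <- match(hosp$hospital_id, s$hospitals$hospital_id)
    list(hospital_id = hosp$hospital_id, travel_min = hosp$travel_min,
         end_lon = s$hospitals$lon[k], end_lat = s$hospitals$lat[k])
  }
}

simulate_unlimited <- function(s, cfg, inc, draws, is_transport) {
  n <- nrow(inc)
  chains <- empty_chain_matrix(n)
  unit_id <- character(n); eta <- numeric(n); base_of <- character(n)
  hosp_id <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    type <- inc$required_type[i]
    prof <- default_profile_for(type, cfg)
    etas <- travel_minutes(s$bases$lon, s$bases$lat, inc$lon[i], inc$lat[i],
                           type, inc$priority[i], prof)
    b <- order(etas, s$bases$base_id)[1]
    eta[i] <- etas[b]
    base_of[i] <- s$bases$base_id[b]
    unit_id[i] <- paste0("virtual:", base_of[i])
    transport <- NULL
    ret_from_lon <- inc$lon[i]; ret_from_lat <- inc$lat[i]
    if (is_transport[i]) {
      leg <- transport_leg(s, cfg, inc, i, type, draws$transport[i])
      transport <- list(travel_min = leg$travel_min,
                        handover_min = draws$handover[i])
      hosp_id[i] <- leg$hospital_id
      ret_from_lon <- leg$end_lon; ret_from_lat <- leg$end_lat
    }
    ret <- travel_minutes(ret_from_lon, ret_from_lat, s$bases$lon[b],
                          s$bases$lat[b], type, "P3", prof)
    tl <- service_timeline(inc$t_call_ems[i], draws$turnout[i], eta[i],
                           draws$on_scene[i], transport, ret)
    chains[i, c("t_call_dispatch", "t_call_ems")] <-
      c(inc$t_call_dispatch[i], inc$t_call_ems[i])
    chains[i, names(tl)[names(tl) != "t_free"]] <- tl[names(tl) != "t_free"]
    chains[i, "t_free"] <- tl[["t_free"]]
  }
  assignments <- data.frame(
    incident_id = inc$incident_id, unit_id = unit_id, policy = "UNLIMITED",
    eta_min = eta, queue_delay_min = 0, t_dispatch = inc$t_call_ems,
    hospital_id = hosp_id, companion_unit_id = NA_character_,
    stringsAsFactors = FALSE)
  list(assignments = assignments, sim_times = sim_times_df(inc, chains),
       queue_log = data.frame(incident_id = character(0), enqueue = numeric(0),
                              dequeue = numeric(0)),
       unserved = character(0))
}

simulate_standard <- function(s, cfg, inc, draws, is_transport, timelines,
                              horizon) {
  n <- nrow(inc)
  units <- s$units
  nu <- nrow(units)
  bidx <- match(units$base_id, s$bases$base_id)
  u_base_lon <- s$bases$lon[bidx]; u_base_lat <- s$bases$lat[bidx]
  u_region <- s$bases$region[bidx]
  u_type <- units$type
  u_prof <- lapply(units$speed_profile_id, function(id) {
    cfg$profiles[[id]] %||% default_profile_for("AMBULANCE", cfg)
  })
  u_tl <- lapply(units$unit_id, function(id) {
    timelines[[id]] %||% matrix(numeric(0), ncol = 2)
  })
  busy_until <- rep(-Inf, nu)
  # CHAINED bookkeeping: where the unit became free and when it is back home
  free_lon <- u_base_lon; free_lat <- u_base_lat
  back_at_base <- rep(-Inf, nu)
  chained <- cfg$follow_up_mode == "CHAINED"
  has_mco <- any(u_type == "MCO")

  chains <- empty_chain_matrix(n)
  a_unit <- rep(NA_character_, n); a_policy <- rep(NA_character_, n)
  a_eta <- rep(NA_real_, n); a_qdelay <- rep(0, n)
  a_dispatch <- rep(NA_real_, n); a_hosp <- rep(NA_character_, n)
  a_companion <- rep(NA_character_, n)
  queue_log <- list()
  overtime_busy <- numeric(nu)

  shift_edges <- sort(unique(unlist(lapply(u_tl, function(m) m[, 1]))))

  unit_pos <- function(k, t) {
    if (chained && t < back_at_base[k]) c(free_lon[k], free_lat[k])
    else c(u_base_lon[k], u_base_lat[k])
  }

  candidates_of <- function(i, t, types) {
    ks <- which(u_type %in% types & busy_until <= t)
    ks <- ks[vapply(ks, function(k) in_intervals(t, u_tl[[k]]), logical(1))]
    if (cfg$enforce_regions) {
      ks <- ks[u_region[ks] == inc$organization[i]]
    }
    if (length(ks) == 0) return(NULL)
    pos <- vapply(ks, unit_pos, numeric(2), t = t)
    eta <- mapply(function(k, plon, plat) {
      travel_minutes(plon, plat, inc$lon[i], inc$lat[i], u_type[k],
                     inc$priority[i], u_prof[[k]])
    }, ks, pos[1, ], pos[2, ])
    km <- haversine_km(pos[1, ], pos[2, ], inc$lon[i], inc$lat[i])
    keep <- rep(TRUE, length(ks))
    if (!is.null(cfg$cutoff_km)) keep <- keep & km <= cfg$cutoff_km
    if (!is.null(cfg$cutoff_min)) keep <- keep & eta <= cfg$cutoff_min
    if (!any(keep)) return(NULL)
    data.frame(unit_id = units$unit_id[ks[keep]], k = ks[keep],
               eta_min = eta[keep], stringsAsFactors = FALSE)
  }

  # ever-servable check for the drain phase: a compatible unit with any shift
  compatible_types <- function(req) {
    if (req == "PEP_CAR" && has_mco) c("PEP_CAR", "MCO") else req
  }
  ever_servable <- function(i) {
    ks <- which(u_type %in% compatible_types(inc$required_type[i]))
    if (cfg$enforce_regions) ks <- ks[u_region[ks] == inc$organization[i]]
    ks <- ks[vapply(ks, function(k) nrow(u_tl[[k]]) > 0, logical(1))]
    if (length(ks) == 0) return(FALSE)
    if (!is.null(cfg$cutoff_km)) {
      km <- haversine_km(u_base_lon[ks], u_base_lat[ks], inc$lon[i], inc$lat[i])
      ks <- ks[km <= cfg$cutoff_km]
    }
    if (length(ks) > 0 && !is.null(cfg$cutoff_min)) {
      eta <- vapply(ks, function(k) {
        travel_minutes(u_base_lon[k], u_base_lat[k], inc$lon[i], inc$lat[i],
                       u_type[k], inc$priority[i], u_prof[[k]])
      }, numeric(1))
      ks <- ks[eta <= cfg$cutoff_min]
    }
    length(ks) > 0
  }

  occupy <- function(k, i, t, eta_min, transport_capable = TRUE) {
    # builds the chain for incident i served by unit k dispatched at t;
    # returns t_free. transport_capable = FALSE (MCO) skips the transport leg.
    type <- u_type[k]
    transport <- NULL
    ret_lon <- inc$lon[i]; ret_lat <- inc$lat[i]
    if (is_transport[i] && transport_capable) {
      leg <- transport_leg(s, cfg, inc, i, type, draws$transport[i])
      transport <- list(travel_min = leg$travel_min,
                        handover_min = draws$handover[i])
      a_hosp[i] <<- leg$hospital_id
      ret_lon <- leg$end_lon; ret_lat <- leg$end_lat
    }
    ret <- travel_minutes(ret_lon, ret_lat, u_base_lon[k], u_base_lat[k],
                          type, "P3", u_prof[[k]])
    tl <- service_timeline(t, draws$turnout[i], eta_min, draws$on_scene[i],
                           transport, ret)
    busy_until[k] <<- tl[["t_free"]]
    free_lon[k] <<- ret_lon; free_lat[k] <<- ret_lat
    back_at_base[k] <<- tl[["t_arrive_base"]]
    tl
  }

  record <- function(i, t, unit_row_k, unit_id, policy, eta_min) {
    a_unit[i] <<- unit_id; a_policy[i] <<- policy; a_eta[i] <<- eta_min
    a_dispatch[i] <<- t
    transport_capable <- u_type[unit_row_k] != "MCO"
    tl <- occupy(unit_row_k, i, t, eta_min, transport_capable)
    chains[i, c("t_call_dispatch", "t_call_ems")] <<-
      c(inc$t_call_dispatch[i], inc$t_call_ems[i])
    chains[i, names(tl)[names(tl) != "t_free"]] <<- tl[names(tl) != "t_free"]
    chains[i, "t_free"] <<- tl[["t_free"]]
    # an MCO cannot transport: a transport incident also gets the closest
    # ambulance as companion for the transport leg
    if (!transport_capable && is_transport[i]) {
      comp <- candidates_of(i, t, "AMBULANCE")
      if (!is.null(comp)) {
        cid <- closest_idle(comp)
        ck <- comp$k[comp$unit_id == cid]
        occupy(ck, i, t, comp$eta_min[comp$unit_id == cid], TRUE)
        a_companion[i] <<- cid
      }
    }
  }

  try_dispatch <- function(i, t) {
    req <- inc$required_type[i]
    prio <- inc$priority[i]
    if (req == "PEP_CAR" && has_mco) {
      ground <- candidates_of(i, t, "PEP_CAR")
      mco <- candidates_of(i, t, "MCO")
      if (!is.null(mco)) {
        mco$round_trip_km <- 2 * haversine_km(u_base_lon[mco$k],
                                              u_base_lat[mco$k],
                                              inc$lon[i], inc$lat[i])
      }
      dec <- mco_or_ground(ground, mco, cfg$mco$range_km %||% Inf)
      if (is.na(dec$unit_id)) return(FALSE)
      cand <- if (dec$policy == "MCO") mco else ground
      k <- cand$k[cand$unit_id == dec$unit_id]
      record(i, t, k, dec$unit_id, dec$policy,
             cand$eta_min[cand$unit_id == dec$unit_id])
      return(TRUE)
    }
    cand <- candidates_of(i, t, req)
    if (prio %in% cfg$high_priority_set) {
      uid <- closest_idle(cand)
      if (is.na(uid)) return(FALSE)
      record(i, t, cand$k[cand$unit_id == uid], uid, "CLOSEST_IDLE",
             cand$eta_min[cand$unit_id == uid])
      return(TRUE)
    }
    dec <- historic_or_closest(inc$historic_unit_id[i], cand)
    if (is.na(dec$unit_id)) return(FALSE)
    record(i, t, cand$k[cand$unit_id == dec$unit_id], dec$unit_id, dec$policy,
           cand$eta_min[cand$unit_id == dec$unit_id])
    TRUE
  }

  qhi <- integer(0); qlo <- integer(0)
  enq <- rep(NA_real_, n)

  enqueue <- function(i, t) {
    enq[i] <<- t
    if (inc$priority[i] %in% cfg$high_priority_set) qhi <<- c(qhi, i)
    else qlo <<- c(qlo, i)
  }

  serve_queue <- function(t) {
    for (i in c(qhi, qlo)) {
      if (try_dispatch(i, t)) {
        a_qdelay[i] <<- (t - inc$t_call_ems[i]) / 60
        a_policy[i] <<- paste0("QUEUED>", a_policy[i])
        queue_log[[length(queue_log) + 1L]] <<-
          data.frame(incident_id = inc$incident_id[i], enqueue = enq[i],
                     dequeue = t, stringsAsFactors = FALSE)
        qhi <<- setdiff(qhi, i); qlo <<- setdiff(qlo, i)
      }
    }
  }

  i <- 1L
  now <- -Inf
  repeat {
    queued <- length(qhi) + length(qlo) > 0
    t_arr <- if (i <= n) inc$t_call_ems[i] else Inf
    t_re <- Inf
    if (queued) {
      frees <- busy_until[is.finite(busy_until) & busy_until > now]
      edges <- shift_edges[shift_edges > now]
      t_re <- min(c(frees, edges, Inf))
    }
    if (!queued && i > n) break
    if (t_re <= t_arr) {
      if (!is.finite(t_re)) {
        # no unit will ever free up or come on shift again: drain
        for (q in c(qhi, qlo)) {
          a_policy[q] <- "UNSERVED"
        }
        qhi <- integer(0); qlo <- integer(0)
        next
      }
      now <- t_re
      serve_queue(now)
    } else {
      now <- t_arr
      if (!ever_servable(i)) {
        a_policy[i] <- "UNSERVED"
      } else if (!try_dispatch(i, now)) {
        a_policy[i] <- "QUEUED"
        enqueue(i, now)
      }
      i <- i + 1L
    }
  }

  assignments <- data.frame(
    incident_id = inc$incident_id, unit_id = a_unit, policy = a_policy,
    eta_min = a_eta, queue_delay_min = a_qdelay, t_dispatch = a_dispatch,
    hospital_id = a_hosp, companion_unit_id = a_companion,
    stringsAsFactors = FALSE)
  queue_log <- if (length(queue_log) > 0) do.call(rbind, queue_log) else
    data.frame(incident_id = character(0), enqueue = numeric(0),
               dequeue = numeric(0))
  list(assignments = assignments, sim_times = sim_times_df(inc, chains),
       queue_log = queue_log,
       unserved = inc$incident_id[!is.na(a_policy) & a_policy == "UNSERVED"])
}

#' @export
print.ems_sim_result <- function(x, ...) {
  n <- nrow(x$assignments)
  cat(sprintf("EMS simulation result (%s mode, seed %d)\n", x$mode, x$seed))
  cat(sprintf("  incidents  : %d (%d unserved, %d queued)\n", n,
              length(x$unserved), nrow(x$queue_log)))
  served <- !is.na(x$assignments$eta_min)
  if (any(served)) {
    cat(sprintf("  mean ETA   : %.1f min, mean queue delay %.2f min\n",
                mean(x$assignments$eta_min[served]),
                mean(x$assignments$queue_delay_min[served])))
  }
  invisible(x)
}
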