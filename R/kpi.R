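# KPIs: event response time under three variants, response-time compliance
# rate (RTCR), prehospital time, utilization and overtime, demand profiles,
# per-community aggregation, scenario deltas.

variant_start_field <- function(variant) {
  switch(variant,
         TRANSIT_ONLY = "t_depart_base",
         PREP_PLUS_TRANSIT = "t_call_ems",
         FROM_DISPATCH_CALL = "t_call_dispatch",
         stop("unknown RT variant: ", variant))
}

#' Event response time
#'
#' One event (a car accident, say) may trigger several incidents; its
#' response time is the first arrival at the scene minus the first call,
#' both taken event-wide. The start point depends on the variant: departure
#' at base (`TRANSIT_ONLY`), the call to the EMS unit
#' (`PREP_PLUS_TRANSIT`), or the call to the dispatch centre
#' (`FROM_DISPATCH_CALL`).
#'
#' @param incident_ids Incident identifiers belonging to one event.
#' @param chains Data frame keyed by `incident_id` carrying the timestamp
#'   chain columns (historical incidents or simulated times).
#' @param variant RT variant code.
#' @return Response time in minutes, or `NA` if the needed fields are
#'   missing from every incident of the event.
#' @export
event_response_time <- function(incident_ids, chains,
                                variant = "PREP_PLUS_TRANSIT") {
  start_f <- variant_start_field(variant)
  rows <- chains[match(incident_ids, chains$incident_id), , drop = FALSE]
  arr <- rows$t_arrive_scene
  st <- rows[[start_f]]
  if (all(is.na(arr)) || all(is.na(st))) return(NA_real_)
  (min(arr, na.rm = TRUE) - min(st, na.rm = TRUE)) / 60
}

#' Response-time compliance rate
#'
#' Percentage of events whose response time is within the maximum allowed
#' response time (boundary compliant: `RT <= MART`). Events with an
#' undefined RT (e.g. unserved incidents) count as non-compliant by
#' default.
#'
#' @param events Data frame `event_id`, `incident_id`.
#' @param chains Timestamp source as in [event_response_time()].
#' @param mart Maximum allowed response time, minutes.
#' @param variant RT variant.
#' @param digits Rounding of the reported rate (default 1 decimal, matching
#'   operational reports); `NULL` returns the unrounded value.
#' @param na_noncompliant Count undefined RTs as non-compliant (`TRUE`,
#'   default) or drop them from the denominator.
#' @return RTCR in percent.
#' @export
rtcr <- function(events, chains, mart = 15, variant = "PREP_PLUS_TRANSIT",
                 digits = 1, na_noncompliant = TRUE) {
  rts <- event_rts(events, chains, variant)
  if (length(rts) == 0) stop("empty event set")
  if (!na_noncompliant) rts <- rts[!is.na(rts)]
  if (length(rts) == 0) stop("no events with defined response time")
  ok <- !is.na(rts) & rts <= mart
  val <- 100 * mean(ok)
  if (is.null(digits)) val else round(val, digits)
}

event_rts <- function(events, chains, variant = "PREP_PLUS_TRANSIT") {
  ids <- split(events$incident_id, events$event_id)
  vapply(ids, event_response_time, numeric(1), chains = chains,
         variant = variant)
}

size_bin <- function(n) {
  cut(n, breaks = c(-1, 9, 99, 999, 9999, Inf),
      labels = c("0-9", "10-99", "100-999", "1000-9999", ">9999"))
}

color_class <- function(rtcr, thresholds = c(70, 85)) {
  ifelse(rtcr < thresholds[1], "RED",
         ifelse(rtcr < thresholds[2], "ORANGE", "GREEN"))
}

#' Per-community compliance
#'
#' Aggregates event response times by community for the map report: one row
#' per community with at least one event, with the event count, the RTCR,
#' the count bin used for circle sizes and a traffic-light colour class.
#' Events are assigned by point-in-polygon when the community table carries
#' a `"polygons"` attribute (boundary counts as inside), otherwise by
#' nearest centroid; events outside every polygon go to `"UNASSIGNED"`.
#'
#' @param events,chains,mart,variant As in [rtcr()].
#' @param incidents Incident table (provides event locations; the location
#'   of an event is its first incident's).
#' @param communities Data frame `community_id`, `name`, `lon`, `lat`.
#' @param color_thresholds RTCR breakpoints for RED/ORANGE/GREEN.
#' @return Data frame with `community_id`, `name`, `n_events`, `rtcr`,
#'   `size_bin`, `color_class`.
#' @export
rtcr_by_community <- function(events, chains, incidents, communities,
                              mart = 15, variant = "PREP_PLUS_TRANSIT",
                              color_thresholds = c(70, 85)) {
  rts <- event_rts(events, chains, variant)
  first_inc <- vapply(split(events$incident_id, events$event_id),
                      function(x) x[1], character(1))
  ei <- match(first_inc, incidents$incident_id)
  elon <- incidents$lon[ei]; elat <- incidents$lat[ei]
  polys <- attr(communities, "polygons")
  if (!is.null(polys)) {
    comm <- rep("UNASSIGNED", length(elon))
    for (cid in names(polys)) {
      hit <- point_in_polygon(elon, elat, polys[[cid]]) & comm == "UNASSIGNED"
      comm[hit] <- cid
    }
  } else {
    comm <- vapply(seq_along(elon), function(k) {
      d <- haversine_km(elon[k], elat[k], communities$lon, communities$lat)
      communities$community_id[which.min(d)]
    }, character(1))
  }
  out <- do.call(rbind, lapply(unique(comm), function(cid) {
    idx <- comm == cid
    r <- rts[idx]
    ok <- !is.na(r) & r <= mart
    data.frame(community_id = cid,
               name = if (cid %in% communities$community_id) {
                 communities$name[match(cid, communities$community_id)]
               } else cid,
               n_events = sum(idx),
               rtcr = round(100 * mean(ok), 1),
               stringsAsFactors = FALSE)
  }))
  out$size_bin <- as.character(size_bin(out$n_events))
  out$color_class <- color_class(out$rtcr, color_thresholds)
  rownames(out) <- NULL
  out
}

#' Prehospital time
#'
#' Call-to-hospital-arrival duration per incident; the working quality
#' limit for tracer diagnoses is 60 minutes. Undefined (reported `NA`, not
#' zero) for incidents without a hospital leg.
#'
#' @param chains Timestamp source.
#' @param limit_min Compliance limit in minutes (default 60).
#' @return Data frame `incident_id`, `pt_min`, `pt_compliant`.
#' @export
prehospital_time <- function(chains, limit_min = 60) {
  pt <- (chains$t_arrive_hospital - chains$t_call_ems) / 60
  data.frame(incident_id = chains$incident_id, pt_min = pt,
             pt_compliant = ifelse(is.na(pt), NA, pt <= limit_min),
             stringsAsFactors = FALSE)
}

#' Unit utilization and overtime
#'
#' Busy time is dispatch to free-again per mission; utilization is busy
#' time over staffed time per unit. Busy time outside staffed intervals is
#' overtime (a mission is completed even when the shift ends), annualized
#' to hours per year over the simulation horizon.
#'
#' @param sim An `ems_sim_result` (STANDARD mode).
#' @return List with `per_unit` (data frame `unit_id`, `busy_h`,
#'   `staffed_h`, `utilization_pct`, `overtime_h_yr`, `flagged`),
#'   `fleet_mean_pct` and `fleet_overtime_h_yr`.
#' @export
utilization <- function(sim) {
  stopifnot(inherits(sim, "ems_sim_result"))
  tl <- sim$timelines
  span <- diff(sim$horizon)
  ann <- 365 * 86400 / span
  a <- sim$assignments
  ch <- sim$sim_times
  busy_iv <- list()
  add_busy <- function(uid, from, to) {
    busy_iv[[uid]] <<- rbind(busy_iv[[uid]], c(from, to))
  }
  for (r in seq_len(nrow(a))) {
    if (is.na(a$unit_id[r]) || startsWith(a$unit_id[r], "virtual:")) next
    add_busy(a$unit_id[r], a$t_dispatch[r], ch$t_free[r])
    if (!is.na(a$companion_unit_id[r])) {
      add_busy(a$companion_unit_id[r], a$t_dispatch[r], ch$t_free[r])
    }
  }
  unit_ids <- names(tl)
  per <- do.call(rbind, lapply(unit_ids, function(uid) {
    staffed <- sum(tl[[uid]][, 2] - tl[[uid]][, 1])
    iv <- busy_iv[[uid]]
    busy <- if (is.null(iv)) 0 else sum(iv[, 2] - iv[, 1])
    inside <- if (is.null(iv)) 0 else {
      sum(vapply(seq_len(nrow(iv)),
                 function(j) interval_overlap(iv[j, 1], iv[j, 2], tl[[uid]]),
                 numeric(1)))
    }
    flagged <- staffed == 0 && busy > 0
    data.frame(unit_id = uid, busy_h = busy / 3600, staffed_h = staffed / 3600,
               utilization_pct = if (flagged || staffed == 0) NA_real_ else
                 100 * busy / staffed,
               overtime_h_yr = (busy - inside) / 3600 * ann,
               flagged = flagged, stringsAsFactors = FALSE)
  }))
  rownames(per) <- NULL
  list(per_unit = per,
       fleet_mean_pct = mean(per$utilization_pct, na.rm = TRUE),
       fleet_overtime_h_yr = sum(per$overtime_h_yr))
}

#' Quarter-hour demand profile
#'
#' Mean number of incidents per quarter-hour bin per day, the curve used to
#' judge whether rosters (the staffed-units line) match demand.
#'
#' @param incidents Incident table (uses `t_call_ems`).
#' @param resolution Bin width in seconds (default 900).
#' @param split `"none"` or `"weekday_weekend"`.
#' @param n_days Number of days the data span; inferred from the time range
#'   when `NULL`.
#' @return Data frame with `bin` (0-based), `start_s` (seconds past
#'   midnight) and `mean_per_day` (one column per split group).
#' @export
demand_profile <- function(incidents, resolution = 900,
                           split = c("none", "weekday_weekend"),
                           n_days = NULL) {
  split <- match.arg(split)
  if (nrow(incidents) == 0) stop("at least one incident required")
  t <- incidents$t_call_ems
  nbin <- 86400 %/% resolution
  day0 <- floor(min(t) / 86400)
  if (is.null(n_days)) n_days <- floor(max(t) / 86400) - day0 + 1
  bin <- (floor(t / resolution)) %% nbin
  base <- data.frame(bin = 0:(nbin - 1), start_s = (0:(nbin - 1)) * resolution)
  if (split == "none") {
    counts <- tabulate(bin + 1L, nbins = nbin)
    base$mean_per_day <- counts / n_days
  } else {
    wd <- (floor(t / 86400)) %% 7 # 0 = Monday (epoch anchor)
    weekend <- wd >= 5
    all_days <- day0:(day0 + n_days - 1)
    n_we <- sum((all_days %% 7) >= 5)
    n_wd <- n_days - n_we
    base$weekday_mean <- tabulate(bin[!weekend] + 1L, nbins = nbin) /
      max(n_wd, 1)
    base$weekend_mean <- tabulate(bin[weekend] + 1L, nbins = nbin) /
      max(n_we, 1)
  }
  base
}

#' Compare two scenarios' KPI sets
#'
#' Expresses an RTCR difference both in percentage points and as the
#' equivalent number of incidents: a gain of +0.7 percentage points on
#' 10,000 incidents means an estimated 70 additional incidents reached
#' within the MART.
#'
#' @param a,b KPI sets as returned by [kpi_set()] (a = reference).
#' @param n_incidents Incident volume the percentage refers to.
#' @return List of deltas: `delta_rtcr_pp`, `incident_equivalent`,
#'   `delta_utilization_pp`, `delta_overtime_h_yr`.
#' @export
compare_scenarios <- function(a, b, n_incidents) {
  if (!identical(a$mart, b$mart) || !identical(a$variant, b$variant)) {
    stop("KPI sets computed under different MART or RT variant")
  }
  d_rtcr <- b$rtcr - a$rtcr
  list(delta_rtcr_pp = d_rtcr,
       incident_equivalent = round(d_rtcr / 100 * n_incidents),
       delta_utilization_pp = (b$utilization_pct %||% NA_real_) -
         (a$utilization_pct %||% NA_real_),
       delta_overtime_h_yr = (b$overtime_h_yr %||% NA_real_) -
         (a$overtime_h_yr %||% NA_real_))
}

#' Full KPI set for a simulation result
#'
#' @param sim An `ems_sim_result`.
#' @param s The scenario it was computed from (supplies events and config).
#' @param digits Rounding for the reported RTCR (`NULL` = unrounded).
#' @return List: `rtcr`, `mart`, `variant`, `n_events`, `n_incidents`,
#'   `utilization_pct`, `overtime_h_yr`, `mean_pt_min`, `pt_compliance_pct`,
#'   `n_unserved`, `profile_ids`.
#' @export
kpi_set <- function(sim, s, digits = 1) {
  cfg <- s$config
  chains <- sim$sim_times
  r <- rtcr(s$events, chains, cfg$mart, cfg$rt_variant, digits = digits,
            na_noncompliant = cfg$count_unserved)
  util <- if (sim$mode == "STANDARD") utilization(sim) else NULL
  pt <- prehospital_time(chains)
  list(rtcr = r, mart = cfg$mart, variant = cfg$rt_variant,
       n_events = length(unique(s$events$event_id)),
       n_incidents = nrow(s$incidents),
       utilization_pct = util$fleet_mean_pct,
       overtime_h_yr = util$fleet_overtime_h_yr,
       mean_pt_min = mean(pt$pt_min, na.rm = TRUE),
       pt_compliance_pct = 100 * mean(pt$pt_compliant, na.rm = TRUE),
       n_unserved = length(sim$unserved),
       profile_ids = names(cfg$profiles))
}
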