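# Brute-force dispatch oracle: re-derives every assignment by scanning all
# units at each decision epoch and applying the policy definitions
# literally. Independent of the engine internals (own distance, roster
# unroll and timeline arithmetic); requires zero-dispersion service times.

oracle_haversine_km <- function(lon1, lat1, lon2, lat2) {
  r <- pi / 180
  dlat <- (lat2 - lat1) * r
  dlon <- (lon2 - lon1) * r
  a <- sin(dlat / 2)^2 + cos(lat1 * r) * cos(lat2 * r) * sin(dlon / 2)^2
  2 * 6371 * asin(sqrt(a))
}

oracle_rosters <- function(shifts, horizon) {
  out <- list()
  for (r in seq_len(nrow(shifts))) {
    u <- shifts$unit_id[r]
    if (shifts$recurrence[r] == "once") {
      offs <- 0
    } else {
      step <- if (shifts$recurrence[r] == "daily") 86400 else 7 * 86400
      offs <- seq(-step * 10, horizon[2] + step, by = step)
    }
    for (o in offs) {
      st <- shifts$start[r] + o; en <- shifts$end[r] + o
      if (en <= horizon[1] || st >= horizon[2]) next
      out[[u]] <- rbind(out[[u]], c(max(st, horizon[1]), min(en, horizon[2])))
    }
  }
  out
}

oracle_simulate <- function(s) {
  cfg <- s$config
  st <- cfg$service_times
  stopifnot(st$turnout_sigma == 0, st$on_scene_sigma == 0,
            st$handover_sigma == 0, st$transport_sigma == 0)
  prof <- cfg$profiles$ground_default
  inc <- s$incidents
  n <- nrow(inc)
  units <- s$units
  nu <- nrow(units)
  b <- match(units$base_id, s$bases$base_id)
  ulon <- s$bases$lon[b]; ulat <- s$bases$lat[b]
  horizon <- cfg$horizon
  ros <- oracle_rosters(s$shifts, horizon)
  on_shift <- function(k, t) {
    m <- ros[[units$unit_id[k]]]
    !is.null(m) && any(t >= m[, 1] & t < m[, 2])
  }
  free_time <- rep(-Inf, nu)
  is_tr <- !is.na(inc$hospital_id) | !is.na(inc$t_arrive_hospital)

  eta_of <- function(k, i) {
    km <- oracle_haversine_km(ulon[k], ulat[k], inc$lon[i], inc$lat[i])
    km * prof$detour_factor / prof$speeds[units$type[k], inc$priority[i]] * 60
  }
  pick <- function(i, t) {
    ks <- which(units$type == inc$required_type[i] & free_time <= t)
    ks <- ks[vapply(ks, on_shift, logical(1), t = t)]
    if (length(ks) == 0) return(NULL)
    eta <- vapply(ks, eta_of, numeric(1), i = i)
    if (!is.null(cfg$cutoff_min)) {
      ks <- ks[eta <= cfg$cutoff_min]; eta <- eta[eta <= cfg$cutoff_min]
      if (length(ks) == 0) return(NULL)
    }
    high <- inc$priority[i] %in% cfg$high_priority_set
    if (!high) {
      h <- inc$historic_unit_id[i]
      if (!is.na(h)) {
        kh <- which(units$unit_id[ks] == h)
        if (length(kh) == 1) return(list(k = ks[kh], eta = eta[kh]))
      }
    }
    o <- order(eta, units$unit_id[ks])[1]
    list(k = ks[o], eta = eta[o])
  }
  serve <- function(i, t, sel) {
    depart_scene <- t + st$turnout_median_min * 60 + sel$eta * 60 +
      st$on_scene_median_min * 60
    free_time[sel$k] <<- if (is_tr[i]) {
      depart_scene + st$transport_median_min * 60 + st$handover_median_min * 60
    } else depart_scene
    assigned[i] <<- units$unit_id[sel$k]
  }

  assigned <- rep(NA_character_, n)
  policy <- rep(NA_character_, n)
  shift_starts <- sort(unique(unlist(lapply(ros, function(m) m[, 1]))))
  qhi <- integer(0); qlo <- integer(0)
  i <- 1L; now <- -Inf
  repeat {
    queued <- length(qhi) + length(qlo) > 0
    if (!queued && i > n) break
    t_arr <- if (i <= n) inc$t_call_ems[i] else Inf
    t_re <- Inf
    if (queued) {
      t_re <- min(c(free_time[free_time > now & is.finite(free_time)],
                    shift_starts[shift_starts > now], Inf))
    }
    if (t_re <= t_arr) {
      if (!is.finite(t_re)) {
        policy[c(qhi, qlo)] <- "UNSERVED"
        qhi <- integer(0); qlo <- integer(0)
        next
      }
      now <- t_re
      for (q in c(qhi, qlo)) {
        sel <- pick(q, now)
        if (!is.null(sel)) {
          serve(q, now, sel)
          qhi <- setdiff(qhi, q); qlo <- setdiff(qlo, q)
        }
      }
    } else {
      now <- t_arr
      servable_ever <- any(units$type == inc$required_type[i] &
                             vapply(units$unit_id,
                                    function(u) !is.null(ros[[u]]),
                                    logical(1)))
      sel <- if (servable_ever) pick(i, now) else NULL
      if (!servable_ever) {
        policy[i] <- "UNSERVED"
      } else if (is.null(sel)) {
        if (inc$priority[i] %in% cfg$high_priority_set) qhi <- c(qhi, i)
        else qlo <- c(qlo, i)
      } else {
        serve(i, now, sel)
      }
      i <- i + 1L
    }
  }
  data.frame(incident_id = inc$incident_id, unit_id = assigned,
             stringsAsFactors = FALSE)
}
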