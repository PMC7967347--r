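# Capacity planning: the unlimited-resources upper bound, the iterative
# reserve-capacity algorithm, the multicopter operation-radius model and
# greedy covering location allocation.

#' Unlimited-resources RTCR bound
#'
#' RTCR of the simulation with unlimited units at the given bases. Any
#' roster change at those bases can at best reach this value; a low bound
#' diagnoses badly located bases rather than an undersized fleet.
#'
#' @param s An `ems_scenario`.
#' @param digits Rounding (`NULL` = unrounded).
#' @return RTCR in percent.
#' @export
unlimited_bound <- function(s, digits = 1) {
  sim <- simulate_scenario(s, "UNLIMITED")
  rtcr(s$events, sim$sim_times, s$config$mart, s$config$rt_variant,
       digits = digits, na_noncompliant = s$config$count_unserved)
}

day_shift_window <- c(7, 19) * 3600 # 07:00-19:00; night is the complement

#' Iterative reserve-capacity planning
#'
#' Starting from the simulated historical scenario (step S0), the algorithm
#' repeatedly simulates adding one candidate unit -- a 12-h day or night
#' shift at each base -- and permanently adds the single unit with the
#' highest impact on RTCR. Base locations never change; only the number of
#' EMS units may. Iteration stops when the target compliance rate is
#' reached, when the best achievable gain falls below `epsilon_pp`
#' (adding resources is then inefficient), or after `max_iter` additions.
#' Gains are compared on unrounded RTCR values; ties go to the smallest
#' `base_id`, day shift before night shift.
#'
#' @param s An `ems_scenario`.
#' @param target Target compliance rate in percent (default
#'   `config$martcr_target`).
#' @param epsilon_pp Minimum worthwhile gain in percentage points (default
#'   `config$epsilon_pp`).
#' @param unit_type Type of the candidate units (default `"AMBULANCE"`).
#' @param max_iter Maximum number of additions (default 20).
#' @return An `ems_capacity_curve`: `steps` data frame (`label`, `base_id`,
#'   `shift`, `rtcr`), `stop_reason` in
#'   `TARGET_REACHED`/`GAIN_BELOW_EPSILON`/`MAX_ITER`, `scenarios` (one
#'   scenario per step, S0 first) and `final` (the last scenario).
#' @export
reserve_capacity <- function(s, target = NULL, epsilon_pp = NULL,
                             unit_type = "AMBULANCE", max_iter = 20) {
  cfg <- s$config
  target <- target %||% cfg$martcr_target
  epsilon_pp <- epsilon_pp %||% cfg$epsilon_pp
  rtcr_of <- function(sc) {
    sim <- simulate_scenario(sc, "STANDARD")
    rtcr(sc$events, sim$sim_times, cfg$mart, cfg$rt_variant, digits = NULL,
         na_noncompliant = cfg$count_unserved)
  }
  horizon <- cfg$horizon %||% default_horizon(s$incidents)
  current <- s
  cur_rtcr <- rtcr_of(s)
  steps <- data.frame(label = "S0", base_id = NA_character_,
                      shift = NA_character_, rtcr = cur_rtcr,
                      stringsAsFactors = FALSE)
  scenarios <- list(S0 = s)
  stop_reason <- NULL
  if (cur_rtcr >= target) stop_reason <- "TARGET_REACHED"
  iter <- 0L
  bases <- s$bases$base_id[order(s$bases$base_id)]
  while (is.null(stop_reason)) {
    if (iter >= max_iter) { stop_reason <- "MAX_ITER"; break }
    best <- NULL
    for (b in bases) {
      for (sh in c("DAY", "NIGHT")) { # DAY first: tie-break order
        cand <- add_candidate_unit(current, b, sh, unit_type, horizon, iter)
        r <- rtcr_of(cand)
        if (is.null(best) || r > best$rtcr + 1e-12) {
          best <- list(scenario = cand, rtcr = r, base_id = b, shift = sh)
        }
      }
    }
    if (is.null(best) || best$rtcr - cur_rtcr < epsilon_pp) {
      stop_reason <- "GAIN_BELOW_EPSILON"
      break
    }
    iter <- iter + 1L
    current <- best$scenario
    cur_rtcr <- best$rtcr
    label <- paste0("S", iter)
    steps <- rbind(steps, data.frame(label = label, base_id = best$base_id,
                                     shift = best$shift, rtcr = cur_rtcr,
                                     stringsAsFactors = FALSE))
    scenarios[[label]] <- current
    if (cur_rtcr >= target) stop_reason <- "TARGET_REACHED"
  }
  structure(list(steps = steps, stop_reason = stop_reason,
                 target = target, epsilon_pp = epsilon_pp,
                 scenarios = scenarios, final = current),
            class = "ems_capacity_curve")
}

# add one unit with a recurring 12-h day or night shift at a base
add_candidate_unit <- function(s, base_id, shift, unit_type, horizon, iter) {
  uid <- sprintf("RC%02d_%s_%s", iter + 1L, base_id, shift)
  s$units <- rbind(s$units, data.frame(
    unit_id = uid, type = unit_type, base_id = base_id,
    speed_profile_id = if (unit_type %in% c("HELICOPTER", "MCO"))
      "air_default" else "ground_default",
    stringsAsFactors = FALSE))
  day0 <- floor(horizon[1] / 86400) * 86400
  win <- if (shift == "DAY") day_shift_window else c(19, 31) * 3600
  s$shifts <- rbind(s$shifts, data.frame(
    unit_id = uid, start = day0 + win[1], end = day0 + win[2],
    recurrence = "daily", weekdays = "1111111", stringsAsFactors = FALSE))
  s
}

#' @export
print.ems_capacity_curve <- function(x, ...) {
  cat("Reserve-capacity curve (target", x$target, "%, epsilon",
      x$epsilon_pp, "pp)\n")
  st <- x$steps
  for (i in seq_len(nrow(st))) {
    added <- if (is.na(st$base_id[i])) "simulated historical" else
      paste0("+", st$shift[i], " unit at ", st$base_id[i])
    cat(sprintf("  %-4s RTCR %5.1f%%  %s\n", st$label[i], st$rtcr[i], added))
  }
  cat("  stop:", x$stop_reason, "\n")
  invisible(x)
}

#' Multicopter operation radius
#'
#' The radius an MCO base can serve results from the aircraft's speed and
#' range: the time-limited radius is `speed * (t_max - overhead) / 60`, the
#' range-limited radius is `range / (2 * missions_per_sortie)` (out and
#' back per mission), and the operation radius is the smaller of the two.
#'
#' @param speed_kmh Cruise speed, km/h.
#' @param range_km Range on one charge, km (`Inf` for time-limited only).
#' @param t_max_min Required arrival time, minutes.
#' @param overhead_min Takeoff plus landing time, minutes.
#' @param missions_per_sortie Missions the aircraft must be able to fly
#'   before recharging.
#' @return Operation radius in km.
#' @export
operation_radius <- function(speed_kmh, range_km, t_max_min,
                             overhead_min = 0, missions_per_sortie = 1) {
  stopifnot(speed_kmh > 0, range_km > 0, t_max_min > 0,
            missions_per_sortie >= 1)
  if (t_max_min <= overhead_min) {
    stop("t_max_min must exceed overhead_min")
  }
  min(speed_kmh * (t_max_min - overhead_min) / 60,
      range_km / (2 * missions_per_sortie))
}

#' Greedy covering location allocation
#'
#' Selects candidate sites so that as many demand points as possible lie
#' within the operation radius of a selected site, with as few sites as
#' possible: repeatedly pick the candidate covering the most uncovered
#' points (ties: smallest candidate index) until coverage is complete or no
#' candidate adds coverage.
#'
#' @param demand Data frame `lon`, `lat` of demand points.
#' @param candidates Data frame `lon`, `lat` of candidate sites.
#' @param radius_km Operation radius (coverage is distance `<= radius_km`).
#' @param require_complete Warn if complete coverage is unattainable.
#' @return An `ems_cover_plan`: `selected` (indices into `candidates`),
#'   `sites` (their coordinates), `radius_km`, `covered_fraction`,
#'   `uncovered` (indices of uncovered demand points).
#' @export
greedy_cover <- function(demand, candidates, radius_km,
                         require_complete = FALSE) {
  stopifnot(radius_km > 0)
  nd <- nrow(demand)
  nc <- nrow(candidates)
  if (nd > 0 && nc == 0) stop("no candidate sites for nonempty demand")
  if (nd == 0) {
    return(structure(list(selected = integer(0),
                          sites = candidates[0, , drop = FALSE],
                          radius_km = radius_km, covered_fraction = 1,
                          uncovered = integer(0)), class = "ems_cover_plan"))
  }
  cover <- matrix(FALSE, nrow = nc, ncol = nd)
  for (j in seq_len(nc)) {
    cover[j, ] <- haversine_km(candidates$lon[j], candidates$lat[j],
                               demand$lon, demand$lat) <= radius_km
  }
  covered <- rep(FALSE, nd)
  selected <- integer(0)
  repeat {
    gains <- rowSums(cover[, !covered, drop = FALSE])
    gains[selected] <- 0
    if (max(gains) == 0) break
    j <- which.max(gains) # which.max takes the first (smallest index) on ties
    selected <- c(selected, j)
    covered <- covered | cover[j, ]
    if (all(covered)) break
  }
  frac <- mean(covered)
  if (require_complete && frac < 1) {
    warning(sprintf("complete coverage unattainable: %d of %d points uncovered",
                    sum(!covered), nd))
  }
  structure(list(selected = selected,
                 sites = candidates[selected, , drop = FALSE],
                 radius_km = radius_km, covered_fraction = frac,
                 uncovered = which(!covered)),
            class = "ems_cover_plan")
}

#' @export
print.ems_cover_plan <- function(x, ...) {
  cat(sprintf("Cover plan: %d site(s), radius %.1f km, %.1f%% covered\n",
              length(x$selected), x$radius_km, 100 * x$covered_fraction))
  invisible(x)
}
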