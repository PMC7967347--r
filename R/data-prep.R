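# Raw dispatch tables -> clean scenario input: standardization, area
# restriction with "external" attribution, the three cleaning rules, event
# grouping, roster expansion.

#' Standardize raw incident tables
#'
#' Renames columns via `column_map`, parses ISO-8601 timestamps into seconds
#' since the scenario epoch and coerces the record to the canonical incident
#' layout. Unknown columns are dropped with a warning; rows whose timestamps
#' fail to parse are excluded and collected.
#'
#' @param raw Data frame of raw records.
#' @param column_map Named character vector mapping raw column name ->
#'   standard column name. Must cover the mandatory fields `incident_id`,
#'   `lon`, `lat`, `priority`, `required_type`, `t_call_ems`. Identity
#'   entries may be omitted for columns already named canonically.
#' @param epoch Scenario epoch (ISO-8601).
#' @return Standardized incident data frame; attribute `"failures"` is a
#'   data frame (`row`, `column`, `value`) of row-level parse failures.
#' @export
standardize_incidents <- function(raw, column_map = NULL,
                                  epoch = DEFAULT_EPOCH) {
  raw <- as.data.frame(raw, stringsAsFactors = FALSE)
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- unname(column_map[names(raw)[hit]])
  }
  mandatory <- c("incident_id", "lon", "lat", "priority", "required_type",
                 "t_call_ems")
  missing <- setdiff(mandatory, names(raw))
  if (length(missing) > 0) {
    stop("unmapped mandatory column(s): ", paste(missing, collapse = ", "))
  }
  known <- c(INCIDENT_COLUMNS, "discontinued")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    warning("dropping unknown column(s): ", paste(unknown, collapse = ", "))
    raw <- raw[, setdiff(names(raw), unknown), drop = FALSE]
  }
  failures <- list()
  bad_rows <- integer(0)
  for (f in intersect(CHAIN_FIELDS, names(raw))) {
    if (is.numeric(raw[[f]])) next # already seconds
    sec <- iso_to_sec(raw[[f]], epoch)
    bad <- attr(sec, "bad")
    if (length(bad) > 0) {
      failures[[length(failures) + 1L]] <-
        data.frame(row = bad, column = f,
                   value = as.character(raw[[f]][bad]),
                   stringsAsFactors = FALSE)
      bad_rows <- union(bad_rows, bad)
    }
    attr(sec, "bad") <- NULL
    raw[[f]] <- sec
  }
  disc <- raw$discontinued
  raw$discontinued <- NULL
  out <- normalize_incidents(raw)
  if (!is.null(disc)) out$discontinued <- as.logical(disc)
  if (length(bad_rows) > 0) out <- out[-bad_rows, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "failures") <- if (length(failures) > 0) {
    do.call(rbind, failures)
  } else {
    data.frame(row = integer(0), column = character(0), value = character(0))
  }
  out
}

#' Restrict incidents to a study area
#'
#' Incidents outside the area polygon are dropped (they belong to adjacent
#' EMS organizations we do not optimize). Incidents inside the area that
#' were served by an organization not in `own_orgs` are kept but attributed
#' to the sentinel organization `"external"`. Points on the polygon boundary
#' count as inside.
#'
#' @param records Standardized incident data frame.
#' @param area Two-column matrix/data frame of polygon vertices (lon, lat).
#' @param own_orgs Character vector of organization identifiers considered
#'   "own".
#' @return The filtered and relabelled records.
#' @export
restrict_to_area <- function(records, area, own_orgs) {
  inside <- point_in_polygon(records$lon, records$lat, area)
  out <- records[inside, , drop = FALSE]
  foreign <- !(out$organization %in% own_orgs)
  out$organization[foreign] <- "external"
  rownames(out) <- NULL
  out
}

#' Clean standardized incident records
#'
#' Applies the three sequential cleaning rules with single attribution
#' (a record failing several rules is counted under the first):
#' \describe{
#'   \item{rule i}{inconsistent or wrong timestamps: any ordering violation
#'     among present chain fields (equivalently a negative implied
#'     duration), optionally a call time outside `horizon`;}
#'   \item{rule ii}{missing turnout or response time: `t_depart_base` or
#'     `t_arrive_scene` absent;}
#'   \item{rule iii}{incomplete chain after arrival at scene: a transport
#'     record (one carrying a `hospital_id` or a hospital-arrival time)
#'     whose post-arrival fields are partial.}
#' }
#' Records flagged `discontinued` are removed beforehand and counted
#' separately; false alarms are not optimized for.
#'
#' @param records Standardized incident data frame.
#' @param horizon Optional `c(start, end)` in seconds; rule i then also
#'   rejects call times outside it.
#' @param rules Character subset of `c("i", "ii", "iii")` to apply.
#' @return List with `records` (retained rows) and `report`, an
#'   `ems_cleaning_report` with fields `n_input`, `n_removed_discontinued`,
#'   `n_removed_inconsistent`, `n_removed_missing_rt`,
#'   `n_removed_incomplete_post_arrival`, `n_retained`.
#' @export
clean_incidents <- function(records, horizon = NULL,
                            rules = c("i", "ii", "iii")) {
  n_input <- nrow(records)
  disc <- if (!is.null(records$discontinued)) {
    !is.na(records$discontinued) & records$discontinued
  } else {
    rep(FALSE, n_input)
  }
  rec <- records[!disc, , drop = FALSE]
  rec$discontinued <- NULL

  fail_i <- if ("i" %in% rules) {
    bad_order <- !chain_order_ok(rec)
    if (!is.null(horizon)) {
      bad_order | rec$t_call_ems < horizon[1] | rec$t_call_ems > horizon[2]
    } else {
      bad_order
    }
  } else rep(FALSE, nrow(rec))

  fail_ii <- if ("ii" %in% rules) {
    is.na(rec$t_depart_base) | is.na(rec$t_arrive_scene)
  } else rep(FALSE, nrow(rec))

  fail_iii <- if ("iii" %in% rules) {
    is_transport <- !is.na(rec$hospital_id) | !is.na(rec$t_arrive_hospital)
    !is.na(rec$t_arrive_scene) & is_transport &
      (is.na(rec$t_depart_scene) | is.na(rec$t_arrive_hospital))
  } else rep(FALSE, nrow(rec))

  # single attribution, order i -> ii -> iii
  r_i <- fail_i
  r_ii <- fail_ii & !r_i
  r_iii <- fail_iii & !r_i & !r_ii
  keep <- !(r_i | r_ii | r_iii)

  report <- structure(list(
    n_input = n_input,
    n_removed_discontinued = sum(disc),
    n_removed_inconsistent = sum(r_i),
    n_removed_missing_rt = sum(r_ii),
    n_removed_incomplete_post_arrival = sum(r_iii),
    n_retained = sum(keep)
  ), class = "ems_cleaning_report")
  out <- rec[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, report = report)
}

#' @export
print.ems_cleaning_report <- function(x, ...) {
  cat("Cleaning report\n")
  cat(sprintf("  input                    : %d\n", x$n_input))
  if (x$n_removed_discontinued > 0) {
    cat(sprintf("  discontinued (pre-rules) : %d\n", x$n_removed_discontinued))
  }
  cat(sprintf("  rule i   inconsistent    : %d\n", x$n_removed_inconsistent))
  cat(sprintf("  rule ii  missing RT      : %d\n", x$n_removed_missing_rt))
  cat(sprintf("  rule iii incomplete      : %d\n",
              x$n_removed_incomplete_post_arrival))
  cat(sprintf("  retained                 : %d\n", x$n_retained))
  invisible(x)
}

#' Group incidents into events
#'
#' One real-world emergency (event) may trigger several incidents. Records
#' sharing an `event_id` form one group. Records without an `event_id` are
#' grouped by a conservative fallback: incidents whose locations are within
#' `max_dist_m` and whose call times are within `max_gap_min` are chained
#' into one group (single linkage).
#'
#' @param records Standardized incident data frame.
#' @param max_dist_m,max_gap_min Fallback thresholds (defaults 100 m, 5 min).
#' @return Data frame `event_id`, `incident_id` partitioning the input.
#' @export
group_events <- function(records, max_dist_m = 100, max_gap_min = 5) {
  n <- nrow(records)
  if (n == 0) {
    return(data.frame(event_id = character(0), incident_id = character(0)))
  }
  has_id <- !is.na(records$event_id) & nzchar(records$event_id)
  out <- list()
  if (any(has_id)) {
    out[[1]] <- data.frame(event_id = records$event_id[has_id],
                           incident_id = records$incident_id[has_id],
                           stringsAsFactors = FALSE)
  }
  if (any(!has_id)) {
    sub <- records[!has_id, , drop = FALSE]
    sub <- sub[order(sub$t_call_ems, sub$incident_id), , drop = FALSE]
    m <- nrow(sub)
    group <- integer(m)
    next_group <- 0L
    for (i in seq_len(m)) {
      assigned <- 0L
      for (j in rev(seq_len(i - 1L))) {
        if (sub$t_call_ems[i] - sub$t_call_ems[j] > max_gap_min * 60) break
        d <- haversine_km(sub$lon[i], sub$lat[i], sub$lon[j], sub$lat[j]) * 1000
        if (d <= max_dist_m) { assigned <- group[j]; break }
      }
      if (assigned == 0L) { next_group <- next_group + 1L; assigned <- next_group }
      group[i] <- assigned
    }
    out[[length(out) + 1L]] <- data.frame(
      event_id = paste0("EVF", formatC(group, width = 5, flag = "0")),
      incident_id = sub$incident_id, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Expand shift rosters into availability timelines
#'
#' Unrolls recurring shifts over a horizon and merges overlapping intervals
#' per unit. The roster grid defaults to 15 minutes: staffing must be
#' resolved at least every quarter of an hour for the demand profile to be
#' meaningful.
#'
#' @param shifts Shift table (`unit_id`, `start`, `end`, `recurrence`,
#'   `weekdays`). `start`/`end` are seconds since the epoch of the first
#'   occurrence; a night shift crossing midnight simply has `end > 86400`.
#' @param horizon Numeric `c(start, end)` seconds since epoch.
#' @param resolution Grid in seconds; must divide 3600.
#' @return Named list (by `unit_id`) of two-column matrices of disjoint,
#'   sorted `(start, end)` intervals clipped to the horizon.
#' @export
expand_rosters <- function(shifts, horizon, resolution = 900) {
  if (3600 %% resolution != 0) stop("resolution must divide 3600")
  if (length(horizon) != 2 || horizon[2] <= horizon[1]) {
    stop("empty horizon")
  }
  units <- unique(shifts$unit_id)
  out <- stats::setNames(vector("list", length(units)), units)
  day <- 86400
  for (u in units) {
    rows <- which(shifts$unit_id == u)
    ivs <- list()
    for (r in rows) {
      s0 <- shifts$start[r]; e0 <- shifts$end[r]
      rec <- shifts$recurrence[r]
      mask <- shifts$weekdays[r] %||% "1111111"
      if (is.na(mask) || !nzchar(mask)) mask <- "1111111"
      maskv <- strsplit(mask, "")[[1]] == "1"
      if (rec == "once") {
        occ <- 0
      } else {
        step <- if (rec == "daily") day else 7 * day
        first_k <- floor((horizon[1] - e0) / step)
        last_k <- ceiling((horizon[2] - s0) / step)
        occ <- step * (first_k:last_k)
      }
      for (off in occ) {
        st <- s0 + off; en <- e0 + off
        if (en <= horizon[1] || st >= horizon[2]) next
        if (rec %in% c("once", "daily")) {
          wd <- (floor(st / day)) %% 7 + 1L # epoch anchored on Monday
          if (!maskv[wd]) next
        }
        ivs[[length(ivs) + 1L]] <- c(max(st, horizon[1]), min(en, horizon[2]))
      }
    }
    out[[u]] <- merge_intervals(do.call(rbind, ivs))
  }
  out
}

#' Number of staffed units at given instants
#'
#' @param timelines Result of [expand_rosters()].
#' @param t Numeric vector of instants (seconds since epoch).
#' @return Integer vector: units on shift at each instant.
#' @export
staffed_units <- function(timelines, t) {
  vapply(t, function(tt) {
    sum(vapply(timelines, function(m) in_intervals(tt, m), logical(1)))
  }, integer(1))
}
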