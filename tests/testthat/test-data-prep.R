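# Standardization, area restriction, the three cleaning rules, event
# grouping, roster expansion.

mk_raw <- function() {
  data.frame(
    incident_id = c("A1", "A2"),
    lon = c(8.5, 8.6), lat = c(47.4, 47.5),
    priority = c("P1", "S2"), required_type = "AMBULANCE",
    t_call_ems = c("2025-01-06T10:00:00Z", "2025-01-06T11:00:00Z"),
    t_depart_base = c("2025-01-06T10:02:00Z", "2025-01-06T11:03:00Z"),
    t_arrive_scene = c("2025-01-06T10:10:00Z", "2025-01-06T11:12:00Z"),
    stringsAsFactors = FALSE)
}

test_that("standardize is the identity on already-standard tables", {
  out <- standardize_incidents(mk_raw())
  expect_equal(out$incident_id, c("A1", "A2"))
  expect_equal(out$t_call_ems, c(10, 11) * 3600)
  expect_equal(out$t_depart_base - out$t_call_ems, c(120, 180))
  expect_equal(nrow(attr(out, "failures")), 0)
})

test_that("column remapping yields the same records as the identity case", {
  raw <- mk_raw()
  names(raw) <- c("einsatz_nr", "laenge", "breite", "prio", "typ",
                  "alarmzeit", "ausrueckzeit", "ankunftzeit")
  map <- c(einsatz_nr = "incident_id", laenge = "lon", breite = "lat",
           prio = "priority", typ = "required_type",
           alarmzeit = "t_call_ems", ausrueckzeit = "t_depart_base",
           ankunftzeit = "t_arrive_scene")
  out_mapped <- standardize_incidents(raw, map)
  out_plain <- standardize_incidents(mk_raw())
  attr(out_mapped, "failures") <- attr(out_plain, "failures") <- NULL
  expect_equal(out_mapped, out_plain)
})

test_that("unparseable timestamps are row-level failures, not errors", {
  raw <- mk_raw()
  raw$t_depart_base[2] <- "not-a-date"
  out <- standardize_incidents(raw)
  expect_equal(nrow(out), 1)
  f <- attr(out, "failures")
  expect_equal(f$row, 2L)
  expect_equal(f$column, "t_depart_base")
  # unknown columns are dropped with a warning
  raw2 <- mk_raw()
  raw2$mystery <- 1
  expect_warning(standardize_incidents(raw2), "mystery")
})

test_that("area restriction drops outside, relabels foreign as external", {
  # unit square polygon; boundary counts as inside
  area <- data.frame(lon = c(8, 9, 9, 8), lat = c(47, 47, 48, 48))
  inside <- data.frame(
    incident_id = sprintf("IN%02d", 1:10),
    lon = seq(8.1, 8.9, length.out = 10), lat = 47.5,
    priority = "P1", required_type = "AMBULANCE", t_call_ems = 0,
    organization = c(rep("own", 7), rep("foreign", 3)),
    stringsAsFactors = FALSE)
  outside <- data.frame(
    incident_id = sprintf("OUT%02d", 1:5),
    lon = 10.5, lat = 49.5,
    priority = "P1", required_type = "AMBULANCE", t_call_ems = 0,
    organization = "own", stringsAsFactors = FALSE)
  rec <- standardize_incidents(rbind(inside, outside))
  out <- restrict_to_area(rec, area, own_orgs = "own")
  expect_equal(nrow(out), 10)
  expect_equal(sum(out$organization == "external"), 3)
  expect_false(any(grepl("^OUT", out$incident_id)))

  # exactly on the boundary: retained
  on_edge <- standardize_incidents(data.frame(
    incident_id = "EDGE", lon = 8.0, lat = 47.5, priority = "P1",
    required_type = "AMBULANCE", t_call_ems = 0, organization = "own"))
  expect_equal(nrow(restrict_to_area(on_edge, area, "own")), 1)
  expect_error(restrict_to_area(rec, area[1:2, ], "own"), "degenerate")
})

clean_pop <- function(n = 40) {
  # transports have a complete post-arrival chain
  data.frame(
    incident_id = sprintf("C%03d", seq_len(n)),
    lon = 8.5, lat = 47.4, priority = "P2", required_type = "AMBULANCE",
    t_call_ems = (seq_len(n) - 1) * 600,
    t_depart_base = (seq_len(n) - 1) * 600 + 90,
    t_arrive_scene = (seq_len(n) - 1) * 600 + 400,
    t_depart_scene = (seq_len(n) - 1) * 600 + 900,
    t_arrive_hospital = (seq_len(n) - 1) * 600 + 1400,
    t_free = (seq_len(n) - 1) * 600 + 1800,
    hospital_id = rep(c("H1", NA), length.out = n),
    stringsAsFactors = FALSE)
}

test_that("clean removes nothing from a clean table and is idempotent", {
  rec <- standardize_incidents(clean_pop())
  res <- clean_incidents(rec)
  expect_equal(res$report$n_retained, nrow(rec))
  expect_equal(res$report$n_removed_inconsistent, 0)
  res2 <- clean_incidents(res$records)
  expect_equal(res2$report$n_retained, res2$report$n_input)
})

test_that("cleaning counts each record once, in rule order i > ii > iii", {
  rec <- standardize_incidents(clean_pop(10))
  # record 1: swapped timestamps AND missing departure -> counted under i
  rec$t_arrive_scene[1] <- rec$t_call_ems[1] - 100
  rec$t_depart_base[1] <- NA
  # record 2: missing scene arrival only -> rule ii
  rec$t_arrive_scene[2] <- NA
  # record 3 (transport): hospital arrival blanked -> rule iii
  stopifnot(!is.na(rec$hospital_id[3]))
  rec$t_arrive_hospital[3] <- NA
  res <- clean_incidents(rec)
  r <- res$report
  expect_equal(r$n_removed_inconsistent, 1)
  expect_equal(r$n_removed_missing_rt, 1)
  expect_equal(r$n_removed_incomplete_post_arrival, 1)
  expect_equal(r$n_retained, 7)
  # conservation
  expect_equal(r$n_input,
               r$n_retained + r$n_removed_discontinued +
                 r$n_removed_inconsistent + r$n_removed_missing_rt +
                 r$n_removed_incomplete_post_arrival)
})

test_that("discontinued incidents are removed before the rules and counted apart", {
  rec <- standardize_incidents(cbind(clean_pop(6),
                                     discontinued = c(TRUE, rep(FALSE, 5))))
  res <- clean_incidents(rec)
  expect_equal(res$report$n_removed_discontinued, 1)
  expect_equal(res$report$n_retained, 5)
})

test_that("event grouping honours shared ids and the fallback rule", {
  # four incidents sharing an event id form one group
  inc <- do.call(rbind, lapply(1:4, function(k) {
    h_incident(paste0("I", k), k, 2, event_id = "E1")
  }))
  g <- group_events(inc)
  expect_equal(length(unique(g$event_id)), 1)
  expect_equal(nrow(g), 4)

  # all distinct ids: one group per incident
  inc2 <- do.call(rbind, lapply(1:4, function(k) {
    h_incident(paste0("I", k), k * 30, 2)
  }))
  expect_equal(length(unique(group_events(inc2)$event_id)), 4)

  # fallback: two no-id incidents 50 m / 2 min apart plus one 10 km away
  near1 <- h_incident("N1", 0, 1)
  near2 <- h_incident("N2", 2, 1 + 0.05)
  far <- h_incident("F1", 1, 11)
  inc3 <- rbind(near1, near2, far)
  inc3$event_id <- NA_character_
  g3 <- group_events(inc3)
  sizes <- sort(as.vector(table(g3$event_id)))
  expect_equal(sizes, c(1, 2))
  # partition: every record in exactly one group
  expect_setequal(g3$incident_id, inc3$incident_id)
  expect_false(any(duplicated(g3$incident_id)))
})

test_that("roster expansion unrolls recurrences and merges adjacent shifts", {
  day <- 86400
  # one daily 07:00-19:00 shift over 2 days -> 2 intervals of 12 h
  sh <- data.frame(unit_id = "U1", start = 7 * 3600, end = 19 * 3600,
                   recurrence = "daily", weekdays = "1111111")
  tl <- expand_rosters(sh, c(0, 2 * day))
  expect_equal(nrow(tl$U1), 2)
  expect_equal(unname(tl$U1[, 2] - tl$U1[, 1]), c(12, 12) * 3600)

  # day + night shift of the same unit merge into continuous coverage
  sh2 <- rbind(sh, data.frame(unit_id = "U1", start = 19 * 3600,
                              end = 31 * 3600, recurrence = "daily",
                              weekdays = "1111111"))
  tl2 <- expand_rosters(sh2, c(7 * 3600, 2 * day))
  expect_equal(nrow(tl2$U1), 1)

  # weekend-only shift over 14 days -> 4 intervals (epoch starts Monday)
  sh3 <- data.frame(unit_id = "U1", start = 8 * 3600, end = 20 * 3600,
                    recurrence = "daily", weekdays = "0000011")
  tl3 <- expand_rosters(sh3, c(0, 14 * day))
  expect_equal(nrow(tl3$U1), 4)

  expect_error(expand_rosters(sh, c(0, day), resolution = 700), "divide")
  expect_error(expand_rosters(sh, c(day, 0)), "horizon")
})

test_that("staffing is invariant under splitting a shift at a grid point", {
  day <- 86400
  whole <- data.frame(unit_id = "U1", start = 6 * 3600, end = 18 * 3600,
                      recurrence = "daily", weekdays = "1111111")
  split <- data.frame(unit_id = "U1",
                      start = c(6, 11.25) * 3600, end = c(11.25, 18) * 3600,
                      recurrence = "daily", weekdays = "1111111")
  probe <- seq(0, 2 * day - 1, by = 900) + 450
  expect_equal(staffed_units(expand_rosters(whole, c(0, 2 * day)), probe),
               staffed_units(expand_rosters(split, c(0, 2 * day)), probe))
})
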