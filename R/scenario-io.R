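# Scenario bundle on disk: one directory of RFC-4180 CSV tables plus
# config.json. Timestamps are ISO-8601 UTC in files, integer seconds since
# the scenario epoch in memory. Missing optional timestamps are empty fields.

#' Write a scenario bundle
#'
#' Writes `incidents.csv`, `events.csv`, `units.csv`, `shifts.csv`,
#' `bases.csv`, optionally `hospitals.csv` and `communities.csv`, and
#' `config.json` into `path`.
#'
#' @param s A valid `ems_scenario`.
#' @param path Directory to create.
#' @param force Overwrite an existing bundle. Without it an existing
#'   directory containing a bundle is an error.
#' @return `path`, invisibly.
#' @export
write_scenario <- function(s, path, force = FALSE) {
  stopifnot(inherits(s, "ems_scenario"))
  if (dir.exists(path) && file.exists(file.path(path, "config.json")) &&
      !isTRUE(force)) {
    stop("bundle already exists at '", path, "'; use force = TRUE to overwrite")
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  epoch <- s$config$epoch
  inc <- s$incidents
  for (f in CHAIN_FIELDS) inc[[f]] <- sec_to_iso(inc[[f]], epoch)
  utils::write.csv(inc, file.path(path, "incidents.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(s$events, file.path(path, "events.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(s$units, file.path(path, "units.csv"), row.names = FALSE,
                   na = "")
  sh <- s$shifts
  sh$start <- sec_to_iso(sh$start, epoch)
  sh$end <- sec_to_iso(sh$end, epoch)
  utils::write.csv(sh, file.path(path, "shifts.csv"), row.names = FALSE,
                   na = "")
  utils::write.csv(s$bases, file.path(path, "bases.csv"), row.names = FALSE,
                   na = "")
  if (!is.null(s$hospitals)) {
    utils::write.csv(s$hospitals, file.path(path, "hospitals.csv"),
                     row.names = FALSE, na = "")
  }
  if (!is.null(s$communities)) {
    utils::write.csv(s$communities, file.path(path, "communities.csv"),
                     row.names = FALSE, na = "")
  }
  jsonlite::write_json(config_to_list(s$config),
                       file.path(path, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  invisible(path)
}

#' Read a scenario bundle
#'
#' Inverse of [write_scenario()]. Parse failures identify file, row and
#' column; a bundle that fails [validate_scenario()] is rejected with the
#' violations listed.
#'
#' @param path Bundle directory.
#' @return A validated `ems_scenario`.
#' @export
read_scenario <- function(path) {
  mandatory <- c("incidents.csv", "events.csv", "units.csv", "shifts.csv",
                 "bases.csv", "config.json")
  for (f in mandatory) {
    if (!file.exists(file.path(path, f))) {
      stop_data("missing mandatory table '", f, "' in bundle '", path, "'")
    }
  }
  cfg <- config_from_list(jsonlite::read_json(file.path(path, "config.json")))
  epoch <- cfg$epoch
  inc <- read_bundle_csv(file.path(path, "incidents.csv"),
                         c("incident_id", "lon", "lat", "priority",
                           "required_type"))
  for (f in CHAIN_FIELDS) {
    if (is.null(inc[[f]])) { inc[[f]] <- NA_real_; next }
    sec <- iso_to_sec(inc[[f]], epoch)
    bad <- attr(sec, "bad")
    if (length(bad) > 0) {
      stop_data("incidents.csv: unparseable timestamp in column '", f,
                "', row ", bad[1])
    }
    attr(sec, "bad") <- NULL
    inc[[f]] <- sec
  }
  events <- read_bundle_csv(file.path(path, "events.csv"),
                            c("event_id", "incident_id"))
  units <- read_bundle_csv(file.path(path, "units.csv"),
                           c("unit_id", "type", "base_id"))
  if (is.null(units$speed_profile_id)) units$speed_profile_id <- "ground_default"
  shifts <- read_bundle_csv(file.path(path, "shifts.csv"),
                            c("unit_id", "start", "end", "recurrence"))
  for (f in c("start", "end")) {
    sec <- iso_to_sec(shifts[[f]], epoch)
    bad <- attr(sec, "bad")
    if (length(bad) > 0) {
      stop_data("shifts.csv: unparseable timestamp in column '", f,
                "', row ", bad[1])
    }
    attr(sec, "bad") <- NULL
    shifts[[f]] <- sec
  }
  if (is.null(shifts$weekdays)) shifts$weekdays <- "1111111"
  # CSV readers strip leading zeros off numeric-looking weekday masks
  shifts$weekdays <- sprintf("%07d", as.integer(shifts$weekdays))
  bases <- read_bundle_csv(file.path(path, "bases.csv"),
                           c("base_id", "lon", "lat"))
  if (is.null(bases$name)) bases$name <- bases$base_id
  if (is.null(bases$region)) bases$region <- "own"
  hospitals <- NULL
  if (file.exists(file.path(path, "hospitals.csv"))) {
    hospitals <- read_bundle_csv(file.path(path, "hospitals.csv"),
                                 c("hospital_id", "lon", "lat", "capabilities"))
    if (nrow(hospitals) == 0) hospitals <- NULL
  }
  communities <- NULL
  if (file.exists(file.path(path, "communities.csv"))) {
    communities <- read_bundle_csv(file.path(path, "communities.csv"),
                                   c("community_id", "name", "lon", "lat"))
  }
  s <- ems_scenario(inc, events, units, shifts, bases, hospitals, communities,
                    cfg)
  v <- validate_scenario(s)
  if (nrow(v) > 0) {
    stop_data("invalid scenario bundle '", path, "': ",
              paste(utils::head(v$message, 5), collapse = "; "),
              if (nrow(v) > 5) sprintf(" (and %d more)", nrow(v) - 5) else "")
  }
  s
}

read_bundle_csv <- function(file, required_cols) {
  tab <- tryCatch(
    utils::read.csv(file, stringsAsFactors = FALSE, check.names = FALSE),
    error = function(e) stop_data(basename(file), ": ", conditionMessage(e)))
  missing <- setdiff(required_cols, names(tab))
  if (length(missing) > 0) {
    stop_data(basename(file), ": schema mismatch, missing column(s) ",
              paste0("'", missing, "'", collapse = ", "))
  }
  for (nm in names(tab)) {
    if (is.character(tab[[nm]])) tab[[nm]][is_blank(tab[[nm]])] <- NA_character_
  }
  tab
}

config_to_list <- function(cfg) {
  out <- unclass(cfg)
  out$profiles <- lapply(cfg$profiles, function(p) {
    u <- unclass(p)
    m <- u$speeds
    u$speeds <- stats::setNames(
      lapply(seq_len(nrow(m)), function(i) as.list(m[i, ])), rownames(m))
    u
  })
  out
}

config_from_list <- function(lst) {
  profiles <- lapply(lst$profiles, function(p) {
    sp <- p$speeds # named list (unit type) of named lists (priority)
    m <- do.call(rbind, lapply(sp, function(row) unlist(row)))
    rownames(m) <- names(sp)
    speed_profile(profile_id = p$profile_id, mode = p$mode, speeds = m,
                  detour_factor = p$detour_factor %||% 1,
                  overhead_min = p$overhead_min %||% 0,
                  backend_scale = unlist(p$backend_scale))
  })
  names(profiles) <- vapply(profiles, function(p) p$profile_id, character(1))
  ems_config(
    mart = lst$mart, martcr_target = lst$martcr_target,
    rt_variant = lst$rt_variant,
    high_priority_set = unlist(lst$high_priority_set),
    cutoff_km = lst$cutoff_km, cutoff_min = lst$cutoff_min,
    enforce_regions = isTRUE(lst$enforce_regions),
    follow_up_mode = lst$follow_up_mode,
    seed = lst$seed, epsilon_pp = lst$epsilon_pp,
    epoch = lst$epoch,
    horizon = if (is.null(lst$horizon)) NULL else unlist(lst$horizon),
    service_times = lst$service_times,
    profiles = profiles,
    mco = lst$mco,
    count_unserved = isTRUE(lst$count_unserved)
  )
}
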