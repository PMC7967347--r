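# Internal helpers shared across modules: time codecs, geometry, enums.

PRIORITY_CODES <- c("P1", "P2", "P3", "S1", "S2", "S3")
UNIT_TYPES <- c("AMBULANCE", "TRANSPORT", "PEP_CAR", "HELICOPTER", "MCO",
                "FIRST_RESPONDER")
TRACER_CODES <- c("TBI", "STROKE", "POLYTRAUMA", "STEMI", "SCD", "SEPSIS",
                  "GENERAL")
# Fig-1 event sequence; present fields must be non-decreasing in this order.
CHAIN_FIELDS <- c("t_call_dispatch", "t_call_ems", "t_depart_base",
                  "t_arrive_scene", "t_depart_scene", "t_arrive_hospital",
                  "t_free", "t_arrive_base")

DEFAULT_EPOCH <- "2025-01-06T00:00:00Z" # a Monday, so weekday masks anchor cleanly

`%||%` <- function(a, b) if (is.null(a)) b else a

parse_epoch <- function(epoch) {
  t <- as.POSIXct(epoch, format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  if (is.na(t)) t <- as.POSIXct(epoch, tz = "UTC")
  if (is.na(t)) stop("unparseable epoch: ", epoch)
  t
}

# seconds-since-epoch -> ISO-8601 UTC string ("" for NA)
sec_to_iso <- function(sec, epoch = DEFAULT_EPOCH) {
  out <- rep("", length(sec))
  ok <- !is.na(sec)
  out[ok] <- format(parse_epoch(epoch) + sec[ok], "%Y-%m-%dT%H:%M:%SZ",
                    tz = "UTC")
  out
}

# ISO-8601 UTC string -> seconds since epoch (NA for ""/NA); attr "bad" holds
# indices that failed to parse
iso_to_sec <- function(x, epoch = DEFAULT_EPOCH) {
  x <- as.character(x)
  out <- rep(NA_real_, length(x))
  nonblank <- !is.na(x) & nzchar(x)
  t <- as.POSIXct(x[nonblank], format = "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out[nonblank] <- as.numeric(t) - as.numeric(parse_epoch(epoch))
  bad <- which(nonblank)[is.na(t)]
  attr(out, "bad") <- bad
  out
}

is_blank <- function(x) is.na(x) | !nzchar(as.character(x))

# Ray casting with explicit boundary test; boundary counts as inside.
# poly: matrix/data.frame with columns lon, lat (ring, need not be closed).
point_in_polygon <- function(lon, lat, poly) {
  poly <- as.matrix(poly[, 1:2])
  n <- nrow(poly)
  if (n < 3L) stop("degenerate polygon: fewer than 3 vertices")
  px <- poly[, 1]; py <- poly[, 2]
  if (px[1] == px[n] && py[1] == py[n]) { # drop closing vertex
    px <- px[-n]; py <- py[-n]; n <- n - 1L
    if (n < 3L) stop("degenerate polygon: fewer than 3 distinct vertices")
  }
  vapply(seq_along(lon), function(k) {
    x <- lon[k]; y <- lat[k]
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      xi <- px[i]; yi <- py[i]; xj <- px[j]; yj <- py[j]
      # on-segment check (boundary inside)
      cross <- (xj - xi) * (y - yi) - (yj - yi) * (x - xi)
      if (abs(cross) < 1e-12 &&
          x >= min(xi, xj) - 1e-12 && x <= max(xi, xj) + 1e-12 &&
          y >= min(yi, yj) - 1e-12 && y <= max(yi, yj) + 1e-12) {
        return(TRUE)
      }
      if ((yi > y) != (yj > y)) {
        xcross <- xi + (y - yi) / (yj - yi) * (xj - xi)
        if (x < xcross) inside <- !inside
      }
      j <- i
    }
    inside
  }, logical(1))
}

# merge sorted/unsorted intervals (2-col matrix start,end) into disjoint union
merge_intervals <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(matrix(numeric(0), ncol = 2))
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1L) for (i in 2:nrow(m)) {
    last <- nrow(out)
    if (m[i, 1] <= out[last, 2]) {
      out[last, 2] <- max(out[last, 2], m[i, 2])
    } else {
      out <- rbind(out, m[i, ])
    }
  }
  out
}

interval_overlap <- function(a_start, a_end, m) {
  if (nrow(m) == 0L) return(0)
  lo <- pmax(a_start, m[, 1]); hi <- pmin(a_end, m[, 2])
  sum(pmax(0, hi - lo))
}

in_intervals <- function(t, m) {
  if (nrow(m) == 0L) return(FALSE)
  any(t >= m[, 1] & t < m[, 2])
}

round1 <- function(x) round(x, 1)

stop_data <- function(...) {
  stop(structure(class = c("ems_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
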