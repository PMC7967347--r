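# Dispatch policies, queueing, unit state machine, determinism.

test_that("a single staffed unit serves a single incident closest-idle", {
  # unit 10 effective minutes away, 1 min turnout: RT = 11 min
  s <- h_scenario(h_incident("I1", 60, 10))
  sim <- simulate_scenario(s, "STANDARD")
  a <- sim$assignments
  expect_equal(a$policy, "CLOSEST_IDLE")
  expect_equal(a$unit_id, "U01")
  expect_equal(a$eta_min, 10, tolerance = 1e-9)
  ch <- sim$sim_times
  expect_equal(ch$t_depart_base, 60 * 60 + 60)
  expect_equal((ch$t_arrive_scene - ch$t_call_ems) / 60, 11, tolerance = 1e-9)
  # non-transport: free when leaving the scene, 10 min on scene
  expect_equal(ch$t_free, ch$t_depart_scene)
  expect_equal((ch$t_depart_scene - ch$t_arrive_scene) / 60, 10)
})

test_that("the second of two simultaneous P1 incidents queues until t_free", {
  inc <- rbind(h_incident("I1", 10, 5), h_incident("I2", 10, 5))
  s <- h_scenario(inc, n_units = 1)
  sim <- simulate_scenario(s, "STANDARD")
  a <- sim$assignments
  expect_equal(a$policy[1], "CLOSEST_IDLE")
  expect_equal(a$policy[2], "QUEUED>CLOSEST_IDLE")
  # first mission: turnout 1 + travel 5 + scene 10 -> free 16 min after call
  t_free1 <- sim$sim_times$t_free[1]
  expect_equal(t_free1, 10 * 60 + 16 * 60)
  expect_equal(sim$queue_log$dequeue, t_free1)
  expect_equal(a$queue_delay_min[2], 16, tolerance = 1e-9)
  # both served by the only unit, with disjoint busy intervals
  expect_equal(a$unit_id, c("U01", "U01"))
  expect_lte(sim$sim_times$t_free[1], a$t_dispatch[2])
})

test_that("equal ETAs break ties to the smallest unit id", {
  s <- h_scenario(h_incident("I1", 10, 5), n_units = 3)
  sim <- simulate_scenario(s, "STANDARD")
  expect_equal(sim$assignments$unit_id, "U01")
  expect_equal(closest_idle(data.frame(unit_id = c("u1", "u2", "u3"),
                                       eta_min = c(7, 5, 9))), "u2")
  expect_equal(closest_idle(data.frame(unit_id = c("u2", "u1"),
                                       eta_min = c(5, 5))), "u1")
  expect_equal(closest_idle(NULL), NA_character_)
})

test_that("candidates beyond the cut-off are never dispatched", {
  s <- h_scenario(h_incident("I1", 10, 10),
                  config = test_config(cutoff_min = 5))
  sim <- simulate_scenario(s, "STANDARD")
  expect_equal(sim$assignments$policy, "UNSERVED")
  expect_true("I1" %in% sim$unserved)
  expect_true(all(is.na(sim$sim_times$t_arrive_scene)))
})

test_that("low priority picks the historic unit even when another is nearer", {
  # two bases; historic unit at the far base
  bases <- data.frame(base_id = c("B1", "B2"), lon = 8.5,
                      lat = c(47.4, pt_north(47.4, 20)),
                      name = c("b1", "b2"), region = "own")
  units <- data.frame(unit_id = c("U01", "U02"), type = "AMBULANCE",
                      base_id = c("B1", "B2"),
                      speed_profile_id = "ground_default")
  shifts <- data.frame(unit_id = c("U01", "U02"), start = 0, end = 86400,
                       recurrence = "once", weekdays = "1111111")
  inc <- h_incident("I1", 60, 2, priority = "P3", historic_unit_id = "U02")
  events <- data.frame(event_id = "I1", incident_id = "I1")
  s <- ems_scenario(inc, events, units, shifts, bases,
                    config = test_config(horizon = c(0, 86400)))
  sim <- simulate_scenario(s, "STANDARD")
  expect_equal(sim$assignments$unit_id, "U02")
  expect_equal(sim$assignments$policy, "HISTORIC")

  # historic unit busy: falls back to the closest idle one
  inc2 <- rbind(h_incident("I0", 55, 19, priority = "P1"), # near B2: U02 takes it
                inc)
  s2 <- ems_scenario(inc2, data.frame(event_id = inc2$incident_id,
                                      incident_id = inc2$incident_id),
                     units, shifts, bases,
                     config = test_config(horizon = c(0, 86400)))
  sim2 <- simulate_scenario(s2, "STANDARD")
  a2 <- sim2$assignments
  expect_equal(a2$unit_id[a2$incident_id == "I0"], "U02")
  expect_equal(a2$unit_id[a2$incident_id == "I1"], "U01")
  expect_equal(a2$policy[a2$incident_id == "I1"], "HISTORIC_FALLBACK_CLOSEST")

  # no historic reference: plain fallback
  d <- historic_or_closest(NA_character_,
                           data.frame(unit_id = "U09", eta_min = 4))
  expect_equal(d$unit_id, "U09")
  expect_equal(d$policy, "HISTORIC_FALLBACK_CLOSEST")
})

test_that("the multicopter rule gates on availability, range and ETA", {
  # rule-level checks
  ground <- data.frame(unit_id = "P1CAR", eta_min = 25)
  mco <- data.frame(unit_id = "MCO1", eta_min = 12, round_trip_km = 40)
  expect_equal(mco_or_ground(ground, mco, range_km = 50)$policy, "MCO")
  mco_far <- transform(mco, round_trip_km = 60)
  d <- mco_or_ground(ground, mco_far, range_km = 50)
  expect_equal(d$policy, "CLOSEST_IDLE")
  expect_equal(d$unit_id, "P1CAR")
  # no MCO in the fleet: decision collapses to closest idle
  expect_equal(mco_or_ground(ground, NULL, 50)$unit_id, "P1CAR")
  # MCO slower than ground PEP: ground wins
  mco_slow <- transform(mco, eta_min = 30)
  expect_equal(mco_or_ground(ground, mco_slow, 50)$unit_id, "P1CAR")
  # no ground PEP at all: MCO despite anything
  expect_equal(mco_or_ground(NULL, mco, 50)$policy, "MCO")
})

test_that("the engine dispatches the MCO when faster and within range", {
  bases <- data.frame(base_id = c("B1", "B2"), lon = 8.5,
                      lat = c(47.4, pt_north(47.4, 5)),
                      name = c("pepbase", "mcobase"), region = "own")
  units <- data.frame(unit_id = c("PEP1", "MCO1"), type = c("PEP_CAR", "MCO"),
                      base_id = c("B1", "B2"),
                      speed_profile_id = c("ground_default", "air_default"))
  shifts <- data.frame(unit_id = c("PEP1", "MCO1"), start = 0, end = 86400,
                       recurrence = "once", weekdays = "1111111")
  # scene 25 km north of B1 -> ground ETA 25 min; 20 km from B2 -> MCO 20 min
  inc <- h_incident("I1", 60, 25, required_type = "PEP_CAR")
  s <- ems_scenario(inc, data.frame(event_id = "I1", incident_id = "I1"),
                    units, shifts, bases,
                    config = test_config(horizon = c(0, 86400)))
  sim <- simulate_scenario(s, "STANDARD")
  expect_equal(sim$assignments$unit_id, "MCO1")
  expect_equal(sim$assignments$policy, "MCO")

  # same geometry but a 30-km range: round trip 40 km exceeds it -> ground
  cfg2 <- test_config(horizon = c(0, 86400))
  cfg2$mco$range_km <- 30
  s2 <- s; s2$config <- cfg2
  sim2 <- simulate_scenario(s2, "STANDARD")
  expect_equal(sim2$assignments$unit_id, "PEP1")
})

test_that("hospital selection skips nearer hospitals without the capability", {
  hosp <- data.frame(hospital_id = c("HNEAR", "HFAR"),
                     lon = 8.5, lat = c(pt_north(47.4, 2), pt_north(47.4, 9)),
                     capabilities = c("GENERAL", "GENERAL;STROKE"))
  sel <- select_hospital(8.5, 47.4, hosp, "STROKE",
                         profile = test_profiles()$ground_default)
  expect_equal(sel$hospital_id, "HFAR")
  expect_false(sel$downgraded)
  # all capable: nearest wins
  sel2 <- select_hospital(8.5, 47.4, hosp, "GENERAL",
                          profile = test_profiles()$ground_default)
  expect_equal(sel2$hospital_id, "HNEAR")
  # capability nowhere: nearest GENERAL, flagged downgraded
  sel3 <- select_hospital(8.5, 47.4, hosp, "TBI",
                          profile = test_profiles()$ground_default)
  expect_equal(sel3$hospital_id, "HNEAR")
  expect_true(sel3$downgraded)
  # no hospital table: transport falls back to the service-time model
  expect_null(select_hospital(8.5, 47.4, NULL, "STROKE"))
})

test_that("service timelines are additive and always ordered", {
  tl <- service_timeline(0, 1, 10, 10, transport = NULL, return_min = 10)
  expect_equal(unname(tl["t_free"]), unname(tl["t_depart_scene"]))
  tl2 <- service_timeline(0, 1, 10, 10,
                          transport = list(travel_min = 8, handover_min = 5),
                          return_min = 4)
  expect_equal(unname(tl2["t_arrive_hospital"] - tl2["t_depart_scene"]),
               8 * 60)
  expect_equal(unname(tl2["t_free"] - tl2["t_arrive_hospital"]), 5 * 60)
  set.seed(42)
  for (k in 1:2000) {
    tr <- if (stats::runif(1) < 0.5) {
      list(travel_min = stats::rlnorm(1, 2, 0.5),
           handover_min = stats::rlnorm(1, 2, 0.5))
    } else NULL
    tl <- service_timeline(stats::runif(1, 0, 1e5), stats::rlnorm(1, 0, 0.5),
                           stats::rlnorm(1, 2, 0.5), stats::rlnorm(1, 2, 0.5),
                           tr, stats::rlnorm(1, 2, 0.5))
    present <- tl[!is.na(tl)]
    expect_false(is.unsorted(present[setdiff(names(present), "t_free")]))
  }
})

test_that("no unit ever serves two incidents with overlapping busy intervals", {
  for (seed in c(3, 17)) {
    s <- rand_mini_scenario(seed)
    sim <- simulate_scenario(s, "STANDARD")
    a <- sim$assignments
    ch <- sim$sim_times
    for (u in unique(stats::na.omit(a$unit_id))) {
      idx <- which(!is.na(a$unit_id) & a$unit_id == u)
      iv <- cbind(a$t_dispatch[idx], ch$t_free[idx])
      iv <- iv[order(iv[, 1]), , drop = FALSE]
      if (nrow(iv) > 1) {
        expect_true(all(iv[-1, 1] >= iv[-nrow(iv), 2] - 1e-9))
      }
    }
  }
})

test_that("identical scenario, config and seed give identical results", {
  cfg <- synth_config(horizon_days = 2, seed = 5)
  s <- gen_scenario(cfg)
  sim1 <- simulate_scenario(s, "STANDARD")
  sim2 <- simulate_scenario(s, "STANDARD")
  expect_identical(sim1$assignments, sim2$assignments)
  expect_identical(sim1$sim_times, sim2$sim_times)
})

test_that("unlimited mode with zero travel and turnout is fully compliant", {
  inc <- do.call(rbind, lapply(1:5, function(k) {
    h_incident(paste0("I", k), k * 10, 0)
  }))
  cfg <- test_config()
  cfg$service_times$turnout_median_min <- 0
  s <- h_scenario(inc, config = cfg)
  sim <- simulate_scenario(s, "UNLIMITED")
  expect_equal(rtcr(s$events, sim$sim_times, 15, "PREP_PLUS_TRANSIT"), 100)
  expect_true(all(sim$assignments$policy == "UNLIMITED"))
  expect_true(all(startsWith(sim$assignments$unit_id, "virtual:")))
})

test_that("chained follow-up mode can dispatch a returning unit from the scene", {
  # incident A far north; incident B near A's scene, called during U01's
  # return leg: CHAINED serves B from the scene position, START_AT_BASE
  # from the base
  inc <- rbind(h_incident("IA", 10, 30), h_incident("IB", 60, 29))
  cfg_chain <- test_config(follow_up_mode = "CHAINED")
  s1 <- h_scenario(inc, config = cfg_chain)
  s2 <- h_scenario(inc, config = test_config())
  eta_chained <- simulate_scenario(s1, "STANDARD")$assignments$eta_min[2]
  eta_base <- simulate_scenario(s2, "STANDARD")$assignments$eta_min[2]
  expect_lt(eta_chained, eta_base)
  expect_equal(eta_chained, 1, tolerance = 1e-6) # 1 km from the IA scene
  expect_equal(eta_base, 29, tolerance = 1e-6)
})
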