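# Per-iteration motion: multi-site hops, lateral moves, crowding and
# processivity detachment, sweep-order semantics.

test_that("an unobstructed fast motor hops its full velocity", {
  geo <- small_geo(30)
  sc <- build_scenario(1, geo)
  r <- run_state(sc, motor_at(2, 1, 1L), 1, test_species(geo))
  m <- r$motors
  expect_identical(m$site, 8L)
  expect_identical(m$lane, 2L)
  expect_identical(m$run_sites, 7L)
  expect_identical(m$status, "on_lattice")
})

test_that("a blocked fast motor detaches when lateral movement is off", {
  geo <- small_geo(30)
  # ATP-depleted everywhere so the detached motor stays in the reservoir
  sc <- build_scenario(2, geo,
                       atp_zones = list(list(lanes = 1:3, site_start = 1,
                                             site_end = 30)),
                       atp_wait_s = 1000)
  ini <- rbind(motor_at(2, 10, 1L), motor_at(2, 13, 2L))
  r <- run_state(sc, ini, 1, test_species(geo))
  m <- r$motors
  expect_identical(m$status[1], "in_reservoir")
  expect_identical(sum(r$sections[[1]]$detach_counts[2, 10, "Kin3F", "crowding"]), 1L)
  expect_identical(m$site[2], 16L)  # the slow leader walked on
})

test_that("a blocked fast motor side-steps to site + v of an adjacent lane", {
  geo <- small_geo(30)
  sc <- build_scenario(1, geo)
  ini <- rbind(motor_at(2, 10, 1L), motor_at(2, 12, 2L))
  # minus-end-first sweep: the trailing fast motor steps before its leader
  r <- run_state(sc, ini, 1, test_species(geo))
  m <- r$motors
  expect_true(m$lane[1] %in% c(1L, 3L))
  expect_identical(m$site[1], 17L)
  expect_identical(m$run_sites[1], 7L)
  expect_identical(m$status[1], "on_lattice")
})

test_that("lateral moves respect blocked sites on the adjacent lanes", {
  geo <- small_geo(30)
  acc <- matrix(TRUE, 3, 30)
  acc[c(1, 3), 17] <- FALSE  # both side-step targets blocked
  sc <- scenario_spec(geo, accessible = acc, lateral_allowed = TRUE,
                      atp_zones = list(list(lanes = 1:3, site_start = 1,
                                            site_end = 30)),
                      atp_wait_s = 1000)
  ini <- rbind(motor_at(2, 10, 1L), motor_at(2, 12, 2L))
  r <- run_state(sc, ini, 1, test_species(geo))
  expect_identical(r$motors$status[1], "in_reservoir")
})

test_that("processivity detachment triggers at the configured run length", {
  geo <- lattice_geometry(mt_length_nm = 4000)
  sc <- build_scenario(1, geo)
  sp <- test_species(geo, p_slow = 130L)
  # a lone slow motor advances 3 sites/iteration: run_sites crosses 130
  # on the 44th hop (132 >= 130) at site 133, then detaches and may
  # immediately reattach to the 3x3 neighbourhood with run_sites reset
  r <- run_state(sc, motor_at(1, 1, 2L), 44, sp)
  det <- r$sections[[1]]$detach_counts
  expect_identical(sum(det[, , "Kin1S", "processivity"]), 1L)
  expect_identical(sum(det[1, 133, "Kin1S", ]), 1L)
  m <- r$motors
  expect_lte(abs(m$site - 133L), 1L)
  expect_lte(m$run_sites, 1L)  # reset on reattachment
  r43 <- run_state(sc, motor_at(1, 1, 2L), 43, sp)
  expect_identical(sum(r43$sections[[1]]$detach_counts), 0L)
  expect_identical(r43$motors$run_sites, 129L)
})

test_that("minus-end-first sweep: a vacancy opened ahead is seen next iteration", {
  geo <- lattice_geometry(mt_length_nm = 4000)
  sc <- build_scenario(2, geo)  # no lateral escape
  sp <- test_species(geo)
  ini <- rbind(motor_at(1, 492, 1L), motor_at(1, 498, 2L))
  r <- run_state(sc, ini, 1, sp, crowding_detach = FALSE)
  m <- r$motors
  expect_identical(m$status[2], "delivered")  # 498 + 3 > 500, clear path
  # the trailing motor was stepped before its leader exited: it stalled
  expect_identical(m$site[1], 492L)
  r2 <- run_state(sc, ini, 2, sp, crowding_detach = FALSE)
  expect_identical(r2$motors$site[1], 499L)
})

test_that("plus-end-first sweep exposes vacancies within the same iteration", {
  geo <- lattice_geometry(mt_length_nm = 4000)
  sc <- build_scenario(2, geo)
  sp <- test_species(geo)
  ini <- rbind(motor_at(1, 492, 1L), motor_at(1, 498, 2L))
  r <- run_state(sc, ini, 1, sp, crowding_detach = FALSE,
                 update_order = "descending")
  m <- r$motors
  expect_identical(m$status[2], "delivered")
  expect_identical(m$site[1], 499L)  # advanced into the space freed ahead
})

test_that("exclusion and ledger invariants hold under randomised stress", {
  geo <- small_geo(60)
  for (seed in 1:3) {
    sc <- build_scenario(sample(1:8, 1), geo)
    r <- run_multi(sc, influx_config(15, 15), species = default_species(geo),
                   horizon_s = 2000 * geo$dt_s, seed = seed,
                   snapshot_every = 100)
    expect_true(all(r$snapshot_ok))
    with(r$snapshots, expect_true(all(
      created == queued + on_lattice + in_reservoir + delivered + leaked +
        in_junction + dropped)))
  }
})

test_that("run length never exceeds processivity while bound", {
  geo <- lattice_geometry(mt_length_nm = 4000)
  r <- run_simulation(build_scenario(1, geo), influx_config(10, 10),
                      horizon_s = 60, seed = 11)
  m <- r$motors[r$motors$status == "on_lattice", ]
  p <- ifelse(m$species == "Kin3F", 780L, 130L)
  expect_true(all(m$run_sites < p))
})
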