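# Langmuir-kinetics reservoirs: capacity, ATP waiting, leakage, FIFO
# reattachment and motor conservation.

# a dead-end lane: all lanes blocked beyond site 20, no lateral movement,
# so fast motors detach where they hit the wall
dead_end <- function(n_sites = 30, capacity = 50, atp_wait_s = 0,
                     lifetime = 1000000L) {
  geo <- small_geo(n_sites)
  acc <- matrix(TRUE, 3, n_sites)
  acc[, 21:n_sites] <- FALSE
  zones <- if (atp_wait_s > 0)
    list(list(lanes = 1:3, site_start = 1, site_end = n_sites))
  sc <- scenario_spec(geo, accessible = acc, lateral_allowed = FALSE,
                      reservoir_capacity = capacity, atp_zones = zones,
                      atp_wait_s = atp_wait_s)
  list(geo = geo, sc = sc,
       sp = test_species(geo, lt_fast = lifetime, lt_slow = lifetime))
}

test_that("a full reservoir refuses detachment and the motor stalls", {
  d <- dead_end(capacity = 1, atp_wait_s = 1000)
  # motor A walks 18 -> hits the wall (gap 2 < 7) and fills the reservoir
  # at (2,18); motor B follows and must stall there when it is refused
  ini <- rbind(motor_at(2, 18, 1L), motor_at(2, 4, 1L))
  r <- run_state(d$sc, ini, 5, d$sp)
  m <- r$motors
  expect_identical(m$status[1], "in_reservoir")
  expect_identical(m$status[2], "on_lattice")
  expect_identical(m$site[2], 18L)  # stalled in place, not destroyed
  expect_identical(sum(r$sections[[1]]$detach_counts), 1L)
})

test_that("reservoir residence beyond the lifetime leaks the motor", {
  d <- dead_end(atp_wait_s = 1000, lifetime = 5L)
  r <- run_state(d$sc, motor_at(2, 18, 1L), 10, d$sp)
  expect_identical(r$motors$status, "leaked")
  expect_identical(r$sections[[1]]$totals[["leaked"]], 1)
  lg <- run_ledger(r)
  expect_identical(lg[["created"]], sum(lg[-1]))
})

test_that("ATP-depleted anchors impose the minimum reservoir residence", {
  wait_s <- 10 * 0.04  # 10 iterations
  d <- dead_end(atp_wait_s = wait_s)
  # detaches on iteration 1; residence reaches 10 on iteration 11
  r8 <- run_state(d$sc, motor_at(2, 18, 1L), 8, d$sp)
  expect_identical(r8$motors$status, "in_reservoir")
  r11 <- run_state(d$sc, motor_at(2, 18, 1L), 11, d$sp)
  expect_identical(r11$motors$status, "on_lattice")
  expect_identical(r11$motors$run_sites, 0L)  # run length reset
  expect_identical(sum(r11$sections[[1]]$reattach_counts[2, 18, ]), 1L)
})

test_that("reattachment lands uniformly on the free neighbourhood cells", {
  geo <- small_geo(30)
  acc <- matrix(TRUE, 3, 30)
  acc[c(1, 3), 9:11] <- FALSE  # adjacent lanes closed around the anchor
  acc[2, 12] <- FALSE          # wall: forces detachment at (2,10)
  sc <- scenario_spec(geo, accessible = acc, lateral_allowed = FALSE)
  sp <- test_species(geo)
  # both motors detach during the sweep; at the reservoir update the fast
  # motor (anchor (2,10)) sees exactly three free cells: (2,9), (2,10), (2,11)
  hits <- integer(3)
  ok <- TRUE
  for (i in 1:3000) {
    r <- run_state(sc, rbind(motor_at(2, 10, 1L), motor_at(2, 11, 2L)),
                   1, sp, seed = i)
    m <- r$motors[1, ]
    ok <- ok && m$status == "on_lattice" && m$lane == 2L &&
      m$site %in% 9:11
    hits[m$site - 8L] <- hits[m$site - 8L] + 1L
  }
  expect_true(ok)
  expect_gt(chisq.test(hits)$p.value, 1e-4)
})

test_that("reservoirs release at most their FIFO head each iteration", {
  wait_s <- 10 * 0.04
  d <- dead_end(capacity = 5, atp_wait_s = wait_s)
  # A fills (2,18) on iteration 1; B walks 4 -> 11 -> 18 and detaches there
  # on iteration 3; both then wait out the ATP constraint
  ini <- rbind(motor_at(2, 18, 1L), motor_at(2, 4, 1L))
  r10 <- run_state(d$sc, ini, 10, d$sp)
  expect_identical(r10$motors$status, c("in_reservoir", "in_reservoir"))
  # iteration 11: A (head, residence 10) reattaches; B (residence 8) waits
  r11 <- run_state(d$sc, ini, 11, d$sp)
  expect_identical(r11$motors$status, c("on_lattice", "in_reservoir"))
  # iteration 13: B's residence reaches 10 and it follows
  r13 <- run_state(d$sc, ini, 13, d$sp)
  expect_identical(r13$motors$status[2], "on_lattice")
})

test_that("no motor leaks in any canonical scenario over a short horizon", {
  geo <- small_geo(100)
  for (id in c(1, 4, 7)) {
    r <- run_simulation(build_scenario(id, geo), influx_config(10, 10),
                        species = default_species(geo),
                        horizon_s = 40, seed = id)
    expect_identical(r$sections[[1]]$totals[["leaked"]], 0)
  }
})

test_that("conservation holds across random detach/reattach interleavings", {
  geo <- small_geo(80)
  total_leaked <- 0
  for (seed in 1:4) {
    sc <- build_scenario(c(2, 4, 5, 7)[seed], geo, reservoir_capacity = 3)
    sp <- test_species(geo, p_fast = 90L, p_slow = 40L, lt_fast = 200L,
                       lt_slow = 200L)
    r <- run_multi(sc, influx_config(20, 20), species = sp,
                   horizon_s = 1500 * geo$dt_s, seed = seed,
                   snapshot_every = 250)
    expect_true(all(r$snapshot_ok))
    with(r$snapshots, expect_true(all(
      created == queued + on_lattice + in_reservoir + delivered + leaked +
        in_junction + dropped)))
    total_leaked <- total_leaked + r$sections[[1]]$totals[["leaked"]]
  }
  expect_gt(total_leaked, 0)  # short lifetimes do bite under congestion
})
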