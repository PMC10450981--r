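# Event accounting: detachment rates, binning, dynamicity, output files.

test_that("detachment_rate is events over window duration", {
  geo <- small_geo(30)
  sc <- build_scenario(2, geo,
                       atp_zones = list(list(lanes = 1:3, site_start = 1,
                                             site_end = 30)),
                       atp_wait_s = 1000)
  # one crowding detachment on iteration 1, then nothing
  ini <- rbind(motor_at(2, 10, 1L), motor_at(2, 13, 2L))
  r <- run_state(sc, ini, 250, test_species(geo))
  expect_equal(detachment_rate(r, "fast"), 1 / 10)  # 1 event / 10 s
  expect_equal(detachment_rate(r, "fast", cause = "crowding"), 1 / 10)
  expect_equal(detachment_rate(r, "fast", cause = "processivity"), 0)
  expect_equal(detachment_rate(r, "fast", window = c(0, 2)), 1 / 2)
  expect_equal(detachment_rate(r, "fast", window = c(5, 10)), 0)
})

test_that("bin_outflow sums non-overlapping bins and flags partial tails", {
  b <- bin_outflow(rep(1, 25))
  expect_equal(as.numeric(b), 25)
  expect_false(attr(b, "partial_last"))
  expect_equal(as.numeric(bin_outflow(c(3, 1, 4, 1, 5), bin_iters = 1)),
               c(3, 1, 4, 1, 5))
  set.seed(8)
  x <- rpois(1013, 2)
  b2 <- bin_outflow(x)
  expect_equal(sum(b2), sum(x))
  expect_true(attr(b2, "partial_last"))
  expect_length(b2, ceiling(1013 / 25))
  expect_error(bin_outflow(x, 0))
})

test_that("binned and detailed outflow agree with the delivery ledger", {
  geo <- small_geo(100)
  r <- run_simulation(build_scenario(1, geo), influx_config(10, 10),
                      horizon_s = 60, seed = 21)
  delivered <- r$sections[[1]]$totals[["delivered"]]
  expect_equal(sum(outflow_binned(r)), delivered)
  expect_equal(sum(outflow_binned(r, by = "lane_species")), delivered)
  expect_equal(sum(outflow_detailed(r)$count), delivered)
})

test_that("dynamicity totals close against the event ledger", {
  geo <- small_geo(60)
  r <- run_simulation(build_scenario(5, geo), influx_config(15, 15),
                      horizon_s = 60, seed = 31)
  s <- r$sections[[1]]
  expect_identical(sum(dynamicity_map(r, "both")),
                   sum(s$detach_counts) + sum(s$reattach_counts))
  expect_equal(dynamicity_profile(r, "both"),
               colSums(dynamicity_map(r, "both")))
  expect_identical(sum(dynamicity_map(r, "fast")) +
                     sum(dynamicity_map(r, "slow")),
                   sum(dynamicity_map(r, "both")))
  # detachment series totals match positional counts
  expect_identical(sum(s$detach_series), sum(s$detach_counts))
})

test_that("a run with no detachments has an all-zero dynamicity profile", {
  geo <- small_geo(30)
  r <- run_state(build_scenario(1, geo), motor_at(2, 1, 1L), 3,
                 test_species(geo))
  expect_true(all(dynamicity_profile(r, "both") == 0))
})

test_that("run outputs are written and metrics.json is consistent", {
  geo <- small_geo(60)
  r <- run_simulation(build_scenario(4, geo), influx_config(10, 10),
                      horizon_s = 20, seed = 2)
  dir <- withr::local_tempdir()
  write_run_outputs(r, dir)
  expect_true(file.exists(file.path(dir, "metrics.json")))
  mj <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(mj$ledger$created,
               r$sections[[1]]$totals[["delivered"]] + mj$ledger$queued +
                 mj$ledger$on_lattice + mj$ledger$in_reservoir +
                 mj$ledger$leaked + mj$ledger$in_junction + mj$ledger$dropped)
  ob <- read.csv(file.path(dir, "outflow_binned_section1.csv"))
  expect_equal(sum(ob$count), r$sections[[1]]$totals[["delivered"]])
})

test_that("identical seeds give byte-identical outputs", {
  geo <- small_geo(60)
  a <- run_simulation(build_scenario(4, geo), influx_config(15, 15),
                      horizon_s = 30, seed = 77)
  b <- run_simulation(build_scenario(4, geo), influx_config(15, 15),
                      horizon_s = 30, seed = 77)
  expect_identical(a$motors, b$motors)
  expect_identical(a$sections, b$sections)
  c2 <- run_simulation(build_scenario(4, geo), influx_config(15, 15),
                       horizon_s = 30, seed = 78)
  expect_false(identical(a$sections[[1]]$outflow, c2$sections[[1]]$outflow))
})
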