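test_that("thermostat parameters are validated field by field", {
  expect_error(thermostat_params(retention = 1.5), "retention")
  expect_error(thermostat_params(deadband = 0), "deadband")
  expect_error(thermostat_params(horizon = 0), "horizon")
  expect_error(thermostat_params(heater_power = -1), "heater_power")
})

test_that("the unregulated room at outdoor equilibrium is a fixed point", {
  p <- thermostat_params(outdoor_amplitude = 0, outdoor_sd = 0,
                         initial_temperature = 18, horizon = 300)
  ep <- thermostat_episode(p, "off", seed = 1)
  expect_true(all(abs(ep$temperature - 18) < 1e-9))
  expect_identical(length(unique(ep$readout)), 1L)
})

test_that("bang-bang control confines the room and settles periodically", {
  p <- thermostat_params()
  ep <- thermostat_episode(p, "on", seed = 2)
  target <- p$setpoint + p$comfort_offset
  burn <- 500:p$horizon
  expect_true(all(ep$temperature[burn] >=
                    target - p$deadband - p$heater_power - 1e-9))
  expect_true(all(ep$temperature[burn] <=
                    target + p$deadband + p$heater_power + 1e-9))
  # readout tail is eventually periodic (here: clamped to one sensor cell)
  expect_false(is.na(tail_period(ep$readout, max_period = 64)))
  # episodes are deterministic given the seed
  ep2 <- thermostat_episode(p, "on", seed = 2)
  expect_identical(ep$readout, ep2$readout)
})

test_that("regulation shows up as a positive ON/OFF compressibility gap", {
  p <- thermostat_params()
  on <- thermostat_episode(p, "on", seed = 5)
  off <- thermostat_episode(p, "off", seed = 5)
  g <- delta_gap(on$readout, off$readout, est_lz76(8))
  expect_gt(g$delta_bits, 0)
})

test_that("reference strings meet their statistical contracts", {
  expect_identical(make_string("constant", 10), rep(0L, 10))
  expect_identical(make_string("periodic", 6, motif = "01"),
                   c(0L, 1L, 0L, 1L, 0L, 1L))
  n <- 1e5
  s <- make_string("bernoulli", n, p = 0.5, seed = 31)
  expect_lte(abs(mean(s) - 0.5), 3 * sqrt(0.25 / n))
  expect_identical(s, make_string("bernoulli", n, p = 0.5, seed = 31))
  expect_error(make_string("weird", 5), "unknown string kind")
})

test_that("the CLI runs, reruns byte-identically, and fails loudly", {
  dir <- tempfile(); dir.create(dir)
  old <- setwd(dir); on.exit(setwd(old))
  # fixtures twice -> identical files
  expect_identical(cli_main(c("fixtures", "thermostat", "--seed", "7",
                              "--out-prefix", "a")), 0L)
  expect_identical(cli_main(c("fixtures", "thermostat", "--seed", "7",
                              "--out-prefix", "b")), 0L)
  expect_identical(unname(tools::md5sum("a_on.csv")),
                   unname(tools::md5sum("b_on.csv")))
  # gap on the generated fixtures
  out <- tempfile(fileext = ".json")
  expect_identical(cli_main(c("gap", "--on", "a_on.csv", "--off", "a_off.csv",
                              "--out", out)), 0L)
  gp <- jsonlite::fromJSON(out)
  expect_gt(gp$delta_bits, 0)
  expect_true(file.exists(paste0(out, ".manifest.json")))
  # missing file -> nonzero exit, message names the path
  expect_message(bad <- cli_main(c("gap", "--on", "nope.csv",
                                   "--off", "a_off.csv")), "nope.csv")
  expect_identical(bad, 1L)
  expect_message(um <- cli_main(c("frobnicate")), "unknown command")
  expect_identical(um, 2L)
  # simulate is byte-identical across reruns
  transducer_to_json(thermostat_world_spec(8, 2), "w.json")
  transducer_to_json(bang_bang_spec(8, 3, 5), "r.json")
  expect_identical(cli_main(c("simulate", "--world", "w.json", "--regulator",
                              "r.json", "--horizon", "120", "--out",
                              "t1.csv")), 0L)
  expect_identical(cli_main(c("simulate", "--world", "w.json", "--regulator",
                              "r.json", "--horizon", "120", "--out",
                              "t2.csv")), 0L)
  expect_identical(unname(tools::md5sum("t1.csv")),
                   unname(tools::md5sum("t2.csv")))
})
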