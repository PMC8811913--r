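test_that("configuration invariants are enforced", {
  expect_error(turbidostat_config(od_setpoint = 0.2), "od_setpoint")
  expect_error(turbidostat_config(q_min = 5, q_max = 4), "q_min")
  expect_error(turbidostat_config(timestep = 0.5), "timestep")
  expect_error(turbidostat_config(timestep = 0), "timestep")
  expect_error(turbidostat_config(duration = -1), "duration")
})

test_that("identical config gives bit-identical trajectories", {
  t1 <- simulate_turbidostat(turbidostat_config(duration = 6, t_start = -3))
  t2 <- simulate_turbidostat(turbidostat_config(duration = 6, t_start = -3))
  expect_identical(t1$state, t2$state)
  expect_identical(t1$overflow, t2$overflow)
})

test_that("no nitrogen, subsistence quota: no growth and no dilution", {
  cfg <- turbidostat_config(feed_nitrate_pre = 0, feed_nitrate_post = 0,
                            q_init = 0.5, q_min = 0.5,
                            duration = 4, t_start = 0)
  traj <- simulate_turbidostat(cfg)
  expect_true(all(traj$state$mu_true == 0))
  expect_equal(nrow(traj$overflow), 0)
  expect_true(all(abs(traj$state$x - traj$state$x[1]) < 1e-9))
})

test_that("external nitrate is drawn down to ~0.03 mM by day 5 and stays low", {
  traj <- default_traj()
  st <- traj$state
  s5 <- st$s_ext[which.min(abs(st$time - 5))]
  expect_gt(s5, 0.015)
  expect_lt(s5, 0.05)
  late <- st$s_ext[st$time >= 5]
  expect_true(all(late < 0.06))
  # pre-switch the feed keeps nitrate near 10 mM
  expect_gt(st$s_ext[which.min(abs(st$time - (-3)))], 8)
})

test_that("quota transition falls between sampling days 5 and 6", {
  traj <- default_traj()
  expect_gt(traj$transition_time, 5)
  expect_lt(traj$transition_time, 6.5)
})

test_that("turbidity stays at most one control step above threshold", {
  traj <- default_traj()
  cfg <- traj$config
  max_over <- cfg$od_threshold * exp(cfg$mu_max * cfg$timestep)
  expect_true(all(traj$state$od735 <= max_over + 1e-12))
  expect_true(all(traj$state$s_ext >= 0))
  expect_true(all(traj$state$q_int >= 0))
  expect_true(all(traj$overflow$overflow_L >= 0))
})

test_that("steady replete feed holds the division rate constant within 1%", {
  cfg <- turbidostat_config(feed_nitrate_post = 10, duration = 15,
                            t_start = -10)
  st <- simulate_turbidostat(cfg)$state
  win <- st$mu_true[st$time >= 0 & st$time <= 5]
  expect_lt(diff(range(win)) / mean(win), 0.01)
})

test_that("the nitrogen budget is closed through every control step", {
  traj <- simulate_turbidostat(turbidostat_config(duration = 8, t_start = -4))
  st <- traj$state
  conv <- 1e-6 / 14
  total <- st$s_ext + st$x * st$q_int * conv   # mM N equivalents in the tank
  ev <- traj$events
  expected <- total[1]
  worst <- 0
  ev_i <- 1L
  for (i in 2:nrow(st)) {
    if (ev_i <= nrow(ev) && isTRUE(all.equal(ev$time[ev_i], st$time[i]))) {
      expected <- expected * (1 - ev$fraction[ev_i]) +
        ev$fraction[ev_i] * ev$feed[ev_i]
      ev_i <- ev_i + 1L
    }
    worst <- max(worst, abs(total[i] - expected) / expected)
    expected <- total[i]
  }
  expect_lt(worst, 1e-3)
})

test_that("noiseless trait table equals the phase-mean trajectory exactly", {
  traj <- default_traj()
  cfg <- traj$config
  cfg$noise_cv <- 0
  tt <- generate_trait_table(traj, cfg)
  expect_equal(unname(as.matrix(tt[, -1])), unname(attr(tt, "noiseless")),
               tolerance = 1e-12)
})

test_that("nitrogen quota phase means are pinned to the tabulated values", {
  traj <- default_traj()
  cfg <- traj$config
  cfg$noise_cv <- 0
  tt <- generate_trait_table(traj, cfg)
  expect_equal(mean(tt$n_int[tt$day <= 4]), 2.78, tolerance = 1e-9)
  expect_equal(mean(tt$n_int[tt$day >= 7]), 0.99, tolerance = 1e-9)
  # noisy table stays close
  ttn <- generate_trait_table(traj)
  expect_equal(mean(ttn$n_int[ttn$day <= 4]), 2.78, tolerance = 0.1)
  expect_equal(mean(ttn$n_int[ttn$day >= 7]), 0.99, tolerance = 0.15)
})

test_that("trait quotas are non-negative for any seed", {
  traj <- default_traj()
  for (seed in c(1, 7, 99)) {
    cfg <- traj$config
    cfg$seed <- seed
    cfg$noise_cv <- 0.3   # aggressive noise to exercise the clip
    tt <- generate_trait_table(traj, cfg)
    expect_true(all(as.matrix(tt[, -1]) >= 0))
  }
})

test_that("requesting days outside the simulated span fails", {
  traj <- simulate_turbidostat(turbidostat_config(duration = 6, t_start = -3))
  expect_error(generate_trait_table(traj, days = -2:15), "span")
})

test_that("trait table generation is deterministic given the seed", {
  traj <- default_traj()
  expect_identical(generate_trait_table(traj), generate_trait_table(traj))
})
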