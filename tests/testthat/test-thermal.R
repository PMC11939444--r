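test_that("thermal budget reproduces the published worst case", {
  dt <- delta_t_budget(1.1e-2, dish_diameter_m = 0.053, duration_h = 0.25,
                       heat_capacity_wh_per_m3k = C_WATER_WH_PER_M3K,
                       volume_m3 = 4.5e-6)
  expect_equal(signif(dt, 2), 1.2e-3)
  expect_equal(delta_t_budget(0), 0)
  # kidney-tissue capacity variant (documented printed-value inconsistency:
  # the formula with printed inputs gives 1.33e-3, see the methods vignette)
  expect_equal(signif(delta_t_budget(1.1e-2,
                      heat_capacity_wh_per_m3k = C_KIDNEY_WH_PER_M3K), 2),
               1.3e-3)
})

test_that("thermal budget is exactly linear / inverse in each factor", {
  set.seed(8)
  for (i in 1:20) {
    p <- runif(1, 1e-7, 1e-1); phi <- runif(1, 0.01, 0.1)
    th <- runif(1, 0.05, 10); cc <- runif(1, 500, 4000)
    v <- runif(1, 1e-7, 1e-4); k <- runif(1, 0.1, 10)
    base <- delta_t_budget(p, phi, th, cc, v)
    expect_equal(delta_t_budget(k * p, phi, th, cc, v), k * base)
    expect_equal(delta_t_budget(p, phi, k * th, cc, v), k * base)
    expect_equal(delta_t_budget(p, sqrt(k) * phi, th, cc, v), k * base)
    expect_equal(delta_t_budget(p, phi, th, k * cc, v), base / k)
    expect_equal(delta_t_budget(p, phi, th, cc, k * v), base / k)
  }
  expect_error(delta_t_budget(-1), "incident")
  expect_error(delta_t_budget(1, duration_h = 0))
})

test_that("IMC tuning follows the first-order-plus-dead-time rules", {
  pl <- plant_model(30, 600, 20)
  g <- imc_pid_gains(pl, closed_loop_tau_s = 120)
  expect_equal(g$kp, 600 / (30 * 140))
  expect_equal(g$ki, g$kp / 600)  # integral time = tau
  expect_equal(g$kd, 0)
  expect_equal(g$setpoint_c, 37)
  # halved gain doubles kp; larger lambda_c is more conservative
  expect_equal(imc_pid_gains(plant_model(60, 600, 20), 120)$kp, g$kp / 2)
  expect_lt(imc_pid_gains(pl, 1200)$kp, g$kp)
  expect_error(imc_pid_gains(plant_model(0, 600, 20), 120), "gain is zero")
})

test_that("step-response identification recovers the plant", {
  pl <- plant_model(30, 600, 20)
  tr <- step_response(pl, duty_from = 0, duty_to = 0.5, duration_s = 5000)
  est <- identify_fopdt(tr, 0.5)
  expect_equal(est$static_gain_c_per_duty, 30, tolerance = 0.02)
  expect_equal(est$time_constant_s, 600, tolerance = 0.02)
  expect_equal(est$dead_time_s, 20, tolerance = 0.02)

  trn <- step_response(pl, 0, 0.5, duration_s = 5000, noise_sd_c = 0.05,
                       seed = 19)
  estn <- identify_fopdt(trn, 0.5)
  expect_equal(estn$static_gain_c_per_duty, 30, tolerance = 0.1)
  expect_equal(estn$time_constant_s, 600, tolerance = 0.1)
  expect_equal(estn$dead_time_s, 20, tolerance = 0.1)

  expect_error(identify_fopdt(tr, 0), "zero step")
  short <- step_response(pl, 0, 0.5, duration_s = 600)
  expect_error(identify_fopdt(short, 0.5), "not settled")
})

test_that("regulation holds the setpoint and rejects load disturbances", {
  pl <- plant_model()
  g <- imc_pid_gains(pl)
  # equilibrium: start at setpoint, no disturbance
  tr <- simulate_regulation(pl, g, duration_s = 1200, start_temp_c = 37)
  expect_lt(max(abs(tr$temp_c - 37)), 1e-9)
  # integral action drives steady-state error to zero under constant load
  trl <- simulate_regulation(pl, g, duration_s = 7200, start_temp_c = 37,
                             load_disturbance_c = -3)
  expect_lt(abs(utils::tail(trl$temp_c, 1) - 37), 0.02)
  # no controller: the plant relaxes to ambient
  off <- list(kp = 0, ki = 0, kd = 0, setpoint_c = 37)
  trd <- simulate_regulation(pl, off, duration_s = 5000, start_temp_c = 37)
  expect_equal(utils::tail(trd$temp_c, 1), 22, tolerance = 0.01)
})

test_that("hood openings give sub-1-degC dips and in-band recovery", {
  pl <- plant_model()
  g <- imc_pid_gains(pl)
  sched <- gen_hood_schedule(2, open_duration_s = 30, spacing_s = 900,
                             start_s = 600)
  tr <- simulate_regulation(pl, g, sched, duration_s = 2400,
                            start_temp_c = 37)
  m <- trace_metrics(tr, setpoint_c = 37, band_c = 0.2)
  expect_lt(m$max_deviation_c, 1)
  expect_gte(m$band_occupancy, 0.95)
  expect_equal(m$n_events, 2)
  # schedule must fit the run
  expect_error(simulate_regulation(pl, g, sched, duration_s = 1000),
               "beyond")
  expect_error(simulate_regulation(pl, g, duration_s = 100, dt_s = 2),
               "dt_s")
})

test_that("seeded noisy runs are reproducible", {
  pl <- plant_model()
  g <- imc_pid_gains(pl)
  a <- simulate_regulation(pl, g, duration_s = 300, start_temp_c = 37,
                           noise_sd_c = 0.02, seed = 5)
  b <- simulate_regulation(pl, g, duration_s = 300, start_temp_c = 37,
                           noise_sd_c = 0.02, seed = 5)
  expect_identical(a, b)
})

test_that("trace metrics report deviations as constructed", {
  tr <- structure(
    data.frame(time_s = 0:99, temp_c = rep(37, 100), duty = 0.5,
               hood_open = FALSE),
    events = gen_hood_schedule(0), class = c("rf_temp_trace", "data.frame"))
  expect_equal(trace_metrics(tr)$max_deviation_c, 0)
  tr$temp_c[50] <- 36.2
  expect_equal(trace_metrics(tr)$max_deviation_c, 0.8)
})

test_that("traces round-trip through CSV", {
  pl <- plant_model()
  tr <- simulate_regulation(pl, imc_pid_gains(pl), duration_s = 100,
                            start_temp_c = 37)
  f <- tempfile(fileext = ".csv")
  write_trace(tr, f)
  back <- read_trace(f)
  expect_equal(back$temp_c, tr$temp_c)
  expect_equal(back$time_s, tr$time_s)
})
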