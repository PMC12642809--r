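test_that("velocity field is plane-Poiseuille with the exact flow rate", {
  dev <- device_preset("bioreactor", flow_rate_ul_min = 100)
  vf <- velocity_field(dev)
  expect_equal(vf$mean_mm_h, 6000 / 0.15)   # 40,000 mm/h
  expect_equal(vf$max_mm_h / vf$mean_mm_h, 1.5)
  expect_equal(vf$profile(0.05), 0)         # no-slip at the wall
  expect_equal(vf$profile(0), vf$max_mm_h)
  # discrete profile integrates to Q for the solver grid
  grid <- pdmsdose:::.channel_grid(dev, chemical("estradiol"),
                                   channel_control())
  expect_equal(sum(grid$v * grid$cap_s), 6000, tolerance = 1e-10)
  v0 <- velocity_field(device_preset("bioreactor", flow_rate_ul_min = 0))
  expect_identical(v0$mean_mm_h, 0)
  expect_identical(v0$profile(0.02), 0)
})

test_that("a non-interacting chemical passes through mass-conserving", {
  dev <- device_preset("bioreactor", flow_rate_ul_min = 10)
  res <- simulate_channel(dev, chemical("aldosterone"),
                          schedule_pulse(1, 0, 1), 2,
                          channel_control(dt_h = 0.002))
  s <- res$series
  n <- nrow(s)
  expect_lt(abs(s$delivered_mass[n] / s$inlet_mass[n] - 1), 0.01)
  m <- dose_metrics(simulate_channel(dev, chemical("aldosterone"),
                                     schedule_pulse(1, 0, 1), 2, qs_control()))
  expect_lt(m$pulse_depletion_percent, 0.1)
  expect_equal(m$delivered_fraction_percent, 100, tolerance = 0.1)
})

test_that("solvers are linear in the schedule amplitude", {
  dev <- device_preset("bioreactor", flow_rate_ul_min = 10)
  prog <- chemical("progesterone")
  r1 <- simulate_channel(dev, prog, schedule_pulse(1, 0, 1), 2, qs_control())
  r2 <- simulate_channel(dev, prog, schedule_pulse(2, 0, 1), 2, qs_control())
  expect_equal(2 * r1$series$delivered_mass, r2$series$delivered_mass,
               tolerance = 1e-9)
  expect_equal(2 * r1$series$avg_channel_conc, r2$series$avg_channel_conc,
               tolerance = 1e-9)
  expect_equal(2 * r1$series$mass_pdms, r2$series$mass_pdms,
               tolerance = 1e-9)
})

test_that("pulse depletion decreases with flow rate for both hormones", {
  for (chem in c("progesterone", "estradiol")) {
    depl <- vapply(c(1, 10, 100), function(q) {
      pulse_metrics(chem, q, t_end = 2)$pulse_depletion_percent
    }, numeric(1))
    expect_true(all(diff(depl) < 0))
  }
})

test_that("the mass ledger closes over 48 h of static exposure", {
  dev <- device_preset("regehr")
  res <- simulate_channel(dev, chemical("estradiol"), schedule_constant(1), 48,
                          channel_control(nx = 4L, dt_h = 0.01))
  expect_lt(abs(res$ledger$relative_gap), 0.005)
  # solution + PDMS exactly account for the loaded mass at every record
  s <- res$series
  expect_equal(s$mass_solution + s$mass_pdms,
               rep(s$mass_solution[1], nrow(s)), tolerance = 1e-8)
})

test_that("a flowing channel's ledger closes to solver tolerance", {
  dev <- device_preset("bioreactor", flow_rate_ul_min = 1)
  res <- simulate_channel(dev, chemical("progesterone"),
                          schedule_pulse(1, 0, 1), 3,
                          channel_control(dt_h = 5e-4))
  expect_lt(abs(res$ledger$relative_gap), 0.005)
})

test_that("simulate_channel with Q = 0 matches the static device", {
  dev <- device_preset("regehr")
  ctl <- channel_control(nx = 4L, dt_h = 0.01)
  st <- simulate_static_device(dev, chemical("estradiol"), c0 = 1,
                               interval_h = 24, refills = 0, control = ctl)
  res <- simulate_channel(dev, chemical("estradiol"), schedule_constant(1), 24,
                          ctl)
  s <- res$series
  loss <- 100 * (s$mass_solution[1] - s$mass_solution[nrow(s)]) /
    s$mass_solution[1]
  expect_equal(st$loss_percent[1], loss, tolerance = 1e-10)
})

test_that("a non-interacting chemical loses nothing in static culture", {
  dev <- device_preset("regehr")
  st <- simulate_static_device(dev, chemical("aldosterone"), c0 = 1,
                               interval_h = 24, refills = 1)
  expect_equal(st$loss_percent, c(0, 0), tolerance = 1e-9)
})

test_that("finite H at its bound matches the equilibrium interface within 1%", {
  # H = 10^1.56 mm/h is non-rate-limiting: enforcing local equilibrium at
  # the wall must give indistinguishable dose metrics
  m_h <- pulse_metrics("estradiol", 1, t_end = 2)
  dev <- device_preset("bioreactor", flow_rate_ul_min = 1)
  ctl <- channel_control(quasi_steady = TRUE, dt_h = 0.005, save_dt_h = 0.005,
                         equilibrium_interface = TRUE)
  m_eq <- dose_metrics(simulate_channel(dev, chemical("estradiol"),
                                        schedule_pulse(1, 0, 1), 2, ctl))
  expect_equal(m_h$pulse_depletion_percent, m_eq$pulse_depletion_percent,
               tolerance = 0.01)
  expect_equal(m_h$post_pulse_release_percent, m_eq$post_pulse_release_percent,
               tolerance = 0.01)
})

test_that("dose metrics are grid-converged within 2% absolute", {
  base <- pulse_metrics("progesterone", 10, t_end = 2)
  dev <- device_preset("bioreactor", flow_rate_ul_min = 10)
  fine <- dose_metrics(simulate_channel(
    dev, chemical("progesterone"), schedule_pulse(1, 0, 1), 2,
    channel_control(nx = 90L, nz_solution = 14L, nz_slab = 40L,
                    quasi_steady = TRUE, dt_h = 0.0025, save_dt_h = 0.0025)))
  expect_lt(abs(base$pulse_depletion_percent - fine$pulse_depletion_percent), 2)
  expect_lt(abs(base$post_pulse_release_percent - fine$post_pulse_release_percent), 2)
})

test_that("quasi-steady channel agrees with a brute-force resolved transient", {
  # independent cross-check of the two drivers: CFL-scale transient
  # stepping vs the quasi-steady reduction, estradiol at Q = 1 uL/min
  m_qs <- pulse_metrics("estradiol", 1, t_end = 2)
  dev <- device_preset("bioreactor", flow_rate_ul_min = 1)
  m_tr <- dose_metrics(simulate_channel(
    dev, chemical("estradiol"), schedule_pulse(1, 0, 1), 2,
    channel_control(dt_h = 2e-4, save_dt_h = 0.01)))
  expect_lt(abs(m_qs$pulse_depletion_percent - m_tr$pulse_depletion_percent), 2)
  expect_lt(abs(m_qs$post_pulse_release_percent - m_tr$post_pulse_release_percent), 2)
})

test_that("device geometry is validated", {
  expect_error(channel_device(10, 1.5, 0.2, 0.1), "slab thickness")
  expect_error(channel_device(10, 1.5, 0.1, 4, flow_rate_ul_min = -1), ">= 0")
  expect_error(simulate_static_device(device_preset("bioreactor",
                                                    flow_rate_ul_min = 5),
                                      chemical("estradiol")),
               "Q = 0")
  expect_error(simulate_channel(device_preset("regehr"), chemical("estradiol"),
                                schedule_constant(1), 1,
                                channel_control(quasi_steady = TRUE)),
               "Q > 0")
})

test_that("metrics validate their window and inlet mass", {
  dev <- device_preset("bioreactor", flow_rate_ul_min = 10)
  res <- simulate_channel(dev, chemical("estradiol"), schedule_pulse(1, 2, 3),
                          4, qs_control())
  expect_error(dose_metrics(res, window = c(3, 1)), "window")
  expect_error(dose_metrics(res, window = c(0, 1)), "no inlet mass")
  m <- dose_metrics(res)
  expect_true(m$pulse_depletion_percent >= 0 &&
                m$pulse_depletion_percent <= 100)
})
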