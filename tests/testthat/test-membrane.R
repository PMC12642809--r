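test_that("closed-form partition equilibrium behaves at its limits", {
  asm <- membrane_assembly()   # 300/300 uL, A = 38.5 mm^2, L = 80 um
  eq0 <- equilibrium_concentrations(asm, 0)
  expect_equal(eq0$c_eq, 0.5)  # c0 * V_src / (V_src + V_snk)
  expect_equal(unname(eq0$mass_fractions["membrane"]), 0)
  # K * A * L = 600 uL: c_eq = c0 / 4 and half the mass in the membrane
  kps <- 600 / (38.5 * 0.08)
  eq1 <- equilibrium_concentrations(asm, kps)
  expect_equal(eq1$c_eq, 0.25)
  expect_equal(unname(eq1$mass_fractions["membrane"]), 0.5)
  eq_inf <- equilibrium_concentrations(asm, 1e9)
  expect_lt(eq_inf$c_eq, 1e-4)
  expect_gt(unname(eq_inf$mass_fractions["membrane"]), 0.999)
})

test_that("long simulations converge to the closed-form equilibrium", {
  asm <- membrane_assembly()
  kps <- 600 / (38.5 * 0.08)
  st <- simulate_membrane(asm, chemical("progesterone"),
                          sample_times = c(0, 100, 300),
                          control = membrane_control(well_mixed = TRUE,
                                                     dt_h = 0.05),
                          override = list(kps = kps, dp = 0.05, h = 36,
                                          ds_eff = 5))
  src_end <- st$series$concentration[st$series$time_h == 300 &
                                       st$series$compartment == "source"]
  snk_end <- st$series$concentration[st$series$time_h == 300 &
                                       st$series$compartment == "sink"]
  expect_equal(src_end, 0.25, tolerance = 0.005)
  expect_equal(snk_end, 0.25, tolerance = 0.005)
})

test_that("an impermeable interface freezes both chambers", {
  asm <- membrane_assembly()
  st <- simulate_membrane(asm, chemical("progesterone"),
                          sample_times = c(0, 12, 24),
                          override = list(h = 0))
  expect_equal(st$series$concentration[st$series$compartment == "source"],
               rep(1, 3), tolerance = 1e-9)
  expect_equal(st$series$concentration[st$series$compartment == "sink"],
               rep(0, 3), tolerance = 1e-12)
})

test_that("aldosterone does not cross the membrane over 24 h", {
  st <- simulate_membrane(membrane_assembly(), chemical("aldosterone"),
                          sample_times = default_times)
  snk <- st$series$concentration[st$series$compartment == "sink"]
  src <- st$series$concentration[st$series$compartment == "source"]
  expect_true(all(snk == 0))
  expect_equal(src, rep(1, length(default_times)), tolerance = 1e-9)
})

test_that("mass is conserved and transfer is monotone", {
  for (f in c(0.05, 0.3)) {
    asm <- membrane_assembly(dmso_fraction = f)
    st <- simulate_membrane(asm, chemical("progesterone"),
                            sample_times = default_times)
    expect_lt(st$mass_drift, 1e-4)
    src <- st$source_grid
    snk <- st$sink_grid
    expect_true(all(diff(src) <= 1e-12))
    expect_true(all(diff(snk) >= -1e-12))
    expect_true(all(st$series$concentration >= 0))
  }
})

test_that("swapping source and sink mirrors the solution exactly", {
  a <- membrane_assembly(c0_source = 1, c0_sink = 0, dmso_fraction = 0.2)
  b <- membrane_assembly(c0_source = 0, c0_sink = 1, dmso_fraction = 0.2)
  est <- chemical("estradiol")
  sa <- simulate_membrane(a, est, sample_times = default_times)
  sb <- simulate_membrane(b, est, sample_times = default_times)
  expect_equal(sa$series$concentration[sa$series$compartment == "source"],
               sb$series$concentration[sb$series$compartment == "sink"],
               tolerance = 1e-10)
  expect_equal(sa$series$concentration[sa$series$compartment == "sink"],
               sb$series$concentration[sb$series$compartment == "source"],
               tolerance = 1e-10)
})

test_that("sampled concentrations are grid-converged below 0.5%", {
  asm <- membrane_assembly(dmso_fraction = 0.1)
  prog <- chemical("progesterone")
  coarse <- simulate_membrane(asm, prog, sample_times = default_times)
  fine <- simulate_membrane(asm, prog, sample_times = default_times,
                            control = membrane_control(n_chamber = 30L,
                                                       n_membrane = 42L,
                                                       dt_h = 0.01))
  scale <- max(coarse$series$concentration)
  expect_lt(max(abs(coarse$series$concentration - fine$series$concentration)) /
              scale, 0.005)
})

test_that("invalid sampling and geometry are rejected", {
  expect_error(membrane_assembly(source_volume_ul = -1), "positive")
  expect_error(simulate_membrane(membrane_assembly(), chemical("estradiol"),
                                 sample_times = c(2, 1)),
               "increasing")
  expect_error(membrane_control(dt_h = 0), "positive")
})
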