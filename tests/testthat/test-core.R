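test_that("cosolvent mixing law reproduces tabulated partition coefficients", {
  est <- chemical("estradiol")
  # aqueous endpoint: K_PW ~ 15.1 for estradiol
  expect_equal(kps_from_fraction(est, 0), 10^1.18, tolerance = 1e-12)
  expect_equal(kps_from_fraction(est, 0), 15.1, tolerance = 0.01)
  # pure-DMSO endpoint is exactly 10^log_kpd
  expect_identical(kps_from_fraction(est, 1), 10^0.03)
  prog <- chemical("progesterone")
  expect_identical(kps_from_fraction(prog, 1), 10^-7.20)
  # mixed composition, evaluated by hand: 10^(0.2*0.03 + 0.8*1.18) = 10^0.950
  expect_equal(kps_from_fraction(est, 0.2), 8.912509, tolerance = 1e-6)
})

test_that("mixing law is exactly log-linear in the DMSO fraction", {
  for (chem in c("progesterone", "estradiol")) {
    p <- chemical(chem)
    f <- seq(0, 1, by = 0.05)
    logk <- log10(vapply(f, function(x) kps_from_fraction(p, x), numeric(1)))
    line <- (1 - f) * p$log_kpw + f * p$log_kpd
    expect_equal(logk, line, tolerance = 1e-12)
  }
})

test_that("partition parameters are validated", {
  ald <- chemical("aldosterone")
  expect_false(ald$interacting)
  expect_error(kps_from_fraction(ald, 0.1), "no partition parameters")
  expect_error(kps_from_fraction(chemical("estradiol"), 1.2), "\\[0, 1\\]")
  expect_error(kps_from_fraction(chemical("estradiol"), -0.1), "\\[0, 1\\]")
  expect_error(chemical_params("x", log_ds = 0.3, log_kpw = 1),
               "needs finite")
  expect_error(chemical_params("x", log_ds = 0.3, log_kpw = 1,
                               interacting = FALSE),
               "non-interacting")
})

test_that("flow-rate conversion is the uL/min to mm^3/h identity", {
  expect_identical(convert_flow_rate(1), 60)
  expect_identical(convert_flow_rate(0), 0)
  expect_identical(convert_flow_rate(100), 6000)
  expect_error(convert_flow_rate(-1), "nonnegative")
})

test_that("chemical configs round-trip through YAML and JSON", {
  prog <- chemical("progesterone")
  for (ext in c("yaml", "json")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    cfg <- list(name = "progesterone", log_kpw = 3.30, log_kpd = -7.20,
                log_dp = -1.90, log_ds = 0.336, log_h = 1.56,
                h_is_lower_bound = TRUE)
    if (ext == "yaml") yaml::write_yaml(cfg, path)
    else jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
    got <- read_chemical_config(path)
    expect_equal(got[c("log_kpw", "log_kpd", "log_dp", "log_ds", "log_h")],
                 prog[c("log_kpw", "log_kpd", "log_dp", "log_ds", "log_h")])
    expect_true(got$h_is_lower_bound)
  }
})
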