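test_that("noiseless synthetic data is fit back to the generating parameters", {
  prog <- chemical("progesterone")
  asm <- membrane_assembly(dmso_fraction = 0.3)
  dat <- generate_membrane_dataset(prog, fractions = 0.3, noise_cv = 0,
                                   replicates = 1, seed = 1,
                                   control = fast_membrane())
  fit <- suppressWarnings(fit_membrane_experiment(dat, asm))
  truth_kps <- 0.3 * prog$log_kpd + 0.7 * prog$log_kpw   # 0.15
  est <- fit$estimates
  expect_lt(fit$ssr, 1e-8)
  expect_equal(est$estimate[est$parameter == "log_kps"], truth_kps,
               tolerance = 0.02)
  expect_equal(est$estimate[est$parameter == "log_ds_eff"], 0.7,
               tolerance = 0.05)
  # truth H = 10^1.56 is non-rate-limiting, so the fit must flag a bound
  expect_true(fit$h_is_lower_bound)
  expect_true(is.finite(fit$h_lower_bound))
})

test_that("single-fraction preconditions are enforced", {
  dat <- generate_membrane_dataset(chemical("estradiol"),
                                   fractions = c(0.1, 0.3), noise_cv = 0,
                                   replicates = 1, seed = 1,
                                   control = fast_membrane())
  expect_error(fit_membrane_experiment(dat, membrane_assembly()),
               "multiple DMSO fractions")
  short <- dat[dat$fraction_dmso == 0.1 & dat$time_h <= 2, ]
  expect_error(fit_membrane_experiment(short, membrane_assembly()),
               "4 time points")
})

test_that("noise-free extrapolation inverts the mixing law exactly", {
  est <- chemical("estradiol")
  f <- c(0.05, 0.1, 0.2, 0.3)
  pts <- data.frame(fraction = f,
                    log_kps = f * est$log_kpd + (1 - f) * est$log_kpw)
  ex <- extrapolate_partition(pts)
  expect_equal(ex$log_kpw, 1.18, tolerance = 1e-10)
  expect_equal(ex$log_kpd, 0.03, tolerance = 1e-10)
  # two exact points define the line
  two <- extrapolate_partition(pts[c(1, 3), ])
  expect_equal(two$log_kpw, 1.18, tolerance = 1e-10)
  expect_error(extrapolate_partition(data.frame(fraction = c(0.1, 0.1),
                                                log_kps = c(1, 2))),
               "distinct")
  expect_error(extrapolate_partition(data.frame(fraction = c(-0.1, 0.3),
                                                log_kps = c(1, 2))),
               "\\[0, 1\\]")
})

test_that("weighted regression agrees with a brute-force grid search", {
  pts <- data.frame(fraction = c(0.05, 0.1, 0.2, 0.3),
                    log_kps = c(2.7, 2.32, 1.15, 0.21),
                    se = c(0.05, 0.08, 0.04, 0.1))
  ex <- extrapolate_partition(pts)
  # independent oracle: nested grid search over (intercept, slope)
  sse <- function(b0, b1) sum((pts$log_kps - b0 - b1 * pts$fraction)^2 / pts$se^2)
  b0 <- 3; b1 <- -8; half <- 4
  for (level in 1:12) {
    g0 <- seq(b0 - half, b0 + half, length.out = 21L)
    g1 <- seq(b1 - 4 * half, b1 + 4 * half, length.out = 21L)
    grid <- expand.grid(b0 = g0, b1 = g1)
    vals <- mapply(sse, grid$b0, grid$b1)
    best <- grid[which.min(vals), ]
    b0 <- best$b0; b1 <- best$b1
    half <- half / 5
  }
  expect_equal(ex$intercept, b0, tolerance = 1e-6)
  expect_equal(ex$slope, b1, tolerance = 1e-6)
})

test_that("log_kps bias vanishes as measurement noise shrinks", {
  prog <- chemical("progesterone")
  asm <- membrane_assembly(dmso_fraction = 0.3)
  truth <- 0.15
  errs <- vapply(c(0.1, 0.02, 0), function(cv) {
    dat <- generate_membrane_dataset(prog, fractions = 0.3, noise_cv = cv,
                                     replicates = 3, seed = 11,
                                     control = fast_membrane())
    fit <- suppressWarnings(fit_membrane_experiment(dat, asm))
    abs(fit$estimates$estimate[1] - truth)
  }, numeric(1))
  expect_lt(errs[3], 0.02)        # noise-free recovery
  expect_lt(errs[2], errs[1] + 0.02)  # shrinking with noise, desk scale
})
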