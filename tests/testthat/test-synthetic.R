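test_that("zero noise reproduces the forward simulation exactly", {
  est <- chemical("estradiol")
  dat <- generate_membrane_dataset(est, fractions = 0.1, noise_cv = 0,
                                   replicates = 2, seed = 3,
                                   control = fast_membrane())
  asm <- membrane_assembly(dmso_fraction = 0.1)
  st <- simulate_membrane(asm, est, ds_eff = effective_ds(0.7),
                          sample_times = default_times,
                          control = fast_membrane())
  for (r in 1:2) {
    sub <- dat[dat$replicate == r, ]
    expect_equal(sub$concentration, st$series$concentration, tolerance = 1e-12)
  }
})

test_that("generation is a pure function of inputs and seed", {
  est <- chemical("estradiol")
  a <- generate_membrane_dataset(est, fractions = c(0.1, 0.3), seed = 9,
                                 control = fast_membrane())
  b <- generate_membrane_dataset(est, fractions = c(0.1, 0.3), seed = 9,
                                 control = fast_membrane())
  c <- generate_membrane_dataset(est, fractions = c(0.1, 0.3), seed = 10,
                                 control = fast_membrane())
  expect_identical(a$concentration, b$concentration)
  expect_false(identical(a$concentration, c$concentration))
  expect_identical(attr(a, "manifest")$seed, 9)
  # the generator must not disturb the caller's RNG stream
  set.seed(123); before <- runif(3)
  set.seed(123)
  invisible(generate_membrane_dataset(est, fractions = 0.1, seed = 1,
                                      control = fast_membrane()))
  expect_identical(runif(3), before)
})

test_that("noise magnitude matches the requested coefficient of variation", {
  est <- chemical("estradiol")
  dat <- generate_membrane_dataset(est, fractions = 0.1,
                                   sample_times = c(0, 6, 24),
                                   noise_cv = 0.05, replicates = 200,
                                   seed = 5, control = fast_membrane())
  sub <- dat[dat$time_h == 6 & dat$compartment == "source", ]
  cv <- stats::sd(sub$concentration) / mean(sub$concentration)
  expect_lt(abs(cv - 0.05), 0.0075)   # within 3 Monte-Carlo sigma of 5%
  # multiplicative noise keeps exact zeros at zero
  zero <- dat[dat$time_h == 0 & dat$compartment == "sink", ]
  expect_true(all(zero$concentration == 0))
  expect_true(all(dat$concentration >= 0))
})

test_that("fractions outside the physical range are rejected", {
  expect_error(generate_membrane_dataset(chemical("estradiol"),
                                         fractions = c(0.1, 1.2)),
               "\\[0, 1\\]")
  expect_error(generate_membrane_dataset(chemical("estradiol"),
                                         noise_cv = -0.1), ">= 0")
})
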