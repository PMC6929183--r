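test_that("delta/ratio conversions are exact and reversible", {
  expect_equal(delta_to_ratio(0, 0.0112), 0.0112)
  expect_equal(delta_to_ratio(1000, 0.0112), 0.0224)
  r <- delta_to_ratio(-57.3, 0.0112)
  expect_equal(ratio_to_delta(r, 0.0112), -57.3, tolerance = 1e-12)
  expect_error(delta_to_ratio(-1000, 0.0112), "-1000")
  expect_error(ratio_to_delta(-1, 0.0112), "positive")
})

test_that("batch parameter validation catches malformed designs", {
  expect_error(batch_experiment_params(k_light = 0), "k_light")
  expect_error(batch_experiment_params(c0 = 0), "positive")
  expect_error(batch_experiment_params(times_h = c(1, 2, 3)), "start at 0")
  expect_error(batch_experiment_params(times_h = c(0, 2, 2)),
               "strictly increasing")
  expect_error(batch_experiment_params(primary = c(C = -1, Cl = 1, H = 1)),
               "positive")
  # bulk KIE_av >= 2 breaks the linearized rate mapping
  expect_error(simulate_batch_experiment(batch_experiment_params(
    primary = c(C = 1, Cl = 1, H = 8), secondary = 1)), "KIE_av")
})

test_that("no fractionation means flat deltas and a null enrichment fit", {
  p <- batch_experiment_params(primary = 1, secondary = 1,
                               conc_noise_rel = 0, delta_noise_permil = 0)
  ds <- simulate_batch_experiment(p)
  expect_equal(ds$d2H_permil, rep(0, nrow(ds)))
  f <- rayleigh_fit(ds, "H")
  expect_equal(f$epsilon_permil, 0, tolerance = 1e-10)
})

test_that("the noise-free generator lies exactly on the Rayleigh line", {
  p <- batch_experiment_params(primary = c(C = 1, Cl = 1, H = 4.5),
                               secondary = 1, conc_noise_rel = 0,
                               delta_noise_permil = 0)
  ds <- simulate_batch_experiment(p)
  # implied bulk: (4.5 + 5)/6 -> epsilon = -583.33 permil
  expect_equal(batch_implied_epsilon(p)$epsilon_permil[3], -1750 / 3,
               tolerance = 1e-12)
  f <- rayleigh_fit(ds, "H")
  expect_equal(f$epsilon_permil, -1750 / 3, tolerance = 1e-8)
  resid <- residuals(f$fit)
  expect_lt(max(abs(resid)), 1e-10)
})

test_that("identical seeds reproduce tables byte-identically, different seeds differ", {
  p1 <- batch_experiment_params(seed = 42)
  p2 <- batch_experiment_params(seed = 42)
  p3 <- batch_experiment_params(seed = 43)
  d1 <- simulate_batch_experiment(p1)
  d2 <- simulate_batch_experiment(p2)
  d3 <- simulate_batch_experiment(p3)
  expect_identical(as.data.frame(d1), as.data.frame(d2))
  expect_false(identical(d1$conc, d3$conc))
})

test_that("the fitted slope is invariant under concentration rescaling", {
  p <- batch_experiment_params(seed = 11)
  ds <- simulate_batch_experiment(p)
  f1 <- rayleigh_fit(ds, "C")
  ds2 <- ds
  ds2$conc <- ds2$conc * 37.5
  attr(ds2, "c0") <- attr(ds, "c0") * 37.5
  f2 <- rayleigh_fit(ds2, "C")
  expect_equal(f2$epsilon_permil, f1$epsilon_permil, tolerance = 1e-12)
})

test_that("noise-free fits recover any enrichment factor in the CSIA range", {
  for (eps in c(-1, -25, -160, -300)) {
    # choose the primary so the bulk KIE_av equals 1 - eps/1000 exactly
    prim <- 6 * (1 - eps / 1000) - 5
    p <- batch_experiment_params(
      primary = c(C = prim, Cl = 1, H = 1), secondary = 1,
      conc_noise_rel = 0, delta_noise_permil = 0)
    f <- rayleigh_fit(simulate_batch_experiment(p), "C")
    expect_lt(abs(f$epsilon_permil - eps), 1e-6)
  }
})

test_that("the through-origin fit errors without degradation and needs 3 points", {
  p <- batch_experiment_params(k_light = 1e-12, conc_noise_rel = 0,
                               delta_noise_permil = 0)
  ds <- simulate_batch_experiment(p)
  expect_error(rayleigh_fit(ds, "C"), "dynamic range")
  p2 <- batch_experiment_params(times_h = c(0, 1))
  ds2 <- simulate_batch_experiment(p2)
  expect_error(rayleigh_fit(ds2, "C"), "3 usable")
})

test_that("AKIE dilution correction behaves and flags its breakdown", {
  expect_equal(epsilon_to_akie(0, 6)$akie, 1)
  a <- epsilon_to_akie(-160, 6)
  expect_equal(a$akie, 25, tolerance = 1e-12)
  expect_match(a$note, "infer_secondary_average")
  expect_equal(epsilon_to_akie(-20, 1)$akie, 1 / (1 - 0.02),
               tolerance = 1e-12)
  expect_error(epsilon_to_akie(-200, 6), "undefined")
})

test_that("batch CSV round trip preserves the fit", {
  p <- batch_experiment_params(seed = 7)
  ds <- simulate_batch_experiment(p)
  path <- withr::local_tempfile(fileext = ".csv")
  write_rayleigh_csv(ds, path)
  back <- read_rayleigh_csv(path)
  for (el in c("C", "Cl", "H")) {
    f1 <- rayleigh_fit(ds, el)
    f2 <- rayleigh_fit(back, el)
    expect_equal(f2$epsilon_permil, f1$epsilon_permil, tolerance = 1e-9)
  }
})

test_that("free-intercept variant agrees with through-origin on clean data", {
  p <- batch_experiment_params(seed = 3, conc_noise_rel = 0,
                               delta_noise_permil = 0.2)
  ds <- simulate_batch_experiment(p)
  f0 <- rayleigh_fit(ds, "C")
  f1 <- rayleigh_fit(ds, "C", intercept = TRUE)
  expect_lt(abs(f0$epsilon_permil - f1$epsilon_permil),
            3 * (f0$se_permil + f1$se_permil))
  expect_true(f0$ci95_permil[1] <= f0$epsilon_permil &&
                f0$epsilon_permil <= f0$ci95_permil[2])
})
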