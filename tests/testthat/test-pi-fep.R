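test_that("the P-bead closed form interpolates classical to quantum", {
  u <- th_298$c2 * 2900 / 298
  kt <- 1 / th_298$beta
  # P = 1 is the classical limit kT ln(beta hbar omega)
  expect_equal(pi_free_energy_ho_exact(2900, th_298, 1), kt * log(u),
               tolerance = 1e-12)
  # large P approaches the exact quantum free energy ~ hbar omega / 2
  f_inf <- pi_free_energy_ho_exact(2900, th_298, 2^14)
  expect_equal(f_inf, ho_quantum_free_energy(2900, th_298),
               tolerance = 1e-6)
  expect_equal(f_inf, 4.1458, tolerance = 1e-3)
})

test_that("bead deviations at 2900 cm-1 and 298 K follow the closed form", {
  devs <- vapply(c(8, 16, 32, 64), function(p) {
    ho_quantum_free_energy(2900, th_298) -
      pi_free_energy_ho_exact(2900, th_298, p)
  }, numeric(1))
  expect_equal(devs, c(0.402, 0.122, 0.0324, 0.0082), tolerance = 1e-2)
  expect_true(all(devs > 0))
})

test_that("harmonic bead free energies increase monotonically in P", {
  f <- vapply(2^(1:10), function(p) pi_free_energy_ho_exact(2900, th_298, p),
              numeric(1))
  expect_true(all(diff(f) > 0))
  expect_true(all(f < ho_quantum_free_energy(2900, th_298)))
})

test_that("bead-convergence selection returns the smallest adequate count", {
  bc <- bead_convergence(2900, th_298, c(8, 16, 32, 64), tolerance = 0.02)
  expect_identical(bc$P, 64L)
  expect_identical(nrow(bc$table), 4L)
  # any tolerance above the largest deviation returns the smallest count
  expect_identical(bead_convergence(2900, th_298, c(8, 16, 32, 64), 1)$P, 8L)
  # soft modes converge immediately
  expect_identical(bead_convergence(100, th_298, c(8, 16, 32, 64), 0.02)$P,
                   8L)
  expect_error(bead_convergence(2900, th_298, c(8, 16), 1e-4),
               "no bead count")
  expect_error(bead_convergence(2900, th_298, c(16, 8), 0.02), "ascending")
})

test_that("bisection paths reproduce the free-ring radius of gyration", {
  set.seed(1)
  for (P in c(8, 32)) {
    d <- sample_free_paths(20000, P, th_298$beta, 1.00782503)
    expect_lt(max(abs(rowMeans(d))), 1e-12)
    msd <- mean(rowMeans(d^2))
    target <- phys_constants()$hbar2_kcal * th_298$beta /
      (12 * 1.00782503) * (1 - 1 / P^2)
    expect_lt(abs(msd - target) / target, 0.05)
  }
  expect_error(sample_free_paths(10, 12, th_298$beta, 1), "power of two")
})

test_that("settings validation enforces the bisection requirement", {
  expect_error(pi_settings(P = 12), "power of two")
  expect_error(pi_settings(P = 64, temperature = -1), "positive")
  expect_error(pi_settings(P = 64, n_config = 0), "positive integers")
})

test_that("the BQCP estimator matches the discretized closed form", {
  pot <- model_potential("harmonic", mass_light = 1.00782503,
                         wavenumber = 2900)
  for (P in c(16, 64)) {
    st <- pi_settings(P = P, temperature = 298, n_config = 2000, n_pi = 10,
                      seed = 400 + P)
    qc <- bqcp_quantum_correction(pot, st)
    target <- pi_free_energy_ho_exact(2900, th_298, P) -
      ho_classical_free_energy(2900, th_298)
    expect_lt(abs(qc$dF_qm - target), 3 * qc$se)
    expect_gt(qc$se, 0)
  }
})

test_that("quantum corrections vanish in the classical and heavy-mass limits", {
  pot <- model_potential("harmonic", mass_light = 1.00782503,
                         wavenumber = 2900)
  st_hot <- pi_settings(P = 16, temperature = 1e6, n_config = 500,
                        n_pi = 5, seed = 21)
  qc_hot <- bqcp_quantum_correction(pot, st_hot)
  # residual correction scales as (hbar omega)^2 / (24 kT) -> ~1e-3 here
  expect_lt(abs(qc_hot$dF_qm), 0.01)
  pot_heavy <- model_potential("harmonic", mass_light = 1.00782503e6,
                               k = pot$k)
  st <- pi_settings(P = 16, temperature = 298, n_config = 500, n_pi = 5,
                    seed = 22)
  qc_heavy <- bqcp_quantum_correction(pot_heavy, st)
  expect_lt(abs(qc_heavy$dF_qm), 1e-4)
})

test_that("too few classical configurations for the jackknife are rejected", {
  pot <- model_potential("harmonic", mass_light = 1, wavenumber = 1000)
  st <- pi_settings(P = 8, temperature = 298, n_config = 5, n_pi = 2,
                    seed = 1)
  expect_error(bqcp_quantum_correction(pot, st), "jackknife")
})

test_that("mass perturbation recovers the isotope free-energy difference", {
  m_l <- 1.00782503; m_h <- 2.01410178
  pot <- model_potential("harmonic", mass_light = m_l, mass_heavy = m_h,
                         wavenumber = 2900)
  st <- pi_settings(P = 32, temperature = 298, n_config = 3000, n_pi = 10,
                    seed = 31)
  paths <- sample_bqcp_paths(pot, st, "light")
  mp <- mass_perturbed_difference(paths, m_h / m_l)
  nu_h <- 2900 * sqrt(m_l / m_h)
  target <- (pi_free_energy_ho_exact(nu_h, th_298, 32) -
               ho_classical_free_energy(nu_h, th_298)) -
    (pi_free_energy_ho_exact(2900, th_298, 32) -
       ho_classical_free_energy(2900, th_298))
  expect_lt(abs(mp$difference - target), 3 * mp$se)
  expect_lt(mp$difference, 0)  # heavy isotopolog has the smaller correction

  # unit mass ratio must return exactly zero
  expect_identical(mass_perturbed_difference(paths, 1)$difference, 0)
  expect_error(mass_perturbed_difference(paths, 0.5), ">= 1")
})

test_that("carbon perturbation on a skeletal mode is far smaller than H/D", {
  st <- pi_settings(P = 32, temperature = 298, n_config = 2000, n_pi = 10,
                    seed = 33)
  pot_c <- model_potential("harmonic", mass_light = 12,
                           mass_heavy = 13.0033548, wavenumber = 1000)
  mp_c <- mass_perturbed_difference(sample_bqcp_paths(pot_c, st, "light"),
                                    13.0033548 / 12)
  pot_h <- model_potential("harmonic", mass_light = 1.00782503,
                           mass_heavy = 2.01410178, wavenumber = 2900)
  mp_h <- mass_perturbed_difference(sample_bqcp_paths(pot_h, st, "light"),
                                    2.01410178 / 1.00782503)
  expect_lt(abs(mp_c$difference), 0.1)
  expect_gt(abs(mp_h$difference), 0.5)
  expect_gt(abs(mp_h$difference) / abs(mp_c$difference), 5)
})

test_that("heavier isotopologs always carry the smaller quantum correction", {
  cases <- list(c(1.00782503, 2.01410178, 2900), c(12, 13.0033548, 1000))
  for (cs in cases) {
    nu_l <- cs[3]; nu_h <- cs[3] * sqrt(cs[1] / cs[2])
    df_l <- ho_quantum_free_energy(nu_l, th_298) -
      ho_classical_free_energy(nu_l, th_298)
    df_h <- ho_quantum_free_energy(nu_h, th_298) -
      ho_classical_free_energy(nu_h, th_298)
    expect_lt(abs(df_h), abs(df_l))
  }
})

test_that("the PI KIE combines corrections with the stated sign convention", {
  mkqc <- function(sp, iso, v) quantum_correction(sp, iso, v, se = 0,
                                                  P = 64, temperature = 298)
  # zero corrections -> unit KIE
  k0 <- pi_kie(list(light = mkqc("reactant", "light", 0),
                    heavy = mkqc("reactant", "heavy", 0)),
               list(light = mkqc("ts", "light", 0),
                    heavy = mkqc("ts", "heavy", 0)), th_298)
  expect_equal(k0$kie, 1, tolerance = 1e-14)

  # semiempirical-level quantum effects: barrier lowered 3.1 kcal/mol for
  # the light and 2.0 for the heavy isotopolog
  kie <- pi_kie(list(light = mkqc("reactant", "light", 0),
                     heavy = mkqc("reactant", "heavy", 0)),
                list(light = mkqc("ts", "light", -3.1),
                     heavy = mkqc("ts", "heavy", -2.0)), th_298)
  expect_equal(kie$kie, exp(1.1 * th_298$beta), tolerance = 1e-12)
  expect_equal(kie$kie, 6.41, tolerance = 1e-2)
  expect_identical(kie$provenance, "pi")

  # swapping isotopolog roles inverts the effect
  swap <- pi_kie(list(light = mkqc("reactant", "light", 0),
                      heavy = mkqc("reactant", "heavy", 0)),
                 list(light = mkqc("ts", "light", -2.0),
                      heavy = mkqc("ts", "heavy", -3.1)), th_298)
  expect_equal(kie$kie * swap$kie, 1, tolerance = 1e-12)

  # mismatched settings are rejected
  bad <- quantum_correction("ts", "heavy", -2, P = 32, temperature = 298)
  expect_error(pi_kie(list(light = mkqc("reactant", "light", 0),
                           heavy = mkqc("reactant", "heavy", 0)),
                      list(light = mkqc("ts", "light", -3.1), heavy = bad),
                      th_298), "bead counts")
})

test_that("in the deep-tunneling-free ZPE regime the PI route matches Bigeleisen per mode", {
  # a 'lost mode' toy: reactant mode nu for light/heavy, absent at the TS;
  # closed-form P-bead corrections at large P reproduce the per-mode
  # Bigeleisen factor for any u
  th_cold <- thermo_settings(120)
  nu_l <- 2900; nu_h <- 2900 * sqrt(1.00782503 / 2.01410178)
  big_p <- 2^12
  dfl <- pi_free_energy_ho_exact(nu_l, th_cold, big_p) -
    ho_classical_free_energy(nu_l, th_cold)
  dfh <- pi_free_energy_ho_exact(nu_h, th_cold, big_p) -
    ho_classical_free_energy(nu_h, th_cold)
  kie_pi_closed <- exp(-th_cold$beta * ((0 - dfl) - (0 - dfh)))
  g <- species_factor(mode_factor_table(frequency_set(nu_l),
                                        frequency_set(nu_h), th_cold))
  expect_equal(kie_pi_closed, 1 / g, tolerance = 1e-4)
})
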