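test_that("identical light and heavy sets give unit factors and unit KIE", {
  fs <- frequency_set(c(500, 1500, 3000))
  tab <- mode_factor_table(fs, fs, th_29815)
  expect_equal(tab$factor, rep(1, 3), tolerance = 1e-14)
  expect_equal(species_factor(tab), 1, tolerance = 1e-14)
  ts <- frequency_set(c(800), imaginary = 1200)
  kie <- semiclassical_kie(fs, fs, ts, ts, th_29815)
  expect_equal(kie$kie, 1, tolerance = 1e-14)
})

test_that("single-mode factor matches the partition-function arithmetic", {
  # independent arithmetic route: g = (u_L/u_H) q(u_L)/q(u_H) with
  # q(u) = exp(-u/2)/(1 - exp(-u))
  l <- frequency_set(2990); h <- frequency_set(2144)
  tab <- mode_factor_table(l, h, th_29815)
  q <- function(u) exp(-u / 2) / (1 - exp(-u))
  u_l <- th_29815$c2 * 2990 / th_29815$temperature
  u_h <- th_29815$c2 * 2144 / th_29815$temperature
  expect_equal(tab$u_light, 14.4288, tolerance = 1e-4)
  expect_equal(tab$u_heavy, 10.3463, tolerance = 1e-4)
  expect_equal(species_factor(tab), (u_l / u_h) * q(u_l) / q(u_h),
               tolerance = 1e-12)
  expect_equal(species_factor(tab), 0.1811019, tolerance = 1e-6)
})

test_that("single-mode reactant with bare imaginary TS gives the closed-form KIE", {
  r_l <- frequency_set(2990); r_h <- frequency_set(2144)
  ts_l <- frequency_set(numeric(0), imaginary = 1500)
  ts_h <- frequency_set(numeric(0), imaginary = 1100)
  kie <- semiclassical_kie(r_l, r_h, ts_l, ts_h, th_29815)
  expect_equal(kie$kie, (1500 / 1100) / 0.1811019, tolerance = 1e-6)
  expect_equal(kie$kie, 7.5297, tolerance = 1e-4)
  expect_equal(kie$components$g_ts, 1)
})

test_that("KIE decreases monotonically with temperature toward the classical limit", {
  r_l <- frequency_set(2990); r_h <- frequency_set(2144)
  ts_l <- frequency_set(numeric(0), imaginary = 1500)
  ts_h <- frequency_set(numeric(0), imaginary = 1100)
  temps <- c(200, 298.15, 400, 600, 1000, 3000)
  kies <- vapply(temps, function(tt) {
    semiclassical_kie(r_l, r_h, ts_l, ts_h, thermo_settings(tt))$kie
  }, numeric(1))
  expect_true(all(diff(kies) < 0))
  hot <- semiclassical_kie(r_l, r_h, ts_l, ts_h, thermo_settings(1e6))
  expect_lt(abs(hot$kie - 1500 / 1100) / (1500 / 1100), 1e-4)
})

test_that("input contracts are enforced", {
  a <- frequency_set(c(500, 1500))
  b <- frequency_set(1500)
  ts <- frequency_set(800, imaginary = 1200)
  expect_error(mode_factor_table(a, b, th_29815), "mismatched")
  expect_error(semiclassical_kie(a, a, a, a, th_29815), "lacks an imaginary")
  expect_error(semiclassical_kie(ts, ts, ts, ts, th_29815),
               "reactant frequency set carries")
  expect_error(thermo_settings(-10), "positive")
})

test_that("swapping light and heavy roles inverts the KIE exactly", {
  rx <- make_toy_reaction(cho_spec())
  sub <- isotope_substitution(2, "H")
  fr <- isotopolog_frequency_sets(rx$reactant, sub)
  ft <- isotopolog_frequency_sets(rx$ts, sub)
  fwd <- semiclassical_kie(fr$light, fr$heavy, ft$light, ft$heavy, th_298)
  rev <- semiclassical_kie(fr$heavy, fr$light, ft$heavy, ft$light, th_298)
  expect_equal(fwd$kie * rev$kie, 1, tolerance = 1e-12)
})

test_that("engine equals the brute-force partition-function oracle on the toys", {
  cho <- make_toy_reaction(cho_spec())
  xccl <- make_toy_reaction(xccl_spec(), labels = c("X", "C", "Cl"))
  cases <- list(list(cho, 2L, "H"), list(cho, 1L, "C"),
                list(xccl, 2L, "C"), list(xccl, 3L, "Cl"))
  for (cs in cases) {
    for (th in list(th_298, thermo_settings(500))) {
      kie <- engine_kie(cs[[1]], cs[[2]], cs[[3]], th)$kie
      ora <- oracle_kie(cs[[1]]$reactant, cs[[1]]$ts,
                        isotope_substitution(cs[[2]], cs[[3]]), th)
      expect_lt(abs(kie - ora) / ora, 1e-6)
    }
  }
})

test_that("a reactant X-H stretch lost at the TS gives a normal H/D KIE at any temperature", {
  for (tt in c(150, 298, 600, 2000)) {
    th <- thermo_settings(tt)
    kie <- engine_kie(make_toy_reaction(cho_spec()), 2L, "H", th)$kie
    expect_gt(kie, 1)
  }
})

test_that("KIE tables are written with the retained components", {
  rx <- make_toy_reaction(cho_spec())
  recs <- list(engine_kie(rx, 2L, "H", th_298),
               position_kie("H2", "H", 1.0156, provenance = "assumed"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_kie_table(recs, path)
  tab <- read.csv(path)
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$KIE[1], recs[[1]]$kie, tolerance = 1e-9)
  expect_equal(tab$nu_ratio[1], recs[[1]]$components$nu_ratio,
               tolerance = 1e-9)
  expect_true(is.na(tab$g_TS[2]))
})
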