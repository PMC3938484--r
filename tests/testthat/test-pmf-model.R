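test_that("Nernst slope Z matches direct evaluation and is linear in T", {
  expect_equal(zeta_factor(thermo_context(310.15)),
               2.302585093 * 8.314 * 310.15 / 96485 * 1000,
               tolerance = 1e-10)
  expect_equal(zeta_factor(thermo_context(310.15)), 61.537, tolerance = 1e-4)
  expect_equal(zeta_factor(thermo_context(303.15)), 60.148, tolerance = 1e-4)
  expect_equal(zeta_factor(thermo_context(2 * 310.15)),
               2 * zeta_factor(thermo_context(310.15)))
  expect_error(thermo_context(-1), "positive")
  expect_error(thermo_context(0), "positive")
})

test_that("pH-gradient force has the Mitchell sign convention", {
  expect_equal(ph_gradient_force(7.0, 7.0), 0)
  # alkaline interior: inward-driving (negative) force
  expect_equal(ph_gradient_force(7.6, 7.0), -36.92, tolerance = 1e-3)
  # acidified interior: inverted, positive force
  expect_equal(ph_gradient_force(5.5, 7.0), 92.31, tolerance = 1e-3)
  expect_error(ph_gradient_force(-0.1, 7), "\\[0, 14\\]")
  expect_error(ph_gradient_force(7, 14.5), "\\[0, 14\\]")
})

test_that("Nernst potential: value, antisymmetry, scale invariance", {
  expect_equal(nernst_potential(100, 100, 1), 0)
  expect_equal(nernst_potential(100, 10, 1), -61.54, tolerance = 1e-3)
  for (z in c(-2L, -1L, 1L, 2L)) {
    for (pair in list(c(3, 70), c(120, 5), c(1e-3, 1))) {
      a <- pair[1]; b <- pair[2]
      expect_equal(nernst_potential(a, b, z), -nernst_potential(b, a, z))
      expect_equal(nernst_potential(10 * a, 10 * b, z),
                   nernst_potential(a, b, z))
    }
  }
  expect_error(nernst_potential(0, 10, 1), "> 0")
  expect_error(nernst_potential(10, -1, 1), "> 0")
  expect_error(nernst_potential(10, 10, 0), "nonzero")
})

test_that("PMF is exactly additive in its two forces", {
  th <- thermo_context()
  expect_equal(pmf_total(-123.0777, 7.6, 7.0), -160, tolerance = 1e-4)
  expect_equal(pmf_total(-80, 7.0, 7.0), -80) # no gradient: PMF = delta_psi
  expect_equal(pmf_total(0, 5.5, 7.0), 92.31, tolerance = 1e-3)
  set.seed(11)
  for (i in 1:25) {
    dpsi <- runif(1, -250, 100)
    ph_i <- runif(1, 4, 9); ph_e <- runif(1, 4, 9)
    expect_identical(pmf_total(dpsi, ph_i, ph_e, th),
                     dpsi + ph_gradient_force(ph_i, ph_e, th))
  }
})

test_that("weak-acid speciation conserves mass and inverts at the pKa", {
  c8 <- octanoic_acid()
  expect_equal(protonated_fraction(c8$pKa, c8), 0.5)
  expect_equal(protonated_fraction(7.0, c8), 1 / (1 + 10^(7 - 4.89)),
               tolerance = 1e-12)
  expect_equal(protonated_fraction(7.0, c8), 0.0077, tolerance = 1e-2)
  grid <- seq(0, 14, by = 0.25)
  f <- protonated_fraction(grid, c8)
  expect_true(all(diff(f) < 0)) # strictly decreasing in pH
  expect_equal(f + (1 - f), rep(1, length(grid))) # speciation conservation
  expect_equal(equimolar_pH(c8), 4.89, tolerance = 1e-9)
  expect_equal(equimolar_pH(acid_species("x", 7.0)), 7.0, tolerance = 1e-9)
  a <- acid_species("y", 6.2)
  expect_equal(protonated_fraction(equimolar_pH(a), a), 0.5, tolerance = 1e-9)
  expect_error(acid_species("bad", 14.2), "pKa")
})

test_that("normal-state closure solves the membrane potential from the PMF anchor", {
  ns <- normal_scenario()
  expect_equal(ns$delta_psi, -123.08, tolerance = 1e-3)
  expect_equal(pmf_total(ns$delta_psi, ns$pH_i, ns$pH_e, ns$thermo), -160)
})

test_that("inorganic shock leaves the membrane potential unchanged", {
  ns <- normal_scenario()
  sh <- apply_shock(ns, "inorganic", 20, measured_pH_i = 5.32, pH_e = 4.0)
  expect_identical(sh$delta_psi, ns$delta_psi)
  expect_equal(sh$pH_i, 5.32)
  expect_equal(sh$pH_e, 4.0)
  # media re-adjusted: pH_e defaults to the normal value
  sh2 <- apply_shock(ns, "inorganic", 20, measured_pH_i = 6.8)
  expect_equal(sh2$pH_e, ns$pH_e)
})

test_that("carboxylic shock shifts the potential by the proton-load Nernst equivalent", {
  ns <- normal_scenario()
  sh <- apply_shock(ns, octanoic_acid(), 20, measured_pH_i = 5.5)
  expect_equal(sh$delta_psi, 6.15, tolerance = 1e-2)
  expect_equal(sh$pmf, 98.46, tolerance = 1e-2)
  expect_true(sh$inverted)
  # dichotomy: any proton load makes the shift strictly positive
  for (ph in c(5.0, 6.0, 7.0, 7.5)) {
    s <- apply_shock(ns, octanoic_acid(), 10, measured_pH_i = ph)
    expect_gt(s$delta_psi, ns$delta_psi)
  }
  expect_warning(apply_shock(ns, octanoic_acid(), 10, measured_pH_i = 7.6),
                 "no proton load")
})

test_that("zero dose is a no-op shock", {
  ns <- normal_scenario()
  sh <- apply_shock(ns, octanoic_acid(), 0, measured_pH_i = 5.5)
  expect_equal(sh$pmf, -160)
  expect_identical(sh$delta_psi, ns$delta_psi)
  expect_false(sh$inverted)
})

test_that("adaptation solver restores the PMF target within tolerance", {
  ns <- normal_scenario()
  sh <- apply_shock(ns, octanoic_acid(), 20, measured_pH_i = 5.5)
  ad <- solve_adaptation(sh)
  expect_equal(ad$delta_psi_required, -252.31, tolerance = 1e-3)
  expect_lt(abs(ad$pmf - (-160)), 0.1)
  expect_true(ad$pmf >= -180 && ad$pmf <= -140)
  expect_false(ad$inverted)
  # inorganic branch also solvable; adapted PMF negative
  shi <- apply_shock(ns, "inorganic", 20, measured_pH_i = 5.32, pH_e = 4.0)
  adi <- solve_adaptation(shi)
  expect_lt(adi$pmf, 0)
  expect_lt(abs(adi$pmf - (-160)), 0.1)
})

test_that("closed-form and bisection adaptation solutions agree", {
  ns <- normal_scenario()
  for (ph in c(5.0, 5.5, 6.5)) {
    sh <- apply_shock(ns, octanoic_acid(), 20, measured_pH_i = ph)
    cf <- solve_adaptation(sh, method = "closed_form")
    bi <- solve_adaptation(sh, method = "bisection")
    alg <- ns$target_pmf_mean - ph_gradient_force(ph, ns$pH_e, ns$thermo)
    expect_equal(cf$delta_psi_required, alg, tolerance = 1e-9)
    expect_lt(abs(bi$delta_psi_required - alg), 1e-2)
  }
})

test_that("ion fold change is unity when the shock already sits at target", {
  ns <- normal_scenario(target_pmf_mean = -160)
  # an inorganic shock engineered to leave the PMF at the target
  sh <- apply_shock(ns, "inorganic", 5, measured_pH_i = 7.6, pH_e = 7.0)
  ad <- solve_adaptation(sh)
  expect_equal(ad$ion_fold_change, 1, tolerance = 1e-12)
  # the C8 case demands a large monovalent-anion accumulation
  shc <- apply_shock(ns, octanoic_acid(), 20, measured_pH_i = 5.5)
  adc <- solve_adaptation(shc)
  expect_gt(adc$ion_fold_change, 1)
})

test_that("scenario YAML round-trips through the three-phase driver", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("acid: C8", "pKa: 4.89", "dose_mM: 20", "pH_i: 5.5",
               "temperature_K: 310.15", "target_pmf_mV: -160",
               "target_range_mV: [-180, -140]"), path)
  sc <- read_scenario(path)
  tab <- run_pmf_scenario(sc$acid, sc$dose_mM, sc$measured_pH_i,
                          pH_e_shock = sc$pH_e_shock, normal = sc$normal)
  expect_equal(tab$label, c("normal", "shock", "adapted"))
  expect_equal(tab$pmf_mV[1], -160)
  expect_true(tab$inverted[2])
  expect_equal(tab$pmf_mV[3], -160, tolerance = 1e-6)
})
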