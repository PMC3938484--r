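test_that("generators are deterministic under a fixed seed", {
  g1 <- gen_growth_curves("c8_10mM", seed = 5)
  g2 <- gen_growth_curves("c8_10mM", seed = 5)
  expect_identical(g1, g2)
  f1 <- gen_fluorescence("control", seed = 5)
  expect_identical(f1, gen_fluorescence("control", seed = 5))
  expect_identical(gen_lipid_profiles("WT", 10, seed = 5),
                   gen_lipid_profiles("WT", 10, seed = 5))
  expect_identical(gen_gaba("c8", seed = 5), gen_gaba("c8", seed = 5))
  expect_identical(attr(gen_de_study(seed = 5), "truth"),
                   attr(gen_de_study(seed = 5), "truth"))
  # different seeds move the noise
  expect_false(identical(g1$control$od,
                         gen_growth_curves("c8_10mM", seed = 6)$control$od))
})

test_that("growth presets embed the configured inhibition", {
  g <- gen_growth_curves("c8_10mM", seed = 17)
  expect_equal(g$truth$inhibition_pct, 23)
  inh <- percent_inhibition(fit_growth_rate(g$control),
                            fit_growth_rate(g$treated))
  expect_lt(abs(inh - 23), 2)
  g0 <- gen_growth_curves("control", seed = 17)
  inh0 <- percent_inhibition(fit_growth_rate(g0$control),
                             fit_growth_rate(g0$treated))
  expect_lt(abs(inh0), 2)
})

test_that("fluorescence presets round-trip through calibration and inversion", {
  fl <- gen_fluorescence("hcl_20mM_unadjusted", seed = 11)
  cal <- fit_calibration(fl$standards)
  est <- estimate_ph(fl$samples$fluorescence, cal)
  expect_false(est$censored)
  expect_lt(abs(est$value - fl$truth$true_pH), 0.05)

  # long-term C8 sample sits below the reporter floor: censored at 5.5
  fl2 <- gen_fluorescence("c8_longterm", seed = 11)
  est2 <- estimate_ph(fl2$samples$fluorescence, fit_calibration(fl2$standards))
  expect_true(est2$censored)
  expect_equal(est2$value, 5.5)

  # production strain stays near-neutral
  fl3 <- gen_fluorescence("production", seed = 11)
  est3 <- estimate_ph(fl3$samples$fluorescence, fit_calibration(fl3$standards))
  expect_false(est3$censored)
  expect_gte(est3$value, 6.5)
  expect_error(gen_fluorescence("nope"), "unknown")
})

test_that("lipid presets satisfy their strain-defining constraints", {
  for (dose in c(0, 10, 30)) {
    d <- gen_lipid_profiles("dcfa", dose, seed = 2)
    expect_equal(unname(d["C17cyc"] + d["C19cyc"]), 0)
    expect_equal(sum(d), 100, tolerance = 0.5)
  }
  cf <- lipid_metrics(gen_lipid_profiles("cfa++", 0, seed = 3))
  expect_gte(cf$cyclopropane_molpct, 32)
  wt <- lipid_metrics(gen_lipid_profiles("WT", 0, seed = 3))
  expect_lte(wt$cyclopropane_molpct, 11)
  expect_error(gen_lipid_profiles("mystery"), "arg")
})

test_that("wildtype dose response lowers S:U and raises average length", {
  doses <- c(0, 10, 20, 30)
  met <- lapply(doses, function(d) {
    lipid_metrics(gen_lipid_profiles("WT", d, seed = 7))
  })
  su <- vapply(met, `[[`, numeric(1), "su_ratio")
  len <- vapply(met, `[[`, numeric(1), "avg_length")
  expect_true(all(diff(su) < 0))
  expect_true(all(diff(len) > 0))
})

test_that("GABA condition means encode the expected pool ordering", {
  ctl <- gen_gaba("control", seed = 1)
  expect_lt(abs(ctl$truth$intracellular - ctl$truth$extracellular) /
              ctl$truth$intracellular, 0.2)
  glu <- gen_gaba("glutamate", seed = 1)
  expect_gt(glu$truth$extracellular, ctl$truth$extracellular) # export up
  tot <- function(x) x$truth$intracellular + x$truth$extracellular
  expect_lt(abs(tot(glu) - tot(ctl)) / tot(ctl), 0.1) # total unchanged
  c8 <- gen_gaba("c8", seed = 1)
  expect_lt(tot(c8), tot(ctl)) # C8 lowers all pools
  expect_lt(tot(gen_gaba("c8_glutamate", seed = 1)), tot(ctl))
  expect_error(gen_gaba("unknown"), "arg")
})

test_that("NCA-model expression is exact at zero noise and feeds validation", {
  topo <- gen_topology(n_tf = 3, n_genes = 15, seed = 14)
  P0 <- matrix(rnorm(3 * 4), 3, 4, dimnames = list(topo$tfs, NULL))
  sim <- gen_expression(topo, P0, noise_sd = 0, n_replicates = 1, seed = 15)
  expect_equal(sim$matrix, sim$truth$A %*% sim$truth$P,
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_true(sim$truth$identifiable)
  expect_identical(sim$matrix,
                   gen_expression(topo, P0, noise_sd = 0,
                                  n_replicates = 1, seed = 15)$matrix)
  # an unidentifiable topology is flagged, not an error
  dup <- regulatory_topology(data.frame(TF = c("a", "b"),
                                        gene = c("g1", "g1")))
  expect_warning(gen_expression(dup, matrix(1, 2, 2), seed = 1),
                 "identifiability")
})

test_that("generated studies pass the consuming validators end to end", {
  st <- gen_de_study(n_genes = 40, n_de = 4, seed = 9)
  expect_s3_class(st, "expression_study")
  g <- gen_growth_curves("c8_10mM", seed = 9)
  expect_s3_class(g$control, "growth_series")
  pr <- gen_lipid_profiles("WT", 10, seed = 9)
  expect_s3_class(pr, "lipid_profile")
  fl <- gen_fluorescence("control", seed = 9)
  expect_s3_class(fit_calibration(fl$standards), "calibration_curve")
  gb <- gen_gaba("control", seed = 9)
  expect_true(gaba_balance(gb$intracellular, gb$extracellular)$total > 0)
})
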