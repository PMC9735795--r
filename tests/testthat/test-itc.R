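test_that("isotherm forward model reproduces limiting regimes", {
  des <- default_itc_design()
  # zero enthalpy: offset only
  expect_equal(simulate_isotherm(1e8, 0, 1, des, dilution_offset = 0.7),
               rep(0.7, 25))
  # stoichiometric (tight-binding) regime: heat per injection ~ dh * moles
  # injected until the equivalence point, then ~ 0
  q <- simulate_isotherm(1e12, -20, 1, des)
  mol_inj <- 6.82e-6 * 0.35e-3
  expect_equal(q[1], -20 * mol_inj * 1e9, tolerance = 1e-3)
  expect_lt(abs(q[25]), abs(q[1]) * 0.01)
  # breakpoint near molar ratio = n: cumulative titrant ~ n * peptide moles
  drop <- which(abs(diff(q)) == max(abs(diff(q))))
  ratio_at_drop <- (drop * mol_inj) / (1e-3 * 30e-6)
  expect_lt(abs(ratio_at_drop - 1), 0.15)
})

test_that("isotherm forward model matches the per-injection equilibrium oracle", {
  des <- default_itc_design()
  q <- simulate_isotherm(1e7, -18, 1, des, dilution_offset = 0.3)
  q_oracle <- oracle_itc_heats(1e7, -18, 1, des, offset = 0.3)
  expect_equal(q, q_oracle, tolerance = 1e-8)
})

test_that("isotherm fit recovers generator truth", {
  f0 <- fit_isotherm(gen_itc_isotherm(kb = 1e8, dh = -20, n = 1,
                                      noise_frac = 0, noise_floor = 0))
  expect_equal(f0$dh_itc, -20, tolerance = 1e-6)
  expect_equal(f0$stoichiometry_n, 1, tolerance = 1e-6)
  expect_equal(log10(f0$kb), 8, tolerance = 1e-6)
  f1 <- fit_isotherm(gen_itc_isotherm(kb = 1e8, dh = -20, n = 1,
                                      noise_frac = 0.01, seed = 3))
  expect_lt(abs(f1$dh_itc / -20 - 1), 0.02)
  expect_lt(abs(f1$stoichiometry_n - 1), 0.02)
})

test_that("isotherm fit is unbiased over repeated noise realisations", {
  est <- vapply(1:50, function(s) {
    f <- fit_isotherm(gen_itc_isotherm(seed = s))
    c(f$dh_itc + 20, f$stoichiometry_n - 1)
  }, numeric(2))
  for (i in 1:2) {
    expect_lt(abs(mean(est[i, ])), 2 * sd(est[i, ]) / sqrt(50))
  }
})

test_that("signal-free heats are rejected", {
  des <- default_itc_design()
  des$heats <- rep(0, 25)
  expect_error(fit_isotherm(des), class = "zf_fit_failure")
})

test_that("buffer correction reproduces reference ledger entries", {
  expect_equal(buffer_corrected_enthalpy(-20.87, 1.56), -13.06,
               tolerance = 0.05 / 13)
  expect_equal(buffer_corrected_enthalpy(-18.83, 1.64), -10.58,
               tolerance = 0.05 / 10)
  expect_equal(buffer_corrected_enthalpy(-15, 0), -15)
})

test_that("thiol deprotonation enthalpy scales with proton count", {
  expect_equal(cys_deprotonation_enthalpy(1.56), 13.23, tolerance = 0.05 / 13)
  expect_equal(cys_deprotonation_enthalpy(0), 0)
  expect_equal(cys_deprotonation_enthalpy(2), 17)
  expect_error(cys_deprotonation_enthalpy(2.5), class = "zf_invalid_input")
})

test_that("Zn-peptide and folding enthalpies follow the bond budget", {
  expect_equal(zn_pep_enthalpy(-13.06, 13.23), -26.29)
  expect_equal(zn_pep_enthalpy(-8.37, 14.31), -22.68)
  expect_equal(zn_pep_enthalpy(0, 0), 0)
  expect_equal(folding_enthalpy(-26.29, 2), -6.29)
  expect_equal(folding_enthalpy(-22.68, 2), -2.68)
  expect_equal(folding_enthalpy(-20, 2), 0)
  expect_error(folding_enthalpy(-20, 5), class = "zf_invalid_input")
})

test_that("Gibbs energy and entropy term close the thermodynamic cycle", {
  expect_equal(gibbs_from_neg_log_kd(14.49), -19.77, tolerance = 0.01 / 19)
  expect_equal(gibbs_from_neg_log_kd(13.50), -18.42, tolerance = 0.01 / 18)
  expect_equal(entropy_term(-19.77, -13.06), -6.71)
  expect_equal(entropy_term(-19.15, -8.37), -10.78)
  expect_equal(entropy_term(-5, -5), 0)
  expect_error(gibbs_from_neg_log_kd(-1), class = "zf_invalid_input")
})

test_that("full decomposition reproduces reference rows and identities", {
  ref_dg <- gibbs_from_neg_log_kd(14.49)
  # moderate-affinity consensus peptide vs the high-affinity reference
  d <- decompose(dh_itc = -18.83, n_h = 1.64, neg_log_kd = 12.30, n_his = 2,
                 reference_dg = ref_dg)
  expect_equal(d$ddg_vs_reference, 2.99, tolerance = 0.01 / 3)
  expect_equal(d$dg, -16.78, tolerance = 0.01 / 16)
  # K/S charge mutant: full ledger within printed rounding
  d2 <- decompose(dh_itc = -16.82, n_h = 1.68, neg_log_kd = 14.04, n_his = 2,
                  reference_dg = ref_dg)
  printed <- c(dg = -19.15, minus_tds = -10.78, dh_std = -8.37,
               dh_cysh = 14.31, dh_zn_pep = -22.68, dh_folding = -2.68)
  for (nm in names(printed)) {
    expect_lt(abs(d2[[nm]] - printed[[nm]]), 0.06)
  }
  # identities hold exactly for every produced ledger
  for (dd in list(d, d2)) expect_length(validate_ledger(dd, tol = 1e-9), 0)
  # reference omitted -> zero difference column
  expect_equal(decompose(-20, 1.5, 13, 2)$ddg_vs_reference, 0)
})

test_that("decomposition responds linearly to the buffer heat", {
  base <- decompose(-20.87, 1.56, 14.49, 2)
  delta <- 0.25
  pert <- decompose(-20.87, 1.56, 14.49, 2,
                    constants = thermo_constants(dh_buff = 5.02 + delta))
  expect_equal(pert$dh_std - base$dh_std, 1.56 * delta, tolerance = 1e-12)
  expect_equal(pert$dh_folding - base$dh_folding, 1.56 * delta,
               tolerance = 1e-12)
  expect_equal(pert$dg, base$dg)
  expect_equal(pert$minus_tds - base$minus_tds, -1.56 * delta,
               tolerance = 1e-12)
})

test_that("injection-table CSV pathway reconstructs an experiment", {
  tmp <- tempfile(fileext = ".csv")
  e <- gen_itc_isotherm(seed = 9)
  write.csv(data.frame(volume_ul = e$injection_volumes,
                       heat_ucal = e$heats), tmp, row.names = FALSE)
  inj <- read_injections_csv(tmp)
  e2 <- itc_from_injections(inj, cell_volume = 1, cell_concentration = 30e-6,
                            syringe_concentration = 0.35e-3)
  f <- fit_isotherm(e2)
  expect_equal(f$dh_itc, fit_isotherm(e)$dh_itc, tolerance = 1e-6)
  unlink(tmp)
})
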