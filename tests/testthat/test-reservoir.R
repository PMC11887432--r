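# Reservoir composition, Davies activity, and exchange-reaction constants.

test_that("Davies equation matches hand arithmetic", {
  expect_identical(davies_log10_gamma(0), 0)
  lg <- davies_log10_gamma(0.1)
  expect_equal(lg, -0.509 * (sqrt(0.1) / (1 + sqrt(0.1)) - 0.03))
  expect_equal(lg, -0.1070, tolerance = 1e-3)
  expect_equal(10^lg, 0.782, tolerance = 1e-3)
  # z^2 scaling: divalent log-coefficient is 4x the monovalent one
  expect_equal(davies_log10_gamma(0.3, z = 2), 4 * davies_log10_gamma(0.3))
  expect_error(davies_log10_gamma(-0.1), "ionic strength")
})

test_that("pure water and salted reservoirs solve to the stated composition", {
  w <- solve_reservoir(7, 0)
  expect_equal(unname(w$conc["H"]), 1e-7, tolerance = 1e-3)
  expect_equal(unname(w$conc["OH"]), unname(w$conc["H"]), tolerance = 1e-9)
  expect_identical(unname(w$conc["Na"]), 0)
  s <- solve_reservoir(7, 0.1)
  expect_equal(s$ionic_strength, 0.1, tolerance = 1e-4)
  expect_equal(s$gamma_pm, 0.782, tolerance = 1e-3)
  expect_equal(unname(s$constants["K_NaCl"]), s$gamma_pm^2 * 0.1 * 0.1)
  expect_equal(unname(s$constants["K_NaCl"]), 6.11e-3, tolerance = 1e-2)
  expect_identical(unname(s$constants["K_H2O"]), 1e-14)
})

test_that("reservoir invariants hold across the (pH, salt) plane", {
  set.seed(42)
  for (k in 1:200) {
    ph <- runif(1, 2, 12)
    cs <- 10^runif(1, -4, 0)
    r <- solve_reservoir(ph, cs)
    expect_silent(validate_reservoir(r))
    # activity-based pH convention round-trips
    expect_equal(-log10(r$gamma_pm * r$conc[["H"]]), ph, tolerance = 1e-9)
  }
})

test_that("composite acid constants close the thermodynamic cycle", {
  r <- solve_reservoir(6, 0.1)
  k <- composite_acid_constants(r, pKa = 4)
  expect_equal(k[["K_acid_Na"]] * r$constants[["K_HCl"]] /
                 r$constants[["K_NaCl"]], k[["K_acid_H"]])
  expect_equal(k[["K_acid_OH"]] * r$constants[["K_H2O"]], k[["K_acid_H"]])
  # ideal reservoir, pH 7, 0.1 M salt, pKa 4: K(HA -> A- + Na+) = 1e2
  ri <- solve_reservoir(7, 0.1, activity = "ideal")
  ki <- composite_acid_constants(ri, pKa = 4)
  expect_equal(ki[["K_acid_Na"]], 1e-4 * ri$conc[["Na"]] / ri$conc[["H"]],
               tolerance = 1e-9)
  expect_equal(ki[["K_acid_Na"]], 1e2, tolerance = 1e-3)
  # constants are independent of which pair reactions are taken as primary:
  # K_HCl recomputed from the NaOH/NaCl/H2O cycle matches the direct value
  expect_equal(r$constants[["K_NaCl"]] * r$constants[["K_H2O"]] /
                 r$constants[["K_NaOH"]], r$constants[["K_HCl"]],
               tolerance = 1e-10)
})

test_that("grand-canonical sampling of the bare reservoir matches the target", {
  # auxiliary ideal-gas simulation of the reservoir alone: recovered ion
  # concentrations agree with the prescribed ones within 3 SE
  res <- solve_reservoir(7, 0.1, activity = "ideal")
  box <- box_from_salt(0.1, 30L)
  tpl <- nanoparticle_template(n_sites = 1, charge_mode = "neutral")
  st <- build_system(tpl, 0L, box, res, mode = "no_interactions", seed = 3)
  ser <- run_simulation(st, mc_schedule(400, config_moves_per_cycle = 10L,
                                        reaction_moves_per_cycle = 60L,
                                        seed = 8))
  s <- summarise_series(ser)
  for (spc in c("Na", "Cl")) {
    bk <- s[[paste0("N_", spc)]]
    target <- res$conc[[spc]] * box$volume * patchtitrate:::.NA_C0_NM3
    expect_lt(abs(bk$mean - target), 3 * bk$se + 1e-9)
  }
  expect_equal(s$D_Na$value, 1, tolerance = 3 * s$D_Na$se / s$D_Na$value)
})
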