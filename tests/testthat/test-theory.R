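# Closed-form Donnan / Henderson-Hasselbalch theory.

test_that("ionic strength is the standard half-sum", {
  expect_equal(ionic_strength(c(Na = 0.1, Cl = 0.1)), 0.1)
  expect_equal(ionic_strength(c(Na = 0.1, Cl = 0.101, H = 1e-3, OH = 1e-11)),
               0.101, tolerance = 1e-6)
  expect_equal(ionic_strength(c(H = 1e-7, OH = 1e-7)), 1e-7)
  expect_equal(ionic_strength(c(Ca = 0.01, Cl = 0.02), z = c(2, 1)), 0.03)
})

test_that("ideal Donnan closed form and its limits", {
  r0 <- donnan_ideal(0, 0.1)
  expect_identical(r0$D_plus, 1)
  expect_identical(r0$delta_pH, 0)
  expect_identical(r0$psi_don, 0)
  # c_A = 2I: D+ = 1 + sqrt(2)
  expect_equal(donnan_ideal(0.2, 0.1)$D_plus, 1 + sqrt(2))
  # strong-confinement regime: D+ -> c_A / I
  r <- donnan_ideal(1.108, 0.01)
  expect_equal(r$D_plus, 110.8, tolerance = 1e-2)
  expect_gte(r$D_plus, 100)
  # reciprocity is exact
  for (ca in c(0, 0.01, 0.5, 2)) {
    d <- donnan_ideal(ca, 0.05)
    expect_equal(d$D_plus * d$D_minus, 1, tolerance = 1e-15)
    expect_equal(d$delta_pH, -log10(d$D_plus))
  }
  # monotone: increasing in c_A, decreasing in I
  ca_grid <- seq(0, 1, by = 0.1)
  D_ca <- vapply(ca_grid, function(ca) donnan_ideal(ca, 0.1)$D_plus, 0)
  expect_true(all(diff(D_ca) > 0))
  I_grid <- c(0.01, 0.05, 0.1, 0.5)
  D_I <- vapply(I_grid, function(I) donnan_ideal(0.2, I)$D_plus, 0)
  expect_true(all(diff(D_I) < 0))
  expect_error(donnan_ideal(0.1, 0), "invalid input")
})

test_that("Henderson-Hasselbalch relation", {
  expect_equal(hh_alpha(4, 4), 0.5)
  expect_equal(hh_alpha(5, 4), 10 / 11)
  expect_lt(hh_alpha(-20, 4), 1e-20)
  expect_gte(hh_alpha(30, 4), 1 - 1e-12)
})

test_that("Donnan potential convention", {
  expect_identical(donnan_potential(1), 0)
  expect_equal(donnan_potential(exp(1), 298), -25.7e-3, tolerance = 1e-2)
  # delta_pH = e psi / (kBT ln 10)
  d <- donnan_ideal(0.3, 0.05)
  kT_e <- pt_constants$k_B * 298 / pt_constants$e
  expect_equal(d$delta_pH, d$psi_don / (kT_e * log(10)), tolerance = 1e-12)
})

test_that("coupled HH+Donnan solver is exact and bounded by ideal HH", {
  # dilute sites: reduces to plain HH
  r <- coupled_hh_donnan(5, 4, 1e-8, 0.1)
  expect_equal(r$alpha, hh_alpha(5, 4), tolerance = 1e-6)
  expect_equal(r$delta_pH, 0, tolerance = 1e-6)
  # Donnan always suppresses ionization of anionic particles
  for (ph in seq(2, 12, by = 0.5)) {
    rc <- coupled_hh_donnan(ph, 4, 0.2, 0.05)
    expect_lte(rc$alpha, hh_alpha(ph, 4) + 1e-12)
    expect_equal(rc$D_plus * rc$D_minus, 1, tolerance = 1e-15)
  }
  # fixed point agrees with a brute-force grid scan of the residual
  resid <- function(a, ph, ca, I) {
    D <- donnan_ideal(a * ca, I)$D_plus
    a - hh_alpha(ph - log10(D), 4)
  }
  for (ph in c(4, 6, 9)) {
    sol <- coupled_hh_donnan(ph, 4, 0.2, 0.05)
    I <- solve_reservoir(ph, 0.05, activity = "ideal")$ionic_strength
    expect_lt(abs(resid(sol$alpha, ph, 0.2, I)), 1e-10)
    grid <- seq(0, 1, length.out = 100001)
    g <- vapply(grid, resid, 0, ph = ph, ca = 0.2, I = I)
    expect_lt(abs(grid[which.min(abs(g))] - sol$alpha), 2e-5)
  }
  # high-pH suppression: with water ions included, delta_pH turns back
  # toward zero at very high pH even though alpha stays 1
  d10 <- coupled_hh_donnan(10, 4, 0.2, 0.05)
  d12 <- coupled_hh_donnan(12, 4, 0.2, 0.05)
  expect_equal(d12$alpha, 1, tolerance = 1e-6)
  expect_lt(abs(d12$delta_pH), abs(d10$delta_pH))
  # without water ions there is no such suppression
  d12b <- coupled_hh_donnan(12, 4, 0.2, 0.05, include_water_ions = FALSE)
  expect_gt(abs(d12b$delta_pH), abs(d12$delta_pH))
})

test_that("theory sweep emits monotone titration curves", {
  tw <- theory_sweep(seq(2, 10, by = 1), pKa = 4, c_acid_total = 0.2,
                     c_salt = 0.05)
  expect_true(all(diff(tw$alpha) > 0))
  expect_true(all(tw$alpha <= tw$alpha_hh + 1e-12))
})
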