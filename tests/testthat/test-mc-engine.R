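# Monte Carlo kernels: acceptance rule, canonical sampling, reproducibility.

test_that("reaction acceptance matches the ideal-limit formula", {
  # one HA site, no ions, ideal system; choose pKa so K_A * V * N_A * c0 = 1
  # => forward acceptance probability is exactly 1, and so is the reverse
  # from the resulting (A-, one H+) state
  box <- box_spec(6)
  VNAc0 <- box$volume * patchtitrate:::.NA_C0_NM3
  pKa <- log10(VNAc0)
  res <- solve_reservoir(5, 0.1, activity = "ideal")
  for (k in 1:5) {
    tpl <- nanoparticle_template(n_sites = 1, pKa = pKa, seed = k)
    st <- build_system(tpl, 1L, box, res, mode = "no_interactions",
                       n_salt_pairs = 0L, seed = k)
    expect_true(attempt_reaction(st, "acid_H", +1))
    expect_identical(system_alpha(st)$n_A, 1L)
    expect_true(attempt_reaction(st, "acid_H", -1))
    expect_identical(system_alpha(st)$n_HA, 1L)
  }
})

test_that("reverse moves without the required particles are rejected", {
  box <- box_spec(6)
  res <- solve_reservoir(5, 0.1, activity = "ideal")
  tpl <- nanoparticle_template(n_sites = 1, pKa = 4, seed = 1)
  st <- build_system(tpl, 1L, box, res, mode = "no_interactions",
                     n_salt_pairs = 0L, seed = 1)
  # all sites protonated: protonation direction has no A- site
  expect_false(attempt_reaction(st, "acid_H", -1))
  # ionize via the Na+ variant; now no H+ exists for the H+ reverse
  while (!attempt_reaction(st, "acid_Na", +1)) NULL
  expect_false(attempt_reaction(st, "acid_H", -1))
  # and NaCl pair deletion has no Cl-
  expect_false(attempt_reaction(st, "NaCl", -1))
})

test_that("ideal titration is stationary at the Henderson-Hasselbalch point", {
  # dilute sites (one site in a 12 nm box) at pH = pKa: the acid-move chain
  # must hold <alpha> = 1/2
  box <- box_spec(12)
  res <- solve_reservoir(4, 0.1, activity = "ideal")
  tpl <- nanoparticle_template(n_sites = 1, pKa = 4, seed = 1)
  st <- build_system(tpl, 1L, box, res, mode = "no_interactions", seed = 2)
  ser <- run_simulation(st, mc_schedule(600, config_moves_per_cycle = 5L,
                                        reaction_moves_per_cycle = 50L,
                                        seed = 30))
  s <- summarise_series(ser)
  th <- coupled_hh_donnan(4, 4, count_to_molar(1, box$volume), 0.1)
  expect_lt(abs(s$alpha$mean - th$alpha), 3 * s$alpha$se)
  expect_lt(abs(s$alpha$mean - 0.5), 3 * s$alpha$se + 0.01)
})

test_that("ideal-gas moves are always accepted and overlaps never", {
  res <- solve_reservoir(7, 0.1, activity = "ideal")
  tpl <- nanoparticle_template(n_sites = 1, charge_mode = "neutral")
  st <- build_system(tpl, 2L, box_from_salt(0.1, 20L), res,
                     mode = "no_interactions", seed = 5)
  ser <- run_simulation(st, mc_schedule(50, 40, 0, seed = 6,
                                        tune_steps = FALSE))
  expect_identical(unname(attr(ser, "acceptance")["config"]), 1)
})

test_that("displacement sampling reproduces the pair Boltzmann distribution", {
  # two neutral WCA ions in a 2 nm box; the minimum-image pair distance r
  # below L/2 is distributed as r^2 exp(-beta u(r))
  L <- 2
  core <- bare_ion_core(L, c(2L, 3L), c(0, 0),
                        rbind(c(0.2, 0, 0), c(1.2, 0, 0)),
                        use_wca = TRUE, use_coulomb = FALSE)
  patchtitrate:::core_refresh(core)
  set.seed(99)
  nsamp <- 3000L
  r <- numeric(nsamp)
  for (k in seq_len(nsamp)) {
    for (m in 1:10) patchtitrate:::core_attempt_displacement(core, 0.6)
    p <- patchtitrate:::core_positions(core)
    d <- p[1, ] - p[2, ]
    d <- d - L * round(d / L)
    r[k] <- sqrt(sum(d^2))
  }
  edges <- seq(0.30, 0.95, length.out = 7)
  keep <- r >= edges[1] & r < edges[length(edges)]
  obs <- hist(r[keep], breaks = edges, plot = FALSE)$counts
  m <- energy_model()
  dens <- function(x) x^2 * exp(-wca_energy(x, c("Na", "Cl"), m))
  p_bin <- vapply(seq_len(length(edges) - 1), function(i)
    integrate(dens, edges[i], edges[i + 1])$value, 0)
  p_bin <- p_bin / sum(p_bin)
  chi <- suppressWarnings(chisq.test(obs, p = p_bin))
  expect_gt(chi$p.value, 0.001)
})

test_that("rigid rotations are free for an isolated particle", {
  res <- solve_reservoir(7, 0.1, activity = "ideal")
  tpl <- nanoparticle_template(n_sites = 10, theta = 0.9, seed = 1)
  st <- build_system(tpl, 1L, box_spec(8), res, mode = "full",
                     n_salt_pairs = 0L, seed = 3)
  set.seed(17)
  acc <- vapply(1:200, function(k) attempt_rotation(st, 1L, pi / 2), TRUE)
  expect_true(all(acc))
  # rigid-body integrity after many rotations
  pos <- patchtitrate:::core_positions(st$core)
  d <- dist(pos[-1, ])  # site-site distances
  d0 <- dist(world_site_positions(tpl, pose(), tpl$core_diameter / 2))
  expect_equal(sort(as.numeric(d)), sort(as.numeric(d0)), tolerance = 1e-9)
})

test_that("orientations are isotropic without a symmetry-breaking field", {
  # a uniformly covered particle in isotropic conditions: the direction to
  # any marked site is uniform on the sphere, so its z-component averages 0
  res <- solve_reservoir(7, 0.05, activity = "ideal")
  tpl <- nanoparticle_template(n_sites = 10, theta = 0, seed = 1)
  st <- build_system(tpl, 1L, box_spec(6), res, mode = "no_interactions",
                     n_salt_pairs = 0L, seed = 3)
  set.seed(23)
  z <- replicate(800, {
    for (m in 1:5) attempt_rotation(st, 1L, pi / 2)
    p <- patchtitrate:::core_positions(st$core)
    v <- p[2, ] - p[1, ]
    v[3] / sqrt(sum(v^2))
  })
  se <- sd(z) / sqrt(length(z) / 3)   # conservative: thin correlation ~3
  expect_lt(abs(mean(z)), 3 * se)
})

test_that("a charged patch orients toward its counterions", {
  # fully ionized theta = 0.9 patch with its 10 counterions: the patch axis
  # aligns with the direction to the nearest counterion (a purely geometric
  # statistic that is symmetric under no interactions)
  res <- solve_reservoir(7, 0.1, activity = "ideal")
  tpl <- nanoparticle_template(n_sites = 10, theta = 0.9, seed = 1,
                               charge_mode = "fixed_fraction",
                               alpha_fixed = 1)
  st <- build_system(tpl, 1L, box_spec(6), res, mode = "fixed_fraction",
                     n_salt_pairs = 0L, seed = 3)
  run_simulation(st, mc_schedule(100, 50, 0, seed = 31))  # equilibrate
  set.seed(41)
  L <- 6
  align <- replicate(400, {
    for (m in 1:10) patchtitrate:::core_attempt_displacement(st$core, 0.5)
    p <- patchtitrate:::core_positions(st$core)
    sp <- patchtitrate:::core_species(st$core)
    core_pos <- p[sp == 0, ]
    axis <- colMeans(p[sp == 1, , drop = FALSE]) - core_pos
    axis <- axis / sqrt(sum(axis^2))
    ions <- p[sp == 2, , drop = FALSE]
    d <- sweep(ions, 2, core_pos)
    d <- d - L * round(d / L)
    nearest <- d[which.min(rowSums(d^2)), ]
    sum(axis * nearest) / sqrt(sum(nearest^2))
  })
  se <- sd(align) / sqrt(length(align) / 3)
  expect_gt(mean(align), 3 * se)
})

test_that("runs are bitwise reproducible and neutral; zero cycles no-op", {
  tpl <- nanoparticle_template(n_sites = 5, theta = 0.5, seed = 2)
  box <- box_from_salt(0.1, 15L)
  res <- solve_reservoir(5, 0.1)
  mk <- function() build_system(tpl, 2L, box, res, mode = "full", seed = 8)
  s1 <- mk(); s2 <- mk()
  ser1 <- run_simulation(s1, mc_schedule(40, 50, 25, seed = 77))
  ser2 <- run_simulation(s2, mc_schedule(40, 50, 25, seed = 77))
  expect_identical(as.data.frame(ser1), as.data.frame(ser2))
  expect_identical(patchtitrate:::core_total_charge(s1$core), 0)
  # zero cycles returns the initial observables only
  s3 <- mk()
  ser0 <- run_simulation(s3, mc_schedule(0, 50, 25, seed = 1))
  expect_identical(nrow(as.data.frame(ser0)), 1L)
  expect_equal(as.data.frame(ser0)$n_HA, 10)
})

test_that("all four pair exchanges hold the reservoir composition ratios", {
  # ideal limit at pH 3: N_Na / N_H matches c_Na / c_H = 100 within 3 SE
  res <- solve_reservoir(3, 0.1, activity = "ideal")
  box <- box_from_salt(0.1, 30L)
  tpl <- nanoparticle_template(n_sites = 1, charge_mode = "neutral")
  st <- build_system(tpl, 0L, box, res, mode = "no_interactions", seed = 3)
  ser <- run_simulation(st, mc_schedule(500, config_moves_per_cycle = 5L,
                                        reaction_moves_per_cycle = 60L,
                                        seed = 12))
  s <- summarise_series(ser)
  ratio <- s$N_Na$mean / s$N_H$mean
  se <- ratio * sqrt((s$N_Na$se / s$N_Na$mean)^2 + (s$N_H$se / s$N_H$mean)^2)
  expect_lt(abs(ratio - res$conc[["Na"]] / res$conc[["H"]]), 3 * se)
})
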