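# WCA, Coulomb, Ewald and move-delta energetics.

test_that("augmented WCA has the stated shape for every species pair", {
  m <- energy_model()
  # offsets derived from the diameters
  expect_equal(unname(m$offsets["Na", "Cl"]), 0)
  expect_equal(unname(m$offsets["core", "Na"]), 0.5325)
  expect_equal(unname(m$offsets["core", "core"]), 1.065)
  for (pair in list(c("Na", "Cl"), c("core", "Na"), c("core", "core"))) {
    off <- m$offsets[pair[1], pair[2]]
    rc <- off + 2^(1 / 6) * m$sigma
    expect_identical(wca_energy(rc, pair, m), 0)            # zero at cutoff
    expect_lt(wca_energy(rc - 1e-12, pair, m), 1e-11)       # continuous
    expect_equal(wca_energy(off + m$sigma, pair, m), m$epsilon)  # eps at contact
    expect_identical(wca_energy(off + 1e-12, pair, m) > 1e10, TRUE)
    if (off > 0) expect_identical(wca_energy(off, pair, m), Inf)
    # monotone decreasing on (r_off, cutoff)
    r <- seq(off + 0.02, rc, length.out = 200)
    expect_true(all(diff(wca_energy(r, pair, m)) < 0))
    # pair symmetry
    expect_identical(wca_energy(off + 0.2, pair, m),
                     wca_energy(off + 0.2, rev(pair), m))
  }
  expect_error(wca_energy(1, c("site", "Na"), m), "missing offset")
})

test_that("Coulomb pair energy and the Bjerrum length are consistent", {
  m <- energy_model()
  expect_equal(coulomb_pair_energy(0.71, 1, 1, m), 1)
  expect_equal(coulomb_pair_energy(0.71, 1, -1, m), -1)
  expect_equal(coulomb_pair_energy(1.42, 1, 1, m), 0.5)
  expect_error(coulomb_pair_energy(0, 1, 1, m), "singular")
  expect_equal(round(bjerrum_length(78.5, 298), 2), 0.71)
  # inverse proportionality: lB * eps_r * T is constant
  expect_equal(bjerrum_length(78.5, 298) * 78.5 * 298,
               bjerrum_length(1, 298) * 1 * 298, tolerance = 1e-12)
  expect_equal(bjerrum_length(1, 298), 78.5 * bjerrum_length(78.5, 298),
               tolerance = 1e-12)
  expect_equal(bjerrum_length(1, 298), 55.8, tolerance = 0.01)
})

test_that("Ewald energy reproduces the rocksalt Madelung constant", {
  M_oracle <- evjen_madelung(8)           # direct-sum oracle
  expect_equal(M_oracle, 1.747565, tolerance = 1e-5)
  pos <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  q <- (-1)^rowSums(pos)
  core <- bare_ion_core(2, rep(2L, 8), q, pos, lB = 1)
  u <- patchtitrate:::core_total_energy(core)
  # energy per ion pair = -M * lB / a_nn, 4 pairs, a_nn = 1
  expect_equal(u$coulomb / 4, -M_oracle, tolerance = 1e-3 * M_oracle)
})

test_that("Ewald limits: zero charges, isolated pair, rigid translation", {
  core0 <- bare_ion_core(5, c(2L, 3L), c(0, 0), rbind(c(0, 0, 0), c(1, 1, 1)))
  expect_equal(patchtitrate:::core_total_energy(core0)$coulomb, 0)
  # +/- pair at r << L approaches the isolated Coulomb energy
  pos <- rbind(c(0, 0, 0), c(0.71, 0, 0))
  core <- bare_ion_core(16, c(2L, 3L), c(1, -1), pos)
  u <- patchtitrate:::core_total_energy(core)$coulomb
  expect_equal(u, coulomb_pair_energy(0.71, 1, -1), tolerance = 0.01)
  # invariance under rigid translation of all charges
  core2 <- bare_ion_core(16, c(2L, 3L), c(1, -1), pos + 3.21)
  u2 <- patchtitrate:::core_total_energy(core2)$coulomb
  expect_equal(u2, u, tolerance = 1e-3 * abs(u))
})

test_that("incremental move deltas match full recomputation", {
  tpl <- nanoparticle_template(n_sites = 5, theta = 0.5, seed = 3)
  res <- solve_reservoir(5, 0.1)
  st <- build_system(tpl, 2L, box_spec(6), res, mode = "full",
                     n_salt_pairs = 10L, seed = 2)
  # null move
  pos <- patchtitrate:::core_positions(st$core)
  n <- nrow(pos)
  expect_equal(move_energy_delta(st, moved = n, new_pos = pos[n, , drop = FALSE]),
               0, tolerance = 1e-12)
  set.seed(31)
  u_prev <- total_system_energy(st)$total
  for (k in 1:10) {
    pos <- patchtitrate:::core_positions(st$core)
    i <- sample(seq_len(nrow(pos)), 1)
    newp <- matrix(pos[i, ] + runif(3, -0.4, 0.4), 1, 3)
    du <- move_energy_delta(st, moved = i, new_pos = newp)
    if (is.finite(du)) {
      move_energy_delta(st, moved = i, new_pos = newp, apply = TRUE)
      u_now <- total_system_energy(st)$total
      expect_equal(du, u_now - u_prev, tolerance = 1e-8)
      u_prev <- u_now
    }
  }
  # insertion then deletion of the same ion pair cancels exactly
  p1 <- matrix(runif(3, 0, 6), 1, 3); p2 <- matrix(runif(3, 0, 6), 1, 3)
  d_ins <- move_energy_delta(st, insert_species = c("Na", "Cl"),
                             insert_charge = c(1, -1),
                             insert_pos = rbind(p1, p2), apply = TRUE)
  nn <- patchtitrate:::core_n(st$core)
  d_del <- move_energy_delta(st, deleted = c(nn - 1L, nn), apply = TRUE)
  expect_equal(d_ins + d_del, 0, tolerance = 1e-8)
  # hard overlap short-circuits to +Inf
  core_pos <- patchtitrate:::core_positions(st$core)[1, ]
  expect_identical(move_energy_delta(st, insert_species = "Na",
                                     insert_charge = 1,
                                     insert_pos = matrix(core_pos, 1, 3)),
                   Inf)
})

test_that("energy bookkeeping stays consistent over many accepted moves", {
  tpl <- nanoparticle_template(n_sites = 10, theta = 0.75, seed = 1)
  res <- solve_reservoir(5, 0.05)
  st <- build_system(tpl, 3L, box_from_salt(0.05, 10L), res, mode = "full",
                     seed = 6)
  ser <- run_simulation(st, mc_schedule(60, 100, 50, seed = 13,
                                        tune_steps = FALSE))
  n <- patchtitrate:::core_n(st$core)
  drift <- abs(patchtitrate:::core_cached_energy(st$core) -
               total_system_energy(st)$total)
  expect_lt(drift, 1e-6 * n)
  expect_identical(patchtitrate:::core_total_charge(st$core), 0)
})

test_that("periodic energy requires a neutral system", {
  tpl <- nanoparticle_template(n_sites = 2, theta = 0, seed = 1)
  res <- solve_reservoir(7, 0.1)
  st <- build_system(tpl, 1L, box_spec(6), res, mode = "full",
                     n_salt_pairs = 2L, seed = 2)
  # inject a bare charge, breaking neutrality
  patchtitrate:::core_try_insert(st$core, 2L, 1.0, runif(3, 0, 6))
  expect_error(total_system_energy(st), "neutrality")
})
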