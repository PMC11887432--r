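# Patch placement, rigid-body transforms and box bookkeeping.

test_that("degenerate and two-site placements are exact", {
  expect_equal(place_patch_sites(1, 0.5), matrix(c(0, 0, 1), 1, 3))
  # two sites on the full sphere maximize separation: antipodal, chord 2
  d2 <- place_patch_sites(2, 0, seed = 3)
  expect_equal(sqrt(sum((d2[1, ] - d2[2, ])^2)), 2, tolerance = 1e-6)
  expect_error(place_patch_sites(0, 0.5), "empty template")
  expect_error(place_patch_sites(5, 1.0), "patchiness")
  expect_error(place_patch_sites(5, 1.2), "patchiness")
})

test_that("placed sites always stay inside the patch cap", {
  for (theta in c(0, 0.5, 0.75, 0.9)) {
    phi_max <- cap_angle(theta)
    for (seed in 1:10) {
      dirs <- place_patch_sites(10, theta, seed = seed)
      expect_equal(unname(sqrt(rowSums(dirs^2))), rep(1, 10),
                   tolerance = 1e-12)
      polar <- acos(pmin(1, dirs[, 3]))
      expect_true(all(polar <= phi_max + 1e-9),
                  info = sprintf("theta=%g seed=%d", theta, seed))
    }
  }
  # theta = 0.90 cap opening is 36.87 degrees
  expect_equal(cap_angle(0.90), acos(1 - 2 * 0.1))
  expect_equal(cap_angle(0.90) * 180 / pi, 36.8699, tolerance = 1e-4)
})

test_that("placement is deterministic in the seed and locally optimal", {
  a <- place_patch_sites(10, 0.75, seed = 42)
  b <- place_patch_sites(10, 0.75, seed = 42)
  expect_identical(a, b)
  # random tangent perturbations (projected back into the cap) never improve
  # the spreading objective
  obj0 <- patchtitrate:::.cap_objective(a)
  phi_max <- cap_angle(0.75)
  set.seed(1)
  for (k in 1:20) {
    pert <- a + matrix(rnorm(30, sd = 1e-4), 10, 3)
    pert <- pert / sqrt(rowSums(pert^2))
    pert <- patchtitrate:::.cap_clamp(pert, phi_max)
    expect_gte(patchtitrate:::.cap_objective(pert), obj0 - 1e-9)
  }
})

test_that("mean site distance decreases with patchiness", {
  msd <- lapply(c(0, 0.5, 0.75, 0.9), function(th) {
    tpl <- nanoparticle_template(theta = th, seed = 1)
    mean_site_distance(tpl)
  })
  dq <- vapply(msd, `[[`, 0, "d_q")
  expect_true(all(diff(dq) < 0))
  dq_ap <- vapply(msd, `[[`, 0, "d_q_allpairs")
  expect_true(all(diff(dq_ap) < 0))
  # ratio column is d_q / lambda_B by construction
  for (m in msd) expect_equal(m$d_q_over_lB, m$d_q / 0.71)
  # two antipodal sites at radius 0.71: d_q is the diameter
  tpl2 <- nanoparticle_template(n_sites = 2, theta = 0, seed = 3)
  expect_equal(mean_site_distance(tpl2, site_radius = 0.71)$d_q, 1.42,
               tolerance = 1e-5)
  tpl1 <- nanoparticle_template(n_sites = 1)
  expect_error(mean_site_distance(tpl1), "fewer than 2")
})

test_that("box volume follows the salt-pair prescription", {
  box <- box_from_salt(0.1, 250L)
  expect_equal(box$volume, 250 / (6.02214076e23 * 100) * 1e27,
               tolerance = 1e-12)   # 4151.4 nm^3
  expect_equal(box$edge_length, 16.0719, tolerance = 1e-4)
  # inverse proportionality in c_salt
  expect_equal(box_from_salt(0.2, 250L)$volume, box$volume / 2)
  expect_error(box_from_salt(0, 250L), "concentration")
  expect_error(box_from_salt(-1, 250L), "concentration")
})

test_that("volume fraction is linear in count and cubic in diameter", {
  box <- box_from_salt(0.1, 250L)
  expect_identical(volume_fraction(0, 1.42, box), 0)
  expect_equal(volume_fraction(10, 1.42, box),
               10 * (pi / 6) * 1.42^3 / box$volume)
  expect_equal(volume_fraction(10, 1.42, box), 3.612e-3, tolerance = 1e-3)
  expect_equal(volume_fraction(20, 1.42, box),
               2 * volume_fraction(10, 1.42, box))
  expect_equal(volume_fraction(10, 2 * 1.42, box),
               8 * volume_fraction(10, 1.42, box))
  expect_gte(np_count_for_phi(1e-5, 1.42, box), 10)
})

test_that("poses are rigid isometries and compose like rotation matrices", {
  tpl <- nanoparticle_template(theta = 0.5, seed = 7)
  set.seed(11)
  d0 <- dist(world_site_positions(tpl, pose()))
  for (k in 1:10) {
    ax <- rnorm(3)
    q <- quat_from_axis_angle(ax, runif(1, 0, 2 * pi))
    p <- pose(runif(3, -5, 5), q)
    w <- world_site_positions(tpl, p, site_radius = 0.71)
    expect_equal(as.numeric(dist(w)), as.numeric(0.71 / 0.71 * dist(tpl$site_dirs * 0.71)),
                 tolerance = 1e-10)
    expect_equal(as.numeric(dist(world_site_positions(tpl, p))),
                 as.numeric(d0), tolerance = 1e-10)
  }
  # identity pose: center + r * dirs
  w0 <- world_site_positions(tpl, pose(c(1, 2, 3)), site_radius = 2)
  expect_equal(w0, sweep(tpl$site_dirs * 2, 2, c(1, 2, 3), "+"))
  # quaternion product matches rotation-matrix composition
  set.seed(12)
  for (k in 1:10) {
    q1 <- quat_from_axis_angle(rnorm(3), runif(1, 0, 2 * pi))
    q2 <- quat_from_axis_angle(rnorm(3), runif(1, 0, 2 * pi))
    expect_equal(quat_to_matrix(quat_multiply(q1, q2)),
                 quat_to_matrix(q1) %*% quat_to_matrix(q2), tolerance = 1e-12)
  }
  expect_error(quaternion(1, 1, 0, 0), "unit norm")
})

test_that("templates validate and round-trip through JSON", {
  tpl <- nanoparticle_template(theta = 0.9, seed = 5)
  f <- tempfile(fileext = ".json")
  template_to_json(tpl, f)
  tpl2 <- template_from_json(f)
  expect_equal(tpl2$site_dirs, tpl$site_dirs, tolerance = 1e-10)
  expect_equal(tpl2$theta, tpl$theta)
  expect_equal(tpl2$pKa, tpl$pKa)
  # a site outside the cap is rejected
  bad <- tpl
  bad$site_dirs[1, ] <- c(0, 0, -1)
  expect_error(validate_template(bad), "cap")
})
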