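# Nanoparticle geometry: patch placement on a spherical cap, rigid-body
# poses, and box / volume-fraction bookkeeping.
#
# A nanoparticle is a rigid sphere of diameter d_np carrying n_sites weakly
# acidic point sites at radius site_radius from the center. The sites live
# inside a single spherical cap covering a fraction (1 - theta) of the
# surface: theta = 0 spreads them over the whole sphere, theta = 0.9
# confines them to 10% of it. Site directions are stored in the body frame
# with the patch axis along +z.

#' Maximum polar angle of the patch cap
#'
#' The cap covering an area fraction `1 - theta` of the unit sphere, centered
#' on the patch axis, has polar opening angle `acos(2*theta - 1)` (from the
#' cap-area formula `A = 2*pi*R^2*(1 - cos(phi))`).
#'
#' @param theta degree of patchiness in `[0, 1)`.
#' @return Opening angle in radians.
#' @export
cap_angle <- function(theta) {
  .check_number(theta, "theta", lower = 0, upper = 1, strict_upper = TRUE)
  acos(1 - 2 * (1 - theta))
}

# sum of inverse pair chord distances (the spreading objective)
.cap_objective <- function(dirs) {
  d <- stats::dist(dirs)
  sum(1 / d)
}

# pull unit vectors with polar angle > phi_max back onto the cap boundary
.cap_clamp <- function(dirs, phi_max) {
  cz <- cos(phi_max)
  out <- dirs
  bad <- dirs[, 3] < cz
  if (any(bad)) {
    sz <- sin(phi_max)
    rho <- sqrt(dirs[bad, 1]^2 + dirs[bad, 2]^2)
    rho[rho < 1e-300] <- 1e-300
    out[bad, 1] <- dirs[bad, 1] / rho * sz
    out[bad, 2] <- dirs[bad, 2] / rho * sz
    out[bad, 3] <- cz
  }
  out
}

#' Place ionizable sites on a spherical cap
#'
#' Spreads `n_sites` unit vectors approximately uniformly over the cap of
#' area fraction `1 - theta` by minimizing the sum of inverse pair chord
#' distances (a Thomson-style objective) with projected-gradient descent
#' under the cap constraint. Random initialization is drawn uniformly on the
#' cap from `seed`; the result is deterministic for a fixed seed.
#'
#' @param n_sites number of sites (1 to 1000).
#' @param theta degree of patchiness in `[0, 1)`.
#' @param seed integer seed for the random initialization.
#' @param max_iter iteration budget of the relaxation.
#' @param tol absolute convergence tolerance on the objective.
#' @return An `n_sites` x 3 matrix of unit vectors (rows), all inside the cap.
#' @export
place_patch_sites <- function(n_sites, theta, seed = 1L, max_iter = 10000L,
                              tol = 1e-10) {
  n_sites <- .check_count(n_sites, "n_sites", min = 0L)
  if (n_sites == 0L) stop("empty template: n_sites must be >= 1", call. = FALSE)
  if (n_sites > 1000L) stop("n_sites must be <= 1000", call. = FALSE)
  if (!is.numeric(theta) || length(theta) != 1L || theta < 0 || theta >= 1)
    stop("invalid patchiness: theta must lie in [0, 1)", call. = FALSE)
  if (n_sites == 1L) return(matrix(c(0, 0, 1), 1, 3))

  phi_max <- cap_angle(theta)
  dirs <- withr_seed(seed, {
    # uniform on the cap: z uniform in [cos(phi_max), 1], azimuth uniform
    z <- stats::runif(n_sites, cos(phi_max), 1)
    az <- stats::runif(n_sites, 0, 2 * pi)
    r <- sqrt(pmax(0, 1 - z^2))
    unname(cbind(r * cos(az), r * sin(az), z))
  })

  obj <- .cap_objective(dirs)
  step <- 0.1
  for (it in seq_len(max_iter)) {
    # gradient of sum 1/d_ij w.r.t. each point
    dx <- outer(dirs[, 1], dirs[, 1], "-")
    dy <- outer(dirs[, 2], dirs[, 2], "-")
    dz <- outer(dirs[, 3], dirs[, 3], "-")
    d2 <- dx^2 + dy^2 + dz^2
    diag(d2) <- Inf
    w <- d2^(-1.5)
    g <- cbind(-rowSums(w * dx), -rowSums(w * dy), -rowSums(w * dz))
    # project onto the sphere tangent plane
    g <- g - dirs * rowSums(g * dirs)
    gn <- sqrt(max(rowSums(g^2)))
    if (gn == 0) break
    repeat {
      cand <- dirs - step / gn * g
      cand <- cand / sqrt(rowSums(cand^2))
      cand <- .cap_clamp(cand, phi_max)
      cand_obj <- .cap_objective(cand)
      if (cand_obj <= obj || step < 1e-14) break
      step <- step / 2
    }
    if (cand_obj > obj) break
    converged <- (obj - cand_obj) < tol
    dirs <- cand
    obj <- cand_obj
    step <- min(step * 1.2, 0.5)
    if (converged) break
  }
  dirs
}

#' Rigid nanoparticle template
#'
#' Blueprint for one nanoparticle: core diameter, number of ionizable sites,
#' degree of patchiness, the site unit vectors (body frame, patch axis +z),
#' the acidity constant and the charging mode.
#'
#' @param core_diameter core diameter in nm (default 1.42, four ion
#'   diameters).
#' @param n_sites number of weakly acidic surface sites.
#' @param theta degree of patchiness in `[0, 1)`.
#' @param pKa acidity constant of the sites (default 4.0).
#' @param charge_mode one of `"titrating"` (sites flip between HA and A-),
#'   `"fixed_fraction"` (all sites carry a constant charge `-alpha_fixed`),
#'   or `"neutral"`.
#' @param alpha_fixed fractional charge per site in `fixed_fraction` mode.
#' @param site_dirs optional n x 3 matrix of site unit vectors; computed with
#'   [place_patch_sites()] when omitted.
#' @param seed seed for the site placement when `site_dirs` is omitted.
#' @return An object of class `np_template`.
#' @export
nanoparticle_template <- function(core_diameter = 1.42, n_sites = 10L,
                                  theta = 0, pKa = 4.0,
                                  charge_mode = c("titrating", "fixed_fraction",
                                                  "neutral"),
                                  alpha_fixed = NULL, site_dirs = NULL,
                                  seed = 1L) {
  charge_mode <- match.arg(charge_mode)
  .check_number(core_diameter, "core_diameter", lower = 0, strict_lower = TRUE)
  n_sites <- .check_count(n_sites, "n_sites", min = 1L)
  if (theta < 0 || theta >= 1)
    stop("invalid patchiness: theta must lie in [0, 1)", call. = FALSE)
  if (charge_mode == "fixed_fraction") {
    if (is.null(alpha_fixed))
      stop("charge_mode 'fixed_fraction' requires alpha_fixed", call. = FALSE)
    .check_number(alpha_fixed, "alpha_fixed", lower = 0, upper = 1)
  } else {
    alpha_fixed <- NULL
  }
  if (is.null(site_dirs)) {
    site_dirs <- place_patch_sites(n_sites, theta, seed = seed)
  } else {
    site_dirs <- unname(as.matrix(site_dirs))
    stopifnot(nrow(site_dirs) == n_sites, ncol(site_dirs) == 3)
  }
  tpl <- structure(list(core_diameter = core_diameter, n_sites = n_sites,
                        theta = theta, pKa = pKa, charge_mode = charge_mode,
                        alpha_fixed = alpha_fixed, site_dirs = site_dirs),
                   class = "np_template")
  validate_template(tpl)
  tpl
}

#' Validate a nanoparticle template
#'
#' Checks unit norms of the site directions (tolerance 1e-12), cap
#' containment at the stated patchiness, and field consistency.
#'
#' @param tpl an `np_template`.
#' @return The template, invisibly; errors on violation.
#' @export
validate_template <- function(tpl) {
  stopifnot(inherits(tpl, "np_template"))
  if (nrow(tpl$site_dirs) != tpl$n_sites)
    stop("n_sites does not match the number of site directions", call. = FALSE)
  norms <- sqrt(rowSums(tpl$site_dirs^2))
  if (any(abs(norms - 1) > 1e-12))
    stop("site directions must be unit vectors (tolerance 1e-12)", call. = FALSE)
  phi_max <- cap_angle(tpl$theta)
  polar <- acos(pmin(1, pmax(-1, tpl$site_dirs[, 3])))
  if (any(polar > phi_max + 1e-9))
    stop("site directions fall outside the patch cap", call. = FALSE)
  invisible(tpl)
}

#' @export
print.np_template <- function(x, ...) {
  cat(sprintf("<np_template> d_np = %g nm, %d sites, theta = %g, pKa = %g, mode = %s\n",
              x$core_diameter, x$n_sites, x$theta, x$pKa, x$charge_mode))
  invisible(x)
}

#' Mean distance between ionizable sites
#'
#' Places the template's sites at `site_radius` from the center and returns
#' the mean nearest-neighbour Euclidean distance `d_q` together with its
#' ratio to the Bjerrum length. The all-pairs mean is reported as a secondary
#' statistic (which average the conventional tabulation uses is ambiguous).
#'
#' @param tpl an `np_template` with at least 2 sites.
#' @param site_radius radius at which sites sit, nm (default: core surface).
#' @param bjerrum Bjerrum length in nm (default 0.71).
#' @return List with `d_q`, `d_q_over_lB`, `d_q_allpairs`,
#'   `d_q_allpairs_over_lB`.
#' @export
mean_site_distance <- function(tpl, site_radius = tpl$core_diameter / 2,
                               bjerrum = 0.71) {
  validate_template(tpl)
  if (tpl$n_sites < 2)
    stop("site distances are undefined for fewer than 2 sites", call. = FALSE)
  .check_number(site_radius, "site_radius", lower = 0, strict_lower = TRUE)
  pos <- tpl$site_dirs * site_radius
  dm <- as.matrix(stats::dist(pos))
  diag(dm) <- Inf
  d_nn <- mean(apply(dm, 1, min))
  d_ap <- mean(dm[upper.tri(dm)])
  list(d_q = d_nn, d_q_over_lB = d_nn / bjerrum,
       d_q_allpairs = d_ap, d_q_allpairs_over_lB = d_ap / bjerrum)
}

#' Simulation box from the target salt content
#'
#' Chooses the cubic box volume so that it holds `n_salt_pairs` NaCl pairs at
#' the permeate salt concentration: `V_box = N_salt / (N_A * c_salt)`.
#'
#' @param c_salt salt concentration in mol/L (> 0).
#' @param n_salt_pairs number of salt ion pairs (default 250).
#' @return Object of class `box_spec` with `edge_length` (nm) and `volume`
#'   (nm^3).
#' @export
box_from_salt <- function(c_salt, n_salt_pairs = 250L) {
  if (!is.numeric(c_salt) || length(c_salt) != 1L || !is.finite(c_salt) ||
      c_salt <= 0)
    stop("invalid concentration: c_salt must be > 0", call. = FALSE)
  n_salt_pairs <- .check_count(n_salt_pairs, "n_salt_pairs", min = 1L)
  vol <- n_salt_pairs / (.NA_C0_NM3 * c_salt)    # nm^3
  structure(list(edge_length = vol^(1 / 3), volume = vol), class = "box_spec")
}

#' Box specification from an edge length
#'
#' @param edge_length cubic box edge in nm.
#' @return Object of class `box_spec`.
#' @export
box_spec <- function(edge_length) {
  .check_number(edge_length, "edge_length", lower = 0, strict_lower = TRUE)
  structure(list(edge_length = edge_length, volume = edge_length^3),
            class = "box_spec")
}

#' @export
print.box_spec <- function(x, ...) {
  cat(sprintf("<box_spec> edge = %.4f nm, V = %.2f nm^3 (periodic)\n",
              x$edge_length, x$volume))
  invisible(x)
}

#' Nanoparticle volume fraction
#'
#' `phi = n_np * (pi/6) * d_np^3 / V_box`.
#'
#' @param n_np number of nanoparticles (>= 0).
#' @param d_np nanoparticle diameter, nm.
#' @param box a `box_spec`.
#' @return Dimensionless volume fraction.
#' @export
volume_fraction <- function(n_np, d_np, box) {
  n_np <- .check_count(n_np, "n_np", min = 0L)
  .check_number(d_np, "d_np", lower = 0, strict_lower = TRUE)
  stopifnot(inherits(box, "box_spec"))
  n_np * (pi / 6) * d_np^3 / box$volume
}

#' Number of nanoparticles for a target volume fraction
#'
#' Rounds `phi * V / v_np` to the nearest integer (at least `n_min`,
#' defaulting to 10 to suppress finite-size effects).
#'
#' @param phi_np target volume fraction.
#' @param d_np nanoparticle diameter, nm.
#' @param box a `box_spec`.
#' @param n_min minimum particle number.
#' @return Integer count.
#' @export
np_count_for_phi <- function(phi_np, d_np, box, n_min = 10L) {
  .check_number(phi_np, "phi_np", lower = 0)
  n <- round(phi_np * box$volume / ((pi / 6) * d_np^3))
  max(as.integer(n), as.integer(n_min))
}

#' Site positions of a posed nanoparticle in the world frame
#'
#' `position + R(orientation) %*% (site_radius * site_dir)` for every site;
#' the rigid body is never wrapped by the periodic boundary.
#'
#' @param tpl an `np_template`.
#' @param pose a [pose()].
#' @param site_radius site radius from the center, nm.
#' @return n_sites x 3 matrix of positions.
#' @export
world_site_positions <- function(tpl, pose, site_radius = tpl$core_diameter / 2) {
  validate_template(tpl)
  stopifnot(inherits(pose, "pt_pose"))
  rotated <- quat_rotate(pose$orientation, tpl$site_dirs * site_radius)
  sweep(rotated, 2, pose$position, "+")
}

#' Export a nanoparticle template to JSON
#'
#' Writes diameter, patchiness, pKa and the site unit vectors (12 significant
#' digits) so a template can be reloaded exactly with
#' [template_from_json()].
#'
#' @param tpl an `np_template`.
#' @param path output file path.
#' @export
template_to_json <- function(tpl, path) {
  validate_template(tpl)
  obj <- list(core_diameter = tpl$core_diameter, n_sites = tpl$n_sites,
              theta = tpl$theta, pKa = tpl$pKa, charge_mode = tpl$charge_mode,
              alpha_fixed = tpl$alpha_fixed,
              site_dirs = signif(unclass(tpl$site_dirs), 12))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Import a nanoparticle template from JSON
#'
#' @param path file written by [template_to_json()].
#' @return An `np_template`.
#' @export
template_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dirs <- matrix(as.numeric(obj$site_dirs), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))   # re-normalize after rounding
  nanoparticle_template(core_diameter = obj$core_diameter,
                        n_sites = obj$n_sites, theta = obj$theta,
                        pKa = obj$pKa, charge_mode = obj$charge_mode,
                        alpha_fixed = obj$alpha_fixed, site_dirs = dirs)
}

# run code with a temporarily seeded RNG, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
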