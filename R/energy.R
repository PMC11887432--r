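# Interaction model: augmented (offset) WCA repulsion, bare Coulomb pairs,
# the Bjerrum length, and wrappers over the compiled periodic-energy core.
#
# The augmented WCA potential shifts the usual purely repulsive LJ form by a
# per-pair offset r_off so that differently sized particles contact at
# r_off + sigma = (d_i + d_j)/2: u(r) = 4 eps [ (sigma/x)^12 - (sigma/x)^6 ]
# + eps with x = r - r_off for x < 2^(1/6) sigma, zero beyond, infinite for
# x <= 0. Electrostatics are the full Coulomb potential u = lB z_i z_j / r
# (in kBT), evaluated under periodic boundaries by Ewald summation with a
# conducting (tinfoil) boundary at a configurable relative accuracy.

#' Bjerrum length
#'
#' `lambda_B = e^2 / (4 pi eps0 eps_r k_B T)`, the distance at which two unit
#' charges interact with thermal energy.
#'
#' @param rel_permittivity relative permittivity of the solvent.
#' @param temperature temperature in K.
#' @return Bjerrum length in nm (0.71 nm for water at 298 K).
#' @export
bjerrum_length <- function(rel_permittivity = 78.5, temperature = 298) {
  .check_number(rel_permittivity, "rel_permittivity", lower = 0, strict_lower = TRUE)
  .check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  cc <- pt_constants
  lb_m <- cc$e^2 / (4 * pi * cc$eps0 * rel_permittivity * cc$k_B * temperature)
  lb_m * 1e9
}

# 6x6 WCA offset matrix by species code; -1 marks pairs with no excluded
# volume (ionizable sites are massless point charges)
.offset_matrix <- function(d_np, d_ion, sigma) {
  m <- matrix(-1, 6, 6, dimnames = list(names(.SPECIES), names(.SPECIES)))
  ion <- c("Na", "Cl", "H", "OH")
  m[ion, ion] <- 0
  m["core", ion] <- (d_np + d_ion) / 2 - sigma
  m[ion, "core"] <- (d_np + d_ion) / 2 - sigma
  m["core", "core"] <- d_np - sigma
  m
}

#' Interaction model parameters
#'
#' Bundles the WCA and electrostatic parameters. Defaults follow the
#' coarse-grained aqueous model: sigma = d_ion = 0.355 nm, eps = 1 kBT,
#' r_cut = 2^(1/6) sigma (purely repulsive), offsets 0 (ion-ion),
#' (d_np + d_ion)/2 - sigma = 0.5325 nm (np-ion) and d_np - sigma = 1.065 nm
#' (np-np) for d_np = 1.42 nm, Bjerrum length 0.71 nm (water, 298 K), Ewald
#' relative accuracy 1e-3.
#'
#' @param sigma WCA range parameter, nm.
#' @param epsilon WCA prefactor, kBT.
#' @param d_np nanoparticle diameter used to derive the offsets, nm.
#' @param d_ion ion diameter, nm.
#' @param bjerrum Bjerrum length, nm.
#' @param ewald_accuracy target relative accuracy of the periodic Coulomb
#'   energy, in (0, 1).
#' @param temperature temperature, K (bookkeeping; energies are in kBT).
#' @param rel_permittivity relative permittivity (bookkeeping).
#' @return Object of class `energy_model`.
#' @export
energy_model <- function(sigma = 0.355, epsilon = 1.0, d_np = 1.42,
                         d_ion = 0.355, bjerrum = 0.71,
                         ewald_accuracy = 1e-3, temperature = 298,
                         rel_permittivity = 78.5) {
  .check_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  .check_number(epsilon, "epsilon", lower = 0)
  .check_number(d_np, "d_np", lower = 0, strict_lower = TRUE)
  .check_number(d_ion, "d_ion", lower = 0, strict_lower = TRUE)
  .check_number(bjerrum, "bjerrum", lower = 0, strict_lower = TRUE)
  .check_number(ewald_accuracy, "ewald_accuracy", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  structure(list(sigma = sigma, epsilon = epsilon,
                 r_cut_factor = 2^(1 / 6), d_np = d_np, d_ion = d_ion,
                 offsets = .offset_matrix(d_np, d_ion, sigma),
                 bjerrum = bjerrum, ewald_accuracy = ewald_accuracy,
                 temperature = temperature,
                 rel_permittivity = rel_permittivity),
            class = "energy_model")
}

#' @export
print.energy_model <- function(x, ...) {
  cat(sprintf(paste0("<energy_model> sigma = %g nm, eps = %g kBT, ",
                     "lB = %g nm, Ewald accuracy = %g\n"),
              x$sigma, x$epsilon, x$bjerrum, x$ewald_accuracy))
  cat(sprintf("  offsets: ion-ion %g, np-ion %g, np-np %g nm\n",
              x$offsets["Na", "Cl"], x$offsets["core", "Na"],
              x$offsets["core", "core"]))
  invisible(x)
}

.pair_offset <- function(pair, model) {
  pair <- as.character(pair)
  if (length(pair) != 2L || !all(pair %in% names(.SPECIES)))
    stop("missing offset: species pair must name two of ",
         paste(names(.SPECIES), collapse = ", "), call. = FALSE)
  off <- model$offsets[pair[1], pair[2]]
  if (off < 0)
    stop(sprintf("missing offset: no excluded volume defined for pair %s-%s",
                 pair[1], pair[2]), call. = FALSE)
  off
}

#' Augmented WCA pair energy
#'
#' @param r center-center distance, nm (vectorized).
#' @param pair length-2 character vector of species names (e.g.
#'   `c("core", "Na")`); determines the offset.
#' @param model an [energy_model()].
#' @return Energy in kBT; `Inf` for `r <= r_off`, 0 beyond the cutoff.
#' @export
wca_energy <- function(r, pair = c("Na", "Cl"), model = energy_model()) {
  off <- .pair_offset(pair, model)
  if (any(r <= 0)) stop("r must be > 0", call. = FALSE)
  x <- r - off
  rc <- model$r_cut_factor * model$sigma
  u <- numeric(length(r))
  u[x <= 0] <- Inf
  inside <- x > 0 & x < rc
  if (any(inside)) {
    s6 <- (model$sigma / x[inside])^6
    u[inside] <- 4 * model$epsilon * (s6^2 - s6) + model$epsilon
  }
  u
}

#' Coulomb pair energy
#'
#' `u = lB * z_i * z_j / r` in kBT.
#'
#' @param r separation, nm (vectorized).
#' @param z_i,z_j valencies.
#' @param model an [energy_model()].
#' @return Energy in kBT.
#' @export
coulomb_pair_energy <- function(r, z_i, z_j, model = energy_model()) {
  if (any(r <= 0)) stop("Coulomb energy is singular at r = 0", call. = FALSE)
  model$bjerrum * z_i * z_j / r
}

#' Total system energy of a simulation state
#'
#' Fresh full evaluation: WCA short range plus the periodic Coulomb energy
#' (Ewald real + reciprocal - self, tinfoil boundary) at the model's accuracy
#' target. Requires a net-neutral state.
#'
#' @param state a `pt_system` (see [build_system()]).
#' @return List with components `wca`, `real`, `recip`, `self`, `coulomb`,
#'   `total`, in kBT.
#' @export
total_system_energy <- function(state) {
  stopifnot(inherits(state, "pt_system"))
  if (state$use_coulomb && abs(core_total_charge(state$core)) > 1e-9)
    stop("neutrality violation: periodic Coulomb energy requires a net-neutral system",
         call. = FALSE)
  core_total_energy(state$core)
}

#' Total periodic electrostatic energy
#'
#' The Coulomb part of [total_system_energy()].
#'
#' @param state a `pt_system`.
#' @return Energy in kBT.
#' @export
total_electrostatic_energy <- function(state) {
  total_system_energy(state)$coulomb
}

#' Energy difference of a compound trial move
#'
#' Evaluates `U(new) - U(old)` for a move combining particle displacements,
#' site charge changes, insertions and deletions, without modifying the
#' state. Hard-core overlap short-circuits to `Inf`.
#'
#' @param state a `pt_system`.
#' @param moved integer indices (1-based) of displaced particles.
#' @param new_pos matrix of their new positions.
#' @param recharged indices of particles whose charge changes.
#' @param new_charge their new charges.
#' @param insert_species,insert_charge,insert_pos inserted particles
#'   (species names, charges, positions).
#' @param deleted indices of deleted particles.
#' @param apply if `TRUE`, commit the move to the state.
#' @return The energy difference in kBT.
#' @export
move_energy_delta <- function(state, moved = integer(), new_pos = NULL,
                              recharged = integer(), new_charge = numeric(),
                              insert_species = character(),
                              insert_charge = numeric(), insert_pos = NULL,
                              deleted = integer(), apply = FALSE) {
  stopifnot(inherits(state, "pt_system"))
  mv <- as.integer(moved) - 1L
  mp <- if (is.null(new_pos)) matrix(0, 0, 3) else
    matrix(as.numeric(new_pos), ncol = 3)
  qc <- as.integer(recharged) - 1L
  isp <- unname(.SPECIES[insert_species])
  if (any(is.na(isp))) stop("unknown insert species", call. = FALSE)
  ip <- if (is.null(insert_pos)) matrix(0, 0, 3) else
    matrix(as.numeric(insert_pos), ncol = 3)
  dl <- as.integer(deleted) - 1L
  if (apply) {
    core_apply(state$core, mv, mp, qc, as.numeric(new_charge),
               as.integer(isp), as.numeric(insert_charge), ip, dl)
  } else {
    core_delta(state$core, mv, mp, qc, as.numeric(new_charge),
               as.integer(isp), as.numeric(insert_charge), ip, dl)
  }
}
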