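# Steric-only ion partitioning: uncharged nanoparticles exclude volume and
# deplete small ions from the retentate. Two independent estimators of the
# cation distribution ratio:
#   * Widom insertion: D+ = <exp(-beta dU_ins)> over random test-ion
#     insertions into equilibrated neutral WCA configurations (the reservoir
#     is ideal at matched conditions, so D+ equals exp(-beta mu_excess));
#   * a charge-free grand-canonical run with ideal reservoir constants,
#     D+ = <c_Na^ret> / c_Na^perm.

#' Steric run specification
#'
#' @param phi_np nanoparticle volume fraction in `[0, 0.5)`.
#' @param d_np nanoparticle diameter, nm.
#' @param d_ion ion diameter, nm (default 0.355).
#' @param n_np number of nanoparticles in the box (sets the box size
#'   together with `phi_np`).
#' @param n_insertions Widom trial insertions per configuration.
#' @param n_configs number of decorrelated configurations.
#' @param n_equil_sweeps MC sweeps for equilibration.
#' @param n_decorr_sweeps MC sweeps between stored configurations.
#' @param seed integer seed.
#' @return Object of class `steric_spec`.
#' @export
steric_spec <- function(phi_np, d_np = 2.84, d_ion = 0.355, n_np = 30L,
                        n_insertions = 1000L, n_configs = 100L,
                        n_equil_sweeps = 400L, n_decorr_sweeps = 10L,
                        seed = 1L) {
  .check_number(phi_np, "phi_np", lower = 0, upper = 0.5, strict_upper = TRUE)
  .check_number(d_np, "d_np", lower = 0, strict_lower = TRUE)
  .check_number(d_ion, "d_ion", lower = 0, strict_lower = TRUE)
  structure(list(phi_np = phi_np, d_np = d_np, d_ion = d_ion,
                 n_np = .check_count(n_np, "n_np", min = 1L),
                 n_insertions = .check_count(n_insertions, "n_insertions", 1L),
                 n_configs = .check_count(n_configs, "n_configs", 1L),
                 n_equil_sweeps = .check_count(n_equil_sweeps,
                                               "n_equil_sweeps", 0L),
                 n_decorr_sweeps = .check_count(n_decorr_sweeps,
                                                "n_decorr_sweeps", 1L),
                 seed = as.integer(seed)),
            class = "steric_spec")
}

# neutral nanoparticle fluid for a steric run; phi = 0 gives an empty box
.steric_system <- function(spec, model) {
  if (spec$phi_np > 0) {
    vol <- spec$n_np * (pi / 6) * spec$d_np^3 / spec$phi_np
    box <- box_spec(vol^(1 / 3))
    n_np <- spec$n_np
  } else {
    box <- box_spec(max(10 * spec$d_ion, 4 * spec$d_np))
    n_np <- 0L
  }
  tpl <- nanoparticle_template(core_diameter = spec$d_np, n_sites = 1L,
                               theta = 0, charge_mode = "neutral")
  res <- solve_reservoir(7, 0.1, activity = "ideal")
  build_system(tpl, n_np, box, res, model = model, mode = "no_electrostatics",
               n_salt_pairs = 0L, seed = spec$seed)
}

#' Widom-insertion estimate of the steric distribution ratio
#'
#' Equilibrates neutral WCA nanoparticles at the requested volume fraction,
#' then performs `n_insertions` uniform test-ion insertions in each of
#' `n_configs` decorrelated configurations:
#' `D+ = <exp(-beta dU_insert)>`. The standard error treats per-configuration
#' means as independent.
#'
#' @param spec a [steric_spec()].
#' @param model an [energy_model()]; defaults to the spec's diameters.
#' @return List with `D_plus`, `se`, `n_insertions_total`, `n_configs`.
#' @export
widom_D_plus <- function(spec,
                         model = energy_model(d_np = spec$d_np,
                                              d_ion = spec$d_ion,
                                              sigma = spec$d_ion)) {
  stopifnot(inherits(spec, "steric_spec"))
  state <- .steric_system(spec, model)
  withr_seed(spec$seed + 1L, {
    sweep_moves <- max(1L, spec$n_np)
    for (i in seq_len(spec$n_equil_sweeps * sweep_moves))
      core_attempt_displacement(state$core, 0.5 * spec$d_np)
    per_config <- numeric(spec$n_configs)
    for (k in seq_len(spec$n_configs)) {
      for (i in seq_len(spec$n_decorr_sweeps * sweep_moves))
        core_attempt_displacement(state$core, 0.5 * spec$d_np)
      bf <- core_widom(state$core, .SPECIES[["Na"]], 0, spec$n_insertions)
      per_config[k] <- mean(bf)
    }
  })
  D <- mean(per_config)
  se <- stats::sd(per_config) / sqrt(spec$n_configs)
  if (D == 0)
    warning("numerical underflow: no accepted Widom insertions", call. = FALSE)
  list(D_plus = D, se = se,
       n_insertions_total = spec$n_insertions * spec$n_configs,
       n_configs = spec$n_configs)
}

#' Grand-canonical estimate of the steric distribution ratio
#'
#' Runs the charge-free engine with ideal-reservoir pair-exchange constants
#' at the spec's volume fraction and reads off
#' `D+ = <c_Na^ret> / c_Na^perm` with a blocking error. Agrees with
#' [widom_D_plus()] within the joint statistical error.
#'
#' @param spec a [steric_spec()].
#' @param c_salt reservoir salt concentration, mol/L.
#' @param n_cycles,moves_per_cycle,exchanges_per_cycle schedule knobs.
#' @param model an [energy_model()].
#' @return List with `D_plus`, `se`.
#' @export
gcmc_D_plus <- function(spec, c_salt = 0.1, n_cycles = 600L,
                        moves_per_cycle = 50L, exchanges_per_cycle = 50L,
                        model = energy_model(d_np = spec$d_np,
                                             d_ion = spec$d_ion,
                                             sigma = spec$d_ion)) {
  stopifnot(inherits(spec, "steric_spec"))
  if (spec$phi_np > 0) {
    vol <- spec$n_np * (pi / 6) * spec$d_np^3 / spec$phi_np
    box <- box_spec(vol^(1 / 3))
    n_np <- spec$n_np
  } else {
    # keep the mean pair number ~100: the electroneutral-pair ensemble
    # depletes <N> by O(1/(4<N>)) at small counts
    box <- box_from_salt(c_salt, 100L)
    n_np <- 0L
  }
  tpl <- nanoparticle_template(core_diameter = spec$d_np, n_sites = 1L,
                               theta = 0, charge_mode = "neutral")
  res <- solve_reservoir(7, c_salt, activity = "ideal")
  state <- build_system(tpl, n_np, box, res, model = model,
                        mode = "no_electrostatics", seed = spec$seed)
  sched <- mc_schedule(n_cycles, config_moves_per_cycle = moves_per_cycle,
                       reaction_moves_per_cycle = exchanges_per_cycle,
                       displacement_step = spec$d_ion, seed = spec$seed + 2L)
  series <- run_simulation(state, sched)
  summ <- summarise_series(series)
  list(D_plus = summ$D_Na$value, se = summ$D_Na$se)
}
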