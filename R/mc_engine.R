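# Retentate sampling: system assembly and the Grand-Reaction Monte Carlo
# driver. Configurational sampling uses single-unit Metropolis moves
# (ion displacements, rigid-body translations and rotations); the chemical
# moves are reaction-ensemble acid moves (three equivalent implementations)
# and grand-canonical electroneutral ion-pair exchanges with the reservoir.
# All moves preserve the net charge exactly, so the periodic Coulomb energy
# is always well defined.

#' Monte Carlo schedule
#'
#' @param n_cycles number of cycles.
#' @param config_moves_per_cycle configurational trials per cycle
#'   (default 1000).
#' @param reaction_moves_per_cycle reaction/exchange trials per cycle
#'   (default 250, the conventional 4:1 mix).
#' @param displacement_step initial side of the displacement cube, nm;
#'   auto-tuned to 30-50% acceptance during equilibration, then frozen
#'   (tuning during production would break detailed balance).
#' @param rotation_step maximum rotation angle, radians.
#' @param seed integer seed; every run with the same seed and state is
#'   bitwise reproducible.
#' @param equilibration_fraction fraction of cycles treated as
#'   equilibration (tuning window and default analysis discard; 0.30).
#' @param observe_every sampling interval in cycles.
#' @param tune_steps logical, auto-tune step sizes during equilibration.
#' @return Object of class `mc_schedule`.
#' @export
mc_schedule <- function(n_cycles, config_moves_per_cycle = 1000L,
                        reaction_moves_per_cycle = 250L,
                        displacement_step = 0.355, rotation_step = pi / 2,
                        seed = 1L, equilibration_fraction = 0.30,
                        observe_every = 1L, tune_steps = TRUE) {
  n_cycles <- .check_count(n_cycles, "n_cycles", min = 0L)
  config_moves_per_cycle <- .check_count(config_moves_per_cycle,
                                         "config_moves_per_cycle", min = 0L)
  reaction_moves_per_cycle <- .check_count(reaction_moves_per_cycle,
                                           "reaction_moves_per_cycle", min = 0L)
  .check_number(equilibration_fraction, "equilibration_fraction", lower = 0,
                upper = 1, strict_upper = TRUE)
  structure(list(n_cycles = n_cycles,
                 config_moves_per_cycle = config_moves_per_cycle,
                 reaction_moves_per_cycle = reaction_moves_per_cycle,
                 displacement_step = displacement_step,
                 rotation_step = rotation_step, seed = as.integer(seed),
                 equilibration_fraction = equilibration_fraction,
                 observe_every = .check_count(observe_every, "observe_every",
                                              min = 1L),
                 tune_steps = isTRUE(tune_steps)),
            class = "mc_schedule")
}

#' Assemble a simulation system
#'
#' Builds the initial retentate state: `n_np` copies of the template at
#' random non-overlapping positions and orientations, all sites protonated
#' (titrating mode) or carrying their fixed fractional charge, plus the
#' initial salt content inserted by rejection sampling. In
#' `fixed_fraction` mode the per-site charge is quantised to
#' `-round(n_sites_total * alpha_fixed) / n_sites_total` so the compensating
#' counterion number is an integer.
#'
#' @param template an [nanoparticle_template()].
#' @param n_np number of nanoparticles.
#' @param box a `box_spec`.
#' @param reservoir a [solve_reservoir()] result.
#' @param model an [energy_model()].
#' @param mode one of `"full"`, `"no_electrostatics"`, `"no_interactions"`,
#'   `"fixed_fraction"`.
#' @param n_salt_pairs initial number of NaCl pairs (defaults to the
#'   reservoir concentration times the box volume).
#' @param site_radius site radius, nm (default: on the core surface).
#' @param seed seed for the random initial configuration.
#' @param max_attempts rejection-sampling budget for insertions.
#' @return Object of class `pt_system`.
#' @export
build_system <- function(template, n_np, box, reservoir,
                         model = energy_model(d_np = template$core_diameter),
                         mode = c("full", "no_electrostatics",
                                  "no_interactions", "fixed_fraction"),
                         n_salt_pairs = NULL,
                         site_radius = template$core_diameter / 2,
                         seed = 1L, max_attempts = 1e6) {
  mode <- match.arg(mode)
  validate_template(template)
  stopifnot(inherits(box, "box_spec"), inherits(reservoir, "reservoir_spec"),
            inherits(model, "energy_model"))
  n_np <- .check_count(n_np, "n_np", min = 0L)
  L <- box$edge_length
  use_wca <- mode %in% c("full", "no_electrostatics", "fixed_fraction")
  use_coulomb <- mode %in% c("full", "fixed_fraction")
  if (use_wca && L < 2 * model$r_cut_factor * model$sigma +
        max(0, model$offsets["core", "core"]))
    stop("box edge too small for the interaction range", call. = FALSE)

  ns <- template$n_sites
  site_q <- 0
  titrating <- template$charge_mode == "titrating" &&
    mode %in% c("full", "no_electrostatics", "no_interactions")
  if (mode == "fixed_fraction" || template$charge_mode == "fixed_fraction") {
    if (is.null(template$alpha_fixed))
      stop("fixed_fraction mode needs a template with alpha_fixed", call. = FALSE)
    ntot <- n_np * ns
    qtot <- round(template$alpha_fixed * ntot)
    site_q <- -qtot / ntot
    titrating <- FALSE
  }

  built <- withr_seed(seed, {
    # nanoparticle cores: random sequential insertion with a contact margin
    min_cc <- if (use_wca) model$offsets["core", "core"] + model$sigma else 0
    centers <- matrix(0, 0, 3)
    attempts <- 0
    while (nrow(centers) < n_np) {
      cand <- stats::runif(3, 0, L)
      ok <- TRUE
      if (nrow(centers) > 0 && min_cc > 0) {
        d <- sweep(centers, 2, cand)
        d <- d - L * round(d / L)
        ok <- all(sqrt(rowSums(d^2)) > min_cc)
      }
      if (ok) centers <- rbind(centers, cand)
      attempts <- attempts + 1
      if (attempts > max_attempts)
        stop("initialization error: could not place nanoparticles without overlap",
             call. = FALSE)
    }
    poses <- lapply(seq_len(max(n_np, 0)), function(i) {
      ax <- stats::rnorm(3); ax <- ax / sqrt(sum(ax^2))
      pose(centers[i, ], quat_from_axis_angle(ax, stats::runif(1, 0, 2 * pi)))
    })
    sp <- integer(0); qv <- numeric(0); posm <- matrix(0, 0, 3); body <- integer(0)
    for (i in seq_len(n_np)) {
      sp <- c(sp, .SPECIES["core"], rep(.SPECIES["site"], ns))
      qv <- c(qv, 0, rep(site_q, ns))
      posm <- rbind(posm, matrix(poses[[i]]$position, 1, 3),
                    world_site_positions(template, poses[[i]], site_radius))
      body <- c(body, rep(i - 1L, ns + 1L))
    }
    n_fixed <- length(sp)
    core <- core_new(L, as.integer(sp), qv, posm, as.integer(body), n_fixed,
                     model$offsets, model$sigma, model$epsilon, model$bjerrum,
                     model$ewald_accuracy, use_wca, use_coulomb)
    # initial small ions: salt pairs plus counterions for any fixed charge
    n_salt <- if (is.null(n_salt_pairs))
      round(reservoir$conc[["Na"]] * box$volume * .NA_C0_NM3) else n_salt_pairs
    n_counter <- round(-site_q * n_np * ns)
    queue <- rbind(
      data.frame(species = rep(c("Na", "Cl"), n_salt),
                 q = rep(c(1, -1), n_salt)),
      if (n_counter > 0) data.frame(species = rep("Na", n_counter),
                                    q = rep(1, n_counter))
    )
    attempts <- 0
    for (k in seq_len(nrow(queue))) {
      repeat {
        attempts <- attempts + 1
        if (attempts > max_attempts)
          stop("initialization error: could not insert initial ions without overlap",
               call. = FALSE)
        if (core_try_insert(core, .SPECIES[[queue$species[k]]], queue$q[k],
                            stats::runif(3, 0, L))) break
      }
    }
    list(core = core, poses = poses)
  })

  state <- structure(list(core = built$core, template = template, n_np = n_np,
                          box = box, reservoir = reservoir, model = model,
                          mode = mode, site_radius = site_radius,
                          titrating = titrating, site_charge = site_q,
                          poses = built$poses,
                          use_wca = use_wca, use_coulomb = use_coulomb),
                     class = "pt_system")
  core_refresh(state$core)
  .check_neutral(state)
  state
}

.check_neutral <- function(state) {
  qt <- core_total_charge(state$core)
  if (abs(qt) > 1e-9)
    stop(sprintf("electroneutrality violated: net charge %g", qt), call. = FALSE)
  invisible(qt)
}

#' @export
print.pt_system <- function(x, ...) {
  cnt <- core_counts(x$core)
  cat(sprintf("<pt_system> mode = %s, L = %.3f nm, %d nanoparticles\n",
              x$mode, x$box$edge_length, x$n_np))
  cat(sprintf("  particles: %d cores, %d sites, Na %d, Cl %d, H %d, OH %d\n",
              cnt[1], cnt[2], cnt[3], cnt[4], cnt[5], cnt[6]))
  invisible(x)
}

# reaction/exchange move table for the engine: type codes as in simcore.cpp
.reaction_table <- function(state) {
  res <- state$reservoir
  k <- res$constants
  types <- integer(0); lnK <- numeric(0)
  if (state$titrating) {
    ka <- composite_acid_constants(res, state$template$pKa)
    types <- c(types, 1L, 2L, 3L)
    lnK <- c(lnK, log(ka[["K_acid_H"]]), log(ka[["K_acid_Na"]]),
             log(ka[["K_acid_OH"]]))
  }
  types <- c(types, 4L, 5L, 6L, 7L)
  lnK <- c(lnK, log(k[["K_NaCl"]]), log(k[["K_HCl"]]), log(k[["K_NaOH"]]),
           log(k[["K_H2O"]]))
  # degenerate reservoirs (zero salt) yield undefined composite constants;
  # such moves are dropped rather than attempted with NaN acceptance
  keep <- !is.nan(lnK)
  list(types = types[keep], lnK = lnK[keep])
}

#' Run a Grand-Reaction Monte Carlo simulation
#'
#' Executes `schedule$n_cycles` cycles of configurational trials followed by
#' reaction/exchange trials (types chosen uniformly, direction +/- 1 with
#' probability 1/2). Displacement and rotation steps are tuned to 30-50%
#' acceptance during the equilibration window and frozen afterwards.
#' Observables (site states, ion counts, total energy) are recorded every
#' `observe_every` cycles over the whole run; the equilibration discard is
#' applied later, at analysis time.
#'
#' @param state a `pt_system` from [build_system()].
#' @param schedule an [mc_schedule()].
#' @return A `pt_series`: data.frame of samples with attributes `reservoir`,
#'   `volume_nm3`, `mode`, `alpha_fixed`, `equilibration_fraction`,
#'   `acceptance`, `steps` and `seed`.
#' @export
run_simulation <- function(state, schedule) {
  stopifnot(inherits(state, "pt_system"), inherits(schedule, "mc_schedule"))
  set.seed(schedule$seed)
  core_refresh(state$core)
  rxn <- .reaction_table(state)
  lnVNAc0 <- log(state$box$volume * .NA_C0_NM3)
  disp <- schedule$displacement_step
  rot <- schedule$rotation_step
  n_eq <- floor(schedule$equilibration_fraction * schedule$n_cycles)
  samples <- list()
  acc <- c(config = 0, rxn = 0); att <- c(config = 0, rxn = 0)

  run_chunk <- function(nc) {
    core_run_cycles(state$core, nc, schedule$config_moves_per_cycle, disp, rot,
                    schedule$reaction_moves_per_cycle, rxn$types, rxn$lnK,
                    lnVNAc0, schedule$observe_every, 500L)
  }
  collect <- function(out, cycle0) {
    s <- out$samples
    if (nrow(s) > 0) { s[, "cycle"] <- s[, "cycle"] + cycle0
      samples[[length(samples) + 1L]] <<- s }
    acc <<- acc + c(out$acc_config, out$acc_rxn)
    att <<- att + c(out$att_config, out$att_rxn)
  }

  done <- 0L
  if (schedule$tune_steps && n_eq > 0 && schedule$config_moves_per_cycle > 0) {
    chunk <- max(5L, min(25L, n_eq %/% 8L))
    while (done < n_eq) {
      nc <- min(chunk, n_eq - done)
      out <- run_chunk(nc)
      collect(out, done)
      done <- done + nc
      if (out$att_config > 0) {
        frac <- out$acc_config / out$att_config
        if (frac < 0.30) disp <- max(disp * 0.7, 0.05 * state$model$sigma)
        if (frac > 0.50) disp <- min(disp * 1.3, state$box$edge_length / 2)
        if (frac < 0.30) rot <- max(rot * 0.8, 0.02)
        if (frac > 0.50) rot <- min(rot * 1.2, pi)
      }
    }
  }
  if (done < schedule$n_cycles) {
    out <- run_chunk(schedule$n_cycles - done)
    collect(out, done)
    done <- schedule$n_cycles
  }

  df <- if (length(samples) > 0) as.data.frame(do.call(rbind, samples)) else
    as.data.frame(matrix(numeric(0), 0, 8,
                         dimnames = list(NULL, c("cycle", "n_HA", "n_A", "N_Na",
                                                 "N_Cl", "N_H", "N_OH", "U"))))
  if (schedule$n_cycles == 0) {
    cnt <- core_counts(state$core)
    df <- data.frame(cycle = 0, n_HA = sum(core_site_charges(state$core) == 0),
                     n_A = sum(core_site_charges(state$core) != 0),
                     N_Na = cnt[3], N_Cl = cnt[4], N_H = cnt[5], N_OH = cnt[6],
                     U = core_cached_energy(state$core))
  }
  .check_neutral(state)
  structure(df, class = c("pt_series", "data.frame"),
            reservoir = state$reservoir, volume_nm3 = state$box$volume,
            mode = state$mode,
            alpha_fixed = if (state$titrating) NULL else -state$site_charge,
            equilibration_fraction = schedule$equilibration_fraction,
            acceptance = c(config = unname(acc[1] / max(att[1], 1)),
                           reaction = unname(acc[2] / max(att[2], 1))),
            steps = c(displacement = disp, rotation = rot),
            seed = schedule$seed)
}

#' Single trial moves (exposed for diagnostics and tests)
#'
#' `attempt_displacement()` proposes one configurational trial (a uniformly
#' chosen ion or rigid body; bodies translate or rotate with probability 1/2
#' each); `attempt_rotation()` rotates a specific nanoparticle;
#' `attempt_reaction()` performs one reaction/exchange trial of the given
#' type.
#'
#' @param state a `pt_system`.
#' @param step displacement cube side, nm.
#' @return Logical: was the trial accepted?
#' @export
attempt_displacement <- function(state, step = 0.355) {
  core_attempt_displacement(state$core, step)
}

#' @rdname attempt_displacement
#' @param body nanoparticle index (1-based).
#' @param max_angle maximum rotation angle, radians.
#' @export
attempt_rotation <- function(state, body = 1L, max_angle = pi / 2) {
  core_attempt_rotation(state$core, as.integer(body) - 1L, max_angle)
}

#' @rdname attempt_displacement
#' @param type move type: `"acid_H"`, `"acid_Na"`, `"acid_OH"`, `"NaCl"`,
#'   `"HCl"`, `"NaOH"`, `"HOH"`.
#' @param xi direction: +1 forward, -1 reverse.
#' @export
attempt_reaction <- function(state, type, xi = 1L) {
  codes <- c(acid_H = 1L, acid_Na = 2L, acid_OH = 3L, NaCl = 4L, HCl = 5L,
             NaOH = 6L, HOH = 7L)
  code <- codes[[type]]
  rxn <- .reaction_table(state)
  pos <- match(code, rxn$types)
  if (is.na(pos)) stop("move type not enabled in this mode", call. = FALSE)
  core_attempt_reaction(state$core, code, as.integer(xi), rxn$lnK[pos],
                        log(state$box$volume * .NA_C0_NM3))
}

#' Current ionization state of a system
#'
#' @param state a `pt_system`.
#' @return List with `n_HA`, `n_A` and `alpha`.
#' @export
system_alpha <- function(state) {
  qs <- core_site_charges(state$core)
  n_HA <- sum(qs == 0); n_A <- sum(qs != 0)
  list(n_HA = n_HA, n_A = n_A,
       alpha = if (state$titrating) n_A / max(1, n_HA + n_A)
               else -state$site_charge)
}
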