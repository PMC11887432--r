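# Shared simulation runs, computed once per test session and cached.
# Common interacting state point: permeate pH 5, 0.05 M salt (25 pairs,
# box edge 9.40 nm), 10 nanoparticles with 10 sites each (pKa 4), i.e.
# c_acid ~ 0.2 M -- small enough to run in seconds, large enough that the
# Donnan and polyelectrolyte effects are both well resolved.

.run_cache <- new.env(parent = emptyenv())

shared_state_point <- list(pH = 5, c_salt = 0.05, n_salt = 25L, n_np = 10L,
                           n_cycles = 300L, n_config = 200L, n_rxn = 100L)

shared_interacting_summary <- function(theta) {
  key <- paste0("full_theta_", theta)
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  p <- shared_state_point
  tpl <- nanoparticle_template(n_sites = 10, theta = theta, seed = 1)
  box <- box_from_salt(p$c_salt, p$n_salt)
  res <- solve_reservoir(p$pH, p$c_salt)
  st <- build_system(tpl, p$n_np, box, res, mode = "full", seed = 4)
  ser <- run_simulation(st, mc_schedule(p$n_cycles, p$n_config, p$n_rxn,
                                        seed = 9))
  out <- list(summary = summarise_series(ser), series = ser, state = st,
              box = box, reservoir = res)
  .run_cache[[key]] <- out
  out
}

shared_fixed_fraction_summary <- function() {
  if (!is.null(.run_cache[["fixed"]])) return(.run_cache[["fixed"]])
  p <- shared_state_point
  base <- shared_interacting_summary(0)
  af <- round(p$n_np * 10 * base$summary$alpha$mean) / (p$n_np * 10)
  tpl <- nanoparticle_template(n_sites = 10, theta = 0, seed = 1,
                               charge_mode = "fixed_fraction",
                               alpha_fixed = af)
  st <- build_system(tpl, p$n_np, base$box, base$reservoir,
                     mode = "fixed_fraction", seed = 4)
  ser <- run_simulation(st, mc_schedule(p$n_cycles, p$n_config, p$n_rxn,
                                        seed = 10))
  out <- list(summary = summarise_series(ser), series = ser, state = st,
              alpha_fixed = af)
  .run_cache[["fixed"]] <- out
  out
}

# no-interactions pH sweep at 0.1 M salt (50 pairs, 10 nanoparticles),
# compared against the coupled HH+Donnan solver
shared_ideal_sweep <- function(pH_values = c(4, 5, 6), n_cycles = 500L) {
  key <- paste0("ideal_", paste(pH_values, collapse = "_"))
  if (!is.null(.run_cache[[key]])) return(.run_cache[[key]])
  rows <- lapply(seq_along(pH_values), function(i) {
    ph <- pH_values[i]
    tpl <- nanoparticle_template(n_sites = 10, theta = 0, seed = 1)
    box <- box_from_salt(0.1, 50L)
    res <- solve_reservoir(ph, 0.1, activity = "ideal")
    st <- build_system(tpl, 10L, box, res, mode = "no_interactions", seed = 4)
    ser <- run_simulation(st, mc_schedule(n_cycles,
                                          config_moves_per_cycle = 100L,
                                          reaction_moves_per_cycle = 250L,
                                          seed = 20 + i))
    s <- summarise_series(ser)
    th <- coupled_hh_donnan(ph, 4, count_to_molar(100, box$volume), 0.1)
    list(pH = ph, sim = s, theory = th)
  })
  .run_cache[[key]] <- rows
  rows
}
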