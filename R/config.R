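# Run configuration: a strict TOML-dialect reader/writer and validation.
# Supported syntax: [section] headers, key = value pairs, "#" comments,
# values being numbers, booleans, double-quoted strings, or flat arrays of
# those. Unknown keys and malformed values are rejected by name - physics
# inputs never pass through silently.

.parse_toml_value <- function(txt, where) {
  txt <- trimws(txt)
  if (txt == "") stop(sprintf("empty value at %s", where), call. = FALSE)
  if (startsWith(txt, "[")) {
    if (!endsWith(txt, "]"))
      stop(sprintf("unterminated array at %s", where), call. = FALSE)
    inner <- trimws(substr(txt, 2, nchar(txt) - 1))
    if (inner == "") return(list())
    parts <- strsplit(inner, ",")[[1]]
    return(unlist(lapply(parts, .parse_toml_value, where = where)))
  }
  if (startsWith(txt, "\"")) {
    if (nchar(txt) < 2 || !endsWith(txt, "\""))
      stop(sprintf("unterminated string at %s", where), call. = FALSE)
    return(substr(txt, 2, nchar(txt) - 1))
  }
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (is.na(num))
    stop(sprintf("cannot parse value '%s' at %s", txt, where), call. = FALSE)
  num
}

.parse_toml <- function(lines) {
  out <- list()
  section <- NULL
  for (i in seq_along(lines)) {
    ln <- lines[i]
    # strip comments outside strings
    if (grepl("#", ln)) {
      inq <- FALSE; cut <- nchar(ln) + 1L
      for (p in seq_len(nchar(ln))) {
        ch <- substr(ln, p, p)
        if (ch == "\"") inq <- !inq
        if (ch == "#" && !inq) { cut <- p; break }
      }
      ln <- substr(ln, 1, cut - 1L)
    }
    ln <- trimws(ln)
    if (ln == "") next
    if (startsWith(ln, "[")) {
      if (!endsWith(ln, "]"))
        stop(sprintf("malformed section header on line %d", i), call. = FALSE)
      section <- trimws(substr(ln, 2, nchar(ln) - 1))
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", ln, fixed = TRUE)
    if (eq < 0) stop(sprintf("expected 'key = value' on line %d", i),
                     call. = FALSE)
    key <- trimws(substr(ln, 1, eq - 1))
    val <- .parse_toml_value(substr(ln, eq + 1, nchar(ln)),
                             sprintf("line %d", i))
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}

# schema: per block, per key: default (NULL = required? none here) + checker
.config_schema <- function() {
  list(
    reservoir = list(pH = 7.0, c_salt_molar = 0.1, activity = "davies"),
    particle = list(d_np_nm = 1.42, n_sites = 10, pKa = 4.0, theta = 0,
                    site_radius_nm = NA_real_, charge_mode = "titrating",
                    alpha_fixed = NA_real_, placement_seed = 1),
    system = list(phi_np = NA_real_, n_np = NA_real_, n_salt_pairs = 250,
                  mode = "full"),
    schedule = list(n_cycles = 5000, config_moves_per_cycle = 1000,
                    reaction_moves_per_cycle = 250,
                    displacement_step = 0.355, rotation_step = pi / 2,
                    seed = 1, equilibration_fraction = 0.30,
                    observe_every = 1),
    output = list(observables_csv = NA_character_,
                  metadata_json = NA_character_,
                  snapshot_xyz = NA_character_, snapshot_every = 0)
  )
}

#' Parse and validate a run configuration
#'
#' Reads a TOML-dialect file with blocks `[reservoir]`, `[particle]`,
#' `[system]`, `[schedule]`, `[output]`. Missing keys take the documented
#' model defaults (d_np 1.42 nm, 10 sites, pKa 4.0, 250 salt pairs, 30%
#' equilibration discard); unknown blocks or keys raise a named validation
#' error.
#'
#' @param path config file path.
#' @return Object of class `run_config` (nested named list).
#' @export
parse_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path),
                               call. = FALSE)
  raw <- .parse_toml(readLines(path, warn = FALSE))
  schema <- .config_schema()
  top_unknown <- setdiff(names(raw), names(schema))
  if (length(top_unknown) > 0)
    stop(sprintf("unknown config block(s): %s",
                 paste(top_unknown, collapse = ", ")), call. = FALSE)
  cfg <- schema
  for (blk in names(raw)) {
    unknown <- setdiff(names(raw[[blk]]), names(schema[[blk]]))
    if (length(unknown) > 0)
      stop(sprintf("unknown key(s) in [%s]: %s", blk,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    for (k in names(raw[[blk]])) cfg[[blk]][[k]] <- raw[[blk]][[k]]
  }
  validate_config(structure(cfg, class = "run_config"))
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`.
#' @return The config, invisibly restructured; errors name the offending key.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  p <- cfg$particle
  if (p$theta < 0 || p$theta >= 1)
    stop("validation error: particle.theta must lie in [0, 1)", call. = FALSE)
  if (!p$charge_mode %in% c("titrating", "fixed_fraction", "neutral"))
    stop("validation error: particle.charge_mode invalid", call. = FALSE)
  if (p$charge_mode == "fixed_fraction" &&
      (is.na(p$alpha_fixed) || p$alpha_fixed < 0 || p$alpha_fixed > 1))
    stop("validation error: particle.alpha_fixed must be set in [0,1] for fixed_fraction",
         call. = FALSE)
  r <- cfg$reservoir
  if (r$pH <= 0 || r$pH >= 14)
    stop("validation error: reservoir.pH must lie in (0, 14)", call. = FALSE)
  if (r$c_salt_molar < 0)
    stop("validation error: reservoir.c_salt_molar must be >= 0", call. = FALSE)
  if (!r$activity %in% c("davies", "ideal"))
    stop("validation error: reservoir.activity invalid", call. = FALSE)
  s <- cfg$system
  if (!s$mode %in% c("full", "no_electrostatics", "no_interactions",
                     "fixed_fraction"))
    stop("validation error: system.mode invalid", call. = FALSE)
  if (is.na(s$phi_np) && is.na(s$n_np))
    stop("validation error: set system.phi_np or system.n_np", call. = FALSE)
  sc <- cfg$schedule
  if (sc$equilibration_fraction < 0 || sc$equilibration_fraction >= 1)
    stop("validation error: schedule.equilibration_fraction must lie in [0, 1)",
         call. = FALSE)
  invisible(cfg)
  cfg
}

.format_toml_value <- function(v) {
  fmt1 <- function(x) {
    if (is.character(x)) sprintf("\"%s\"", x)
    else if (is.logical(x)) ifelse(x, "true", "false")
    else format(x, digits = 17, scientific = FALSE, trim = TRUE)
  }
  if (length(v) == 1L) fmt1(v)
  else sprintf("[%s]", paste(vapply(v, fmt1, ""), collapse = ", "))
}

#' Serialize a run configuration
#'
#' Writes the config back in the same TOML dialect; parse -> write -> parse
#' is idempotent.
#'
#' @param cfg a `run_config`.
#' @param path output path.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  lines <- character(0)
  for (blk in names(cfg)) {
    lines <- c(lines, sprintf("[%s]", blk))
    for (k in names(cfg[[blk]])) {
      v <- cfg[[blk]][[k]]
      if (length(v) == 1L && is.na(v) && !is.character(v)) next
      if (length(v) == 1L && is.character(v) && is.na(v)) next
      lines <- c(lines, sprintf("%s = %s", k, .format_toml_value(v)))
    }
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Stable hash of a run configuration
#'
#' MD5 of the serialized config; embedded in all output artifacts for
#' provenance.
#'
#' @param cfg a `run_config`.
#' @return Hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".toml")
  on.exit(unlink(tf))
  write_config(cfg, tf)
  unname(tools::md5sum(tf))
}

#' Run one experiment from a configuration
#'
#' Assembles the reservoir, template, box and system from a `run_config`,
#' runs the schedule, and returns the summary. When `[output]` paths are
#' set, writes the observable CSV (cycle, alpha, N_Na, N_Cl, N_H, N_OH,
#' U_total) and a metadata JSON (resolved reservoir composition, seeds,
#' config hash).
#'
#' @param cfg a `run_config` (or path to one).
#' @param mode optional override of `system.mode`.
#' @param seed optional override of `schedule.seed`.
#' @return List with `summary` (from [summarise_series()]), `series`,
#'   `state`, and `metadata`.
#' @export
run_experiment <- function(cfg, mode = NULL, seed = NULL) {
  if (is.character(cfg)) cfg <- parse_config(cfg)
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(mode)) cfg$system$mode <- mode
  if (!is.null(seed)) cfg$schedule$seed <- as.integer(seed)
  validate_config(cfg)
  p <- cfg$particle; s <- cfg$system; r <- cfg$reservoir; sc <- cfg$schedule
  mode <- s$mode
  activity <- if (mode == "no_interactions") "ideal" else r$activity
  res <- solve_reservoir(r$pH, r$c_salt_molar, activity = activity)
  tpl <- nanoparticle_template(core_diameter = p$d_np_nm,
                               n_sites = as.integer(p$n_sites),
                               theta = p$theta, pKa = p$pKa,
                               charge_mode = if (mode == "fixed_fraction")
                                 "fixed_fraction" else p$charge_mode,
                               alpha_fixed = if (!is.na(p$alpha_fixed))
                                 p$alpha_fixed else NULL,
                               seed = as.integer(p$placement_seed))
  box <- box_from_salt(max(r$c_salt_molar, 1e-6),
                       as.integer(s$n_salt_pairs))
  n_np <- if (!is.na(s$n_np)) as.integer(s$n_np) else
    np_count_for_phi(s$phi_np, p$d_np_nm, box)
  site_radius <- if (is.na(p$site_radius_nm)) p$d_np_nm / 2 else
    p$site_radius_nm
  model <- energy_model(d_np = p$d_np_nm)
  state <- build_system(tpl, n_np, box, res, model = model, mode = mode,
                        site_radius = site_radius, seed = sc$seed)
  sched <- mc_schedule(n_cycles = as.integer(sc$n_cycles),
                       config_moves_per_cycle = as.integer(sc$config_moves_per_cycle),
                       reaction_moves_per_cycle = as.integer(sc$reaction_moves_per_cycle),
                       displacement_step = sc$displacement_step,
                       rotation_step = sc$rotation_step,
                       seed = as.integer(sc$seed),
                       equilibration_fraction = sc$equilibration_fraction,
                       observe_every = as.integer(sc$observe_every))
  series <- run_simulation(state, sched)
  summ <- summarise_series(series)
  meta <- list(config_hash = config_hash(cfg), seed = sc$seed, mode = mode,
               n_np = n_np, box_edge_nm = box$edge_length,
               phi_np = volume_fraction(n_np, p$d_np_nm, box),
               reservoir = list(pH = res$pH, c_salt = res$c_salt,
                                gamma_pm = res$gamma_pm,
                                conc = as.list(res$conc),
                                constants = as.list(res$constants)),
               acceptance = as.list(attr(series, "acceptance")),
               steps = as.list(attr(series, "steps")))
  o <- cfg$output
  if (!is.na(o$observables_csv)) {
    df <- as.data.frame(series)
    df$alpha <- if (state$titrating) df$n_A / pmax(1, df$n_A + df$n_HA) else
      -state$site_charge
    utils::write.csv(df[, c("cycle", "alpha", "N_Na", "N_Cl", "N_H", "N_OH",
                            "U")],
                     o$observables_csv, row.names = FALSE)
  }
  if (!is.na(o$metadata_json)) {
    jsonlite::write_json(c(meta, list(summary = list(
      alpha_mean = summ$alpha$mean, alpha_SE = summ$alpha$se,
      D_Na = summ$D_Na$value, D_Na_SE = summ$D_Na$se,
      D_H = summ$D_H$value, D_Cl = summ$D_Cl$value,
      delta_pH = summ$delta_pH$value, delta_pH_SE = summ$delta_pH$se))),
      o$metadata_json, auto_unbox = TRUE, digits = NA)
  }
  if (!is.na(o$snapshot_xyz)) write_snapshot(state, o$snapshot_xyz)
  list(summary = summ, series = series, state = state, metadata = meta)
}

#' Sweep one axis of a configuration
#'
#' Runs one experiment per value of the sweep axis with per-point derived
#' seeds (`base seed + index`). Failed points are recorded with an error
#' status and the sweep continues.
#'
#' @param cfg a `run_config` (or path).
#' @param axis one of `"pH"`, `"theta"`, `"phi_np"`, `"c_salt"`.
#' @param values numeric vector of axis values.
#' @param csv optional path for the tidy results CSV.
#' @return data.frame, one row per state point: axis value, `alpha`,
#'   `alpha_se`, `D_Na`, `D_Na_se`, `delta_pH`, `delta_pH_se`, seed,
#'   n_cycles, mode, config hash, package version, status.
#' @export
run_sweep <- function(cfg, axis = c("pH", "theta", "phi_np", "c_salt"),
                      values, csv = NULL) {
  axis <- match.arg(axis)
  if (is.character(cfg)) cfg <- parse_config(cfg)
  base_seed <- cfg$schedule$seed
  hash <- config_hash(cfg)
  ver <- as.character(utils::packageVersion("patchtitrate"))
  rows <- lapply(seq_along(values), function(i) {
    ci <- cfg
    v <- values[i]
    switch(axis,
           pH = { ci$reservoir$pH <- v },
           theta = { ci$particle$theta <- v },
           phi_np = { ci$system$phi_np <- v; ci$system$n_np <- NA_real_ },
           c_salt = { ci$reservoir$c_salt_molar <- v })
    ci$schedule$seed <- base_seed + i
    out <- tryCatch({
      r <- run_experiment(ci)
      s <- r$summary
      data.frame(axis = axis, value = v, alpha = s$alpha$mean,
                 alpha_se = s$alpha$se, D_Na = s$D_Na$value,
                 D_Na_se = s$D_Na$se, delta_pH = s$delta_pH$value,
                 delta_pH_se = s$delta_pH$se, seed = ci$schedule$seed,
                 n_cycles = ci$schedule$n_cycles, mode = ci$system$mode,
                 config_hash = hash, version = ver, status = "ok")
    }, error = function(e) {
      data.frame(axis = axis, value = v, alpha = NA_real_, alpha_se = NA_real_,
                 D_Na = NA_real_, D_Na_se = NA_real_, delta_pH = NA_real_,
                 delta_pH_se = NA_real_, seed = ci$schedule$seed,
                 n_cycles = ci$schedule$n_cycles, mode = ci$system$mode,
                 config_hash = hash, version = ver,
                 status = paste("error:", conditionMessage(e)))
    })
    out
  })
  df <- do.call(rbind, rows)
  if (!is.null(csv)) utils::write.csv(df, csv, row.names = FALSE)
  df
}
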