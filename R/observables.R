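# Observables: ionization degree, distribution ratios, delta-pH, and
# blocking-based error bars for correlated Monte Carlo series.

#' Degree of ionization
#'
#' `alpha = n_A / (n_A + n_HA)` (vectorized).
#'
#' @param n_A number of deprotonated (A-) sites.
#' @param n_HA number of protonated (HA) sites.
#' @return Ionization degree in `[0, 1]`.
#' @export
ionization_degree <- function(n_A, n_HA) {
  if (any(n_A < 0) || any(n_HA < 0) || any(n_A + n_HA < 1))
    stop("undefined alpha: need at least one site", call. = FALSE)
  n_A / (n_A + n_HA)
}

#' Distribution ratio of an ion
#'
#' `D = c_ret / c_perm`, with the retentate concentration taken per box
#' volume (the operational definition uses concentrations, not activities).
#'
#' @param c_ret retentate concentration, mol/L.
#' @param c_perm permeate concentration, mol/L (> 0).
#' @return Dimensionless ratio.
#' @export
distribution_ratio <- function(c_ret, c_perm) {
  if (any(c_perm <= 0))
    stop("undefined ratio: permeate concentration must be > 0", call. = FALSE)
  c_ret / c_perm
}

#' Mean particle count to a molar concentration
#'
#' `c = N / (V N_A)` for a box volume in nm^3.
#'
#' @param n mean particle number.
#' @param volume_nm3 box volume, nm^3.
#' @return Concentration, mol/L.
#' @export
count_to_molar <- function(n, volume_nm3) {
  n / (volume_nm3 * .NA_C0_NM3)
}

#' pH difference from a cation distribution ratio
#'
#' `delta_pH = pH_ret - pH_perm = -log10(D_cation)`; negative when the
#' retentate holds anionic particles.
#'
#' @param D_cation distribution ratio of any monovalent cation (> 0).
#' @return Signed pH difference.
#' @export
delta_pH <- function(D_cation) {
  if (any(D_cation <= 0)) stop("delta_pH requires D > 0", call. = FALSE)
  -log10(D_cation)
}

#' Blocking (block-averaging) error estimate
#'
#' Discards the leading `equilibration_fraction` of the series, then doubles
#' the block size until the blocked standard error of the mean plateaus
#' (relative change below `plateau_tol` across two consecutive doublings).
#' The ratio of the plateau variance to the naive variance estimates the
#' statistical inefficiency `g = 1 + 2 tau`, from which the autocorrelation
#' time is reported in units of the sampling interval.
#'
#' @param x numeric series of correlated samples.
#' @param equilibration_fraction fraction discarded from the front
#'   (default 0.30).
#' @param min_blocks smallest number of blocks at which a blocked SE is
#'   still trusted.
#' @param plateau_tol relative-change threshold defining the plateau.
#' @return List with `mean`, `se`, `tau_est`, `n_used`, and the per-level
#'   table `blocks` (block size, number of blocks, SE).
#' @export
blocking_error <- function(x, equilibration_fraction = 0.30,
                           min_blocks = 16L, plateau_tol = 0.05) {
  x <- as.numeric(x)
  n0 <- length(x)
  drop <- floor(equilibration_fraction * n0)
  x <- x[(drop + 1):n0]
  n <- length(x)
  if (n < 64)
    stop("insufficient data: need at least 64 post-equilibration samples",
         call. = FALSE)
  m <- mean(x)
  var0 <- stats::var(x)
  if (var0 == 0)
    return(list(mean = m, se = 0, tau_est = 0, n_used = n,
                blocks = data.frame(block = 1L, n_blocks = n, se = 0)))
  levels <- list()
  b <- 1L
  y <- x
  se_prev <- NA_real_
  se_prev2 <- NA_real_
  se_plateau <- NA_real_
  repeat {
    nb <- length(y)
    if (nb < min_blocks) break
    se <- stats::sd(y) / sqrt(nb)
    levels[[length(levels) + 1L]] <- data.frame(block = b, n_blocks = nb, se = se)
    if (!is.na(se_prev2) && se > 0 &&
        abs(se - se_prev) < plateau_tol * se &&
        abs(se_prev - se_prev2) < plateau_tol * se && is.na(se_plateau)) {
      se_plateau <- se
    }
    se_prev2 <- se_prev
    se_prev <- se
    # halve: average consecutive pairs
    nh <- nb %/% 2L
    y <- (y[seq(1, 2 * nh, by = 2)] + y[seq(2, 2 * nh, by = 2)]) / 2
    b <- 2L * b
  }
  blocks <- do.call(rbind, levels)
  if (is.na(se_plateau)) se_plateau <- max(blocks$se)  # no plateau: be conservative
  g <- (se_plateau^2 * n) / var0                        # statistical inefficiency
  tau <- max(0, (g - 1) / 2)
  list(mean = m, se = se_plateau, tau_est = tau, n_used = n, blocks = blocks)
}

#' Summarise a simulation series
#'
#' Turns the raw per-cycle samples of [run_simulation()] into the standard
#' observables with blocking errors: the mean ionization degree, the ion
#' distribution ratios against the run's reservoir, and the signed (and
#' absolute) delta-pH from the sodium ratio.
#'
#' @param series a `pt_series` from [run_simulation()].
#' @param equilibration_fraction discard fraction (defaults to the value
#'   stored in the series).
#' @return List of per-observable summaries plus derived quantities
#'   `D_Na`, `D_H`, `D_Cl`, `delta_pH` (each with `value` and `se`).
#' @export
summarise_series <- function(series,
                             equilibration_fraction = attr(series, "equilibration_fraction")) {
  stopifnot(inherits(series, "pt_series"))
  res <- attr(series, "reservoir")
  vol <- attr(series, "volume_nm3")
  df <- as.data.frame(series)
  af <- attr(series, "alpha_fixed")
  alpha_series <- if (is.null(af)) df$n_A / (df$n_A + df$n_HA)
                  else rep(af, nrow(df))
  out <- list()
  out$alpha <- blocking_error(alpha_series, equilibration_fraction)
  for (spc in c("Na", "Cl", "H", "OH")) {
    out[[paste0("N_", spc)]] <- blocking_error(df[[paste0("N_", spc)]],
                                               equilibration_fraction)
  }
  out$U <- blocking_error(df$U, equilibration_fraction)
  ratio <- function(bk, spc) {
    cp <- res$conc[[spc]]
    list(value = distribution_ratio(count_to_molar(bk$mean, vol), cp),
         se = count_to_molar(bk$se, vol) / cp)
  }
  out$D_Na <- ratio(out$N_Na, "Na")
  out$D_Cl <- ratio(out$N_Cl, "Cl")
  out$D_H <- ratio(out$N_H, "H")
  dp <- delta_pH(out$D_Na$value)
  dp_se <- out$D_Na$se / (out$D_Na$value * log(10))
  out$delta_pH <- list(value = dp, se = dp_se)
  out$delta_pH_abs <- list(value = abs(dp), se = dp_se)
  out
}
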