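# Closed-form reference theory: ideal Donnan partitioning, the
# Henderson-Hasselbalch equation, and their self-consistent coupling.
#
# Monovalent electroneutrality in the retentate with a nonexchangeable
# anion concentration c_A and permeate ionic strength I gives
# D * I = I / D + c_A, whose positive root is
# D+ = (c_A + sqrt(c_A^2 + 4 I^2)) / (2 I); anions follow D- = 1/D+ and the
# pH offset is delta_pH = -log10(D+). Coupling to titration closes the
# feedback loop alpha = HH(pH_perm + delta_pH(alpha)).

#' Ionic strength of an electrolyte mixture
#'
#' `I = 1/2 sum c_i z_i^2`.
#'
#' @param conc named numeric vector of concentrations, mol/L.
#' @param z valencies, recycled against `conc` (default all 1).
#' @return Ionic strength, mol/L.
#' @export
ionic_strength <- function(conc, z = rep(1, length(conc))) {
  if (any(conc < 0)) stop("concentrations must be >= 0", call. = FALSE)
  0.5 * sum(conc * z^2)
}

.donnan_result <- function(D_plus, alpha = NA_real_, pH_perm = NA_real_,
                           temperature = 298) {
  delta_pH <- -log10(D_plus)
  structure(list(D_plus = D_plus, D_minus = 1 / D_plus, delta_pH = delta_pH,
                 psi_don = donnan_potential(D_plus, temperature),
                 alpha = alpha, pH_ret = pH_perm + delta_pH,
                 pH_perm = pH_perm),
            class = "donnan_result")
}

#' @export
print.donnan_result <- function(x, ...) {
  cat(sprintf("<donnan_result> D+ = %.4g, D- = %.4g, delta_pH = %.4f\n",
              x$D_plus, x$D_minus, x$delta_pH))
  cat(sprintf("  psi_Don = %.4g mV, alpha = %.4g, pH_ret = %.4g\n",
              1e3 * x$psi_don, x$alpha, x$pH_ret))
  invisible(x)
}

#' Ideal Donnan partitioning
#'
#' Distribution ratios of monovalent ions for a fixed nonexchangeable anion
#' concentration. In the limit `c_A -> 0`, `D+ -> 1`; for `c_A >> I`,
#' `D+ -> c_A / I`.
#'
#' @param c_A nonexchangeable anion concentration in the retentate, mol/L.
#' @param I permeate ionic strength, mol/L (> 0).
#' @param temperature temperature in K (for the Donnan potential).
#' @return Object of class `donnan_result` (fields `D_plus`, `D_minus`,
#'   `delta_pH`, `psi_don`).
#' @export
donnan_ideal <- function(c_A, I, temperature = 298) {
  .check_number(c_A, "c_A", lower = 0)
  if (!is.numeric(I) || length(I) != 1L || !is.finite(I) || I <= 0)
    stop("invalid input: ionic strength must be > 0", call. = FALSE)
  D <- (c_A + sqrt(c_A^2 + 4 * I^2)) / (2 * I)
  .donnan_result(D, temperature = temperature)
}

#' Henderson-Hasselbalch ionization degree
#'
#' `alpha = 1 / (1 + 10^(pKa - pH))`, the exact relation between the degree
#' of ionization and the pH felt by the sites.
#'
#' @param pH local (retentate) pH.
#' @param pKa acidity constant.
#' @return Ionization degree in `[0, 1]` (vectorized over `pH`).
#' @export
hh_alpha <- function(pH, pKa) {
  1 / (1 + 10^(pKa - pH))
}

#' Donnan potential from the cation distribution ratio
#'
#' `psi = -(k_B T / e) ln D+`, so that `D_{+/-} = exp(-/+ e psi / k_B T)`.
#'
#' @param D_plus cation distribution ratio (> 0).
#' @param temperature temperature, K.
#' @return Potential in volts (negative when the retentate holds anionic
#'   particles).
#' @export
donnan_potential <- function(D_plus, temperature = 298) {
  if (any(D_plus <= 0)) stop("D_plus must be > 0", call. = FALSE)
  -(pt_constants$k_B * temperature / pt_constants$e) * log(D_plus)
}

#' Coupled Henderson-Hasselbalch + Donnan solver
#'
#' Self-consistent solution of `alpha = hh_alpha(pH_perm + delta_pH(alpha))`
#' with `c_A = alpha * c_acid_total` and the permeate ionic strength taken
#' from the (ideal) reservoir composition, including the H+/OH-
#' contributions by default — these produce the high-pH suppression of the
#' Donnan effect when `c_OH` becomes comparable to the salt. Damped
#' fixed-point iteration (factor 0.5) to 1e-12 in alpha.
#'
#' @param pH_perm permeate pH.
#' @param pKa site acidity constant.
#' @param c_acid_total total concentration of ionizable sites in the
#'   retentate, mol/L.
#' @param c_salt permeate salt concentration, mol/L.
#' @param include_water_ions include H+/OH- in the permeate ionic strength
#'   (default `TRUE`).
#' @param temperature temperature, K.
#' @param tol,max_iter convergence control.
#' @return Object of class `donnan_result` including the converged `alpha`
#'   and `pH_ret`.
#' @export
coupled_hh_donnan <- function(pH_perm, pKa, c_acid_total, c_salt,
                              include_water_ions = TRUE, temperature = 298,
                              tol = 1e-12, max_iter = 10000L) {
  .check_number(pH_perm, "pH_perm", lower = 0, upper = 14)
  .check_number(c_acid_total, "c_acid_total", lower = 0)
  .check_number(c_salt, "c_salt", lower = 0)
  res <- solve_reservoir(pH_perm, c_salt, activity = "ideal")
  I <- if (include_water_ions) res$ionic_strength else c_salt
  if (I <= 0) stop("invalid input: permeate ionic strength must be > 0",
                   call. = FALSE)
  alpha <- hh_alpha(pH_perm, pKa)
  damp <- 0.5
  for (it in seq_len(max_iter)) {
    D <- donnan_ideal(alpha * c_acid_total, I)$D_plus
    a_new <- hh_alpha(pH_perm - log10(D), pKa)
    a_next <- (1 - damp) * alpha + damp * a_new
    if (abs(a_next - alpha) < tol) { alpha <- a_next; break }
    alpha <- a_next
    if (it == max_iter)
      stop(sprintf("coupled HH+Donnan solver did not converge (pH=%g, c_A=%g, c_salt=%g, last alpha=%g)",
                   pH_perm, c_acid_total, c_salt, alpha), call. = FALSE)
  }
  D <- donnan_ideal(alpha * c_acid_total, I)$D_plus
  .donnan_result(D, alpha = alpha, pH_perm = pH_perm,
                 temperature = temperature)
}

#' Theory sweep over permeate pH
#'
#' Evaluates [coupled_hh_donnan()] on a pH grid; the closed-form reference
#' curves for titration experiments.
#'
#' @param pH_values numeric vector of permeate pH values.
#' @param pKa acidity constant.
#' @param c_acid_total site concentration, mol/L.
#' @param c_salt salt concentration, mol/L.
#' @param ... passed to [coupled_hh_donnan()].
#' @return data.frame with columns `pH_perm`, `alpha`, `D_plus`, `delta_pH`,
#'   `pH_ret`, `alpha_hh` (the uncoupled HH value).
#' @export
theory_sweep <- function(pH_values, pKa = 4.0, c_acid_total, c_salt, ...) {
  rows <- lapply(pH_values, function(ph) {
    r <- coupled_hh_donnan(ph, pKa, c_acid_total, c_salt, ...)
    data.frame(pH_perm = ph, alpha = r$alpha, D_plus = r$D_plus,
               delta_pH = r$delta_pH, pH_ret = r$pH_ret,
               alpha_hh = hh_alpha(ph, pKa))
  })
  do.call(rbind, rows)
}
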