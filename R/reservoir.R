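# Reservoir (permeate) composition at prescribed pH and salt concentration.
#
# The permeate is an aqueous NaCl solution whose pH is adjusted with excess
# strong acid (HCl, pH <= 7) or strong base (NaOH, pH > 7). Given the target
# pH (activity convention) and c_salt, the four ion concentrations follow
# from the water activity product and electroneutrality; the mean activity
# coefficient comes from the empirical Davies equation and is iterated to
# self-consistency. The equilibrium constants of the virtual electroneutral
# ion-pair exchange reactions (the grand-canonical coupling) are then
# K_ij = gamma_pm^2 c_i c_j / c0^2, with the water pair fixed to
# K_w = 1e-14.

#' Davies activity coefficient
#'
#' `log10(gamma) = -A z^2 (sqrt(I)/(1 + sqrt(I)) - 0.3 I)` with A = 0.509 at
#' 298 K.
#'
#' @param I ionic strength, mol/L (>= 0).
#' @param z ion valency.
#' @param A Debye-Hueckel coefficient.
#' @return `log10(gamma)` (dimensionless).
#' @export
davies_log10_gamma <- function(I, z = 1, A = 0.509) {
  if (any(!is.finite(I)) || any(I < 0))
    stop("invalid ionic strength: I must be >= 0", call. = FALSE)
  -A * z^2 * (sqrt(I) / (1 + sqrt(I)) - 0.3 * I)
}

#' Solve the reservoir composition
#'
#' Fixed-point solve of the permeate composition at a given pH and salt
#' concentration. With the activity-based pH convention,
#' `pH = -log10(gamma_pm c_H / c0)`, the proton concentration is
#' `c_H = 10^-pH / gamma_pm`, the hydroxide concentration follows from the
#' water activity product `(gamma c_H)(gamma c_OH) = 1e-14`, and the Na/Cl
#' concentrations from electroneutrality with the excess-strong-electrolyte
#' convention (HCl below pH 7, NaOH above). The ionic strength and
#' `gamma_pm` are iterated to 1e-12 relative convergence.
#'
#' @param pH target reservoir pH, in (0, 14).
#' @param c_salt NaCl concentration, mol/L (>= 0).
#' @param activity `"davies"` (default) or `"ideal"` (gamma = 1; used by the
#'   non-interacting reference ensemble).
#' @return Object of class `reservoir_spec` with fields `pH`, `c_salt`,
#'   `conc` (H, OH, Na, Cl in mol/L), `ionic_strength`, `gamma_pm`, and
#'   `constants` (K_NaCl, K_HCl, K_NaOH, K_H2O).
#' @export
solve_reservoir <- function(pH, c_salt, activity = c("davies", "ideal")) {
  activity <- match.arg(activity)
  .check_number(pH, "pH", lower = 0, upper = 14, strict_lower = TRUE,
                strict_upper = TRUE)
  .check_number(c_salt, "c_salt", lower = 0)
  Kw <- 1e-14
  gamma <- 1.0
  for (it in 1:200) {
    c_H <- 10^(-pH) / gamma
    c_OH <- Kw / (gamma^2 * c_H)
    if (pH <= 7) {
      c_Na <- c_salt
      c_Cl <- c_salt + c_H - c_OH
    } else {
      c_Cl <- c_salt
      c_Na <- c_salt + c_OH - c_H
    }
    # clamp roundoff-scale negatives (e.g. pure water at pH exactly 7)
    tol <- 1e-9 * (c_salt + c_H + c_OH)
    if (c_Cl < 0 && c_Cl > -tol) c_Cl <- 0
    if (c_Na < 0 && c_Na > -tol) c_Na <- 0
    if (c_Cl < 0 || c_Na < 0)
      stop("infeasible reservoir: requested pH implies a negative ion concentration",
           call. = FALSE)
    I <- 0.5 * (c_H + c_OH + c_Na + c_Cl)
    g_new <- if (activity == "davies") 10^davies_log10_gamma(I) else 1.0
    if (abs(g_new - gamma) <= 1e-12 * gamma) { gamma <- g_new; break }
    gamma <- g_new
  }
  c_H <- 10^(-pH) / gamma
  c_OH <- Kw / (gamma^2 * c_H)
  if (pH <= 7) { c_Na <- c_salt; c_Cl <- c_salt + c_H - c_OH }
  else         { c_Cl <- c_salt; c_Na <- c_salt + c_OH - c_H }
  tol <- 1e-9 * (c_salt + c_H + c_OH)
  if (c_Cl < 0 && c_Cl > -tol) c_Cl <- 0
  if (c_Na < 0 && c_Na > -tol) c_Na <- 0
  I <- 0.5 * (c_H + c_OH + c_Na + c_Cl)
  conc <- c(H = c_H, OH = c_OH, Na = c_Na, Cl = c_Cl)
  constants <- c(K_NaCl = gamma^2 * c_Na * c_Cl,
                 K_HCl  = gamma^2 * c_H * c_Cl,
                 K_NaOH = gamma^2 * c_Na * c_OH,
                 K_H2O  = Kw)
  structure(list(pH = pH, c_salt = c_salt, activity = activity, conc = conc,
                 ionic_strength = I, gamma_pm = gamma, constants = constants),
            class = "reservoir_spec")
}

#' @export
print.reservoir_spec <- function(x, ...) {
  cat(sprintf("<reservoir_spec> pH = %g, c_salt = %g mol/L (%s activity)\n",
              x$pH, x$c_salt, x$activity))
  cat(sprintf("  I = %.4g mol/L, gamma_pm = %.4f\n", x$ionic_strength,
              x$gamma_pm))
  cat(sprintf("  c_H = %.3e, c_OH = %.3e, c_Na = %.3e, c_Cl = %.3e mol/L\n",
              x$conc["H"], x$conc["OH"], x$conc["Na"], x$conc["Cl"]))
  invisible(x)
}

#' Validate reservoir invariants
#'
#' Electroneutrality, the water activity product, and the thermodynamic
#' cycle `K_NaOH * K_HCl = K_NaCl * K_H2O`.
#'
#' @param res a `reservoir_spec`.
#' @return The reservoir, invisibly; errors on violation.
#' @export
validate_reservoir <- function(res) {
  stopifnot(inherits(res, "reservoir_spec"))
  cc <- res$conc
  tot <- cc["Na"] + cc["H"] + cc["Cl"] + cc["OH"]
  if (abs((cc["Na"] + cc["H"]) - (cc["Cl"] + cc["OH"])) > 1e-12 * tot)
    stop("reservoir is not electroneutral", call. = FALSE)
  aw <- (res$gamma_pm * cc["H"]) * (res$gamma_pm * cc["OH"])
  if (abs(aw - 1e-14) > 1e-10 * 1e-14 + 1e-24)
    stop("water activity product violated", call. = FALSE)
  k <- res$constants
  if (abs(k["K_NaOH"] * k["K_HCl"] - k["K_NaCl"] * k["K_H2O"]) >
      1e-10 * abs(k["K_NaCl"] * k["K_H2O"]))
    stop("thermodynamic cycle of pair constants violated", call. = FALSE)
  invisible(res)
}

#' Composite acid-reaction constants
#'
#' Constants of the alternative implementations of the acid dissociation
#' used to improve sampling: `HA -> A- + Na+` with
#' `K = K_A K_NaCl / K_HCl`, and `HA + OH- -> A-` with `K = K_A / K_H2O`.
#' Both are exact products/ratios of previously derived constants, so every
#' variant samples the same equilibrium.
#'
#' @param res a `reservoir_spec`.
#' @param pKa site acidity constant.
#' @return Named numeric vector `K_acid_H`, `K_acid_Na`, `K_acid_OH`.
#' @export
composite_acid_constants <- function(res, pKa) {
  stopifnot(inherits(res, "reservoir_spec"))
  KA <- 10^(-pKa)
  k <- res$constants
  c(K_acid_H = KA,
    K_acid_Na = unname(KA * k["K_NaCl"] / k["K_HCl"]),
    K_acid_OH = unname(KA / k["K_H2O"]))
}
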